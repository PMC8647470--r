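test_that("transition matrix composes treatment effect and competing risks", {
  p <- asthma_parameters()
  m <- build_transition_matrix(p, "triple", age = 30, life_table = zero_life_table())
  expect_equal(m["CONTROLLED", "EXAC_OCS"], 0.12 * 0.85)
  expect_equal(m["EXAC_OCS", "EXAC_ED"], (1 - 0.0002) * 0.47)
  expect_equal(m["EXAC_OCS", "DEATH_ASTHMA"], 0.0002)
  # off-treatment loses the relative-risk benefit
  m_off <- build_transition_matrix(p, "triple", age = 30, on_treatment = FALSE,
                                   life_table = zero_life_table())
  expect_equal(m_off["CONTROLLED", "EXAC_OCS"], 0.12)
  # the dual arm is the rr = 1 reference
  m_dual <- build_transition_matrix(p, "dual", age = 30,
                                    life_table = zero_life_table())
  expect_equal(m_dual["CONTROLLED", "EXAC_OCS"], 0.12)
  # background mortality applied first, disease transitions scaled by (1 - q)
  lt <- const_life_table(0.026)
  q <- per_cycle_background_mortality(lt, 30, 26)
  m_bg <- build_transition_matrix(p, "dual", age = 30, life_table = lt)
  expect_equal(m_bg["CONTROLLED", "DEATH_OTHER"], q)
  expect_equal(m_bg["CONTROLLED", "EXAC_OCS"], (1 - q) * 0.12)
})

test_that("degenerate inputs freeze the cohort and rows always sum to 1", {
  p0 <- no_event_params()
  m <- build_transition_matrix(p0, "dual", age = 18, life_table = zero_life_table())
  # no exacerbations, no deaths: the controlled state and the absorbing
  # states are fixed points; the (unoccupied) tunnel states still drain back
  # to CONTROLLED by construction
  expect_equal(m["CONTROLLED", "CONTROLLED"], 1)
  expect_equal(m["DEATH_ASTHMA", "DEATH_ASTHMA"], 1)
  expect_equal(m["DEATH_OTHER", "DEATH_OTHER"], 1)
  for (s in c("EXAC_OCS", "EXAC_ED", "EXAC_HOSP")) {
    expect_equal(m[s, "CONTROLLED"], 1)
  }
  for (age in c(18, 45, 80)) {
    for (strat in c("triple", "dual")) {
      m <- build_transition_matrix(asthma_parameters(), strat, age = age)
      expect_equal(unname(rowSums(m)), rep(1, 6), tolerance = 1e-12)
      expect_true(all(m >= 0 & m <= 1))
    }
  }
  # death states are absorbing
  m <- build_transition_matrix(asthma_parameters(), "triple", age = 40)
  expect_equal(m["DEATH_ASTHMA", "DEATH_ASTHMA"], 1)
  expect_equal(m["DEATH_OTHER", "DEATH_OTHER"], 1)
})

test_that("an out-of-range composed probability names the offending row", {
  p_bad <- asthma_parameters(params = list(rr_exacerbation = list(base = 0.85)))
  p_bad$table$base[p_bad$table$name == "rr_exacerbation"] <- 9 # bypass validation
  err <- tryCatch(build_transition_matrix(p_bad, "triple", age = 18,
                                          life_table = zero_life_table()),
                  error = function(e) e)
  expect_s3_class(err, "asthmacea_model_error")
  expect_match(paste(conditionMessage(err), collapse = " "), "p_exac")
})

test_that("a disease-free year of perfect utility accrues exactly 1 QALY", {
  res <- run_cohort(no_event_params(), "dual", life_table = zero_life_table())
  expect_equal(res$discounted_qaly, 1.0, tolerance = 1e-12)
  expect_equal(res$undiscounted_qaly, 1.0, tolerance = 1e-12)
  expect_equal(res$person_years_undisc, 1.0, tolerance = 1e-12)
  # drug cost over the year: 26 cycles at $13.5 under trapezoidal weights
  expect_equal(res$undiscounted_cost, 13.5 * 26, tolerance = 1e-12)
})

test_that("discounting matches the start-of-cycle geometric series", {
  p <- no_event_params(settings = list(half_cycle_correction = FALSE))
  p$table$base[p$table$name == "annual_discount"] <- 0.05
  p$table$high[p$table$name == "annual_discount"] <- 0.05
  res <- run_cohort(p, "dual", life_table = zero_life_table())
  oracle <- sum((1 / 26) * 1.05^(-(0:25) / 26))
  expect_equal(res$discounted_qaly, oracle, tolerance = 1e-12)
})

test_that("cohort trace conserves mass with monotone absorbing death states", {
  for (strat in c("triple", "dual")) {
    res <- run_cohort(quick_params(), strat)
    occ <- as.matrix(res$trace[, markov_states()])
    expect_equal(unname(rowSums(occ)), rep(1, nrow(occ)), tolerance = 1e-10)
    expect_true(all(diff(occ[, "DEATH_ASTHMA"]) >= -1e-15))
    expect_true(all(diff(occ[, "DEATH_OTHER"]) >= -1e-15))
  }
  # as the age horizon grows the cohort is fully absorbed
  res <- run_cohort(asthma_parameters(settings = list(max_age = 200L)), "dual")
  final <- res$trace[nrow(res$trace), ]
  expect_gt(final$DEATH_ASTHMA + final$DEATH_OTHER, 0.9999)
})

test_that("discounted totals equal undiscounted totals when the rate is zero", {
  p <- quick_params(params = list(annual_discount = list(base = 0, low = 0)))
  for (strat in c("triple", "dual")) {
    res <- run_cohort(p, strat)
    expect_identical(res$discounted_cost, res$undiscounted_cost)
    expect_identical(res$discounted_qaly, res$undiscounted_qaly)
  }
})

test_that("QALYs are non-increasing in the relative risk and in decrements", {
  base <- run_cohort(quick_params(), "triple")
  worse_rr <- run_cohort(quick_params(params = list(rr_exacerbation = list(base = 0.95, high = 0.95))), "triple")
  expect_lte(worse_rr$discounted_qaly, base$discounted_qaly)
  worse_du <- run_cohort(quick_params(params = list(du_ocs = list(base = 0.13))), "triple")
  expect_lte(worse_du$discounted_qaly, base$discounted_qaly)
  no_du <- run_cohort(quick_params(params = list(
    du_ocs = list(base = 0.08), du_ed = list(base = 0.11),
    du_hosp = list(base = 0.15))), "triple")
  expect_gte(no_du$discounted_qaly, base$discounted_qaly)
})

test_that("treatment discontinuation at 52 weeks dilutes the triple-arm benefit", {
  full <- quick_params(params = list(persistence_triple = list(base = 1, high = 1)))
  none <- quick_params(params = list(persistence_triple = list(base = 0.63)))
  res_full <- run_cohort(full, "triple")
  res_part <- run_cohort(none, "triple")
  expect_gt(res_full$discounted_qaly, res_part$discounted_qaly)
  expect_gt(res_full$discounted_cost, res_part$discounted_cost)
  # the dual arm is unaffected by its persistence value (rr = 1, same cost)
  d1 <- run_cohort(quick_params(params = list(persistence_dual = list(base = 0.9, high = 0.9))), "dual")
  d2 <- run_cohort(quick_params(params = list(persistence_dual = list(base = 0.42))), "dual")
  expect_equal(d1$discounted_cost, d2$discounted_cost, tolerance = 1e-12)
  expect_equal(d1$discounted_qaly, d2$discounted_qaly, tolerance = 1e-12)
})

test_that("incremental comparison classifies dominance and computes the ICER", {
  s <- default_settings()
  inc <- incremental(fake_result(304, 1.55, "triple", settings = s),
                     fake_result(0, 0, "dual", settings = s))
  expect_equal(round(inc$icer, 1), 196.1)
  expect_equal(inc$classification, "tradeoff_NE")
  expect_true(inc$cost_effective)  # 196 < 19,000

  dom <- incremental(fake_result(-10, 0.5, "triple", settings = s),
                     fake_result(0, 0, "dual", settings = s))
  expect_equal(dom$classification, "dominant")
  expect_true(is.na(dom$icer))

  same <- incremental(fake_result(100, 2, "triple", settings = s),
                      fake_result(100, 2, "dual", settings = s))
  expect_equal(same$delta_cost, 0)
  expect_equal(same$delta_qaly, 0)
  expect_true(same$icer_undefined)
  expect_equal(same$classification, "equivalent")

  dtd <- incremental(fake_result(50, -1, "triple", settings = s),
                     fake_result(0, 0, "dual", settings = s))
  expect_equal(dtd$classification, "dominated")
  expect_true(is.na(icer(5, 0)))

  s2 <- default_settings(); s2$start_age <- 40L
  expect_error(incremental(fake_result(1, 1, settings = s),
                           fake_result(1, 1, settings = s2)),
               class = "asthmacea_validation_error")
})

test_that("scaling every cost by k scales dCost and ICER by k, QALYs unchanged", {
  k <- 3.5
  p1 <- quick_params()
  p2 <- quick_params()
  idx <- p2$table$role == "cost"
  p2$table$base[idx] <- p2$table$base[idx] * k
  p2$table$low[idx] <- p2$table$low[idx] * k
  p2$table$high[idx] <- p2$table$high[idx] * k
  inc1 <- base_case(p1)$incremental
  inc2 <- base_case(p2)$incremental
  expect_equal(inc2$delta_cost, k * inc1$delta_cost, tolerance = 1e-10)
  expect_equal(inc2$icer, k * inc1$icer, tolerance = 1e-10)
  expect_equal(inc2$delta_qaly, inc1$delta_qaly, tolerance = 1e-12)
})

test_that("triple therapy improves first-year exacerbation-free survival", {
  bc <- base_case(quick_params())
  expect_gt(bc$triple$exacerbation_free_1yr, bc$dual$exacerbation_free_1yr)
  # closed form at zero background mortality
  res <- run_cohort(asthma_parameters(), "dual", life_table = zero_life_table())
  expect_equal(res$exacerbation_free_1yr, (1 - 0.12)^26, tolerance = 1e-12)
})

test_that("utility decrement accrual bases are both supported", {
  p_ev <- quick_params()
  p_cy <- quick_params(settings = list(decrement_basis = "per_cycle"))
  r_ev <- run_cohort(p_ev, "dual")
  r_cy <- run_cohort(p_cy, "dual")
  # per-event annual decrements charge ~26x more QALY loss per exacerbation
  expect_gt(r_cy$discounted_qaly, r_ev$discounted_qaly)
  # identical occupancy: the accounting basis does not change the trace
  expect_equal(r_ev$trace$CONTROLLED, r_cy$trace$CONTROLLED, tolerance = 1e-14)
})
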