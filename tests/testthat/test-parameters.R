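test_that("packaged defaults reproduce the published base-case inputs", {
  p <- asthma_parameters()
  expect_s3_class(p, "asthma_params")
  expect_equal(param_base(p, "rr_exacerbation"), 0.85)
  expect_equal(param_base(p, "u_controlled"), 0.74)
  expect_equal(param_base(p, "p_controlled_to_ocs"), 0.12)
  expect_equal(param_base(p, "p_ocs_to_ed"), 0.47)
  expect_equal(param_base(p, "p_ed_to_hosp"), 0.15)
  expect_equal(param_base(p, "p_asthma_death"), 0.0002)
  expect_equal(param_base(p, "annual_discount"), 0.05)
  expect_equal(p$settings$wtp_per_qaly, 19000)
  expect_equal(p$settings$cycles_per_year * p$settings$cycle_length_weeks, 52)
})

test_that("every printed input row is represented exactly once", {
  printed <- tibble::tribble(
    ~name, ~base, ~low, ~high,
    "cost_tiotropium", 60, 45, 75,
    "cost_umeclidinium", 32, 24, 40,
    "cost_glycopyrronium", 32, 24, 40,
    "cost_ics_laba", 27, 20, 34,
    "cost_ed_visit", 26, 20, 33,
    "cost_hosp_day", 80, 60, 100,
    "u_controlled", 0.74, 0.56, 0.93,
    "du_ocs", 0.10, 0.08, 0.13,
    "du_ed", 0.15, 0.11, 0.19,
    "du_hosp", 0.20, 0.15, 0.25,
    "rr_exacerbation", 0.85, 0.78, 0.92,   # printed bounds, reordered low <= high
    "persistence_triple", 0.63, 0.47, 0.79,
    "persistence_dual", 0.56, 0.42, 0.70,
    "p_controlled_to_ocs", 0.12, 0.07, 0.12, # printed high equals base
    "p_ocs_to_ed", 0.47, 0.35, 0.59,
    "p_ed_to_hosp", 0.15, 0.11, 0.19,
    "p_asthma_death", 0.0002, 0.00014, 0.00024,
    "annual_discount", 0.05, 0.00, 0.06
  )
  tab <- asthma_parameters()$table
  for (i in seq_len(nrow(printed))) {
    row <- tab[tab$name == printed$name[i], ]
    expect_equal(nrow(row), 1, info = printed$name[i])
    expect_equal(row$base, printed$base[i], info = printed$name[i])
    expect_equal(row$low, printed$low[i], info = printed$name[i])
    expect_equal(row$high, printed$high[i], info = printed$name[i])
  }
  # the only non-printed row is the configurable OCS-burst event cost
  expect_setequal(setdiff(tab$name, printed$name), "cost_ocs_burst")
  expect_equal(param_base(asthma_parameters(), "cost_ocs_burst"), 0)
})

test_that("overrides apply and validation rejects out-of-bound inputs", {
  p0 <- asthma_parameters(params = list(annual_discount = list(base = 0, low = 0)))
  expect_equal(param_base(p0, "annual_discount"), 0)
  expect_error(asthma_parameters(params = list(u_controlled = list(base = 1.2, high = 1.2))),
               class = "asthmacea_validation_error")
  expect_error(asthma_parameters(params = list(cost_ed_visit = list(low = 50))),
               regexp = "low.*high|outside",
               class = "asthmacea_validation_error")
  err <- tryCatch(asthma_parameters(params = list(not_a_param = 1)),
                  error = function(e) e)
  expect_s3_class(err, "asthmacea_validation_error")
  expect_match(paste(conditionMessage(err), collapse = " "), "not_a_param")
  expect_error(asthma_parameters(settings = list(triple_drug_mix = c(0.5, 0.4, 0.2))),
               class = "asthmacea_validation_error")
  expect_error(asthma_parameters(settings = list(cycles_per_year = 10L)),
               class = "asthmacea_validation_error")
})

test_that("config files load, round-trip and reject schema violations", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("params:",
               "  annual_discount: {base: 0.0, low: 0.0}",
               "  cost_tiotropium: {base: 55}",
               "settings:",
               "  hosp_los_days: 3"), cfg)
  p <- load_parameters(cfg)
  expect_equal(param_base(p, "annual_discount"), 0)
  expect_equal(param_base(p, "cost_tiotropium"), 55)
  expect_equal(p$settings$hosp_los_days, 3)

  # defaults round-trip field-for-field through write/load
  out <- tempfile(fileext = ".yaml")
  orig <- asthma_parameters()
  write_parameters(orig, out)
  back <- load_parameters(out)
  expect_equal(back$table, orig$table)
  expect_equal(back$settings, orig$settings)

  bad <- tempfile(fileext = ".yaml")
  writeLines(c("params:", "  u_controlled: {base: 1.2, high: 1.3}"), bad)
  expect_error(load_parameters(bad), class = "asthmacea_validation_error")
  writeLines("unexpected_top_level: 1", bad)
  expect_error(load_parameters(bad), class = "asthmacea_validation_error")
  expect_error(load_parameters("/nonexistent/path.yaml"),
               class = "asthmacea_io_error")

  # CSV export carries one row per parameter
  csv <- tempfile(fileext = ".csv")
  export_parameters(orig, csv)
  exported <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(exported$name, orig$table$name)
  expect_equal(exported$base, orig$table$base)
})

test_that("range expansion applies the +/-25% rule with role clipping", {
  expect_equal(expand_range(list(base = 0.12, low = NA, high = NA,
                                 role = "probability"), "high"), 0.15)
  expect_equal(expand_range(list(base = 0.74, low = NA, high = NA,
                                 role = "utility"), "high"), 0.925)
  expect_equal(expand_range(list(base = 0.9, low = NA, high = NA,
                                 role = "utility"), "high"), 1)  # clipped
  expect_equal(expand_range(list(base = 0, low = NA, high = NA,
                                 role = "cost"), "low"), 0)
  expect_equal(expand_range(list(base = 0, low = NA, high = NA,
                                 role = "cost"), "high"), 0)
  # explicit printed bounds win over the rule
  rng <- param_range(asthma_parameters(), "p_controlled_to_ocs")
  expect_equal(expand_range(rng, "high"), 0.12)
  # the strict flag recomputes that row's high from the rule
  strict <- asthma_parameters(settings = list(strict_25pct = TRUE))
  expect_equal(param_range(strict, "p_controlled_to_ocs")$high, 0.15)
  # ordering property across all roles after clipping
  tab <- asthma_parameters()$table
  for (i in seq_len(nrow(tab))) {
    rng <- list(base = tab$base[i], low = NA, high = NA, role = tab$role[i])
    expect_lte(expand_range(rng, "low"), tab$base[i])
    expect_gte(expand_range(rng, "high"), tab$base[i])
  }
})

test_that("strategy drug costs convert 4-week prices to the model cycle", {
  p <- asthma_parameters()
  expect_equal(strategy_drug_cost_per_cycle(p, "dual"), 27 / 2)
  p_tio <- asthma_parameters(settings = list(
    triple_drug_mix = c(tiotropium = 1, umeclidinium = 0, glycopyrronium = 0)))
  expect_equal(strategy_drug_cost_per_cycle(p_tio, "triple"), (60 + 27) / 2)
  # with 4-week cycles the per-cycle cost equals the quoted price
  p4 <- asthma_parameters(settings = list(cycle_length_weeks = 4,
                                          cycles_per_year = 13L))
  expect_equal(strategy_drug_cost_per_cycle(p4, "dual"), 27)
  expect_equal(strategy_params(p, "dual")$rr_exacerbation, 1)
  expect_equal(strategy_params(p, "triple")$persistence_52wk, 0.63)
})
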