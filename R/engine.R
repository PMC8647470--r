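#' Health states of the cohort model
#'
#' Ordered states: controlled asthma, the three escalating exacerbation
#' levels (oral corticosteroid burst, emergency department visit,
#' hospitalization), asthma-related death and death from other causes. The
#' exacerbation states are single-cycle tunnel states: occupants either
#' escalate to the next severity level, die, or return to the controlled
#' state in the following cycle. Both death states are absorbing.
#'
#' @return Character vector of the six state names.
#' @export
markov_states <- function() {
  c("CONTROLLED", "EXAC_OCS", "EXAC_ED", "EXAC_HOSP", "DEATH_ASTHMA", "DEATH_OTHER")
}

# per-cycle transition matrix given raw per-cycle probabilities
# competing risks: background mortality is applied first; disease transitions
# are scaled by the surviving mass (1 - q) so rows sum to 1 for any inputs
build_matrix_impl <- function(p_exac, p_ocs_ed, p_ed_hosp, p_ad, q_bg,
                              asthma_death_states = "all_exacerbation") {
  probs <- c(p_exac = p_exac, p_ocs_ed = p_ocs_ed, p_ed_hosp = p_ed_hosp,
             p_ad = p_ad, q_bg = q_bg)
  bad <- names(probs)[probs < 0 | probs > 1 | !is.finite(probs)]
  if (length(bad) > 0) {
    abort(c("Composed transition probability outside [0, 1].",
            setNames(bad, rep("x", length(bad)))),
          class = "asthmacea_model_error")
  }
  s <- markov_states()
  m <- matrix(0, 6, 6, dimnames = list(s, s))
  a <- 1 - q_bg
  ad <- function(state) {
    if (asthma_death_states == "hospital_only" && state != "EXAC_HOSP") 0 else p_ad
  }

  m["CONTROLLED", "EXAC_OCS"] <- a * p_exac
  m["CONTROLLED", "CONTROLLED"] <- a * (1 - p_exac)
  m["CONTROLLED", "DEATH_OTHER"] <- q_bg

  d <- ad("EXAC_OCS")
  m["EXAC_OCS", "DEATH_ASTHMA"] <- a * d
  m["EXAC_OCS", "EXAC_ED"] <- a * (1 - d) * p_ocs_ed
  m["EXAC_OCS", "CONTROLLED"] <- a * (1 - d) * (1 - p_ocs_ed)
  m["EXAC_OCS", "DEATH_OTHER"] <- q_bg

  d <- ad("EXAC_ED")
  m["EXAC_ED", "DEATH_ASTHMA"] <- a * d
  m["EXAC_ED", "EXAC_HOSP"] <- a * (1 - d) * p_ed_hosp
  m["EXAC_ED", "CONTROLLED"] <- a * (1 - d) * (1 - p_ed_hosp)
  m["EXAC_ED", "DEATH_OTHER"] <- q_bg

  d <- ad("EXAC_HOSP")
  m["EXAC_HOSP", "DEATH_ASTHMA"] <- a * d
  m["EXAC_HOSP", "CONTROLLED"] <- a * (1 - d)
  m["EXAC_HOSP", "DEATH_OTHER"] <- q_bg

  m["DEATH_ASTHMA", "DEATH_ASTHMA"] <- 1
  m["DEATH_OTHER", "DEATH_OTHER"] <- 1
  m
}

#' Build the per-cycle transition matrix
#'
#' The controlled-to-exacerbation probability is multiplied by the
#' exacerbation relative risk when the strategy is triple therapy and the
#' patient is on treatment; escalation probabilities (burst to emergency
#' visit, emergency visit to hospitalization) and the per-cycle asthma
#' mortality from exacerbation states are treatment-independent. Background
#' mortality at the given age is applied first, with disease transitions
#' scaled by the surviving fraction so every row sums to 1.
#'
#' @param params An `asthma_params` bundle.
#' @param strategy `"triple"` or `"dual"`.
#' @param age Age in years (used for background mortality).
#' @param on_treatment Logical; discontinued patients lose the relative-risk
#'   benefit (`rr = 1`).
#' @param life_table A `life_table`; default synthetic Gompertz-Makeham table.
#' @return A 6x6 row-stochastic matrix with `age`, `strategy` and
#'   `on_treatment` attributes.
#' @examples
#' m <- build_transition_matrix(asthma_parameters(), "triple", age = 18)
#' rowSums(m)
#' @export
build_transition_matrix <- function(params, strategy = c("triple", "dual"),
                                    age, on_treatment = TRUE,
                                    life_table = NULL) {
  strategy <- match.arg(strategy)
  life_table <- life_table %||% make_life_table()
  set <- params$settings
  rr <- if (strategy == "triple" && on_treatment) param_base(params, "rr_exacerbation") else 1
  q <- per_cycle_background_mortality(life_table, age, set$cycles_per_year)
  m <- build_matrix_impl(
    p_exac = param_base(params, "p_controlled_to_ocs") * rr,
    p_ocs_ed = param_base(params, "p_ocs_to_ed"),
    p_ed_hosp = param_base(params, "p_ed_to_hosp"),
    p_ad = param_base(params, "p_asthma_death"),
    q_bg = q,
    asthma_death_states = set$asthma_death_states
  )
  attr(m, "age") <- age
  attr(m, "strategy") <- strategy
  attr(m, "on_treatment") <- on_treatment
  m
}

# all per-age-year matrices needed for one strategy, as a list with the
# on-treatment and off-treatment (rr = 1) variants; shared with the microsim
# oracle so both estimate the same process
transition_matrices <- function(params, strategy, life_table = NULL) {
  life_table <- life_table %||% make_life_table()
  set <- params$settings
  ages <- set$start_age:(set$max_age - 1)
  rr <- if (strategy == "triple") param_base(params, "rr_exacerbation") else 1
  p_exac <- param_base(params, "p_controlled_to_ocs")
  p_oe <- param_base(params, "p_ocs_to_ed")
  p_eh <- param_base(params, "p_ed_to_hosp")
  p_ad <- param_base(params, "p_asthma_death")
  qs <- per_cycle_background_mortality(life_table, ages, set$cycles_per_year)
  on <- lapply(qs, function(q) build_matrix_impl(p_exac * rr, p_oe, p_eh, p_ad, q,
                                                 set$asthma_death_states))
  off <- if (rr == 1) on else {
    lapply(qs, function(q) build_matrix_impl(p_exac, p_oe, p_eh, p_ad, q,
                                             set$asthma_death_states))
  }
  list(ages = ages, q_cycle = qs, on = on, off = off)
}

# per-cycle reward vectors (per unit occupancy), on the package's accounting
# conventions:
#  * drug cost accrues per cycle to every alive occupant of the block;
#  * event costs are charged on entry to an exacerbation state (tunnel states
#    make occupancy == entries);
#  * QALYs: under "per_event_annual" every alive occupant accrues the
#    controlled-state utility over the cycle and each exacerbation entry is
#    charged a one-off QALY loss equal to the (annual-scale) decrement;
#    under "per_cycle" the decrement instead reduces the state utility for
#    the single cycle spent in the state.
reward_vectors <- function(params, drug_cost_per_cycle) {
  set <- params$settings
  cpy <- set$cycles_per_year
  u <- param_base(params, "u_controlled")
  du <- c(param_base(params, "du_ocs"), param_base(params, "du_ed"),
          param_base(params, "du_hosp"))
  event_cost <- c(param_base(params, "cost_ocs_burst"),
                  param_base(params, "cost_ed_visit"),
                  param_base(params, "cost_hosp_day") * set$hosp_los_days)
  cost <- c(drug_cost_per_cycle + c(0, event_cost), 0, 0)
  qaly <- if (set$decrement_basis == "per_event_annual") {
    c(u / cpy, u / cpy - du, 0, 0)
  } else {
    c(u, u - du, 0, 0) / cpy
  }
  list(cost = cost, qaly = qaly)
}

discount_factors <- function(r, t, cpy) (1 + r)^(-t / cpy)

# trapezoidal half-cycle weights over trace rows 0..T; without the
# correction the start-of-cycle membership convention is used (rows 0..T-1)
cycle_weights <- function(n_rows, half_cycle) {
  w <- rep(1, n_rows)
  if (half_cycle) {
    w[1] <- 0.5
    w[n_rows] <- 0.5
  } else {
    w[n_rows] <- 0
  }
  w
}

#' Run the deterministic cohort model for one strategy
#'
#' A closed cohort starts 100% in the controlled state at `start_age` and is
#' propagated in `cycle_length_weeks`-week cycles until `max_age` or until
#' the alive mass falls below 1e-9. At the end of the 52nd week the alive
#' cohort splits into a persistent sub-cohort (fraction `persistence_52wk`,
#' keeping the relative-risk benefit and the strategy's drug cost) and a
#' discontinued sub-cohort (relative risk 1; triple-arm discontinuers revert
#' to the dual-therapy drug cost) which are propagated in parallel and
#' re-aggregated in the reported trace. Costs and QALYs are accumulated with
#' trapezoidal half-cycle correction and discounted at the annual rate
#' converted to per-cycle compounding.
#'
#' @param params An `asthma_params` bundle.
#' @param strategy `"triple"` or `"dual"`.
#' @param life_table A `life_table`; default synthetic table.
#' @return A `strategy_result` object: discounted and undiscounted cost and
#'   QALY totals, discounted and undiscounted person-years, the probability
#'   of surviving the first model year free of any exacerbation, annual
#'   exacerbation event rates, and the full per-cycle trace as a tibble.
#' @examples
#' res <- run_cohort(asthma_parameters(), "dual")
#' glance(res)
#' @export
run_cohort <- function(params, strategy = c("triple", "dual"), life_table = NULL) {
  strategy <- match.arg(strategy)
  life_table <- life_table %||% make_life_table()
  set <- params$settings
  cpy <- set$cycles_per_year
  n_max <- (set$max_age - set$start_age) * cpy

  mats <- transition_matrices(params, strategy, life_table)
  persistence <- param_base(params, paste0("persistence_", strategy))
  drug_on <- strategy_drug_cost_per_cycle(params, strategy)
  drug_off <- strategy_drug_cost_per_cycle(params, "dual")

  occ_on <- c(1, 0, 0, 0, 0, 0)
  occ_off <- numeric(6)
  trace <- matrix(0, n_max + 1, 6,
                  dimnames = list(NULL, markov_states()))
  alive_on <- numeric(n_max + 1)
  alive_off <- numeric(n_max + 1)
  trace[1, ] <- occ_on
  alive_on[1] <- 1

  t_final <- n_max
  for (t in seq_len(n_max)) {
    year_idx <- (t - 1) %/% cpy + 1
    occ_on <- drop(occ_on %*% mats$on[[year_idx]])
    if (alive_off[t] > 0 || t > cpy) occ_off <- drop(occ_off %*% mats$off[[year_idx]])
    if (t == cpy) {
      leave <- (1 - persistence) * occ_on[1:4]
      occ_on[1:4] <- occ_on[1:4] - leave
      occ_off[1:4] <- occ_off[1:4] + leave
    }
    row <- occ_on + occ_off
    trace[t + 1, ] <- row
    alive_on[t + 1] <- sum(occ_on[1:4])
    alive_off[t + 1] <- sum(occ_off[1:4])
    if (alive_on[t + 1] + alive_off[t + 1] < 1e-9) {
      t_final <- t
      break
    }
  }
  n_rows <- t_final + 1
  trace <- trace[seq_len(n_rows), , drop = FALSE]
  alive_on <- alive_on[seq_len(n_rows)]
  alive_off <- alive_off[seq_len(n_rows)]

  rw_on <- reward_vectors(params, drug_on)
  rw_off <- reward_vectors(params, drug_off)
  # QALY rewards do not depend on the block, only costs do: compute the
  # event/utility parts on the aggregated trace and drug cost per block
  qaly_cycle <- drop(trace %*% rw_on$qaly)
  event_cost_cycle <- drop(trace %*% (rw_on$cost - c(drug_on, drug_on, drug_on, drug_on, 0, 0)))
  drug_cost_cycle <- drug_on * alive_on + drug_off * alive_off
  cost_cycle <- event_cost_cycle + drug_cost_cycle

  if (any(!is.finite(cost_cycle)) || any(!is.finite(qaly_cycle))) {
    bad <- which(!is.finite(cost_cycle) | !is.finite(qaly_cycle))[1] - 1
    abort(paste0("Non-finite accumulation at cycle ", bad),
          class = "asthmacea_model_error")
  }

  r <- param_base(params, "annual_discount")
  tt <- 0:t_final
  disc <- discount_factors(r, tt, cpy)
  w <- cycle_weights(n_rows, set$half_cycle_correction)
  alive <- alive_on + alive_off

  discounted_cost <- sum(w * disc * cost_cycle)
  discounted_qaly <- sum(w * disc * qaly_cycle)
  undiscounted_cost <- sum(w * cost_cycle)
  undiscounted_qaly <- sum(w * qaly_cycle)
  py_disc <- sum(w * disc * alive) / cpy
  py_undisc <- sum(w * alive) / cpy

  # exacerbation-free first year: stay controlled and alive through the
  # first cycles_per_year cycles (all on treatment; the split happens after)
  rr_eff <- if (strategy == "triple") param_base(params, "rr_exacerbation") else 1
  p1 <- param_base(params, "p_controlled_to_ocs") * rr_eff
  q1 <- mats$q_cycle[1]
  exac_free_1yr <- ((1 - q1) * (1 - p1))^cpy

  entries <- colSums(trace[-1, c("EXAC_OCS", "EXAC_ED", "EXAC_HOSP"), drop = FALSE])
  event_rates <- entries / py_undisc

  structure(list(
    strategy = strategy,
    discounted_cost = discounted_cost,
    discounted_qaly = discounted_qaly,
    undiscounted_cost = undiscounted_cost,
    undiscounted_qaly = undiscounted_qaly,
    person_years_disc = py_disc,
    person_years_undisc = py_undisc,
    exacerbation_free_1yr = exac_free_1yr,
    annual_event_rates = setNames(as.numeric(event_rates),
                                  c("ocs_burst", "ed_visit", "hospitalization")),
    n_cycles = t_final,
    trace = tibble(
      cycle = tt,
      year = tt / cpy,
      age = set$start_age + tt / cpy,
      as_tibble(trace),
      cost = cost_cycle,
      qaly = qaly_cycle,
      cost_disc = w * disc * cost_cycle,
      qaly_disc = w * disc * qaly_cycle
    ),
    settings = set
  ), class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result> %s therapy\n", x$strategy))
  cat(sprintf("  discounted: cost $%.2f, QALYs %.4f over %d cycles (%.1f discounted person-years)\n",
              x$discounted_cost, x$discounted_qaly, x$n_cycles, x$person_years_disc))
  cat(sprintf("  undiscounted: cost $%.2f, QALYs %.4f (%.1f person-years)\n",
              x$undiscounted_cost, x$undiscounted_qaly, x$person_years_undisc))
  cat(sprintf("  exacerbation-free first year: %.4f\n", x$exacerbation_free_1yr))
  invisible(x)
}

#' @describeIn run_cohort Per-cycle trace of a fitted strategy as a tibble.
#' @param x A `strategy_result`.
#' @param ... Unused.
#' @export
tidy.strategy_result <- function(x, ...) x$trace

#' @describeIn run_cohort One-row summary of a fitted strategy.
#' @export
glance.strategy_result <- function(x, ...) {
  tibble(
    strategy = x$strategy,
    discounted_cost = x$discounted_cost,
    discounted_qaly = x$discounted_qaly,
    undiscounted_cost = x$undiscounted_cost,
    undiscounted_qaly = x$undiscounted_qaly,
    person_years_disc = x$person_years_disc,
    person_years_undisc = x$person_years_undisc,
    exacerbation_free_1yr = x$exacerbation_free_1yr,
    n_cycles = x$n_cycles
  )
}

#' Incremental cost-effectiveness ratio
#'
#' Plain ratio `delta_cost / delta_qaly`; `NA` when `delta_qaly` is zero.
#'
#' @param delta_cost Incremental cost (USD).
#' @param delta_qaly Incremental QALYs.
#' @return USD per QALY, vectorized.
#' @examples
#' icer(304, 1.55)
#' @export
icer <- function(delta_cost, delta_qaly) {
  ifelse(delta_qaly == 0, NA_real_, delta_cost / delta_qaly)
}

#' Incremental comparison of two strategies
#'
#' Computes incremental discounted cost and QALYs (`a` minus `b`, i.e.
#' intervention minus comparator), the ICER (reported only in the
#' higher-cost/higher-QALY trade-off quadrant), a dominance classification,
#' per-strategy cost-effectiveness ratios, both quantities normalized per
#' discounted person-year, the net monetary benefit at the willingness-to-pay
#' threshold and the resulting cost-effectiveness verdict.
#'
#' @param a,b `strategy_result` objects from identical settings
#'   (intervention and comparator).
#' @param wtp Willingness to pay per QALY; default from the bundle settings
#'   captured in `a`.
#' @return An `asthma_incremental` object (a list; see [tidy()] for the
#'   one-row tibble form).
#' @examples
#' p <- asthma_parameters()
#' inc <- incremental(run_cohort(p, "triple"), run_cohort(p, "dual"))
#' tidy(inc)
#' @export
incremental <- function(a, b, wtp = NULL) {
  stopifnot(inherits(a, "strategy_result"), inherits(b, "strategy_result"))
  if (!identical(a$settings, b$settings)) {
    abort("Both strategy results must come from identical settings.",
          class = "asthmacea_validation_error")
  }
  wtp <- wtp %||% a$settings$wtp_per_qaly
  dc <- a$discounted_cost - b$discounted_cost
  de <- a$discounted_qaly - b$discounted_qaly
  # QALY differences below numerical noise are treated as exact ties so the
  # ICER is flagged undefined rather than exploding
  if (abs(de) < 1e-12) de <- 0
  classification <- if (de > 0 && dc > 0) "tradeoff_NE"
  else if (de > 0) "dominant"
  else if (de < 0 && dc < 0) "tradeoff_SW"
  else if (de < 0) "dominated"
  else if (dc > 0) "dominated"
  else if (dc < 0) "dominant"
  else "equivalent"
  ic <- if (classification == "tradeoff_NE") dc / de else NA_real_
  nmb_val <- nmb(wtp, de, dc)
  structure(list(
    intervention = a$strategy,
    comparator = b$strategy,
    delta_cost = dc,
    delta_qaly = de,
    icer = ic,
    icer_undefined = de == 0,
    classification = classification,
    ce_ratio_intervention = a$discounted_cost / a$discounted_qaly,
    ce_ratio_comparator = b$discounted_cost / b$discounted_qaly,
    delta_cost_per_person_year =
      a$discounted_cost / a$person_years_disc - b$discounted_cost / b$person_years_disc,
    delta_qaly_per_person_year =
      a$discounted_qaly / a$person_years_disc - b$discounted_qaly / b$person_years_disc,
    wtp = wtp,
    nmb = nmb_val,
    cost_effective = nmb_val > 0
  ), class = "asthma_incremental")
}

#' @export
print.asthma_incremental <- function(x, ...) {
  cat(sprintf("<asthma_incremental> %s vs %s\n", x$intervention, x$comparator))
  cat(sprintf("  dCost $%.2f  dQALY %.4f  (%s)\n", x$delta_cost, x$delta_qaly,
              x$classification))
  if (!is.na(x$icer)) cat(sprintf("  ICER $%.1f per QALY\n", x$icer))
  cat(sprintf("  NMB at $%s/QALY: $%.0f (%scost-effective)\n",
              format(x$wtp, big.mark = ","), x$nmb,
              if (x$cost_effective) "" else "not "))
  invisible(x)
}

#' @describeIn incremental One-row tibble of the comparison.
#' @param x An `asthma_incremental`.
#' @param ... Unused.
#' @export
tidy.asthma_incremental <- function(x, ...) {
  tibble(
    intervention = x$intervention, comparator = x$comparator,
    delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
    icer = x$icer, classification = x$classification,
    delta_cost_per_person_year = x$delta_cost_per_person_year,
    delta_qaly_per_person_year = x$delta_qaly_per_person_year,
    nmb = x$nmb, wtp = x$wtp, cost_effective = x$cost_effective
  )
}

#' Deterministic base-case evaluation of both strategies
#'
#' Runs the cohort model once per strategy at base-case parameter values and
#' assembles the strategy totals and the incremental comparison in one
#' results table.
#'
#' @param params An `asthma_params` bundle.
#' @param life_table Optional `life_table`.
#' @return An `asthma_base_case` object with elements `results` (a tibble,
#'   one row per strategy, mirroring the usual cost-effectiveness table
#'   layout), `incremental`, `triple` and `dual` (the `strategy_result`s).
#' @examples
#' bc <- base_case(asthma_parameters())
#' bc$results
#' @export
base_case <- function(params, life_table = NULL) {
  life_table <- life_table %||% make_life_table()
  triple <- run_cohort(params, "triple", life_table)
  dual <- run_cohort(params, "dual", life_table)
  inc <- incremental(triple, dual)
  results <- tibble(
    strategy = c("triple", "dual"),
    cost = c(triple$discounted_cost, dual$discounted_cost),
    delta_cost = c(inc$delta_cost, NA),
    qaly = c(triple$discounted_qaly, dual$discounted_qaly),
    delta_qaly = c(inc$delta_qaly, NA),
    ce_ratio = c(inc$ce_ratio_intervention, inc$ce_ratio_comparator),
    icer = c(inc$icer, NA),
    exacerbation_free_1yr = c(triple$exacerbation_free_1yr,
                              dual$exacerbation_free_1yr)
  )
  structure(list(results = results, incremental = inc,
                 triple = triple, dual = dual),
            class = "asthma_base_case")
}

#' @export
print.asthma_base_case <- function(x, ...) {
  cat("<asthma_base_case> deterministic cost-utility results\n")
  print(x$results)
  print(x$incremental)
  invisible(x)
}

#' @describeIn base_case Strategy-level results tibble.
#' @param x An `asthma_base_case`.
#' @param ... Unused.
#' @export
tidy.asthma_base_case <- function(x, ...) x$results

#' @describeIn base_case One-row incremental summary.
#' @export
glance.asthma_base_case <- function(x, ...) tidy(x$incremental)
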