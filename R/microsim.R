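#' Individual-level microsimulation oracle
#'
#' Simulates `n` independent patients through the exact per-cycle transition
#' matrices of the cohort engine, with identical accounting conventions
#' (event charging on state entry, per-cycle drug cost while alive,
#' trapezoidal half-cycle weights, per-cycle discounting, and a Bernoulli
#' treatment-discontinuation split at 52 weeks). Patient-level means are
#' therefore unbiased Monte-Carlo estimators of the cohort model's
#' expectations, which makes this the brute-force validation oracle for
#' [run_cohort()].
#'
#' @param params An `asthma_params` bundle.
#' @param strategy `"triple"` or `"dual"`.
#' @param n Number of simulated patients.
#' @param seed Integer seed (reproducible given the seed).
#' @param life_table Optional `life_table`.
#' @param keep_paths Return the per-patient state paths (long tibble;
#'   memory-heavy for large `n`).
#' @return A `microsim_result`: a list with `mean_cost`, `mean_qaly`,
#'   `se_cost`, `se_qaly` (discounted), undiscounted counterparts, annual
#'   exacerbation event rates, the fraction of patients alive per cycle
#'   (`survival`), `n`, and optionally `paths`.
#' @examples
#' \donttest{
#' ms <- simulate_patients(asthma_parameters(), "dual", n = 500, seed = 7)
#' ms$mean_qaly
#' }
#' @export
simulate_patients <- function(params, strategy = c("triple", "dual"), n,
                              seed = 1, life_table = NULL,
                              keep_paths = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(n >= 1)
  life_table <- life_table %||% make_life_table()
  set <- params$settings
  cpy <- set$cycles_per_year
  n_max <- (set$max_age - set$start_age) * cpy

  mats <- transition_matrices(params, strategy, life_table)
  cum_on <- lapply(mats$on, function(m) t(apply(m, 1, cumsum)))
  cum_off <- lapply(mats$off, function(m) t(apply(m, 1, cumsum)))
  persistence <- param_base(params, paste0("persistence_", strategy))
  rw_on <- reward_vectors(params, strategy_drug_cost_per_cycle(params, strategy))
  rw_off <- reward_vectors(params, strategy_drug_cost_per_cycle(params, "dual"))
  r <- param_base(params, "annual_discount")

  set.seed(seed)
  state <- rep(1L, n)          # everyone starts CONTROLLED
  on_trt <- rep(TRUE, n)
  cost <- numeric(n); qaly <- numeric(n)
  cost_u <- numeric(n); qaly_u <- numeric(n)
  events <- c(ocs_burst = 0, ed_visit = 0, hospitalization = 0)
  person_cycles <- 0
  alive_per_cycle <- numeric(n_max + 1)
  paths <- if (keep_paths) vector("list", n_max + 1) else NULL

  hcc <- set$half_cycle_correction
  w0 <- if (hcc) 0.5 else 1

  accrue <- function(idx, weight, disc) {
    if (length(idx) == 0) return()
    rw_c <- ifelse(on_trt[idx], rw_on$cost[state[idx]], rw_off$cost[state[idx]])
    rw_q <- rw_on$qaly[state[idx]]  # QALY rewards identical across blocks
    cost[idx] <<- cost[idx] + weight * disc * rw_c
    qaly[idx] <<- qaly[idx] + weight * disc * rw_q
    cost_u[idx] <<- cost_u[idx] + weight * rw_c
    qaly_u[idx] <<- qaly_u[idx] + weight * rw_q
  }

  alive_per_cycle[1] <- 1
  accrue(seq_len(n), w0, 1)
  if (keep_paths) paths[[1]] <- tibble(patient = seq_len(n), cycle = 0L,
                                       state = markov_states()[state])

  t_final <- n_max
  for (t in seq_len(n_max)) {
    alive <- which(state <= 4L)
    if (length(alive) == 0) { t_final <- t; break }
    year_idx <- (t - 1) %/% cpy + 1
    u <- runif(length(alive))
    nxt <- state[alive]
    for (blk in c(TRUE, FALSE)) {
      cm <- if (blk) cum_on[[year_idx]] else cum_off[[year_idx]]
      for (s in 1:4) {
        sel <- which(on_trt[alive] == blk & state[alive] == s)
        if (length(sel) > 0) {
          nxt[sel] <- findInterval(u[sel], cm[s, ], left.open = FALSE) + 1L
        }
      }
    }
    state[alive] <- as.integer(nxt)
    if (t == cpy) {
      al <- which(state <= 4L)
      on_trt[al] <- runif(length(al)) < persistence
    }
    events["ocs_burst"] <- events["ocs_burst"] + sum(state == 2L)
    events["ed_visit"] <- events["ed_visit"] + sum(state == 3L)
    events["hospitalization"] <- events["hospitalization"] + sum(state == 4L)
    n_alive <- sum(state <= 4L)
    alive_per_cycle[t + 1] <- n_alive / n
    person_cycles <- person_cycles + n_alive
    is_last <- t == n_max || n_alive == 0
    weight <- if (is_last && hcc) 0.5 else if (is_last && !hcc) 0 else 1
    if (weight > 0) accrue(seq_len(n), weight, discount_factors(r, t, cpy))
    if (keep_paths) paths[[t + 1]] <- tibble(patient = which(state <= 4L),
                                             cycle = t,
                                             state = markov_states()[state[state <= 4L]])
    if (n_alive == 0) { t_final <- t; break }
  }

  py_undisc <- person_cycles / cpy / n
  structure(list(
    strategy = strategy,
    n = n,
    mean_cost = mean(cost), se_cost = stats::sd(cost) / sqrt(n),
    mean_qaly = mean(qaly), se_qaly = stats::sd(qaly) / sqrt(n),
    mean_cost_undisc = mean(cost_u), mean_qaly_undisc = mean(qaly_u),
    person_years_undisc = py_undisc,
    annual_event_rates = events / (person_cycles / cpy),
    survival = tibble(cycle = 0:t_final,
                      alive = alive_per_cycle[seq_len(t_final + 1)]),
    paths = if (keep_paths) list_rbind(paths) else NULL
  ), class = "microsim_result")
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf("<microsim_result> %s therapy, n = %d patients\n", x$strategy, x$n))
  cat(sprintf("  mean discounted cost $%.2f (se %.2f); mean discounted QALYs %.4f (se %.4f)\n",
              x$mean_cost, x$se_cost, x$mean_qaly, x$se_qaly))
  invisible(x)
}

#' Random valid parameter bundle for property testing
#'
#' Draws a structurally valid bundle: transition probabilities in (0, 0.9),
#' the controlled-state utility in (0.3, 1) with decrements small enough to
#' keep state utilities non-negative, costs in (1, 500), the relative risk in
#' (0.5, 1) and persistence proportions in (0.3, 0.9), each with a +/-25%
#' range clipped to its role's bounds. The returned bundle always passes
#' [validate_parameters()].
#'
#' @param seed Integer seed.
#' @return An `asthma_params` bundle.
#' @export
random_parameter_table <- function(seed) {
  set.seed(seed)
  tab <- default_parameter_table()
  draw <- function(role, name) {
    switch(role,
           cost = if (name == "cost_ocs_burst") runif(1, 0, 50) else runif(1, 1, 500),
           probability = runif(1, 1e-4, 0.9),
           utility = runif(1, 0.3, 1),
           relative_risk = runif(1, 0.5, 1),
           proportion = runif(1, 0.3, 0.9),
           rate = runif(1, 0, 0.08),
           stop("unhandled role"))
  }
  for (i in seq_len(nrow(tab))) {
    if (tab$role[i] == "utility_decrement") next
    tab$base[i] <- draw(tab$role[i], tab$name[i])
  }
  u <- tab$base[tab$name == "u_controlled"]
  for (i in which(tab$role == "utility_decrement")) {
    tab$base[i] <- runif(1, 0.005, u / 4)
  }
  for (i in seq_len(nrow(tab))) {
    rng <- list(base = tab$base[i], low = NA_real_, high = NA_real_,
                role = tab$role[i])
    tab$low[i] <- expand_range(rng, "low")
    tab$high[i] <- expand_range(rng, "high")
  }
  x <- structure(list(table = tab, settings = default_settings()),
                 class = "asthma_params")
  validate_parameters(x)
}
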