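#' Moment-matched parameter distributions for the probabilistic analysis
#'
#' The probabilistic sensitivity analysis samples the relative risk,
#' utilities (and utility decrements), and treatment-persistence proportions
#' from beta distributions; costs from gamma distributions; and transition
#' probabilities from Dirichlet distributions over each source state's
#' branches. All fits are moment-matched: the distribution mean equals the
#' base-case value and the standard deviation is derived from the printed
#' low-high range treated as a 95% interval, `sd = (high - low) / 3.92`.
#'
#' @name distribution_fitting
NULL

range_sd <- function(low, high) (high - low) / 3.92

fixed_spec <- function(value, name = NULL) {
  structure(list(family = "fixed", value = value, mean = value, sd = 0,
                 name = name), class = "dist_spec")
}

#' Fit a beta distribution to a (base, low, high) range
#'
#' Matches `mean = base` and `sd = (high - low) / 3.92`:
#' `alpha = m (m (1 - m) / s^2 - 1)`, `beta = alpha (1 - m) / m`.
#' A zero-width range yields a degenerate `fixed` spec.
#'
#' @param range One-row tibble or list with `base`, `low`, `high` (see
#'   [param_range()]).
#' @return A `dist_spec` with `family`, `shape1`, `shape2`, `mean`, `sd`.
#' @examples
#' fit_beta(list(base = 0.85, low = 0.78, high = 0.92))
#' @export
fit_beta <- function(range) {
  m <- range$base
  s <- range_sd(range$low, range$high)
  if (s == 0) return(fixed_spec(m, range$name))
  if (m <= 0 || m >= 1) {
    abort("fit_beta() needs 0 < base < 1 for a non-degenerate range.",
          class = "asthmacea_fit_error")
  }
  nu <- m * (1 - m) / s^2 - 1
  a <- m * nu
  b <- a * (1 - m) / m
  if (a <= 0 || b <= 0) {
    abort("Implied beta shape <= 0; the range is too wide for the base value (try a narrower range).",
          class = "asthmacea_fit_error")
  }
  structure(list(family = "beta", shape1 = a, shape2 = b,
                 mean = a / (a + b), sd = sqrt(a * b / ((a + b)^2 * (a + b + 1))),
                 name = range$name %||% NULL),
            class = "dist_spec")
}

#' Fit a gamma distribution to a (base, low, high) cost range
#'
#' Matches `mean = base` and `sd = (high - low) / 3.92`:
#' `shape = (m / s)^2`, `scale = s^2 / m`. A zero-width range (including a
#' zero base cost) yields a degenerate `fixed` spec.
#'
#' @inheritParams fit_beta
#' @return A `dist_spec` with `family`, `shape`, `scale`, `mean`, `sd`.
#' @examples
#' fit_gamma(list(base = 60, low = 45, high = 75))
#' @export
fit_gamma <- function(range) {
  m <- range$base
  s <- range_sd(range$low, range$high)
  if (s == 0) return(fixed_spec(m, range$name))
  if (m <= 0) {
    abort("fit_gamma() needs base > 0 for a non-degenerate range.",
          class = "asthmacea_fit_error")
  }
  k <- (m / s)^2
  theta <- s^2 / m
  structure(list(family = "gamma", shape = k, scale = theta,
                 mean = k * theta, sd = sqrt(k) * theta,
                 name = range$name %||% NULL),
            class = "dist_spec")
}

#' Fit a Dirichlet distribution to the branches of one source state
#'
#' Concentrations are `alpha_i = p_i * N` with the effective sample size `N`
#' solved so that the beta marginal of the largest branch has standard
#' deviation `(high - low) / 3.92` for that branch:
#' `p (1 - p) / (N + 1) = s^2`. The residual (stay/return) branch receives
#' the remaining concentration mass. With a single uncertain branch the
#' Dirichlet reduces exactly to its beta marginal, which is how draws are
#' generated.
#'
#' @param branches A list of one or more branch ranges (each with `base`,
#'   `low`, `high`); base values plus the residual must sum to 1 or less.
#' @return A `dist_spec` with `family = "dirichlet"`, concentration vector
#'   `alpha` (residual branch last), `mean` (branch means) and `sd` of the
#'   largest branch.
#' @examples
#' fit_dirichlet(list(list(base = 0.47, low = 0.35, high = 0.59)))
#' @export
fit_dirichlet <- function(branches) {
  if (!is.list(branches[[1]])) branches <- list(branches)
  p <- map_dbl(branches, "base")
  if (sum(p) > 1 + 1e-12) {
    abort("Branch base probabilities exceed 1; no residual branch remains.",
          class = "asthmacea_fit_error")
  }
  i_max <- which.max(p)
  s <- range_sd(branches[[i_max]]$low, branches[[i_max]]$high)
  if (s == 0) return(fixed_spec(p, branches[[i_max]]$name))
  pm <- p[i_max]
  n_eff <- pm * (1 - pm) / s^2 - 1
  if (!is.finite(n_eff) || n_eff <= 0) {
    abort("No positive effective sample size matches the marginal sd constraint.",
          class = "asthmacea_fit_error")
  }
  alpha <- c(p, 1 - sum(p)) * n_eff
  structure(list(family = "dirichlet", alpha = alpha, n_eff = n_eff,
                 mean = p, sd = sqrt(pm * (1 - pm) / (n_eff + 1)),
                 name = branches[[i_max]]$name %||% NULL),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec> %s%s  mean %.5g  sd %.5g\n", x$family,
              if (!is.null(x$name)) paste0(" [", x$name, "]") else "",
              mean(x$mean), x$sd))
  invisible(x)
}

#' Draw one value from a fitted distribution spec
#'
#' For Dirichlet specs the draw is the first-branch marginal (beta with
#' `shape1 = alpha_1`, `shape2 = sum(alpha) - alpha_1`), which for the
#' two-branch transition rows used in this model is the exact Dirichlet
#' sampling distribution of the uncertain branch.
#'
#' @param spec A `dist_spec`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_dist <- function(spec, n = 1) {
  switch(spec$family,
         fixed = rep(spec$value[1], n),
         beta = rbeta(n, spec$shape1, spec$shape2),
         gamma = rgamma(n, shape = spec$shape, scale = spec$scale),
         dirichlet = rbeta(n, spec$alpha[1], sum(spec$alpha) - spec$alpha[1]),
         abort(paste0("Unknown distribution family: ", spec$family),
               class = "asthmacea_fit_error"))
}

#' Fit sampling distributions for every uncertain parameter of the bundle
#'
#' Family assignment: beta for the relative risk, the controlled-state
#' utility, utility decrements and treatment-persistence proportions; gamma
#' for costs (zero-valued costs stay fixed); Dirichlet for the per-cycle
#' transition probabilities (each modelled as the uncertain branch of its
#' source state against the residual stay/return branch). The annual
#' discount rate is not sampled (it is varied in the deterministic
#' sensitivity analysis only).
#'
#' @param params An `asthma_params` bundle.
#' @return Named list of `dist_spec` objects, one per table row.
#' @export
fit_distributions <- function(params) {
  tab <- params$table
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    row <- as.list(tab[i, ])
    if (row$low == row$high) return(fixed_spec(row$base, row$name))
    switch(row$role,
           cost = fit_gamma(row),
           utility = ,
           utility_decrement = ,
           proportion = ,
           relative_risk = fit_beta(row),
           probability = fit_dirichlet(list(row)),
           rate = fixed_spec(row$base, row$name),
           fixed_spec(row$base, row$name))
  })
  setNames(specs, tab$name)
}

#' Draw a full parameter bundle from fitted distributions
#'
#' Returns a copy of `params` whose base values are replaced by one random
#' draw per uncertain parameter. Draws violating the bundle's structural
#' validity (for example a sampled decrement exceeding the sampled
#' controlled-state utility under the per-cycle accrual basis) are detected
#' by the caller via [validate_parameters()].
#'
#' @param params An `asthma_params` bundle.
#' @param specs As returned by [fit_distributions()].
#' @return An `asthma_params` bundle with drawn base values (ranges kept).
#' @export
draw_parameters <- function(params, specs) {
  tab <- params$table
  tab$base <- map_dbl(tab$name, function(nm) draw_dist(specs[[nm]], 1))
  out <- params
  out$table <- tab
  out
}
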