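#' Net monetary benefit
#'
#' `wtp * delta_qaly - delta_cost`. Positive net monetary benefit is
#' equivalent to the ICER lying below the willingness-to-pay threshold when
#' the QALY gain is positive.
#'
#' @param wtp Willingness to pay per QALY (USD).
#' @param delta_qaly Incremental QALYs.
#' @param delta_cost Incremental cost (USD).
#' @return USD, vectorized.
#' @examples
#' nmb(19000, 1.55, 304)
#' @export
nmb <- function(wtp, delta_qaly, delta_cost) wtp * delta_qaly - delta_cost

# structural validity of one PSA draw; bounds hold by construction of the
# sampling families, but a drawn decrement can exceed the drawn utility,
# which makes a state utility negative under the per-cycle accrual basis
psa_draw_valid <- function(params) {
  tab <- params$table
  if (params$settings$decrement_basis != "per_cycle") return(TRUE)
  u <- tab$base[tab$name == "u_controlled"]
  dmax <- max(tab$base[tab$role == "utility_decrement"])
  u - dmax >= 0
}

#' Probabilistic sensitivity analysis (second-order Monte Carlo)
#'
#' For each replicate, one value is drawn per uncertain parameter from the
#' moment-matched distributions of [fit_distributions()] and the cohort model
#' is run for both strategies with that shared parameter set (parameters
#' common to the arms — utilities, event costs, transition probabilities —
#' use the same draw in both arms; `shared_draws = FALSE` instead draws the
#' common parameters independently per arm). Replicates producing a
#' structurally invalid bundle are rejected and redrawn; more than 5%
#' rejections is an error.
#'
#' @param params An `asthma_params` bundle.
#' @param n_reps Number of replicates (default 1000).
#' @param seed Integer seed; the result is fully reproducible given the seed.
#' @param life_table Optional `life_table`.
#' @param shared_draws Share common-parameter draws across arms (default
#'   TRUE).
#' @return An `asthma_psa` object with `results` (tibble: `replicate`,
#'   `strategy`, `cost`, `qaly`, `person_years_disc`), `deltas` (tibble:
#'   `replicate`, `delta_cost`, `delta_qaly`, `delta_cost_per_person_year`),
#'   `n_reps`, `seed`, `n_rejected`, and the base-case `params`.
#' @examples
#' \donttest{
#' psa <- run_psa(asthma_parameters(), n_reps = 20, seed = 1)
#' glance(psa)
#' }
#' @export
run_psa <- function(params, n_reps = 1000, seed = 1, life_table = NULL,
                    shared_draws = TRUE) {
  stopifnot(n_reps >= 1)
  life_table <- life_table %||% make_life_table()
  specs <- fit_distributions(params)
  set.seed(seed)

  arm_specific <- c("rr_exacerbation", "persistence_triple", "persistence_dual")
  max_reject <- ceiling(0.05 * n_reps)
  n_rejected <- 0

  one_rep <- function(rep_id) {
    repeat {
      draw_a <- draw_parameters(params, specs)
      draw_b <- if (shared_draws) draw_a else {
        d <- draw_parameters(params, specs)
        # the arm-specific parameters always come from the same draw object
        # so the two arms differ only in genuinely common parameters
        d$table$base[d$table$name %in% arm_specific] <-
          draw_a$table$base[draw_a$table$name %in% arm_specific]
        d
      }
      if (psa_draw_valid(draw_a) && psa_draw_valid(draw_b)) break
      n_rejected <<- n_rejected + 1
      if (n_rejected > max_reject) {
        abort(paste0("More than 5% of PSA draws rejected (",
                     n_rejected, " rejections)."),
              class = "asthmacea_model_error")
      }
    }
    triple <- run_cohort(draw_a, "triple", life_table)
    dual <- run_cohort(draw_b, "dual", life_table)
    tibble(
      replicate = rep_id,
      strategy = c("triple", "dual"),
      cost = c(triple$discounted_cost, dual$discounted_cost),
      qaly = c(triple$discounted_qaly, dual$discounted_qaly),
      person_years_disc = c(triple$person_years_disc, dual$person_years_disc)
    )
  }

  results <- list_rbind(map(seq_len(n_reps), one_rep))
  wide <- results |>
    tidyr::pivot_wider(id_cols = "replicate", names_from = "strategy",
                       values_from = c("cost", "qaly", "person_years_disc"))
  deltas <- tibble(
    replicate = wide$replicate,
    delta_cost = wide$cost_triple - wide$cost_dual,
    delta_qaly = wide$qaly_triple - wide$qaly_dual,
    delta_cost_per_person_year =
      wide$cost_triple / wide$person_years_disc_triple -
      wide$cost_dual / wide$person_years_disc_dual
  )
  if (n_rejected > 0) {
    warn(paste0(n_rejected, " PSA draw(s) rejected and redrawn."))
  }
  structure(list(results = results, deltas = deltas, n_reps = n_reps,
                 seed = seed, n_rejected = n_rejected,
                 shared_draws = shared_draws, params = params),
            class = "asthma_psa")
}

#' @export
print.asthma_psa <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<asthma_psa> %d replicates (seed %d)\n", x$n_reps, x$seed))
  cat(sprintf("  mean dCost $%.2f  mean dQALY %.4f  ICER of means $%.1f/QALY\n",
              g$mean_delta_cost, g$mean_delta_qaly, g$icer_of_means))
  cat(sprintf("  CE-plane quadrants (NE/NW/SW/SE): %.1f%% / %.1f%% / %.1f%% / %.1f%%\n",
              100 * g$q1, 100 * g$q2, 100 * g$q3, 100 * g$q4))
  invisible(x)
}

#' @describeIn run_psa Per-replicate incremental results.
#' @param x An `asthma_psa`.
#' @param ... Unused.
#' @export
tidy.asthma_psa <- function(x, ...) x$deltas

#' @describeIn run_psa One-row probabilistic summary: replicate means, the
#'   probabilistic ICER computed as the ratio of mean incremental cost to
#'   mean incremental QALYs, quadrant proportions and the probability of
#'   cost-effectiveness at the configured threshold.
#' @export
glance.asthma_psa <- function(x, ...) {
  d <- x$deltas
  q <- quadrant_proportions(x)
  wtp <- x$params$settings$wtp_per_qaly
  tibble(
    n_reps = x$n_reps,
    mean_delta_cost = mean(d$delta_cost),
    mean_delta_qaly = mean(d$delta_qaly),
    mean_delta_cost_per_person_year = mean(d$delta_cost_per_person_year),
    icer_of_means = icer(mean(d$delta_cost), mean(d$delta_qaly)),
    q1 = q$proportion[q$quadrant == "NE"],
    q2 = q$proportion[q$quadrant == "NW"],
    q3 = q$proportion[q$quadrant == "SW"],
    q4 = q$proportion[q$quadrant == "SE"],
    prob_cost_effective_at_wtp = mean(nmb(wtp, d$delta_qaly, d$delta_cost) > 0),
    n_rejected = x$n_rejected
  )
}

#' Cost-effectiveness plane quadrant proportions
#'
#' Fractions of replicates falling in each quadrant of the
#' (incremental QALY, incremental cost) plane: NE (more effective, more
#' costly), NW (more effective, cost saving), SW (less effective, cost
#' saving), SE (less effective, more costly). Boundary replicates (an exact
#' zero on either axis) are assigned to the NE quadrant.
#'
#' @param psa An `asthma_psa` object.
#' @return A tibble with columns `quadrant`, `n`, `proportion`.
#' @export
quadrant_proportions <- function(psa) {
  d <- psa$deltas
  de <- d$delta_qaly
  dc <- d$delta_cost
  boundary <- de == 0 | dc == 0
  quadrant <- dplyr::case_when(
    boundary ~ "NE",
    de > 0 & dc > 0 ~ "NE",
    de > 0 & dc < 0 ~ "NW",
    de < 0 & dc < 0 ~ "SW",
    .default = "SE"
  )
  counts <- table(factor(quadrant, levels = c("NE", "NW", "SW", "SE")))
  tibble(quadrant = names(counts), n = as.integer(counts),
         proportion = as.numeric(counts) / length(de))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of replicates with
#' strictly positive net monetary benefit for the intervention (ties count
#' as not cost-effective). The smallest grid value reaching probability 0.5
#' is attached as the `threshold` attribute (`NA` if the curve never reaches
#' 0.5 on the grid).
#'
#' @param psa An `asthma_psa` object.
#' @param wtp_grid Strictly increasing willingness-to-pay grid; the default
#'   spans $0-$2,000 in $50 steps plus the configured decision threshold.
#' @return A tibble of class `asthma_ceac` with columns `wtp` and
#'   `prob_cost_effective`, and attribute `threshold`.
#' @export
ceac <- function(psa, wtp_grid = NULL) {
  wtp_grid <- wtp_grid %||%
    sort(unique(c(seq(0, 2000, by = 50), psa$params$settings$wtp_per_qaly)))
  if (length(wtp_grid) == 0 || is.unsorted(wtp_grid, strictly = TRUE)) {
    abort("wtp_grid must be non-empty and strictly increasing.",
          class = "asthmacea_validation_error")
  }
  d <- psa$deltas
  prob <- map_dbl(wtp_grid, function(w) mean(nmb(w, d$delta_qaly, d$delta_cost) > 0))
  out <- tibble(wtp = wtp_grid, prob_cost_effective = prob)
  crossing <- wtp_grid[prob >= 0.5]
  attr(out, "threshold") <- if (length(crossing) > 0) crossing[1] else NA_real_
  class(out) <- c("asthma_ceac", class(out))
  out
}

#' @describeIn ceac The smallest willingness-to-pay on the grid at which the
#'   probability of cost-effectiveness reaches 0.5.
#' @param x An `asthma_ceac` tibble.
#' @export
ceac_threshold <- function(x) attr(x, "threshold")
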