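#' Cost-effectiveness plane scatter plot
#'
#' Per-replicate incremental (QALY, cost) pairs with the willingness-to-pay
#' line through the origin.
#'
#' @param psa An `asthma_psa` object, or a tibble with `delta_qaly` and
#'   `delta_cost` columns.
#' @param wtp Willingness-to-pay slope to draw; `NULL` suppresses the line.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, wtp = NULL) {
  d <- if (inherits(psa, "asthma_psa")) {
    wtp <- wtp %||% psa$params$settings$wtp_per_qaly
    psa$deltas
  } else as_tibble(psa)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8, colour = "#2c7fb8") +
    ggplot2::labs(x = "Incremental QALYs (triple - dual)",
                  y = "Incremental cost (US$)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) {
    p <- p + ggplot2::geom_abline(slope = wtp, intercept = 0,
                                  linetype = "dashed", colour = "firebrick")
  }
  p
}

#' @export
autoplot.asthma_psa <- function(object, ...) plot_ce_plane(object, ...)

#' Cost-effectiveness acceptability curve plot
#'
#' @param x An `asthma_ceac` tibble (from [ceac()]) or a tibble with `wtp`
#'   and `prob_cost_effective` columns.
#' @return A ggplot object.
#' @export
plot_ceac <- function(x) {
  ggplot2::ggplot(as_tibble(x),
                  ggplot2::aes(x = .data$wtp, y = .data$prob_cost_effective)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (US$ per QALY)",
                  y = "Probability triple therapy is cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.asthma_ceac <- function(object, ...) plot_ceac(object)

#' Tornado diagram of the one-way sensitivity analysis
#'
#' Horizontal bars span each parameter's ICER at its low and high bound,
#' centred on the base-case ICER; parameters are ordered by spread.
#'
#' @param dsa An `asthma_dsa` tibble (from [one_way_dsa()]).
#' @return A ggplot object.
#' @export
plot_tornado <- function(dsa) {
  base_icer <- attr(dsa, "icer_base")
  d <- as_tibble(dsa) |>
    filter(!is.na(.data$spread), .data$spread > 0) |>
    mutate(parameter = factor(.data$parameter, levels = rev(.data$parameter)))
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_at_low,
                                       xend = .data$icer_at_high,
                                       y = .data$parameter,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "#2c7fb8") +
    ggplot2::geom_vline(xintercept = base_icer, linetype = "dashed") +
    ggplot2::labs(x = "ICER (US$ per QALY)", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.asthma_dsa <- function(object, ...) plot_tornado(object)

#' Cohort trace plot
#'
#' State occupancy of the cohort over time for one strategy.
#'
#' @param result A `strategy_result` (from [run_cohort()]).
#' @return A ggplot object.
#' @export
plot_trace <- function(result) {
  d <- result$trace |>
    tidyr::pivot_longer(cols = all_of(markov_states()),
                        names_to = "state", values_to = "occupancy") |>
    mutate(state = factor(.data$state, levels = markov_states()))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$year, y = .data$occupancy,
                                  colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Years in model", y = "Cohort occupancy",
                  title = paste0("Cohort trace: ", result$strategy, " therapy")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.strategy_result <- function(object, ...) plot_trace(object)
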