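#' One-way deterministic sensitivity analysis (tornado)
#'
#' Each parameter with a non-degenerate range is set in turn to its low and
#' then its high bound, all other parameters held at base, and the
#' deterministic ICER of triple versus dual therapy is recomputed. Rows are
#' sorted by decreasing spread `|icer_at_high - icer_at_low|`. Extremes at
#' which the comparison leaves the higher-cost/higher-QALY quadrant carry the
#' dominance classification instead of a numeric ICER.
#'
#' @param params An `asthma_params` bundle.
#' @param life_table Optional `life_table`.
#' @param parameters Optional character vector restricting the analysis to a
#'   subset of parameter names; default every table row with `low < high`
#'   (zero-valued costs have degenerate ranges and are skipped
#'   automatically).
#' @return A tibble of class `asthma_dsa` with columns `parameter`, `low`,
#'   `high`, `icer_at_low`, `icer_at_high`, `class_at_low`, `class_at_high`,
#'   `spread`, sorted by non-increasing spread. Attributes: `icer_base`
#'   (base-case ICER), `wtp`, and `robust` (`TRUE` when no one-way ICER
#'   exceeds the willingness-to-pay threshold).
#' @examples
#' \donttest{
#' dsa <- one_way_dsa(asthma_parameters())
#' attr(dsa, "robust")
#' }
#' @export
one_way_dsa <- function(params, life_table = NULL, parameters = NULL) {
  life_table <- life_table %||% make_life_table()
  tab <- params$table
  parameters <- parameters %||% tab$name[tab$low < tab$high]
  unknown <- setdiff(parameters, tab$name)
  if (length(unknown) > 0) {
    abort(c("Unknown parameter(s) in DSA request.",
            setNames(unknown, rep("x", length(unknown)))),
          class = "asthmacea_validation_error")
  }

  eval_at <- function(name, value) {
    p <- params
    p$table$base[p$table$name == name] <- value
    inc <- base_case(p, life_table)$incremental
    list(icer = inc$icer, class = inc$classification)
  }

  base_inc <- base_case(params, life_table)$incremental
  rows <- map(parameters, function(nm) {
    rng <- param_range(params, nm)
    lo <- eval_at(nm, rng$low)
    hi <- eval_at(nm, rng$high)
    spread <- if (!is.na(lo$icer) && !is.na(hi$icer)) abs(hi$icer - lo$icer) else NA_real_
    tibble(parameter = nm, low = rng$low, high = rng$high,
           icer_at_low = lo$icer, icer_at_high = hi$icer,
           class_at_low = lo$class, class_at_high = hi$class,
           spread = spread)
  })
  out <- list_rbind(rows) |> arrange(desc(.data$spread))
  wtp <- params$settings$wtp_per_qaly
  attr(out, "icer_base") <- base_inc$icer
  attr(out, "wtp") <- wtp
  attr(out, "robust") <-
    !any(c(out$icer_at_low, out$icer_at_high) > wtp, na.rm = TRUE)
  class(out) <- c("asthma_dsa", class(out))
  out
}

#' @describeIn one_way_dsa The tornado table as a plain tibble.
#' @param x An `asthma_dsa` object.
#' @param ... Unused.
#' @export
tidy.asthma_dsa <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "asthma_dsa")
  attr(out, "icer_base") <- NULL
  attr(out, "wtp") <- NULL
  attr(out, "robust") <- NULL
  as_tibble(out)
}

#' @describeIn one_way_dsa One-row summary: base-case ICER, threshold,
#'   robustness flag and the widest one-way spread.
#' @export
glance.asthma_dsa <- function(x, ...) {
  tibble(
    icer_base = attr(x, "icer_base"),
    wtp = attr(x, "wtp"),
    robust = attr(x, "robust"),
    n_parameters = nrow(x),
    max_icer = max(c(x$icer_at_low, x$icer_at_high), na.rm = TRUE),
    max_spread = max(x$spread, na.rm = TRUE)
  )
}
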