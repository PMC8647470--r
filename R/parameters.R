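#' Model parameters for the triple- versus dual-therapy cost-utility model
#'
#' `asthma_parameters()` builds the full, validated parameter bundle used by
#' every other function in the package. The defaults encode the published
#' base-case inputs of the model: per-4-week drug acquisition costs, event
#' costs, the controlled-state utility and per-event utility decrements, the
#' relative risk of exacerbation under triple therapy, 52-week treatment
#' persistence for each arm, per-cycle transition probabilities between the
#' exacerbation severity levels, and the annual discount rate.
#'
#' Each uncertain quantity is stored as a `(base, low, high)` range with a
#' semantic `role` (`cost`, `utility`, `utility_decrement`, `probability`,
#' `relative_risk`, `proportion`, `rate`). The same bundle is the single
#' source of truth for the deterministic base case, the one-way sensitivity
#' analysis and the probabilistic sensitivity analysis.
#'
#' @param params Named list of overrides for parameter ranges. Each element is
#'   a scalar (replacing `base` and rescaling `low`/`high` is *not* done; a
#'   scalar replaces `base` only) or a list with any of `base`, `low`, `high`.
#' @param settings Named list of overrides for economic/model settings, see
#'   [default_settings()].
#' @return An object of class `asthma_params`: a list with elements
#'   `table` (a tibble with columns `name`, `role`, `base`, `low`, `high`,
#'   `source`) and `settings` (a named list).
#' @examples
#' p <- asthma_parameters()
#' param_base(p, "rr_exacerbation")
#' p0 <- asthma_parameters(settings = list(annual_discount = list(base = 0)))
#' @export
asthma_parameters <- function(params = list(), settings = list()) {
  tab <- default_parameter_table()
  set <- default_settings()

  # the discount rate lives in the table (it has a DSA range) but is also a
  # settings concept; accept overrides through either route
  if (!is.null(settings$annual_discount)) {
    params$annual_discount <- settings$annual_discount
    settings$annual_discount <- NULL
  }

  bad <- setdiff(names(params), tab$name)
  if (length(bad) > 0) {
    abort(c("Unknown parameter name(s) in config.",
            setNames(bad, rep("x", length(bad)))),
          class = "asthmacea_validation_error")
  }
  for (nm in names(params)) {
    ov <- params[[nm]]
    i <- which(tab$name == nm)
    if (is.numeric(ov) && length(ov) == 1) {
      tab$base[i] <- ov
    } else if (is.list(ov)) {
      extra <- setdiff(names(ov), c("base", "low", "high"))
      if (length(extra) > 0) {
        abort(c(paste0("Invalid field(s) for parameter '", nm, "'."),
                setNames(extra, rep("x", length(extra)))),
              class = "asthmacea_validation_error")
      }
      for (f in names(ov)) tab[[f]][i] <- ov[[f]]
    } else {
      abort(paste0("Override for '", nm, "' must be a scalar or a list."),
            class = "asthmacea_validation_error")
    }
  }

  bad_set <- setdiff(names(settings), names(set))
  if (length(bad_set) > 0) {
    abort(c("Unknown setting(s) in config.",
            setNames(bad_set, rep("x", length(bad_set)))),
          class = "asthmacea_validation_error")
  }
  set[names(settings)] <- settings

  if (isTRUE(set$strict_25pct)) {
    # recompute the controlled->OCS high bound from the +/-25% rule instead of
    # keeping the printed high (which equals the base for that row)
    i <- which(tab$name == "p_controlled_to_ocs")
    tab$high[i] <- min(tab$base[i] * 1.25, 1)
  }

  x <- structure(list(table = tab, settings = set), class = "asthma_params")
  validate_parameters(x)
}

#' Default parameter table (published base-case inputs)
#'
#' One row per printed input of the model's parameter table, plus the two
#' configurable quantities the publication leaves unstated (the oral
#' corticosteroid burst event cost, default 0, and nothing else: the
#' hospitalization length of stay is a setting). Ranges are the printed
#' high/low values; the relative-risk row is normalized so `low <= high`.
#'
#' @return A tibble with columns `name`, `role`, `base`, `low`, `high`, `source`.
#' @export
default_parameter_table <- function() {
  tribble_row <- function(name, role, base, low, high, source) {
    tibble(name = name, role = role, base = base, low = low, high = high,
           source = source)
  }
  bind_rows(
    tribble_row("cost_tiotropium",     "cost", 60, 45, 75, "drug price registry, per 4-week cycle"),
    tribble_row("cost_umeclidinium",   "cost", 32, 24, 40, "drug price registry, per 4-week cycle"),
    tribble_row("cost_glycopyrronium", "cost", 32, 24, 40, "drug price registry, per 4-week cycle"),
    tribble_row("cost_ics_laba",       "cost", 27, 20, 34, "drug price registry, per 4-week cycle"),
    tribble_row("cost_ed_visit",       "cost", 26, 20, 33, "costing study, per episode"),
    tribble_row("cost_hosp_day",       "cost", 80, 60, 100, "costing study, per inpatient day"),
    tribble_row("cost_ocs_burst",      "cost", 0, 0, 0, "not costed in source; configurable"),
    tribble_row("u_controlled",        "utility", 0.74, 0.56, 0.93, "utility systematic review"),
    tribble_row("du_ocs",              "utility_decrement", 0.10, 0.08, 0.13, "utility systematic review"),
    tribble_row("du_ed",               "utility_decrement", 0.15, 0.11, 0.19, "utility systematic review"),
    tribble_row("du_hosp",             "utility_decrement", 0.20, 0.15, 0.25, "utility systematic review"),
    tribble_row("rr_exacerbation",     "relative_risk", 0.85, 0.78, 0.92, "meta-analysis of triple vs dual therapy"),
    tribble_row("persistence_triple",  "proportion", 0.63, 0.47, 0.79, "adherence studies, fraction on treatment at 52 weeks"),
    tribble_row("persistence_dual",    "proportion", 0.56, 0.42, 0.70, "adherence studies, fraction on treatment at 52 weeks"),
    tribble_row("p_controlled_to_ocs", "probability", 0.12, 0.07, 0.12, "clinical trials, per 2-week cycle"),
    tribble_row("p_ocs_to_ed",         "probability", 0.47, 0.35, 0.59, "clinical trials, per episode"),
    tribble_row("p_ed_to_hosp",        "probability", 0.15, 0.11, 0.19, "clinical trials, per episode"),
    tribble_row("p_asthma_death",      "probability", 0.0002, 0.00014, 0.00024, "national statistics, per cycle in exacerbation"),
    tribble_row("annual_discount",     "rate", 0.05, 0.00, 0.06, "national economic-evaluation guideline")
  )
}

#' Default economic and structural settings
#'
#' @return Named list: `wtp_per_qaly` (USD per QALY, 19000),
#'   `cycle_length_weeks` (2), `cycles_per_year` (26), `start_age` (18),
#'   `max_age` (100), `half_cycle_correction` (TRUE), `hosp_los_days` (5),
#'   `triple_drug_mix` (market-share weights over tiotropium, umeclidinium
#'   and glycopyrronium; default equal thirds), `decrement_basis`
#'   (`"per_event_annual"` or `"per_cycle"`), `strict_25pct` (FALSE),
#'   `asthma_death_states` (`"all_exacerbation"` or `"hospital_only"`),
#'   `currency_note`.
#' @export
default_settings <- function() {
  list(
    wtp_per_qaly = 19000,
    cycle_length_weeks = 2,
    cycles_per_year = 26L,
    start_age = 18L,
    max_age = 100L,
    half_cycle_correction = TRUE,
    hosp_los_days = 5,
    triple_drug_mix = c(tiotropium = 1 / 3, umeclidinium = 1 / 3,
                        glycopyrronium = 1 / 3),
    decrement_basis = "per_event_annual",
    strict_25pct = FALSE,
    asthma_death_states = "all_exacerbation",
    currency_note = "US$1.00 = COP$3,500"
  )
}

role_bounds <- function(role) {
  switch(role,
         cost = c(0, Inf),
         utility = c(0, 1),
         utility_decrement = c(0, 1),
         probability = c(0, 1),
         proportion = c(0, 1),
         rate = c(0, 1),
         relative_risk = c(0, Inf),
         c(-Inf, Inf))
}

#' Validate a parameter bundle
#'
#' Checks range ordering (`low <= base <= high`), role-specific bounds,
#' non-negative state utilities, the market-share simplex constraint and the
#' cycle-accounting identity (cycles per year x cycle length = 52 weeks).
#'
#' @param x An `asthma_params` object.
#' @return `x`, invisibly-validated (returned unchanged); aborts with a
#'   `asthmacea_validation_error` listing the offending keys otherwise.
#' @export
validate_parameters <- function(x) {
  stopifnot(inherits(x, "asthma_params"))
  tab <- x$table
  set <- x$settings
  problems <- character()

  for (i in seq_len(nrow(tab))) {
    nm <- tab$name[i]; b <- tab$base[i]; lo <- tab$low[i]; hi <- tab$high[i]
    bounds <- role_bounds(tab$role[i])
    if (!all(is.finite(c(b, lo, hi)))) {
      problems <- c(problems, paste0(nm, ": non-finite value"))
      next
    }
    if (lo > hi) {
      problems <- c(problems, paste0(nm, ": low (", lo, ") > high (", hi, ") after normalization"))
    }
    if (b < lo || b > hi) {
      problems <- c(problems, paste0(nm, ": base (", b, ") outside [low, high]"))
    }
    if (b < bounds[1] || b > bounds[2] || lo < bounds[1] || hi > bounds[2]) {
      problems <- c(problems, paste0(nm, ": value outside ", tab$role[i],
                                     " bounds [", bounds[1], ", ", bounds[2], "]"))
    }
  }

  u <- tab$base[tab$name == "u_controlled"]
  dmax <- max(tab$base[tab$role == "utility_decrement"])
  if (length(u) == 1 && u - dmax < 0) {
    problems <- c(problems, "u_controlled minus the largest utility decrement is negative (state utility below 0)")
  }

  if (abs(sum(set$triple_drug_mix) - 1) > 1e-9) {
    problems <- c(problems, "triple_drug_mix does not sum to 1")
  }
  if (any(set$triple_drug_mix < 0)) {
    problems <- c(problems, "triple_drug_mix has negative weights")
  }
  if (set$cycles_per_year * set$cycle_length_weeks != 52) {
    problems <- c(problems, "cycles_per_year x cycle_length_weeks must equal 52")
  }
  if (!set$decrement_basis %in% c("per_event_annual", "per_cycle")) {
    problems <- c(problems, "decrement_basis must be 'per_event_annual' or 'per_cycle'")
  }
  if (!set$asthma_death_states %in% c("all_exacerbation", "hospital_only")) {
    problems <- c(problems, "asthma_death_states must be 'all_exacerbation' or 'hospital_only'")
  }
  if (set$start_age >= set$max_age) {
    problems <- c(problems, "start_age must be below max_age")
  }
  if (set$hosp_los_days < 0) problems <- c(problems, "hosp_los_days must be >= 0")

  if (length(problems) > 0) {
    abort(c("Invalid parameter bundle.", setNames(problems, rep("x", length(problems)))),
          class = "asthmacea_validation_error")
  }
  x
}

#' Load parameters from a YAML config file
#'
#' With `path = NULL` the packaged defaults (the published base case) are
#' returned. The config schema is a YAML mapping with optional top-level keys
#' `params` (parameter name -> scalar base or `{base, low, high}`) and
#' `settings` (see [default_settings()]).
#'
#' @param path Path to a YAML config file, or `NULL` for defaults.
#' @return A validated `asthma_params` bundle.
#' @export
load_parameters <- function(path = NULL) {
  if (is.null(path)) return(asthma_parameters())
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path), class = "asthmacea_io_error")
  }
  cfg <- yaml::read_yaml(path)
  extra <- setdiff(names(cfg), c("params", "settings"))
  if (length(extra) > 0) {
    abort(c("Unknown top-level config key(s).", setNames(extra, rep("x", length(extra)))),
          class = "asthmacea_validation_error")
  }
  if (!is.null(cfg$settings$triple_drug_mix)) {
    cfg$settings$triple_drug_mix <- unlist(cfg$settings$triple_drug_mix)
  }
  asthma_parameters(params = cfg$params %||% list(),
                    settings = cfg$settings %||% list())
}

#' Write a parameter bundle to a YAML config file
#'
#' The written file round-trips through [load_parameters()] field-for-field.
#'
#' @param x An `asthma_params` bundle.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(x, path) {
  stopifnot(inherits(x, "asthma_params"))
  params <- lapply(seq_len(nrow(x$table)), function(i) {
    list(base = x$table$base[i], low = x$table$low[i], high = x$table$high[i])
  })
  names(params) <- x$table$name
  set <- x$settings
  set$triple_drug_mix <- as.list(set$triple_drug_mix)
  yaml::write_yaml(list(params = params, settings = set), path, precision = 15)
  invisible(path)
}

#' Export the parameter table as CSV
#'
#' One row per parameter with columns `name`, `role`, `base`, `low`, `high`,
#' `source`.
#'
#' @param x An `asthma_params` bundle.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_parameters <- function(x, path) {
  stopifnot(inherits(x, "asthma_params"))
  readr::write_csv(x$table, path)
  invisible(path)
}

#' Look up one parameter range or its base value
#'
#' @param x An `asthma_params` bundle.
#' @param name Parameter name (a row of `x$table`).
#' @return `param_range()` returns a one-row tibble; `param_base()` the base
#'   value as a scalar.
#' @export
param_range <- function(x, name) {
  i <- which(x$table$name == name)
  if (length(i) != 1) {
    abort(paste0("Unknown parameter: ", name), class = "asthmacea_validation_error")
  }
  x$table[i, ]
}

#' @rdname param_range
#' @export
param_base <- function(x, name) param_range(x, name)$base

#' Expand a parameter range to its low or high sensitivity bound
#'
#' When a printed bound is available it is returned as-is; when absent
#' (`NA`), the +/-25% rule is applied to the base value and the result is
#' clipped to the bounds implied by the parameter's role (probabilities,
#' utilities and proportions to \[0, 1\]; costs to \[0, Inf)).
#'
#' @param range A one-row tibble as returned by [param_range()], or a list
#'   with `base`, `low`, `high` and `role`.
#' @param direction `"low"` or `"high"`.
#' @return The bound value as a scalar.
#' @examples
#' expand_range(list(base = 0.74, low = NA, high = NA, role = "utility"), "high")
#' @export
expand_range <- function(range, direction = c("low", "high")) {
  direction <- match.arg(direction)
  b <- range$base
  bounds <- role_bounds(range$role)
  explicit <- if (direction == "low") range$low else range$high
  if (!is.null(explicit) && length(explicit) == 1 && !is.na(explicit)) {
    return(explicit)
  }
  v <- if (direction == "low") b * 0.75 else b * 1.25
  min(max(v, bounds[1]), bounds[2])
}

#' Per-cycle drug acquisition cost of a strategy
#'
#' Drug costs are quoted per 4-week cycle; the model cycle is
#' `cycle_length_weeks` long, so the per-cycle cost is the 4-week cost scaled
#' by `cycle_length_weeks / 4`. The triple-therapy cost is the market-share
#' weighted long-acting muscarinic antagonist cost plus the dual-therapy
#' (ICS+LABA) cost.
#'
#' @param params An `asthma_params` bundle.
#' @param strategy `"triple"` or `"dual"`.
#' @return USD per model cycle, scalar.
#' @examples
#' strategy_drug_cost_per_cycle(asthma_parameters(), "dual") # 27 / 2
#' @export
strategy_drug_cost_per_cycle <- function(params, strategy = c("triple", "dual")) {
  strategy <- match.arg(strategy)
  set <- params$settings
  scale <- set$cycle_length_weeks / 4
  dual4 <- param_base(params, "cost_ics_laba")
  if (strategy == "dual") return(dual4 * scale)
  mix <- set$triple_drug_mix
  lama4 <- sum(mix * c(param_base(params, "cost_tiotropium"),
                       param_base(params, "cost_umeclidinium"),
                       param_base(params, "cost_glycopyrronium")))
  (lama4 + dual4) * scale
}

#' Strategy definition derived from a parameter bundle
#'
#' @param params An `asthma_params` bundle.
#' @param strategy `"triple"` or `"dual"`.
#' @return A list with `name`, `drug_cost_per_cycle`, `rr_exacerbation`
#'   (1 for the reference dual arm) and `persistence_52wk`.
#' @export
strategy_params <- function(params, strategy = c("triple", "dual")) {
  strategy <- match.arg(strategy)
  list(
    name = strategy,
    drug_cost_per_cycle = strategy_drug_cost_per_cycle(params, strategy),
    rr_exacerbation = if (strategy == "triple") param_base(params, "rr_exacerbation") else 1,
    persistence_52wk = param_base(params, paste0("persistence_", strategy))
  )
}

#' @export
print.asthma_params <- function(x, ...) {
  cat("<asthma_params> cost-utility model inputs\n")
  cat(sprintf("  %d parameters; discount %.1f%%/yr; WTP $%s/QALY; ages %d-%d; %d x %g-week cycles/yr\n",
              nrow(x$table), 100 * param_base(x, "annual_discount"),
              format(x$settings$wtp_per_qaly, big.mark = ","),
              x$settings$start_age, x$settings$max_age,
              x$settings$cycles_per_year, x$settings$cycle_length_weeks))
  print(x$table, n = nrow(x$table))
  invisible(x)
}

#' @export
tidy.asthma_params <- function(x, ...) x$table
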