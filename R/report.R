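#' Reporting runs: base case, probabilistic and deterministic sensitivity
#'
#' These functions are the package's batch entry points (also exposed by the
#' command-line wrapper shipped in `inst/scripts/asthmacea-cli.R`). Each run
#' writes its tabular outputs as CSV, regenerates every figure from the
#' exported CSVs (never from in-memory-only state), and records a run
#' manifest with the configuration hash, seeds, software version and output
#' file list so identical manifests imply identical tabular outputs.
#'
#' @name reporting
NULL

round_display <- function(results) {
  results |>
    mutate(across(dplyr::any_of(c("cost", "delta_cost", "icer", "ce_ratio",
                                  "icer_at_low", "icer_at_high", "spread")),
                  ~ round(.x, 0)),
           across(dplyr::any_of(c("qaly", "delta_qaly")), ~ round(.x, 2)))
}

write_manifest <- function(out_dir, command, params, seed, n_reps, files) {
  manifest <- list(
    command = command,
    config_hash = rlang::hash(list(params$table, params$settings)),
    seed = seed,
    n_reps = n_reps,
    package_version = as.character(utils::packageVersion("asthmacea")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    settings_used = params$settings[c("wtp_per_qaly", "start_age", "max_age",
                                      "half_cycle_correction", "hosp_los_days",
                                      "decrement_basis", "strict_25pct",
                                      "asthma_death_states")],
    triple_drug_mix = as.list(params$settings$triple_drug_mix),
    outputs = files
  )
  path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    abort(paste0("Cannot create output directory: ", out_dir),
          class = "asthmacea_io_error")
  }
  out_dir
}

#' @describeIn reporting Deterministic base case: writes `base_case.csv`
#'   (full precision), `base_case_display.csv` (rounded to $1 and 0.01 QALY),
#'   and the per-strategy cohort traces.
#' @param config Path to a YAML config, an `asthma_params` bundle, or `NULL`
#'   for the packaged defaults.
#' @param out_dir Output directory (created if needed).
#' @param life_table Optional `life_table` (or CSV path).
#' @return The run's primary result object, invisibly (`asthma_base_case`,
#'   `asthma_psa` or `asthma_dsa`).
#' @export
report_base_case <- function(config = NULL, out_dir, life_table = NULL) {
  params <- resolve_config(config)
  lt <- resolve_life_table(life_table)
  ensure_dir(out_dir)
  bc <- base_case(params, lt)
  res <- bc$results |>
    mutate(verdict = ifelse(.data$strategy == "triple",
                            ifelse(bc$incremental$cost_effective,
                                   "cost-effective", "not cost-effective"), NA))
  files <- c("base_case.csv", "base_case_display.csv", "incremental.csv",
             "trace_triple.csv", "trace_dual.csv")
  readr::write_csv(res, file.path(out_dir, "base_case.csv"))
  readr::write_csv(round_display(res), file.path(out_dir, "base_case_display.csv"))
  readr::write_csv(tidy(bc$incremental), file.path(out_dir, "incremental.csv"))
  readr::write_csv(bc$triple$trace, file.path(out_dir, "trace_triple.csv"))
  readr::write_csv(bc$dual$trace, file.path(out_dir, "trace_dual.csv"))
  write_manifest(out_dir, "base-case", params, seed = NA, n_reps = NA, files)
  invisible(bc)
}

#' @describeIn reporting Probabilistic sensitivity analysis: writes the
#'   per-replicate results, the incremental pairs with net monetary benefit,
#'   quadrant proportions, the acceptability curve, a one-row summary, and
#'   the cost-effectiveness plane / CEAC figures (rendered from the CSVs).
#' @param n_reps Number of PSA replicates.
#' @param seed Integer seed.
#' @param wtp_grid Willingness-to-pay grid for the acceptability curve.
#' @export
report_psa <- function(config = NULL, out_dir, n_reps = 1000, seed = 1,
                       life_table = NULL, wtp_grid = NULL) {
  params <- resolve_config(config)
  lt <- resolve_life_table(life_table)
  ensure_dir(out_dir)
  psa <- run_psa(params, n_reps = n_reps, seed = seed, life_table = lt)
  wtp <- params$settings$wtp_per_qaly
  reps <- psa$deltas |>
    mutate(nmb = nmb(wtp, .data$delta_qaly, .data$delta_cost))
  cc <- ceac(psa, wtp_grid)
  files <- c("psa_results.csv", "psa_incremental.csv", "psa_quadrants.csv",
             "ceac.csv", "psa_summary.csv", "ce_plane.png", "ceac.png")
  readr::write_csv(psa$results, file.path(out_dir, "psa_results.csv"))
  readr::write_csv(reps, file.path(out_dir, "psa_incremental.csv"))
  readr::write_csv(quadrant_proportions(psa), file.path(out_dir, "psa_quadrants.csv"))
  readr::write_csv(as_tibble(cc), file.path(out_dir, "ceac.csv"))
  summary_row <- glance(psa) |>
    mutate(ceac_threshold = ceac_threshold(cc),
           verdict = ifelse(.data$icer_of_means < wtp & .data$mean_delta_qaly > 0,
                            "cost-effective", "not cost-effective"))
  readr::write_csv(summary_row, file.path(out_dir, "psa_summary.csv"))

  # figures are rebuilt from the exported artifacts
  inc_csv <- readr::read_csv(file.path(out_dir, "psa_incremental.csv"),
                             show_col_types = FALSE)
  ggplot2::ggsave(file.path(out_dir, "ce_plane.png"),
                  plot_ce_plane(inc_csv, wtp = wtp),
                  width = 6, height = 5, dpi = 150)
  ceac_csv <- readr::read_csv(file.path(out_dir, "ceac.csv"),
                              show_col_types = FALSE)
  ggplot2::ggsave(file.path(out_dir, "ceac.png"), plot_ceac(ceac_csv),
                  width = 6, height = 4, dpi = 150)
  write_manifest(out_dir, "psa", params, seed = seed, n_reps = n_reps, files)
  invisible(psa)
}

#' @describeIn reporting One-way deterministic sensitivity analysis: writes
#'   the sorted tornado table (with the robustness flag) and the tornado
#'   figure.
#' @export
report_dsa <- function(config = NULL, out_dir, life_table = NULL) {
  params <- resolve_config(config)
  lt <- resolve_life_table(life_table)
  ensure_dir(out_dir)
  dsa <- one_way_dsa(params, lt)
  tab <- as_tibble(dsa) |>
    mutate(icer_base = attr(dsa, "icer_base"),
           wtp = attr(dsa, "wtp"),
           robust = attr(dsa, "robust"))
  files <- c("tornado.csv", "tornado.png")
  readr::write_csv(tab, file.path(out_dir, "tornado.csv"))
  tor_csv <- readr::read_csv(file.path(out_dir, "tornado.csv"),
                             show_col_types = FALSE)
  tor <- structure(tor_csv, icer_base = tor_csv$icer_base[1],
                   wtp = tor_csv$wtp[1])
  ggplot2::ggsave(file.path(out_dir, "tornado.png"), plot_tornado(tor),
                  width = 6, height = 5, dpi = 150)
  write_manifest(out_dir, "dsa", params, seed = NA, n_reps = NA, files)
  invisible(dsa)
}

resolve_config <- function(config) {
  if (is.null(config)) return(load_parameters())
  if (inherits(config, "asthma_params")) return(config)
  load_parameters(config)
}

resolve_life_table <- function(life_table) {
  if (is.null(life_table)) return(make_life_table())
  if (inherits(life_table, "life_table")) return(life_table)
  read_life_table(life_table)
}
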