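#' Synthetic Gompertz-Makeham life table
#'
#' Background (all-cause, non-asthma) mortality enters the model as an annual
#' death probability per year of age. National life-table values are not
#' shipped with the package; instead a synthetic table is generated from the
#' Gompertz-Makeham law
#' \deqn{q(x) = 1 - \exp\{-(a + b e^{c x})\},}
#' whose defaults (`a = 5e-4`, `b = 3e-5`, `c = 0.09`) give adult mortality of
#' realistic order (about 6.5e-4 at age 18, 0.007 at 60, 0.04 at 80). A real
#' life table supplied via [read_life_table()] takes precedence anywhere a
#' life table is accepted.
#'
#' @param a Makeham (age-independent) hazard component, `>= 0`.
#' @param b Gompertz baseline hazard, `> 0`.
#' @param c Gompertz log-slope per year of age, `> 0`.
#' @param ages Integer ages covered (default 0-100).
#' @return A tibble with columns `age` and `annual_death_probability`, class
#'   `life_table`.
#' @examples
#' lt <- make_life_table()
#' lt$annual_death_probability[lt$age == 80]
#' @export
make_life_table <- function(a = 5e-4, b = 3e-5, c = 0.09, ages = 0:100) {
  if (a < 0 || b <= 0 || c <= 0) {
    abort("make_life_table() requires a >= 0, b > 0, c > 0.",
          class = "asthmacea_validation_error")
  }
  hazard <- a + b * exp(c * ages)
  q <- 1 - exp(-hazard)
  if (any(!is.finite(q)) || any(q >= 1)) {
    abort("Gompertz-Makeham parameters imply annual death probability >= 1 within the age range.",
          class = "asthmacea_validation_error")
  }
  structure(tibble(age = as.integer(ages), annual_death_probability = q),
            class = c("life_table", "tbl_df", "tbl", "data.frame"))
}

#' Read a life table from CSV
#'
#' Expected columns: `age`, `annual_death_probability`, and optionally `sex`.
#' When a `sex` column is present the probabilities are averaged across sexes
#' within each age (the model runs a sex-averaged cohort).
#'
#' @param path CSV path.
#' @return A `life_table` tibble.
#' @export
read_life_table <- function(path) {
  lt <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("age", "annual_death_probability") %in% names(lt))) {
    abort("Life table CSV needs columns 'age' and 'annual_death_probability'.",
          class = "asthmacea_validation_error")
  }
  if ("sex" %in% names(lt)) {
    lt <- lt |>
      group_by(.data$age) |>
      summarise(annual_death_probability = mean(.data$annual_death_probability),
                .groups = "drop")
  }
  lt <- lt |> arrange(.data$age)
  if (any(lt$annual_death_probability < 0 | lt$annual_death_probability > 1)) {
    abort("Life table probabilities must lie in [0, 1].",
          class = "asthmacea_validation_error")
  }
  structure(as_tibble(lt[, c("age", "annual_death_probability")]),
            class = c("life_table", "tbl_df", "tbl", "data.frame"))
}

#' Annual background death probability at a given age
#'
#' Ages above the table's support use the terminal row's probability.
#'
#' @param life_table A `life_table` tibble.
#' @param age Age in years (fractional ages are floored).
#' @return Annual death probability, vectorized over `age`.
#' @export
annual_mortality <- function(life_table, age) {
  a <- floor(age)
  idx <- match(pmin(a, max(life_table$age)), life_table$age)
  if (anyNA(idx)) {
    abort("Age below the life table's support.", class = "asthmacea_validation_error")
  }
  life_table$annual_death_probability[idx]
}

#' Convert an annual death probability to a per-cycle probability
#'
#' Uses the constant-hazard-within-year conversion
#' `1 - (1 - q)^(1 / cycles_per_year)`.
#'
#' @param life_table A `life_table` tibble.
#' @param age Age in years.
#' @param cycles_per_year Model cycles per year.
#' @return Per-cycle death probability, vectorized over `age`.
#' @examples
#' lt <- make_life_table()
#' per_cycle_background_mortality(lt, 60, 26)
#' @export
per_cycle_background_mortality <- function(life_table, age, cycles_per_year) {
  q <- annual_mortality(life_table, age)
  1 - (1 - q)^(1 / cycles_per_year)
}
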