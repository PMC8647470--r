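# fixtures are built in code; no data files

# life table with identical annual death probability at every age
const_life_table <- function(q, ages = 0:120) {
  structure(tibble::tibble(age = as.integer(ages),
                           annual_death_probability = q),
            class = c("life_table", "tbl_df", "tbl", "data.frame"))
}

zero_life_table <- function() const_life_table(0)

# default bundle with a shortened horizon for fast unit tests
quick_params <- function(params = list(), settings = list()) {
  settings$max_age <- settings$max_age %||% 40L
  asthma_parameters(params = params, settings = settings)
}

# degenerate disease-free bundle: no transitions, no asthma deaths, perfect
# utility, zero discounting, one-year horizon
no_event_params <- function(settings = list()) {
  base_settings <- list(max_age = 19L)
  base_settings[names(settings)] <- settings
  asthma_parameters(
    params = list(
      p_controlled_to_ocs = list(base = 0, low = 0, high = 0),
      p_ocs_to_ed = list(base = 0, low = 0, high = 0),
      p_ed_to_hosp = list(base = 0, low = 0, high = 0),
      p_asthma_death = list(base = 0, low = 0, high = 0),
      u_controlled = list(base = 1, low = 1, high = 1),
      annual_discount = list(base = 0, low = 0, high = 0)
    ),
    settings = base_settings
  )
}

# minimal strategy_result stub for incremental() arithmetic tests
fake_result <- function(cost, qaly, strategy = "triple", py = 10,
                        settings = default_settings()) {
  structure(list(strategy = strategy, discounted_cost = cost,
                 discounted_qaly = qaly, person_years_disc = py,
                 settings = settings),
            class = "strategy_result")
}

`%||%` <- rlang::`%||%`
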