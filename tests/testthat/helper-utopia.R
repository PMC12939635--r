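# Small parameter sets used across tests.

# A fast-breeding micro-population: one pair, immediate readiness, no delay.
pair_params <- function(...) {
  defaults <- list(
    n_initial_females = 1, n_initial_males = 1,
    mate_readiness = 1, initial_delay = 0, mating_age = 0,
    horizon = 60, seed = 1
  )
  do.call(simulation_params, utils::modifyList(defaults, list(...)))
}

# Build a synthetic run from bare census columns (for metric tests).
fake_run <- function(n_total, n_adult = pmax(0, round(n_total / 4)),
                     days = seq_along(n_total) - 1L) {
  records <- data.frame(
    day = as.integer(days), n_total = as.integer(n_total),
    n_adult = as.integer(n_adult),
    births = 0L, deaths = 0L, abandoned_litters = 0L,
    n_pregnant = 0L, n_beautiful = 0L, mean_deviation = 1
  )
  mouseutopia:::run_from_records(records)
}
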