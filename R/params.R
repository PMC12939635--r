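#' Behavioral-sink parameters
#'
#' Parameters of the overcrowding pathologies that drive the population's
#' collapse. Two population-count thresholds act as critical densities (the
#' pen area is constant, so raw counts stand in for density): above
#' `n_crit_individual` every living mouse's individual deviation factor is
#' multiplied once per day by `n_crit_individual / N`; above `n_crit_social`
#' due litters are abandoned with probability `p_abandon` and untested adult
#' males become permanent non-breeding "beautiful ones" with probability
#' `p_beautiful`. With `enabled = FALSE` all sink operations are no-ops and
#' the engine reduces exactly to the pure growth-phase model.
#'
#' @param enabled Logical; master switch.
#' @param n_crit_individual Critical population count for individual
#'   processes (deviation decay).
#' @param n_crit_social Critical population count for social processes
#'   (abandonment, beautiful ones).
#' @param p_abandon Probability a due litter is abandoned, per delivery,
#'   while above `n_crit_social`.
#' @param p_beautiful Probability an adult male becomes a beautiful one at
#'   his single lifetime test.
#' @return An object of class `sink_params`.
#' @export
sink_params <- function(enabled = FALSE, n_crit_individual = 400,
                        n_crit_social = 300, p_abandon = 0.3,
                        p_beautiful = 0.1) {
  sp <- list(
    enabled = isTRUE(enabled),
    n_crit_individual = n_crit_individual,
    n_crit_social = n_crit_social,
    p_abandon = p_abandon,
    p_beautiful = p_beautiful
  )
  class(sp) <- "sink_params"
  validate_sink_params(sp)
  sp
}

validate_sink_params <- function(sp) {
  for (f in c("n_crit_individual", "n_crit_social")) {
    v <- sp[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("sink_params: '%s' must be a single positive count", f),
           call. = FALSE)
    }
  }
  for (f in c("p_abandon", "p_beautiful")) {
    v <- sp[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("sink_params: '%s' must be a probability in [0, 1]", f),
           call. = FALSE)
    }
  }
  invisible(sp)
}

#' Simulation parameters
#'
#' The full parameter set for one simulated universe. Defaults are the
#' best-fitting growth-phase calibration (preset "set1", see
#' [preset_params()]) with the behavioral sink disabled.
#'
#' @param mate_readiness Per-day probability that a non-pregnant female
#'   attempts conception.
#' @param litter_mean,litter_sd Mean and standard deviation (pups) of the
#'   Gaussian litter-size distribution.
#' @param litter_cap Optional upper clamp on litter size (`Inf` = none).
#' @param p_male Probability a pup is male (sex ratio).
#' @param zone_mode `"none"` (ignore zones) or `"natal"` (pups inherit the
#'   mother's zone; per-zone births are tallied but zones never affect
#'   dynamics).
#' @param n_zones Number of zones when `zone_mode = "natal"`.
#' @param initial_delay Days before any conception is possible, modelling the
#'   founders' initial turmoil and adjustment.
#' @param gestation_min,gestation_max Gestation length bounds in days;
#'   each pregnancy draws a uniform integer from this interval.
#' @param adult_age Census age threshold in days: mice at least this old are
#'   counted as adults and males are tested for beautiful-ones status.
#' @param mating_age Effective minimum age in days for conception eligibility
#'   (females attempting, males being selected). Kept separate from
#'   `adult_age`, which is a census category; the default 15 is calibrated so
#'   the preset ensembles reproduce the reported growth-phase census (see the
#'   methods vignette).
#' @param initial_age Age in days of the founders at day 0.
#' @param n_initial_females,n_initial_males Founder counts.
#' @param horizon Last simulated day (must be positive).
#' @param seed Integer seed for the run's RNG stream.
#' @param lifespan A [lifespan_params()] object.
#' @param sink A [sink_params()] object.
#' @return An object of class `simulation_params`.
#' @examples
#' p <- simulation_params(horizon = 50, seed = 42)
#' run <- run_simulation(p)
#' run
#' @export
simulation_params <- function(mate_readiness = 0.01,
                              litter_mean = 10, litter_sd = 1,
                              litter_cap = Inf,
                              p_male = 0.54,
                              zone_mode = c("none", "natal"), n_zones = 16,
                              initial_delay = 60,
                              gestation_min = 19, gestation_max = 23,
                              adult_age = 65, mating_age = 15,
                              initial_age = adult_age,
                              n_initial_females = 4, n_initial_males = 4,
                              horizon = 315, seed = 1,
                              lifespan = lifespan_params(),
                              sink = sink_params()) {
  p <- list(
    mate_readiness = mate_readiness,
    litter_mean = litter_mean, litter_sd = litter_sd, litter_cap = litter_cap,
    p_male = p_male,
    zone_mode = match.arg(zone_mode), n_zones = n_zones,
    initial_delay = initial_delay,
    gestation_min = gestation_min, gestation_max = gestation_max,
    adult_age = adult_age, mating_age = mating_age, initial_age = initial_age,
    n_initial_females = n_initial_females, n_initial_males = n_initial_males,
    horizon = horizon, seed = seed,
    lifespan = lifespan, sink = sink
  )
  class(p) <- "simulation_params"
  validate_params(p)
  p
}

scalar_num <- function(v) is.numeric(v) && length(v) == 1L && !is.na(v)

#' Validate a simulation_params object
#'
#' Checks every field's domain and throws an error naming the offending field.
#' Called by [simulation_params()] and [load_config()].
#'
#' @param p A `simulation_params` object.
#' @return `p`, invisibly, if valid.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "simulation_params"))
  probs <- c("mate_readiness", "p_male")
  for (f in probs) {
    if (!scalar_num(p[[f]]) || p[[f]] < 0 || p[[f]] > 1) {
      stop(sprintf("invalid config: '%s' must be a probability in [0, 1]", f),
           call. = FALSE)
    }
  }
  nonneg <- c("litter_sd", "initial_delay", "adult_age", "mating_age",
              "initial_age")
  for (f in nonneg) {
    if (!scalar_num(p[[f]]) || p[[f]] < 0) {
      stop(sprintf("invalid config: '%s' must be non-negative", f),
           call. = FALSE)
    }
  }
  if (!scalar_num(p$litter_mean)) {
    stop("invalid config: 'litter_mean' must be a number", call. = FALSE)
  }
  if (!scalar_num(p$litter_cap) || p$litter_cap < 0) {
    stop("invalid config: 'litter_cap' must be non-negative", call. = FALSE)
  }
  for (f in c("gestation_min", "gestation_max")) {
    if (!scalar_num(p[[f]]) || p[[f]] < 1) {
      stop(sprintf("invalid config: '%s' must be at least 1 day", f),
           call. = FALSE)
    }
  }
  if (p$gestation_min > p$gestation_max) {
    stop("invalid config: 'gestation_min' must not exceed 'gestation_max'",
         call. = FALSE)
  }
  for (f in c("n_initial_females", "n_initial_males")) {
    if (!scalar_num(p[[f]]) || p[[f]] < 0 || p[[f]] != round(p[[f]])) {
      stop(sprintf("invalid config: '%s' must be a non-negative integer", f),
           call. = FALSE)
    }
  }
  if (!scalar_num(p$n_zones) || p$n_zones < 1 || p$n_zones != round(p$n_zones)) {
    stop("invalid config: 'n_zones' must be a positive integer", call. = FALSE)
  }
  if (!scalar_num(p$horizon) || p$horizon <= 0) {
    stop("invalid config: 'horizon' must be positive", call. = FALSE)
  }
  if (!scalar_num(p$seed) || p$seed != round(p$seed)) {
    stop("invalid config: 'seed' must be an integer", call. = FALSE)
  }
  if (!inherits(p$lifespan, "lifespan_params")) {
    stop("invalid config: 'lifespan' must be a lifespan_params object",
         call. = FALSE)
  }
  if (!inherits(p$sink, "sink_params")) {
    stop("invalid config: 'sink' must be a sink_params object", call. = FALSE)
  }
  validate_sink_params(p$sink)
  invisible(p)
}

#' @export
print.simulation_params <- function(x, ...) {
  cat("Simulation parameters\n")
  cat(sprintf("  mate readiness : %.4g /female/day (delay %d d)\n",
              x$mate_readiness, as.integer(x$initial_delay)))
  cat(sprintf("  litter size    : Normal(%.3g, %.3g), sex ratio p(male) = %.3g\n",
              x$litter_mean, x$litter_sd, x$p_male))
  cat(sprintf("  gestation      : uniform on [%d, %d] days\n",
              as.integer(x$gestation_min), as.integer(x$gestation_max)))
  cat(sprintf("  founders       : %dF + %dM at age %d d; adult age %d d\n",
              as.integer(x$n_initial_females), as.integer(x$n_initial_males),
              as.integer(x$initial_age), as.integer(x$adult_age)))
  cat(sprintf("  zones          : %s\n",
              if (x$zone_mode == "none") "none"
              else sprintf("natal bookkeeping, %d zones", as.integer(x$n_zones))))
  if (x$sink$enabled) {
    cat(sprintf(paste0("  sink           : ON (N_crit ind %d / soc %d, ",
                       "p_abandon %.3g, p_beautiful %.3g)\n"),
                as.integer(x$sink$n_crit_individual),
                as.integer(x$sink$n_crit_social),
                x$sink$p_abandon, x$sink$p_beautiful))
  } else {
    cat("  sink           : off (pure growth phase)\n")
  }
  cat(sprintf("  horizon %d days, seed %d\n",
              as.integer(x$horizon), as.integer(x$seed)))
  invisible(x)
}
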