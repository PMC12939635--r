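## Behavioral-sink mechanisms: deviation decay, newborn deviation,
## "beautiful ones" assignment and litter abandonment. All four are no-ops
## when the sink is disabled, which reduces the engine to the pure
## growth-phase model.

#' Daily deviation-factor decay under crowding
#'
#' If the living population N exceeds the individual critical density, every
#' living mouse's deviation factor is multiplied once by
#' `n_crit_individual / N` (strictly below 1), so an individual's deviation
#' never increases during its lifetime and the population mean degrades for
#' as long as crowding persists. Comparison is strict: N equal to the
#' threshold leaves deviations unchanged.
#'
#' @param state A population state.
#' @param sink A [sink_params()] object.
#' @return The state, invisibly (modified in place).
#' @export
apply_deviation_decay <- function(state, sink) {
  if (!sink$enabled) return(invisible(state))
  alive <- living(state)
  n <- length(alive)
  if (n > sink$n_crit_individual) {
    state$deviation[alive] <- state$deviation[alive] * (sink$n_crit_individual / n)
  }
  invisible(state)
}

#' Deviation factor of a newborn
#'
#' The arithmetic mean of the parents' deviation factors. A pup can therefore
#' exceed one parent's value, but never the larger of the two, so breeding
#' cannot raise the population mean above the breeders' level.
#'
#' @param mother_deviation,father_deviation Parental deviation factors in
#'   `[0, 1]` (vectorised).
#' @return The pup's deviation factor.
#' @export
newborn_deviation <- function(mother_deviation, father_deviation) {
  if (any(mother_deviation < 0 | mother_deviation > 1 |
            father_deviation < 0 | father_deviation > 1)) {
    stop("newborn_deviation: parental deviations must lie in [0, 1]",
         call. = FALSE)
  }
  (mother_deviation + father_deviation) / 2
}

#' Assign "beautiful ones"
#'
#' While the living population exceeds the social critical density, every
#' living adult male not yet tested takes a single lifetime Bernoulli test:
#' with probability `p_beautiful` he permanently becomes a beautiful one —
#' withdrawn from mating and excluded from father selection. Males already
#' adult when the threshold is first crossed are tested that day; males
#' reaching adulthood during crowding are tested then. A male is never
#' re-tested.
#'
#' @param state A population state.
#' @param sink A [sink_params()] object.
#' @param adult_age Census adulthood threshold in days.
#' @return The state, invisibly (modified in place).
#' @export
assign_beautiful <- function(state, sink, adult_age) {
  if (!sink$enabled) return(invisible(state))
  alive <- living(state)
  if (length(alive) <= sink$n_crit_social) return(invisible(state))
  cand <- alive[state$is_male[alive] & !state$beautiful_tested[alive] &
                  state$day - state$birth_day[alive] >= adult_age]
  if (length(cand) == 0L) return(invisible(state))
  state$beautiful_tested[cand] <- TRUE
  hit <- stats::runif(length(cand)) < sink$p_beautiful
  state$beautiful[cand[hit]] <- TRUE
  invisible(state)
}

#' Litter abandonment check at delivery
#'
#' Returns `TRUE` (the whole litter is abandoned, no pups enter the roster)
#' with probability `p_abandon` if and only if the current living population
#' strictly exceeds the social critical density; otherwise `FALSE`. The
#' mother's pregnancy is consumed either way; abandoned litters are tallied.
#'
#' @param state A population state.
#' @param sink A [sink_params()] object.
#' @param mother Roster id of the female delivering today.
#' @return Logical: abandon this litter?
#' @export
abandonment_check <- function(state, sink, mother) {
  if (!sink$enabled) return(FALSE)
  n <- length(living(state))
  if (n <= sink$n_crit_social) return(FALSE)
  abandon <- stats::runif(1) < sink$p_abandon
  if (abandon) {
    state$abandoned_today <- state$abandoned_today + 1L
    state$cum_abandoned <- state$cum_abandoned + 1L
  }
  abandon
}
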