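## Agent roster and the daily update engine.
##
## The population state is an environment holding one vector per agent field,
## indexed by agent id (ids are never reused; dead mice keep their row so a
## sire's last known deviation factor stays available to litters conceived
## before his death). All per-day operations are vectorised over the roster.

new_state <- function(params) {
  st <- new.env(parent = emptyenv())
  st$day <- 0L
  st$n <- 0L
  st$cap <- 0L
  st$is_male <- logical(0)
  st$birth_day <- integer(0)
  st$deviation <- numeric(0)
  st$beautiful <- logical(0)
  st$beautiful_tested <- logical(0)
  st$pregnant <- logical(0)
  st$due_day <- integer(0)
  st$sire_id <- integer(0)
  st$mother_id <- integer(0)
  st$father_id <- integer(0)
  st$zone <- integer(0)
  st$alive <- logical(0)
  st$cum_births <- 0L
  st$cum_deaths <- 0L
  st$cum_abandoned <- 0L
  st$births_today <- 0L
  st$deaths_today <- 0L
  st$abandoned_today <- 0L
  st$per_zone_births <- if (params$zone_mode == "natal") {
    integer(params$n_zones)
  } else {
    NULL
  }
  st
}

ensure_capacity <- function(st, extra) {
  need <- st$n + extra
  if (need <= st$cap) return(invisible(st))
  new_cap <- max(need, 2L * st$cap, 64L)
  grow <- function(v, fill) c(v, rep(fill, new_cap - length(v)))
  st$is_male <- grow(st$is_male, NA)
  st$birth_day <- grow(st$birth_day, NA_integer_)
  st$deviation <- grow(st$deviation, NA_real_)
  st$beautiful <- grow(st$beautiful, FALSE)
  st$beautiful_tested <- grow(st$beautiful_tested, FALSE)
  st$pregnant <- grow(st$pregnant, FALSE)
  st$due_day <- grow(st$due_day, NA_integer_)
  st$sire_id <- grow(st$sire_id, NA_integer_)
  st$mother_id <- grow(st$mother_id, NA_integer_)
  st$father_id <- grow(st$father_id, NA_integer_)
  st$zone <- grow(st$zone, NA_integer_)
  st$alive <- grow(st$alive, FALSE)
  st$cap <- new_cap
  invisible(st)
}

add_mice <- function(st, is_male, birth_day, deviation, zone,
                     mother_id = NA_integer_, father_id = NA_integer_) {
  k <- length(is_male)
  if (k == 0L) return(invisible(st))
  ensure_capacity(st, k)
  idx <- st$n + seq_len(k)
  st$is_male[idx] <- is_male
  st$birth_day[idx] <- as.integer(birth_day)
  st$deviation[idx] <- deviation
  st$beautiful[idx] <- FALSE
  st$beautiful_tested[idx] <- FALSE
  st$pregnant[idx] <- FALSE
  st$due_day[idx] <- NA_integer_
  st$sire_id[idx] <- NA_integer_
  st$mother_id[idx] <- rep_len(as.integer(mother_id), k)
  st$father_id[idx] <- rep_len(as.integer(father_id), k)
  st$zone[idx] <- rep_len(as.integer(zone), k)
  st$alive[idx] <- TRUE
  st$n <- st$n + k
  invisible(st)
}

living <- function(st) which(st$alive[seq_len(st$n)])

#' Initialise the founding population
#'
#' Creates the day-0 roster: `n_initial_females` females and `n_initial_males`
#' males (default 4 + 4, the eight founders introduced into the universe),
#' all aged `initial_age` (their `birth_day` is `-initial_age`), deviation
#' factor 1, not pregnant, not beautiful. When `zone_mode = "natal"` founders
#' get zones drawn uniformly at random (consuming the current RNG stream).
#'
#' @param params A [simulation_params()] object.
#' @return A population state (an environment; see [step_day()]).
#' @export
init_population <- function(params) {
  validate_params(params)
  st <- new_state(params)
  nf <- as.integer(params$n_initial_females)
  nm <- as.integer(params$n_initial_males)
  k <- nf + nm
  if (k > 0L) {
    zone <- if (params$zone_mode == "natal") {
      sample.int(params$n_zones, k, replace = TRUE) - 1L
    } else {
      NA_integer_
    }
    add_mice(st,
             is_male = rep(c(FALSE, TRUE), c(nf, nm)),
             birth_day = rep(-as.integer(params$initial_age), k),
             deviation = rep(1, k),
             zone = zone)
  }
  st
}

#' Count living adults
#'
#' Number of living mice whose age (`day - birth_day`) is at least
#' `adult_age`.
#'
#' @param state A population state.
#' @param adult_age Census adulthood threshold in days.
#' @return Integer count.
#' @export
count_adults <- function(state, adult_age) {
  alive <- living(state)
  sum(state$day - state$birth_day[alive] >= adult_age)
}

#' Apply daily mortality
#'
#' Each living mouse dies during the day with its sex- and age-specific
#' hazard [daily_death_probability()]. A pregnant female's death cancels her
#' litter. Deaths are tallied into the day's record.
#'
#' @param state A population state.
#' @param params A [simulation_params()] object.
#' @return The state, invisibly (modified in place).
#' @export
apply_mortality <- function(state, params) {
  alive <- living(state)
  if (length(alive) == 0L) return(invisible(state))
  age <- state$day - state$birth_day[alive]
  h <- numeric(length(alive))
  m <- state$is_male[alive]
  if (any(m)) h[m] <- daily_death_probability(params$lifespan, "male", age[m])
  if (any(!m)) h[!m] <- daily_death_probability(params$lifespan, "female", age[!m])
  dies <- stats::runif(length(alive)) < h
  if (any(dies)) {
    dead <- alive[dies]
    state$alive[dead] <- FALSE
    # a pregnant female's death cancels her litter
    state$pregnant[dead] <- FALSE
    state$due_day[dead] <- NA_integer_
    state$deaths_today <- state$deaths_today + length(dead)
    state$cum_deaths <- state$cum_deaths + length(dead)
  }
  invisible(state)
}

#' Sample one litter size
#'
#' Draws from the Gaussian litter-size distribution, scales by the mother's
#' individual deviation factor, rounds half away from zero and clamps below
#' at 0 (and above at `cap` if finite). A crowding-degraded mother
#' (deviation near 0) therefore delivers few or no pups.
#'
#' @param litter_mean,litter_sd Gaussian parameters (pups).
#' @param mother_deviation The mother's deviation factor in `[0, 1]`.
#' @param cap Optional upper clamp (default `Inf`).
#' @return A non-negative integer litter size.
#' @export
sample_litter_size <- function(litter_mean, litter_sd, mother_deviation,
                               cap = Inf) {
  x <- mother_deviation * stats::rnorm(1, litter_mean, litter_sd)
  n <- sign(x) * floor(abs(x) + 0.5)  # round half away from zero
  as.integer(min(max(0, n), cap))
}

#' Deliver due litters
#'
#' Every living female whose due day is today delivers. First the litter
#' abandonment check runs ([abandonment_check()]); if the litter is kept, its
#' size is drawn by [sample_litter_size()] and the pups enter the roster with
#' today's birth day, sex male with probability `p_male`, deviation factor
#' equal to the parents' mean ([newborn_deviation()]; a sire who died during
#' gestation contributes his last known value) and, under natal zone mode,
#' the mother's zone. The pregnancy is consumed either way.
#'
#' @inheritParams apply_mortality
#' @return The state, invisibly (modified in place).
#' @export
deliver_litters <- function(state, params) {
  alive <- living(state)
  due <- alive[state$pregnant[alive] &
                 !is.na(state$due_day[alive]) &
                 state$due_day[alive] == state$day]
  if (length(due) == 0L) return(invisible(state))
  natal <- params$zone_mode == "natal"
  for (i in due) {
    if (!abandonment_check(state, params$sink, i)) {
      n_pups <- sample_litter_size(params$litter_mean, params$litter_sd,
                                   state$deviation[i], params$litter_cap)
      if (n_pups > 0L) {
        sire <- state$sire_id[i]
        dev <- newborn_deviation(state$deviation[i], state$deviation[sire])
        add_mice(state,
                 is_male = stats::runif(n_pups) < params$p_male,
                 birth_day = state$day,
                 deviation = rep(dev, n_pups),
                 zone = state$zone[i],
                 mother_id = i, father_id = sire)
        state$births_today <- state$births_today + n_pups
        state$cum_births <- state$cum_births + n_pups
        if (natal) {
          z <- state$zone[i] + 1L
          state$per_zone_births[z] <- state$per_zone_births[z] + n_pups
        }
      }
    }
    state$pregnant[i] <- FALSE
    state$due_day[i] <- NA_integer_
    state$sire_id[i] <- NA_integer_
  }
  invisible(state)
}

#' Attempt conceptions
#'
#' From `initial_delay` onwards, each living non-pregnant female of mating
#' age attempts conception with probability `mate_readiness`: a candidate
#' father is drawn uniformly from the living non-beautiful males of mating
#' age, and the attempt succeeds with probability equal to his deviation
#' factor. On success the female becomes pregnant with a due day a uniform
#' integer `gestation_min..gestation_max` days ahead and the sire is
#' recorded. A failed attempt (including no eligible male) does nothing
#' further for her today.
#'
#' @inheritParams apply_mortality
#' @return The state, invisibly (modified in place).
#' @export
attempt_conceptions <- function(state, params) {
  if (state$day < params$initial_delay) return(invisible(state))
  alive <- living(state)
  if (length(alive) == 0L) return(invisible(state))
  age <- state$day - state$birth_day[alive]
  females <- alive[!state$is_male[alive] & !state$pregnant[alive] &
                     age >= params$mating_age]
  if (length(females) == 0L) return(invisible(state))
  attempting <- females[stats::runif(length(females)) < params$mate_readiness]
  if (length(attempting) == 0L) return(invisible(state))
  males <- alive[state$is_male[alive] & !state$beautiful[alive] &
                   age >= params$mating_age]
  if (length(males) == 0L) return(invisible(state))
  father <- males[sample.int(length(males), length(attempting), replace = TRUE)]
  ok <- stats::runif(length(attempting)) < state$deviation[father]
  if (any(ok)) {
    conceived <- attempting[ok]
    g <- params$gestation_min +
      sample.int(params$gestation_max - params$gestation_min + 1L,
                 length(conceived), replace = TRUE) - 1L
    state$pregnant[conceived] <- TRUE
    state$due_day[conceived] <- state$day + as.integer(g)
    state$sire_id[conceived] <- father[ok]
  }
  invisible(state)
}

make_record <- function(state, params) {
  alive <- living(state)
  n_total <- length(alive)
  rec <- list(
    day = state$day,
    n_total = n_total,
    n_adult = count_adults(state, params$adult_age),
    births = state$births_today,
    deaths = state$deaths_today,
    abandoned_litters = state$abandoned_today,
    n_pregnant = sum(state$pregnant[alive]),
    n_beautiful = sum(state$beautiful[alive]),
    # mean deviation is recorded to 6 decimals (the CSV schema's precision)
    mean_deviation = if (n_total > 0L) {
      round(mean(state$deviation[alive]), 6)
    } else {
      NA_real_
    }
  )
  if (params$zone_mode == "natal") {
    rec$per_zone_births <- state$per_zone_births
  }
  rec
}

#' Advance the simulation by one day
#'
#' Executes the daily cycle in fixed order: (1) advance the day counter;
#' (2) mortality ([apply_mortality()]); (3) deliveries ([deliver_litters()]);
#' (4) conceptions ([attempt_conceptions()]); (5) end-of-day density effects
#' on the end-of-day census, newborns included ([apply_deviation_decay()]
#' then [assign_beautiful()]); (6) emit the day's census record.
#'
#' @inheritParams apply_mortality
#' @return A list: the day's record fields (`day`, `n_total`, `n_adult`,
#'   `births`, `deaths`, `abandoned_litters`, `n_pregnant`, `n_beautiful`,
#'   `mean_deviation`, and `per_zone_births` under natal zone mode). The
#'   state is modified in place.
#' @export
step_day <- function(state, params) {
  state$day <- state$day + 1L
  state$births_today <- 0L
  state$deaths_today <- 0L
  state$abandoned_today <- 0L
  if (!is.null(state$per_zone_births)) {
    state$per_zone_births[] <- 0L
  }
  apply_mortality(state, params)
  deliver_litters(state, params)
  attempt_conceptions(state, params)
  apply_deviation_decay(state, params$sink)
  assign_beautiful(state, params$sink, params$adult_age)
  make_record(state, params)
}

#' Run one simulation
#'
#' Seeds the RNG with `params$seed`, initialises the founders and iterates
#' [step_day()] until the horizon or extinction, whichever comes first.
#'
#' @param params A [simulation_params()] object.
#' @return An object of class `utopia_run`: a list with elements `params`,
#'   `seed`, `records` (a data frame with one row per day, day 0 included),
#'   `extinction_day` (first day with no living mice, or `NA`),
#'   `first_birth_day` and `last_birth_day` (`NA` if no births).
#' @examples
#' run <- run_simulation(simulation_params(horizon = 120, seed = 7))
#' peak(run)
#' @export
run_simulation <- function(params) {
  validate_params(params)
  set.seed(as.integer(params$seed))
  state <- init_population(params)
  horizon <- as.integer(params$horizon)
  n_zone_cols <- if (params$zone_mode == "natal") params$n_zones else 0L
  mat <- matrix(NA_real_, nrow = horizon + 1L, ncol = 9L + n_zone_cols)
  rec <- make_record(state, params)
  mat[1L, ] <- unlist(rec, use.names = FALSE)
  n_days <- 0L
  if (rec$n_total > 0L) {
    for (d in seq_len(horizon)) {
      rec <- step_day(state, params)
      mat[d + 1L, ] <- unlist(rec, use.names = FALSE)
      n_days <- d
      if (rec$n_total == 0L) break
    }
  }
  mat <- mat[seq_len(n_days + 1L), , drop = FALSE]
  records <- as.data.frame(mat)
  base_cols <- c("day", "n_total", "n_adult", "births", "deaths",
                 "abandoned_litters", "n_pregnant", "n_beautiful",
                 "mean_deviation")
  names(records) <- c(base_cols,
                      if (n_zone_cols > 0L) paste0("zone_", seq_len(n_zone_cols) - 1L))
  int_cols <- setdiff(names(records), "mean_deviation")
  records[int_cols] <- lapply(records[int_cols], as.integer)
  ext <- records$day[records$n_total == 0L]
  birth_days <- records$day[records$births > 0L]
  structure(
    list(
      params = params,
      seed = as.integer(params$seed),
      records = records,
      extinction_day = if (length(ext)) ext[1L] else NA_integer_,
      first_birth_day = if (length(birth_days)) birth_days[1L] else NA_integer_,
      last_birth_day = if (length(birth_days)) birth_days[length(birth_days)] else NA_integer_
    ),
    class = "utopia_run"
  )
}
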