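#' Sex-specific lifespan parameters
#'
#' Parameters of the parametric survivorship law
#' \deqn{S_i(t) = 1 - \exp(-\alpha_i (T_{i,\max} - t)),}
#' where \eqn{i} indexes sex, \eqn{t} is age in days, \eqn{T_{i,\max}} is the
#' maximum attainable age and \eqn{\alpha_i} controls the curvature. Defaults
#' are the values used for the simulated universe: laboratory-mouse
#' survivorship rescaled so that males can reach almost 1000 days and females
#' proportionally 1143 days, matching the very old survivors observed at the
#' end of the original experiment.
#'
#' @param t_max_male,t_max_female Maximum age in days, by sex.
#' @param alpha_male,alpha_female Curvature parameter in 1/day, by sex.
#' @return An object of class `lifespan_params` (a named list).
#' @examples
#' lp <- lifespan_params()
#' survivorship(lp, "female", 0:3)
#' @export
lifespan_params <- function(t_max_male = 1000, t_max_female = 1143,
                            alpha_male = 4.87e-3, alpha_female = 4.16e-3) {
  lp <- list(
    t_max_male = t_max_male, t_max_female = t_max_female,
    alpha_male = alpha_male, alpha_female = alpha_female
  )
  for (f in names(lp)) {
    v <- lp[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("lifespan_params: '%s' must be a single positive number", f),
           call. = FALSE)
    }
  }
  class(lp) <- "lifespan_params"
  lp
}

sex_field <- function(params, sex, what) {
  sex <- match.arg(sex, c("male", "female"))
  params[[paste0(what, "_", sex)]]
}

#' Survivorship: probability of being alive at a given age
#'
#' Evaluates \eqn{S(t) = 1 - \exp(-\alpha (T_{\max} - t))}, clamped to
#' \eqn{[0, 1]}; ages at or beyond \eqn{T_{\max}} return 0. Note that
#' \eqn{S(0) < 1} (about 0.992 for males at the defaults): the curve is a
#' population survivorship fit, and only its ratios matter once converted to a
#' conditional daily hazard (see [daily_death_probability()]).
#'
#' @param params A [lifespan_params()] object.
#' @param sex `"male"` or `"female"`.
#' @param age Age in days (vectorised, must be non-negative).
#' @return Survival probabilities in `[0, 1]`.
#' @seealso [daily_death_probability()], [sample_survives()]
#' @export
survivorship <- function(params, sex, age) {
  stopifnot(inherits(params, "lifespan_params"))
  if (any(age < 0)) stop("survivorship: age must be non-negative", call. = FALSE)
  alpha <- sex_field(params, sex, "alpha")
  t_max <- sex_field(params, sex, "t_max")
  pmin(1, pmax(0, 1 - exp(-alpha * (t_max - age))))
}

#' Conditional daily death probability (hazard)
#'
#' Converts the survivorship curve into the per-day hazard that drives agent
#' deaths: \eqn{h(t) = (S(t) - S(t+1)) / S(t)}, the probability of dying
#' during day \eqn{t} given survival to its start. Any age at or beyond
#' \eqn{T_{\max} - 1} gives \eqn{h = 1} (death is certain because
#' \eqn{S(T_{\max}) = 0}). The product \eqn{\prod_{a<T} (1 - h(a))} equals
#' \eqn{S(T)/S(0)} exactly, so a cohort of agents killed by daily hazard draws
#' reproduces the survivorship curve as the fraction still alive.
#'
#' @inheritParams survivorship
#' @return Hazards in `[0, 1]` (vectorised over `age`).
#' @export
daily_death_probability <- function(params, sex, age) {
  stopifnot(inherits(params, "lifespan_params"))
  if (any(age < 0)) {
    stop("daily_death_probability: age must be non-negative", call. = FALSE)
  }
  t_max <- sex_field(params, sex, "t_max")
  s0 <- survivorship(params, sex, age)
  s1 <- survivorship(params, sex, pmin(age + 1, t_max))
  h <- ifelse(s0 > 0, (s0 - s1) / s0, 1)
  h[age >= t_max - 1] <- 1
  pmin(1, pmax(0, h))
}

#' Sample daily survival for one or more agents
#'
#' Bernoulli draw against [daily_death_probability()]; `TRUE` means the agent
#' survives the day. Uses the session RNG stream, so results are reproducible
#' under `set.seed()`.
#'
#' @inheritParams survivorship
#' @return Logical vector, `TRUE` where the agent survives.
#' @export
sample_survives <- function(params, sex, age) {
  h <- daily_death_probability(params, sex, age)
  stats::runif(length(h)) >= h
}
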