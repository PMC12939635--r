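## Packaged reference data: the experiment's anchor points and the three
## calibrated parameter presets.

#' Experimental anchor points
#'
#' The six census anchors reported for the original universe: 8 founders at
#' day 0, first litter on day 104, 620 mice (150 adults) on day 315, 2200
#' mice on day 560, and the last litter around day 600. Anchors are used for
#' comparison ([compare_to_anchors()]) and run selection, never for fitting.
#'
#' @return A data frame with columns `day` (`NA` for the event anchors),
#'   `measure` (`n_total`, `n_adult`, `first_litter_day`, `last_litter_day`)
#'   and `value`.
#' @export
anchors <- function() {
  path <- system.file("extdata", "calhoun_anchors.csv",
                      package = "mouseutopia", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Calibrated parameter presets
#'
#' The three exemplary growth-phase parameter sets whose ensembles are
#' consistent with the experiment's day-315 census: all Gaussian litters,
#' no sector role, and
#' \itemize{
#'   \item `set1`: readiness 0.01, litter 10 +/- 1, p(male) 0.54, delay 60;
#'   \item `set2`: readiness 0.01, litter 8 +/- 2, p(male) 0.52, delay 60;
#'   \item `set3`: readiness 0.02, litter 10 +/- 4, p(male) 0.52, delay 70.
#' }
#' Engine settings not named by a preset take the [simulation_params()]
#' defaults; `...` overrides any field (e.g. `horizon`, `seed`, `sink`).
#'
#' @param name One of `"set1"`, `"set2"`, `"set3"`.
#' @param ... Named overrides applied on top of the preset.
#' @return A [simulation_params()] object.
#' @examples
#' preset_params("set1")$p_male
#' preset_params("set3", horizon = 100, seed = 3)
#' @export
preset_params <- function(name, ...) {
  name <- match.arg(name, c("set1", "set2", "set3"))
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "mouseutopia", mustWork = TRUE)
  p <- load_config(path)
  overrides <- list(...)
  if (length(overrides)) p <- modify_params(p, overrides)
  p
}

#' Compare a run against the experimental anchors
#'
#' One row per anchor with the simulated value and its absolute and relative
#' deviation. Census anchors compare the run's record on the anchor day
#' (marked not covered if the run ended earlier); the first/last-litter
#' anchors compare the run's first and last birth days.
#'
#' @param run A `utopia_run`.
#' @return A data frame with columns `day`, `measure`, `value`, `simulated`,
#'   `abs_dev`, `rel_dev`, `covered`.
#' @export
compare_to_anchors <- function(run) {
  stopifnot(inherits(run, "utopia_run"))
  a <- anchors()
  sim <- vapply(seq_len(nrow(a)), function(i) {
    m <- a$measure[i]
    if (m == "first_litter_day") return(as.numeric(run$first_birth_day))
    if (m == "last_litter_day") return(as.numeric(run$last_birth_day))
    rec <- run_at_day(run, a$day[i])
    if (is.null(rec)) NA_real_ else as.numeric(rec[[m]])
  }, numeric(1))
  a$simulated <- sim
  a$abs_dev <- sim - a$value
  a$rel_dev <- a$abs_dev / a$value
  a$covered <- !is.na(sim)
  a
}
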