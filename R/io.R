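## Configuration files, trajectory CSVs, run manifests, ensembles and the
## calibration sweep.

config_error <- function(msg) {
  stop(errorCondition(msg, class = c("utopia_config_error", "error")))
}

top_level_fields <- function() {
  setdiff(names(formals(simulation_params)), c("lifespan", "sink"))
}

#' Modify simulation parameters
#'
#' Applies named overrides to a [simulation_params()] object and revalidates.
#' `lifespan` and `sink` accept either parameter objects or plain named lists
#' of overrides for the nested fields.
#'
#' @param params A `simulation_params` object.
#' @param overrides Named list of fields to replace.
#' @return A new, validated `simulation_params` object.
#' @export
modify_params <- function(params, overrides) {
  stopifnot(inherits(params, "simulation_params"))
  known <- c(top_level_fields(), "lifespan", "sink")
  bad <- setdiff(names(overrides), known)
  if (length(bad)) {
    config_error(sprintf("invalid config: unknown field(s): %s",
                         paste(bad, collapse = ", ")))
  }
  p <- unclass(params)
  for (f in names(overrides)) {
    v <- overrides[[f]]
    if (f == "lifespan" && !inherits(v, "lifespan_params")) {
      v <- do.call(lifespan_params, utils::modifyList(unclass(p$lifespan), v))
    }
    if (f == "sink" && !inherits(v, "sink_params")) {
      v <- do.call(sink_params, utils::modifyList(unclass(p$sink), v))
    }
    p[[f]] <- v
  }
  class(p) <- "simulation_params"
  tryCatch(validate_params(p), error = function(e) config_error(conditionMessage(e)))
  p
}

#' Load a configuration file
#'
#' Reads a YAML configuration, applies it over the [simulation_params()]
#' defaults and validates. Unknown keys (top level or inside the `lifespan` /
#' `sink` sections) are errors, as are out-of-domain values; error messages
#' name the offending field. An empty file yields the full defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated `simulation_params` object.
#' @seealso [save_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    config_error(sprintf("config file not found: %s", path))
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) config_error("invalid config: not a key-value mapping")
  for (sec in c("lifespan", "sink")) {
    if (!is.null(cfg[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]),
                     names(formals(get(paste0(sec, "_params")))))
      if (length(bad)) {
        config_error(sprintf("invalid config: unknown field(s) in '%s': %s",
                             sec, paste(bad, collapse = ", ")))
      }
    }
  }
  modify_params(simulation_params(), cfg)
}

params_to_list <- function(params) {
  p <- unclass(params)
  p$lifespan <- unclass(p$lifespan)
  p$sink <- unclass(p$sink)
  p
}

#' Save a configuration file
#'
#' Serialises a `simulation_params` object to YAML. [load_config()] of the
#' result reproduces the object exactly (round trip).
#'
#' @param params A `simulation_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path) {
  stopifnot(inherits(params, "simulation_params"))
  yaml::write_yaml(params_to_list(params), path)
  invisible(path)
}

#' Write a run's daily records to CSV
#'
#' One row per simulated day with columns `day`, `n_total`, `n_adult`,
#' `births`, `deaths`, `abandoned_litters`, `n_pregnant`, `n_beautiful`,
#' `mean_deviation` and, under natal zone mode, `zone_0 ..
#' zone_{n_zones-1}`. `mean_deviation` is written with fixed 6 decimal
#' places so output is byte-deterministic.
#'
#' @param run A `utopia_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_timeseries()]
#' @export
write_timeseries <- function(run, path) {
  stopifnot(inherits(run, "utopia_run"))
  df <- run$records
  md <- df$mean_deviation
  df$mean_deviation <- ifelse(is.na(md), "NA", sprintf("%.6f", md))
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Read a trajectory CSV back into a run object
#'
#' Rebuilds a `utopia_run` (with `params = NULL`, `seed = NA`) from a CSV
#' written by [write_timeseries()], recovering the extinction and first/last
#' birth days from the records. Sufficient for re-summarisation and anchor
#' comparison.
#'
#' @param path Path to a trajectory CSV.
#' @return A `utopia_run`.
#' @export
read_timeseries <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  run_from_records(records)
}

run_from_records <- function(records, params = NULL, seed = NA_integer_) {
  ext <- records$day[records$n_total == 0L]
  birth_days <- records$day[records$births > 0L]
  structure(
    list(
      params = params, seed = seed, records = records,
      extinction_day = if (length(ext)) ext[1L] else NA_integer_,
      first_birth_day = if (length(birth_days)) birth_days[1L] else NA_integer_,
      last_birth_day = if (length(birth_days)) birth_days[length(birth_days)] else NA_integer_
    ),
    class = "utopia_run"
  )
}

#' Write an ensemble summary to CSV
#'
#' One row per day, columns `<measure>_<stat>` as in [ensemble_summary()].
#'
#' @param summary An `ensemble_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE)
  invisible(path)
}

#' Run a Monte-Carlo ensemble
#'
#' Runs `n_runs` independent simulations; run `k` uses seed `base_seed + k`,
#' so the ensemble is reproducible and runs are independent of execution
#' order.
#'
#' @param params A [simulation_params()] object (its own `seed` is ignored).
#' @param n_runs Number of runs (at least 1).
#' @param base_seed Base seed; default `params$seed`.
#' @return An object of class `utopia_ensemble`: list with `runs` (list of
#'   `utopia_run`), `summary` ([ensemble_summary()]), `params`, `n_runs`,
#'   `base_seed`.
#' @examples
#' ens <- run_ensemble(simulation_params(horizon = 60), n_runs = 3, base_seed = 10)
#' ens$summary[ens$summary$day == 60, ]
#' @export
run_ensemble <- function(params, n_runs, base_seed = params$seed) {
  stopifnot(inherits(params, "simulation_params"), n_runs >= 1)
  runs <- lapply(seq_len(n_runs), function(k) {
    run_simulation(modify_params(params, list(seed = base_seed + k)))
  })
  structure(
    list(runs = runs, summary = ensemble_summary(runs), params = params,
         n_runs = as.integer(n_runs), base_seed = as.integer(base_seed)),
    class = "utopia_ensemble"
  )
}

#' Calibration sweep over a parameter grid
#'
#' Runs an ensemble at every grid point and ranks points by the mean
#' [consistency()] metric of the day-`at_day` census (runs extinct by then
#' count as census 0). Also counts each point's runs passing
#' [select_matching_runs()].
#'
#' @param grid A data frame; each column is a `simulation_params` field, each
#'   row a grid point.
#' @param params Base parameters the grid overrides (default
#'   [simulation_params()]).
#' @param n_runs Ensemble size per grid point.
#' @param base_seed Base seed; grid point `i` uses seeds
#'   `base_seed + (i-1) * n_runs + 1..n_runs`.
#' @param at_day Evaluation day (default 315).
#' @param expected_total,expected_adult,tol Passed to
#'   [select_matching_runs()].
#' @return The grid with added columns `mean_consistency` and `n_matching`,
#'   ranked ascending by `mean_consistency`.
#' @export
calibrate <- function(grid, params = simulation_params(), n_runs = 20,
                      base_seed = params$seed, at_day = 315,
                      expected_total = 620, expected_adult = 150, tol = 20) {
  stopifnot(is.data.frame(grid))
  if (nrow(grid) == 0L) config_error("calibrate: empty grid")
  res <- lapply(seq_len(nrow(grid)), function(i) {
    overrides <- as.list(grid[i, , drop = FALSE])
    pt <- modify_params(params, overrides)
    ens <- run_ensemble(pt, n_runs,
                        base_seed = base_seed + (i - 1L) * n_runs)
    census <- vapply(ens$runs, function(r) {
      rec <- run_at_day(r, at_day)
      if (is.null(rec)) c(0, 0) else c(rec$n_total, rec$n_adult)
    }, numeric(2))
    matched <- select_matching_runs(ens$runs, expected_total, expected_adult,
                                    tol, at_day)
    data.frame(
      mean_consistency = mean(consistency(census[1, ], census[2, ])),
      n_matching = length(matched)
    )
  })
  out <- cbind(grid, do.call(rbind, res))
  out <- out[order(out$mean_consistency), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a run manifest
#'
#' A JSON manifest recording the tool version, timestamp, seed, full
#' configuration snapshot and output paths, written next to the outputs so
#' any result can be reproduced bit-for-bit from its manifest.
#'
#' @param params The `simulation_params` used (configuration snapshot).
#' @param seed The seed (or base seed) the outputs were produced with.
#' @param outputs Character vector of output paths.
#' @param path Manifest path; default first output + `.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(params, seed, outputs,
                           path = paste0(outputs[1], ".manifest.json")) {
  manifest <- list(
    tool = "mouseutopia",
    version = as.character(utils::packageVersion("mouseutopia")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    outputs = outputs,
    config = params_to_list(params)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
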