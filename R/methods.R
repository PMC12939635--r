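## print / summary / plot methods for runs and ensembles.

#' @export
print.utopia_run <- function(x, ...) {
  last <- x$records[nrow(x$records), ]
  pk <- peak(x)
  cat(sprintf("<utopia_run> %d days simulated (seed %s)\n",
              last$day, ifelse(is.na(x$seed), "?", x$seed)))
  cat(sprintf("  final census : %d mice (%d adults) on day %d\n",
              last$n_total, last$n_adult, last$day))
  cat(sprintf("  peak         : %d mice on day %d\n", pk["size"], pk["day"]))
  cat(sprintf("  births       : first %s, last %s; extinction %s\n",
              ifelse(is.na(x$first_birth_day), "none", x$first_birth_day),
              ifelse(is.na(x$last_birth_day), "none", x$last_birth_day),
              ifelse(is.na(x$extinction_day), "not reached", x$extinction_day)))
  invisible(x)
}

#' @export
summary.utopia_run <- function(object, ...) {
  r <- object$records
  out <- list(
    days = max(r$day),
    final = c(n_total = r$n_total[nrow(r)], n_adult = r$n_adult[nrow(r)]),
    peak = peak(object),
    total_births = sum(r$births),
    total_deaths = sum(r$deaths),
    abandoned_litters = sum(r$abandoned_litters),
    first_birth_day = object$first_birth_day,
    last_birth_day = object$last_birth_day,
    extinction_day = object$extinction_day
  )
  class(out) <- "summary.utopia_run"
  out
}

#' @export
print.summary.utopia_run <- function(x, ...) {
  cat(sprintf("Run of %d days: final %d mice (%d adults); peak %d on day %d\n",
              x$days, x$final["n_total"], x$final["n_adult"],
              x$peak["size"], x$peak["day"]))
  cat(sprintf("  %d births, %d deaths, %d abandoned litters\n",
              x$total_births, x$total_deaths, x$abandoned_litters))
  cat(sprintf("  first birth %s, last birth %s, extinction %s\n",
              ifelse(is.na(x$first_birth_day), "none", x$first_birth_day),
              ifelse(is.na(x$last_birth_day), "none", x$last_birth_day),
              ifelse(is.na(x$extinction_day), "not reached", x$extinction_day)))
  invisible(x)
}

#' Plot a run's trajectory
#'
#' Total population and adult counts against time, optionally on a log scale.
#'
#' @param x A `utopia_run`.
#' @param log Plot the count axis logarithmically (default `FALSE`).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.utopia_run <- function(x, log = FALSE, ...) {
  r <- x$records
  graphics::plot(r$day, r$n_total, type = "l",
                 log = if (log) "y" else "",
                 xlab = "day", ylab = "mice",
                 ylim = c(if (log) 1 else 0, max(r$n_total, 1)), ...)
  graphics::lines(r$day, r$n_adult, col = 2)
  graphics::legend("topleft", legend = c("total", "adult"), col = 1:2,
                   lty = 1, bty = "n")
  invisible(x)
}

#' @export
print.utopia_ensemble <- function(x, ...) {
  s <- x$summary
  last <- s[nrow(s), ]
  n_ext <- sum(vapply(x$runs, function(r) !is.na(r$extinction_day), logical(1)))
  cat(sprintf("<utopia_ensemble> %d runs, base seed %d, %d days\n",
              x$n_runs, x$base_seed, last$day))
  cat(sprintf("  final day: total %.1f +/- %.1f (median %g), adult %.1f +/- %.1f\n",
              last$total_mean, last$total_sd, last$total_median,
              last$adult_mean, last$adult_sd))
  cat(sprintf("  %d of %d runs extinct within the horizon\n", n_ext, x$n_runs))
  invisible(x)
}

#' Plot an ensemble's trajectory band
#'
#' Median total population with the interquartile band and the min-max
#' envelope across runs; the adult median is overlaid.
#'
#' @param x A `utopia_ensemble`.
#' @param log Plot the count axis logarithmically (default `FALSE`).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.utopia_ensemble <- function(x, log = FALSE, ...) {
  s <- x$summary
  lo <- if (log) pmax(s$total_min, 1) else s$total_min
  q1 <- if (log) pmax(s$total_q1, 1) else s$total_q1
  graphics::plot(s$day, pmax(s$total_median, if (log) 1 else 0), type = "n",
                 log = if (log) "y" else "",
                 xlab = "day", ylab = "mice",
                 ylim = c(if (log) 1 else 0, max(s$total_max, 1)), ...)
  graphics::polygon(c(s$day, rev(s$day)), c(lo, rev(s$total_max)),
                    col = "grey90", border = NA)
  graphics::polygon(c(s$day, rev(s$day)), c(q1, rev(s$total_q3)),
                    col = "grey75", border = NA)
  graphics::lines(s$day, pmax(s$total_median, if (log) 1 else 0))
  graphics::lines(s$day, pmax(s$adult_median, if (log) 1 else 0), col = 2)
  graphics::legend("topleft",
                   legend = c("total (median)", "adult (median)",
                              "IQR", "min-max"),
                   col = c(1, 2, NA, NA), lty = c(1, 1, NA, NA),
                   fill = c(NA, NA, "grey75", "grey90"),
                   border = NA, bty = "n")
  invisible(x)
}
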