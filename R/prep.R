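#' Smooth a proxy series with a cubic smoothing spline
#'
#' Fits a penalized cubic smoothing spline to the series and returns the
#' fitted curve evaluated on the original time grid.  The smoothing
#' parameter follows the `spar` convention of [stats::smooth.spline()]: the
#' roughness-penalty weight is a monotone increasing function of `spar`,
#' with `spar` near 0 approaching interpolation of the data and `spar`
#' near 1 approaching a linear fit, so the residual sum of squares against
#' the raw data is non-decreasing in `spar`.  Warfare series use
#' `spar = 0.90` and the hydroclimate proxy `spar = 0.65` in the default
#' analysis configuration.
#'
#' Because a heavily smoothed curve can overshoot the range of a bounded
#' index (the warfare index lives in \[0, 6\]), an optional `clip` range is
#' applied to the fitted values.
#'
#' @param series A [proxy_series()] with at least 4 points.
#' @param spar Smoothing parameter in \[0, 1\].
#' @param clip Optional length-2 numeric range to which fitted values are
#'   clipped (e.g. `c(0, 6)` for the warfare index); `NULL` for none.
#' @return A [proxy_series()] on the same time grid.
#' @examples
#' x <- proxy_series(1:50, sin(1:50 / 5) + rnorm(50, sd = 0.1))
#' s <- smooth_spline(x, spar = 0.7)
#' @export
smooth_spline <- function(series, spar, clip = NULL) {
  stopifnot(inherits(series, "proxy_ts"))
  if (length(series$times) < 4) {
    stop("smoothing requires at least 4 points, got ", length(series$times),
         call. = FALSE)
  }
  if (!is.numeric(spar) || length(spar) != 1 || spar < 0 || spar > 1) {
    stop("`spar` must be a single number in [0, 1]", call. = FALSE)
  }
  # A constant or exactly linear series is a fixed point of the smoother
  # (zero roughness penalty and zero residuals); short-circuiting also
  # avoids smooth.spline()'s degenerate-scale warnings on such input.
  lin_resid <- stats::residuals(stats::lm(series$values ~ series$times))
  if (stats::sd(series$values) < 1e-12 ||
      max(abs(lin_resid)) < 1e-10 * max(1, max(abs(series$values)))) {
    fitted <- series$values
  } else {
    sm <- stats::smooth.spline(series$times, series$values, spar = spar,
                               cv = NA, keep.data = FALSE)
    fitted <- stats::predict(sm, series$times)$y
  }
  if (!is.null(clip)) {
    fitted <- pmin(pmax(fitted, min(clip)), max(clip))
  }
  proxy_series(series$times, fitted,
               label = paste0(series$label, " (smoothed)"),
               step = series$step)
}

#' Resample a series onto a uniform calendar grid
#'
#' Evaluates the (typically smoothed) series at `start, start + step, ...,
#' end`, using linear interpolation between neighbouring source points
#' when a target year is absent from the source grid.  The requested
#' window must lie within the source span.
#'
#' @param series A [proxy_series()].
#' @param step Grid spacing in years (the analysis default is 25).
#' @param start,end First and last calendar years AD of the target grid;
#'   `step` must divide `end - start`.
#' @return A [proxy_series()] on the uniform grid with the given `step`.
#' @examples
#' x <- proxy_series(50:1500, rnorm(1451))
#' length(resample(x, 25, 50, 1500)$times)  # 59
#' @export
resample <- function(series, step, start, end) {
  stopifnot(inherits(series, "proxy_ts"))
  if (start < series$times[1] || end > series$times[length(series$times)]) {
    stop(sprintf(
      "requested window AD %s-%s outside source span AD %s-%s",
      format(start), format(end), format(series$times[1]),
      format(series$times[length(series$times)])), call. = FALSE)
  }
  if (end <= start || (end - start) %% step != 0) {
    stop("`step` must divide `end - start` with end > start", call. = FALSE)
  }
  grid <- seq(start, end, by = step)
  vals <- stats::approx(series$times, series$values, xout = grid,
                        method = "linear", ties = "ordered")$y
  proxy_series(grid, vals, label = series$label, step = step)
}

#' Log growth rates of a positive series
#'
#' Computes one-step log rates of change, `log(x[t]) - log(x[t - step])`,
#' the response variable of the dynamic models.  The rate for the step
#' ending at time `t` is stamped at `t`.  All source values must be
#' strictly positive; for the warfare index, which can legitimately be 0,
#' a `floor` can be supplied so that values below it are raised to the
#' floor before taking logs.
#'
#' @param series A [proxy_series()] with strictly positive values (after
#'   flooring, if requested).
#' @param floor Optional positive floor applied as `pmax(values, floor)`
#'   before the log transform (the pipeline default for warfare is 0.1);
#'   its use is reported with a message.  `NULL` to disable.
#' @return A [rate_series()] of length `length(series) - 1`.
#' @examples
#' growth_rates(proxy_series(1:3, c(1, exp(1), exp(2))))$values  # 1 1
#' @export
growth_rates <- function(series, floor = NULL) {
  stopifnot(inherits(series, "proxy_ts"))
  v <- series$values
  if (!is.null(floor)) {
    stopifnot(is.numeric(floor), floor > 0)
    n_floored <- sum(v < floor)
    if (n_floored > 0) {
      message(sprintf("growth_rates: %d value(s) of '%s' raised to floor %g",
                      n_floored, series$label, floor))
      v <- pmax(v, floor)
    }
  }
  if (any(v <= 0)) {
    bad <- series$times[which(v <= 0)[1]]
    stop(sprintf("log rate undefined: non-positive value at year AD %s",
                 format(bad)), call. = FALSE)
  }
  rate_series(series$times[-1], diff(log(v)),
              label = paste0("rate of ", series$label), step = series$step)
}

#' Assemble the aligned analysis table
#'
#' Combines resampled population (normalized and unnormalized SPD),
#' warfare and climate series, plus their log growth rates, into one table
#' whose columns mirror the exchange layout used for the processed series:
#' `calBP`, `yearAD`, `SPDn`, `SPDnn`, `Rn`, `Rnn`, `LithPct`, `War`,
#' `Rwar`.  `calBP` is `1950 - yearAD` (radiocarbon convention).  Rates
#' are stamped at the closing year of their step, so the first row carries
#' `NA` rates.
#'
#' @param spd_n,spd_nn Normalized and unnormalized population proxy series
#'   on the analysis grid.
#' @param climate Climate proxy series on the same grid.
#' @param warfare Warfare index series on the same grid.
#' @param warfare_floor Floor passed to [growth_rates()] for the warfare
#'   series.
#' @return A data frame with the nine columns above.
#' @export
sdata_table <- function(spd_n, spd_nn, climate, warfare,
                        warfare_floor = 0.1) {
  grids <- list(spd_n$times, spd_nn$times, climate$times, warfare$times)
  if (!all(vapply(grids, identical, logical(1), y = spd_n$times))) {
    stop("all series must share the same time grid", call. = FALSE)
  }
  pad <- function(r) c(NA_real_, r$values)
  data.frame(
    calBP = 1950 - spd_n$times,
    yearAD = spd_n$times,
    SPDn = spd_n$values,
    SPDnn = spd_nn$values,
    Rn = pad(growth_rates(spd_n)),
    Rnn = pad(growth_rates(spd_nn)),
    LithPct = climate$values,
    War = warfare$values,
    Rwar = pad(suppressMessages(growth_rates(warfare,
                                             floor = warfare_floor)))
  )
}
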