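#' Proxy time series
#'
#' The universal currency of the pipeline: a calendar-year-indexed sequence
#' of real values for one of the three proxies — a paleodemographic proxy
#' (SPD probability mass), a warfare-intensity index in \[0, 6\], or a
#' hydroclimate proxy (e.g. lithic concentration in percent).
#'
#' @param times Integer calendar years AD, strictly increasing.
#' @param values Numeric values, one per year in `times`.
#' @param label Free-text label carried through the pipeline.
#' @param step Nominal spacing in years between consecutive points (1 for
#'   annual input, 25 after resampling to the analysis grid).  Defaults to
#'   the modal observed spacing.
#'
#' @return An object of class `proxy_ts`: a list with elements `times`,
#'   `values`, `label` and `step`.
#' @examples
#' x <- proxy_series(2000:2010, rnorm(11, 10), label = "demo")
#' x
#' @export
proxy_series <- function(times, values, label = "", step = NULL) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have the same length", call. = FALSE)
  }
  if (length(times) >= 2 && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (anyNA(times) || anyNA(values)) {
    stop("`times` and `values` must not contain NA", call. = FALSE)
  }
  if (is.null(step)) {
    d <- diff(times)
    step <- if (length(d)) as.numeric(names(which.max(table(d)))) else 1
  }
  structure(list(times = times, values = values, label = as.character(label),
                 step = step),
            class = "proxy_ts")
}

#' @export
print.proxy_ts <- function(x, ...) {
  cat(sprintf("<proxy_ts> %s: %d points, AD %s-%s, step %s yr\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$times), format(min(x$times)), format(max(x$times)),
              format(x$step)))
  cat(sprintf("  values: [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.proxy_ts <- function(x, ...) {
  data.frame(year = x$times, value = x$values)
}

#' @export
length.proxy_ts <- function(x) length(x$times)

#' Log rate-of-change series
#'
#' Holds one-step log differences of a positive proxy series.  The rate for
#' the step from `t - step` to `t` is stamped at `t`, so that it aligns
#' with predictors observed at `t - step` in the regression layout used for
#' model fitting.
#'
#' @param times Calendar years AD at which the rates are stamped.
#' @param values Log rates of change per step.
#' @param label Label, typically derived from the source series.
#' @param step Step length in years inherited from the source series.
#' @return An object of class `rate_ts`.
#' @seealso [growth_rates()]
#' @export
rate_series <- function(times, values, label = "", step = NULL) {
  out <- proxy_series(times, values, label = label, step = step)
  class(out) <- c("rate_ts", "proxy_ts")
  out
}

#' @export
print.rate_ts <- function(x, ...) {
  cat(sprintf("<rate_ts> %s: %d log rates, AD %s-%s, step %s yr\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$times), format(min(x$times)), format(max(x$times)),
              format(x$step)))
  invisible(x)
}

#' Read a two-column proxy CSV
#'
#' Expects a header and columns `year` (calendar years AD) and `value`;
#' any further columns are ignored.
#'
#' @param path Path to the CSV file.
#' @param label Label for the resulting series (default: file name).
#' @return A [proxy_series()] object.
#' @export
read_proxy_csv <- function(path, label = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("year", "value") %in% names(df))) {
    stop("proxy CSV must have columns `year` and `value`: ", path,
         call. = FALSE)
  }
  if (is.null(label)) label <- sub("\\.csv$", "", basename(path))
  df <- df[order(df$year), , drop = FALSE]
  proxy_series(df$year, df$value, label = label)
}

#' Warfare period coding
#'
#' Ordinal defensive-settlement codes attached to broad chrono-cultural
#' periods (e.g. Early Intermediate Period, Middle Horizon), before
#' conversion to an annual index.  Codes are per-period sums of 0/1/2
#' (absent/present/common) scores over evidence categories, so the
#' aggregate lies in \[0, 6\].  Period year boundaries are user-supplied:
#' a period owns its start year and excludes its end year (half-open
#' intervals), which makes contiguity unambiguous at the boundaries.
#'
#' @param name Character vector of period names.
#' @param start,end Integer start (inclusive) and end (exclusive) calendar
#'   years AD of each period.
#' @param code Integer warfare code in \[0, 6\] per period.
#' @return An object of class `warfare_coding` (a data frame).
#' @examples
#' warfare_coding(c("EIP", "MH"), c(0, 600), c(600, 1000), c(1, 3))
#' @export
warfare_coding <- function(name, start, end, code) {
  df <- data.frame(name = as.character(name), start = as.numeric(start),
                   end = as.numeric(end), code = as.numeric(code))
  df <- df[order(df$start), , drop = FALSE]
  if (any(df$end <= df$start)) {
    stop("each period must satisfy start < end", call. = FALSE)
  }
  if (nrow(df) > 1 && any(df$start[-1] != df$end[-nrow(df)])) {
    stop("periods must be contiguous and non-overlapping", call. = FALSE)
  }
  if (any(df$code < 0 | df$code > 6)) {
    stop("warfare codes must lie in [0, 6]", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("warfare_coding", "data.frame")
  df
}

#' Read a warfare period table
#'
#' Accepts CSV (columns `name`, `start`, `end`, `code`) or YAML (a list of
#' mappings with the same keys).
#'
#' @param path Path to a `.csv`, `.yml` or `.yaml` file.
#' @return A [warfare_coding()] object.
#' @export
read_warfare_coding <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    df <- do.call(rbind, lapply(raw, as.data.frame))
  } else {
    df <- utils::read.csv(path)
  }
  need <- c("name", "start", "end", "code")
  if (!all(need %in% names(df))) {
    stop("warfare period table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  warfare_coding(df$name, df$start, df$end, df$code)
}

#' Expand period-coded warfare into an annual index
#'
#' Translates the coarse chrono-cultural coding into an annual step
#' function: the value at year `y` is the code of the period containing
#' `y` under the half-open convention (a period owns its start year,
#' excludes its end year).
#'
#' @param coding A [warfare_coding()] object.
#' @param years Integer years to evaluate, or a length-2 vector
#'   `c(from, to)` expanded to an annual sequence.
#' @return A [proxy_series()] with one value per year, all in \[0, 6\].
#' @examples
#' wc <- warfare_coding(c("a", "b"), c(0, 500), c(500, 1000), c(1, 3))
#' w <- encode_warfare(wc, c(490, 510))
#' w$values
#' @export
encode_warfare <- function(coding, years) {
  stopifnot(inherits(coding, "warfare_coding"))
  if (length(years) == 2 && diff(years) > 1) years <- seq(years[1], years[2])
  idx <- findInterval(years, coding$start)
  bad <- idx == 0 | years >= coding$end[pmin(idx, nrow(coding))]
  if (any(bad)) {
    stop("years not covered by any period: ",
         paste(utils::head(years[bad], 5), collapse = ", "), call. = FALSE)
  }
  proxy_series(years, coding$code[idx], label = "warfare index", step = 1)
}
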