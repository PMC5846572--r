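# Glucose trace data model: construction, CSV I/O, unit conversion,
# gap detection and decimation.

MMOL_PER_MGDL <- 18.016  # glucose molar mass, g/mol: 1 mmol/L = 18.016 mg/dL

#' Normalize a glucose unit label
#'
#' Accepts common spellings ("mg/dL", "mgdl", "mmol/L", "mmoll", any case)
#' and returns the canonical tag.
#'
#' @param unit A unit label.
#' @return `"mg/dL"` or `"mmol/L"`.
#' @keywords internal
normalize_unit <- function(unit) {
  if (!is.character(unit) || length(unit) != 1L || is.na(unit)) {
    stop("`unit` must be a single string", call. = FALSE)
  }
  key <- gsub("[^a-z]", "", tolower(unit))
  switch(key,
    mgdl = "mg/dL",
    mmoll = "mmol/L",
    stop(sprintf("unknown glucose unit '%s' (use \"mg/dL\" or \"mmol/L\")", unit),
         call. = FALSE)
  )
}

#' Construct a CGM glucose trace
#'
#' A `glucose_trace` is the object every metric in this package consumes:
#' a timestamped series of glucose concentrations with a unit tag and the
#' sensor's nominal sampling interval.
#'
#' @param time Numeric vector of sample times in minutes since the start of
#'   the trace.  Must be non-negative and strictly increasing.
#' @param glucose Numeric vector of glucose concentrations, same length as
#'   `time`.  Must be strictly positive and finite.
#' @param unit Glucose unit, `"mg/dL"` (default) or `"mmol/L"`.
#' @param nominal_interval Nominal sampling interval of the sensor in
#'   minutes (default 5, the usual CGM transmission rate).  Used only to
#'   derive defaults (gap threshold, CONGA pairing tolerance); metric
#'   computations always use the actual timestamp differences.
#'
#' @return An object of class `glucose_trace`.
#' @examples
#' tr <- glucose_trace(c(0, 5, 10), c(100, 110, 120))
#' tr
#' @export
glucose_trace <- function(time, glucose, unit = "mg/dL", nominal_interval = 5) {
  time <- as.numeric(time)
  glucose <- as.numeric(glucose)
  unit <- normalize_unit(unit)
  if (length(time) != length(glucose)) {
    stop("`time` and `glucose` must have the same length", call. = FALSE)
  }
  if (length(time) < 2L) {
    stop("insufficient data: a glucose trace needs at least 2 samples",
         call. = FALSE)
  }
  if (anyNA(time) || any(!is.finite(time)) || any(time < 0)) {
    stop("`time` must be finite, non-negative minutes since trace start",
         call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    bad <- time[which(diff(time) <= 0)[1] + 1L]
    stop(sprintf("timestamps must be strictly increasing (violation at t = %g min)",
                 bad), call. = FALSE)
  }
  if (anyNA(glucose) || any(!is.finite(glucose)) || any(glucose <= 0)) {
    stop("`glucose` values must be strictly positive and finite", call. = FALSE)
  }
  if (!is.numeric(nominal_interval) || length(nominal_interval) != 1L ||
      !is.finite(nominal_interval) || nominal_interval <= 0) {
    stop("`nominal_interval` must be a single positive number of minutes",
         call. = FALSE)
  }
  structure(
    list(time = time, glucose = glucose, unit = unit,
         nominal_interval = as.numeric(nominal_interval)),
    class = "glucose_trace"
  )
}

#' @export
print.glucose_trace <- function(x, ...) {
  cat(sprintf("<glucose_trace> %d samples over %.1f h (%s, nominal %g min)\n",
              length(x$time), diff(range(x$time)) / 60, x$unit,
              x$nominal_interval))
  cat(sprintf("  glucose: %.1f .. %.1f (mean %.1f)\n",
              min(x$glucose), max(x$glucose), mean(x$glucose)))
  invisible(x)
}

#' @export
as.data.frame.glucose_trace <- function(x, ...) {
  data.frame(time = x$time, glucose = x$glucose)
}

#' Number of samples in a trace
#' @param x A `glucose_trace`.
#' @export
length.glucose_trace <- function(x) length(x$time)

parse_timestamps <- function(x, column) {
  if (is.numeric(x)) {
    return(as.numeric(x))  # epoch seconds
  }
  x <- as.character(x)
  fmts <- c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
            "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  ts <- as.POSIXct(x, tz = "UTC", tryFormats = fmts, optional = TRUE)
  if (anyNA(ts)) {
    suppressWarnings(num <- as.numeric(x))
    if (!anyNA(num)) return(num)
    stop(sprintf(
      "input-format error: column '%s' contains unparseable timestamps (e.g. '%s')",
      column, x[which(is.na(ts))[1]]), call. = FALSE)
  }
  as.numeric(ts)
}

#' Read a CGM trace from CSV
#'
#' Reads a headered CSV with a timestamp column (ISO-8601 or epoch seconds)
#' and a numeric glucose column.  Rows with missing glucose are dropped —
#' dropping creates gaps that [detect_gaps()] finds downstream.  Rows need
#' not be in chronological order; the returned trace is sorted by time, with
#' time expressed in minutes since the earliest sample.
#'
#' @param path Path to a CSV file.
#' @param timestamp_column,glucose_column Column names (defaults
#'   `"timestamp"`, `"glucose"`).
#' @param unit Unit of the glucose column (default `"mg/dL"`).
#' @param nominal_interval Nominal sampling interval in minutes (default 5).
#'
#' @return A [glucose_trace()].
#' @examples
#' path <- system.file("extdata", "example_trace.csv", package = "gvp")
#' tr <- read_trace(path)
#' gvp(tr)
#' @seealso [write_trace()]
#' @export
read_trace <- function(path, timestamp_column = "timestamp",
                       glucose_column = "glucose", unit = "mg/dL",
                       nominal_interval = 5) {
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) {
      stop(sprintf("input-format error: cannot read '%s' as CSV (%s)",
                   path, conditionMessage(e)), call. = FALSE)
    }
  )
  for (col in c(timestamp_column, glucose_column)) {
    if (!col %in% names(df)) {
      stop(sprintf("input-format error: column '%s' not found in '%s'",
                   col, path), call. = FALSE)
    }
  }
  secs <- parse_timestamps(df[[timestamp_column]], timestamp_column)
  gluc <- suppressWarnings(as.numeric(df[[glucose_column]]))
  keep <- !is.na(gluc) & !is.na(secs)
  secs <- secs[keep]
  gluc <- gluc[keep]
  if (length(secs) < 2L) {
    stop("insufficient data: fewer than 2 valid rows after dropping missing glucose",
         call. = FALSE)
  }
  ord <- order(secs)
  secs <- secs[ord]
  gluc <- gluc[ord]
  if (any(diff(secs) == 0)) {
    dup <- secs[which(diff(secs) == 0)[1]]
    stop(sprintf("duplicate timestamp at %s",
                 format(as.POSIXct(dup, tz = "UTC", origin = "1970-01-01"),
                        "%Y-%m-%dT%H:%M:%SZ")), call. = FALSE)
  }
  glucose_trace((secs - secs[1]) / 60, gluc, unit = unit,
                nominal_interval = nominal_interval)
}

#' Write a CGM trace to CSV
#'
#' Emits the same dialect [read_trace()] accepts: ISO-8601 UTC timestamps
#' and glucose rounded to one decimal.
#'
#' @param trace A `glucose_trace`.
#' @param path Output file path.
#' @param start POSIXct origin mapped to trace time 0 (default
#'   2000-01-01 00:00:00 UTC).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path,
                        start = as.POSIXct("2000-01-01 00:00:00", tz = "UTC")) {
  stopifnot(inherits(trace, "glucose_trace"))
  ts <- format(start + trace$time * 60, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  df <- data.frame(timestamp = ts, glucose = sprintf("%.1f", trace$glucose))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert the glucose unit of a trace
#'
#' Multiplies by 18.016 mg/dL per mmol/L (the molar mass of glucose) when
#' converting mmol/L to mg/dL, divides for the reverse, and is the identity
#' when the units already match.  GVP is unit-dependent, so traces should be
#' converted to mg/dL before computing it.
#'
#' @param trace A `glucose_trace`.
#' @param target_unit `"mg/dL"` or `"mmol/L"`.
#' @return A `glucose_trace` in the target unit.
#' @examples
#' tr <- glucose_trace(c(0, 5), c(5, 6), unit = "mmol/L")
#' convert_units(tr, "mg/dL")$glucose  # 90.08 108.10
#' @export
convert_units <- function(trace, target_unit) {
  stopifnot(inherits(trace, "glucose_trace"))
  target_unit <- normalize_unit(target_unit)
  if (identical(trace$unit, target_unit)) return(trace)
  g <- if (target_unit == "mg/dL") trace$glucose * MMOL_PER_MGDL
       else trace$glucose / MMOL_PER_MGDL
  glucose_trace(trace$time, g, unit = target_unit,
                nominal_interval = trace$nominal_interval)
}

#' Detect recording gaps in a trace
#'
#' Splits the trace into runs of contiguous samples: consecutive samples
#' more than `gap_threshold` minutes apart start a new run, and the bridging
#' interval is excluded from all downstream length computations (both the
#' trace length L and the baseline length L0, which implements shortening
#' the ideal line length by the amount of missing data).
#'
#' @param trace A `glucose_trace`.
#' @param gap_threshold Minutes; consecutive spacings above this open a gap.
#'   Default 1.5 times the nominal interval (7.5 min for 5-min data), which
#'   tolerates transmission jitter while catching a single missed reading.
#'
#' @return A `gap_report`: list with `runs` (data frame of start/end sample
#'   indices), `gap_intervals` (data frame of excluded `(t_start, t_end)`),
#'   `excluded_minutes`, and the `gap_threshold` used.
#' @examples
#' tr <- glucose_trace(c(0, 5, 10, 30, 35), c(100, 120, 110, 130, 125))
#' detect_gaps(tr)  # one gap (10, 30), 20 min excluded
#' @export
detect_gaps <- function(trace, gap_threshold = NULL) {
  stopifnot(inherits(trace, "glucose_trace"))
  if (is.null(gap_threshold)) gap_threshold <- 1.5 * trace$nominal_interval
  if (!is.numeric(gap_threshold) || length(gap_threshold) != 1L ||
      !is.finite(gap_threshold) || gap_threshold <= 0) {
    stop("`gap_threshold` must be a single positive number of minutes",
         call. = FALSE)
  }
  n <- length(trace$time)
  dt <- diff(trace$time)
  brk <- which(dt > gap_threshold)
  runs <- data.frame(start = c(1L, brk + 1L), end = c(brk, n))
  gaps <- data.frame(t_start = trace$time[brk], t_end = trace$time[brk + 1L])
  structure(
    list(runs = runs, gap_intervals = gaps,
         excluded_minutes = sum(gaps$t_end - gaps$t_start),
         gap_threshold = gap_threshold),
    class = "gap_report"
  )
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf("<gap_report> %d run(s), %d gap(s), %.1f min excluded (threshold %g min)\n",
              nrow(x$runs), nrow(x$gap_intervals), x$excluded_minutes,
              x$gap_threshold))
  invisible(x)
}

#' Decimate a trace to a coarser sampling interval
#'
#' Keeps every `factor`-th sample starting from the first and multiplies the
#' nominal interval accordingly (5-min data with `factor = 3` becomes 15-min
#' data).  Coarser sampling acts as a low-pass filter and reduces apparent
#' glycemic variability, so this is the tool for sampling-interval
#' sensitivity studies.
#'
#' @param trace A `glucose_trace`.
#' @param factor Positive integer decimation factor; `1` returns the trace
#'   unchanged.
#' @return A `glucose_trace`.
#' @export
resample_trace <- function(trace, factor) {
  stopifnot(inherits(trace, "glucose_trace"))
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor < 1 || factor != round(factor)) {
    stop("`factor` must be a positive integer", call. = FALSE)
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(trace)
  n <- length(trace$time)
  if (n < factor + 1L) {
    stop(sprintf("insufficient data: decimation by %d needs at least %d samples",
                 factor, factor + 1L), call. = FALSE)
  }
  idx <- seq.int(1L, n, by = factor)
  glucose_trace(trace$time[idx], trace$glucose[idx], unit = trace$unit,
                nominal_interval = trace$nominal_interval * factor)
}
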