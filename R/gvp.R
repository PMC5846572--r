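# The glycemic variability percentage: segment decomposition, line
# lengths L and L0, and the GVP statistic itself.
#
# The CGM trace is treated as a polyline in the (time, glucose) plane.
# Its arc length L = sum over segments of sqrt(dx^2 + dy^2), with dx in
# minutes and dy in mg/dL, is compared with the flat-line baseline
# L0 = sum(dx); GVP = (L/L0 - 1) * 100 is the percentage excess length.
# The mixed units are deliberate: no rescaling of the time axis is
# applied, which is what makes the statistic reproduce its published
# reference values, and also why the glucose unit matters (mg/dL is
# canonical).

check_unit_for_gvp <- function(trace, allow_mmol) {
  if (trace$unit == "mg/dL") return(invisible(TRUE))
  if (!allow_mmol) {
    stop(paste0(
      "trace is in mmol/L but GVP is unit-dependent and defined in mg/dL; ",
      "call convert_units(trace, \"mg/dL\") first, or pass allow_mmol = TRUE ",
      "to compute on the mmol/L scale anyway"), call. = FALSE)
  }
  warning("computing an arc-length statistic on mmol/L values; ",
          "the result is not comparable to mg/dL-based reference ranges",
          call. = FALSE)
  invisible(TRUE)
}

#' Decompose a trace into line segments
#'
#' Produces one `(dx, dy)` pair per within-run pair of consecutive samples:
#' `dx` is the time between two successive measurements (minutes) and `dy`
#' the change in glucose over that interval.  Pairs that straddle a
#' recording gap are excluded.
#'
#' @param trace A [glucose_trace()] in mg/dL (see `allow_mmol`).
#' @param gaps A `gap_report` from [detect_gaps()]; computed with the
#'   default threshold when omitted.
#' @param allow_mmol Permit a mmol/L trace (with a warning).  The arc
#'   length mixes glucose and time units, so the result depends on the
#'   glucose unit; mg/dL is the convention.
#'
#' @return A `segment_decomposition`: list with numeric `dx`, `dy` and the
#'   segment count `n`.
#' @export
decompose_segments <- function(trace, gaps = NULL, allow_mmol = FALSE) {
  stopifnot(inherits(trace, "glucose_trace"))
  check_unit_for_gvp(trace, allow_mmol)
  if (is.null(gaps)) gaps <- detect_gaps(trace)
  stopifnot(inherits(gaps, "gap_report"))
  dx <- dy <- list()
  for (r in seq_len(nrow(gaps$runs))) {
    i <- gaps$runs$start[r]:gaps$runs$end[r]
    if (length(i) < 2L) next
    dx[[length(dx) + 1L]] <- diff(trace$time[i])
    dy[[length(dy) + 1L]] <- diff(trace$glucose[i])
  }
  dx <- unlist(dx) %||% numeric(0)
  dy <- unlist(dy) %||% numeric(0)
  if (length(dx) < 1L) {
    stop("insufficient data: no within-run segment (all runs are singletons)",
         call. = FALSE)
  }
  structure(list(dx = dx, dy = dy, n = length(dx)),
            class = "segment_decomposition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Arc length of a segment decomposition
#'
#' `L = sum_i sqrt(dx_i^2 + dy_i^2)` over all segments (Pythagorean sum of
#' the horizontal and vertical components).
#'
#' @param seg A `segment_decomposition` from [decompose_segments()].
#' @return The trace line length L (mixed minutes/mg-dL units).
#' @export
trace_length <- function(seg) {
  stopifnot(inherits(seg, "segment_decomposition"), seg$n >= 1L)
  sum(sqrt(seg$dx^2 + seg$dy^2))
}

#' Baseline (ideal) line length of a segment decomposition
#'
#' `L0 = sum_i dx_i`: the elapsed within-run time in minutes, i.e. total
#' duration shortened by any excluded gap time.  This is the length of a
#' perfectly flat trace over the same recorded time.
#'
#' @inheritParams trace_length
#' @return L0 in minutes.
#' @export
baseline_length <- function(seg) {
  stopifnot(inherits(seg, "segment_decomposition"), seg$n >= 1L)
  sum(seg$dx)
}

#' GVP from precomputed line lengths
#'
#' `GVP = (L / L0 - 1) * 100`, the percentage by which the trace is longer
#' than a flat line over the same duration.
#'
#' @param L Trace line length.
#' @param L0 Baseline line length, `> 0`.
#' @return GVP in percent.
#' @examples
#' gvp_from_lengths(13349, 9670)  # 38.05
#' @export
gvp_from_lengths <- function(L, L0) {
  stopifnot(is.numeric(L), is.numeric(L0), all(L0 > 0))
  (L / L0 - 1) * 100
}

#' Glycemic variability percentage of a CGM trace
#'
#' The headline statistic of this package: the arc length of the CGM trace
#' in the (time, glucose) plane, normalized to the flat-line length for the
#' same recorded duration, expressed as a percentage excess.  A constant
#' trace gives 0; higher amplitude *or* higher frequency of glucose
#' oscillations both increase it, which distinguishes GVP from SD and CV.
#' Recording gaps shorten both L and L0 (run-wise computation), so missing
#' data does not masquerade as low variability.
#'
#' @inheritParams decompose_segments
#' @param gap_threshold Minutes; passed to [detect_gaps()].  Default 1.5
#'   times the nominal sampling interval.
#'
#' @return A `gvp_result`: list with `L`, `L0`, `gvp_percent` (full
#'   precision; printing rounds to the nearest integer percent),
#'   `n_segments` and `excluded_minutes`.
#' @examples
#' tr <- square_wave(full_period_h = 12)
#' gvp(tr)  # ~95%
#' @export
gvp <- function(trace, gap_threshold = NULL, allow_mmol = FALSE) {
  stopifnot(inherits(trace, "glucose_trace"))
  gaps <- detect_gaps(trace, gap_threshold)
  seg <- decompose_segments(trace, gaps, allow_mmol = allow_mmol)
  L <- trace_length(seg)
  L0 <- baseline_length(seg)
  stopifnot(L >= L0, L0 > 0)
  structure(
    list(L = L, L0 = L0, gvp_percent = gvp_from_lengths(L, L0),
         n_segments = seg$n, excluded_minutes = gaps$excluded_minutes),
    class = "gvp_result"
  )
}

#' @export
print.gvp_result <- function(x, ...) {
  cat(sprintf("<gvp_result> GVP = %.0f%%  (L = %.0f, L0 = %.0f, %d segments",
              round(x$gvp_percent), x$L, x$L0, x$n_segments))
  if (x$excluded_minutes > 0) {
    cat(sprintf(", %.0f min of gaps excluded", x$excluded_minutes))
  }
  cat(")\n")
  invisible(x)
}
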