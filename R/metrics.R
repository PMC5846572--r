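# Classic glycemic-variability metrics used for comparison with GVP:
# SD, CV, distance traveled, MAG, CONGA(n), MAGE.
#
# SD and CV see only the amplitude distribution of glucose values and are
# blind to their temporal ordering; distance traveled, MAG, CONGA and GVP
# also respond to the frequency of oscillations.

#' Mean, sample SD and coefficient of variation of a trace
#'
#' @param trace A [glucose_trace()].
#' @return Named list with `mean`, `sd` (sample, n-1 denominator) and
#'   `cv = sd / mean`, all on the trace's glucose unit.
#' @export
mean_sd_cv <- function(trace) {
  stopifnot(inherits(trace, "glucose_trace"))
  m <- mean(trace$glucose)
  s <- stats::sd(trace$glucose)
  list(mean = m, sd = s, cv = s / m)
}

#' Distance traveled: total absolute glucose change
#'
#' The sum of absolute differences in glucose between successive
#' measurements, over within-run segments only (pairs straddling a
#' recording gap are skipped).
#'
#' @param trace A [glucose_trace()].
#' @param gaps Optional `gap_report`; computed with the default threshold
#'   when omitted.
#' @return Total distance traveled in the trace's glucose unit.
#' @export
distance_traveled <- function(trace, gaps = NULL) {
  seg <- suppressWarnings(decompose_segments(trace, gaps, allow_mmol = TRUE))
  sum(abs(seg$dy))
}

#' MAG: mean absolute glucose change per hour
#'
#' [distance_traveled()] normalized by the within-run elapsed time in
#' hours, so that `mag * elapsed_hours == distance_traveled` exactly.
#'
#' @inheritParams distance_traveled
#' @return MAG in glucose units per hour.
#' @export
mag <- function(trace, gaps = NULL) {
  seg <- suppressWarnings(decompose_segments(trace, gaps, allow_mmol = TRUE))
  hours <- sum(seg$dx) / 60
  if (hours <= 0) stop("insufficient data: no elapsed within-run time", call. = FALSE)
  sum(abs(seg$dy)) / hours
}

#' CONGA(n): continuous overall net glycemic action
#'
#' The sample standard deviation of the signed differences
#' `D_t = G(t) - G(t - lag_hours)` over every observation for which a
#' sample exists `lag_hours` earlier, within half the nominal sampling
#' interval.  For regular 5-min data with a 1-h lag each sample is paired
#' with the one 12 positions earlier.
#'
#' @param trace A [glucose_trace()].
#' @param lag_hours Positive lag in hours (default 1, i.e. CONGA1).
#' @return SD of the lagged differences, in the trace's glucose unit.
#' @export
conga <- function(trace, lag_hours = 1) {
  stopifnot(inherits(trace, "glucose_trace"))
  if (!is.numeric(lag_hours) || length(lag_hours) != 1L || lag_hours <= 0) {
    stop("`lag_hours` must be a single positive number", call. = FALSE)
  }
  lag_min <- lag_hours * 60
  tol <- trace$nominal_interval / 2
  t <- trace$time
  g <- trace$glucose
  target <- t - lag_min
  # nearest earlier sample to each target time, accepted if within tol
  pos <- findInterval(target, t)
  best <- integer(length(t))
  for (i in seq_along(t)) {
    cand <- pos[i] + c(0L, 1L)
    cand <- cand[cand >= 1L & cand <= length(t)]
    if (length(cand) == 0L) next
    d <- abs(t[cand] - target[i])
    j <- cand[which.min(d)]
    if (abs(t[j] - target[i]) <= tol) best[i] <- j
  }
  ok <- best > 0L
  if (sum(ok) < 2L) {
    stop("insufficient data: fewer than 2 lagged pairs for CONGA", call. = FALSE)
  }
  stats::sd(g[ok] - g[best[ok]])
}

#' MAGE: mean amplitude of glycemic excursions
#'
#' Turning points are found after collapsing monotone runs of the series;
#' an excursion between consecutive turning points qualifies when its
#' peak-to-nadir amplitude exceeds one sample SD of the whole trace.  MAGE
#' is the mean amplitude of qualifying excursions measured in the direction
#' (rising or falling) of the first qualifying excursion, and 0 when none
#' qualify.
#'
#' @param trace A [glucose_trace()] with at least 3 samples.
#' @return MAGE in the trace's glucose unit (0 when no excursion exceeds
#'   one SD).
#' @export
mage <- function(trace) {
  stopifnot(inherits(trace, "glucose_trace"))
  g <- trace$glucose
  if (length(g) < 3L) {
    stop("insufficient data: MAGE needs at least 3 samples", call. = FALSE)
  }
  s <- stats::sd(g)
  if (s == 0) return(0)
  # collapse plateaus: keep values where the series actually moves
  d <- diff(g)
  v <- c(g[1], g[-1][d != 0])
  if (length(v) < 2L) return(0)
  dd <- diff(v)
  turn <- c(TRUE, diff(sign(dd)) != 0, TRUE)  # endpoints + sign changes
  tv <- v[turn]
  amp <- diff(tv)                 # signed excursion amplitudes
  qual <- abs(amp) > s
  if (!any(qual)) return(0)
  dir <- sign(amp[qual][1])       # direction of first qualifying excursion
  mean(abs(amp[qual & sign(amp) == dir]))
}

#' All comparison metrics for one trace
#'
#' Convenience wrapper computing the mean, SD, CV, distance traveled, MAG,
#' CONGA at the requested lags, MAGE and GVP for a single trace.
#'
#' @param trace A [glucose_trace()] in mg/dL.
#' @param gap_threshold Minutes; passed to [detect_gaps()].
#' @param conga_lags Numeric vector of CONGA lags in hours (default 1).
#' @return A one-row [tibble::tibble()] with columns `mean`, `sd`, `cv`,
#'   `distance_traveled`, `mag`, `conga_<lag>h`, `mage`, `gvp_percent`.
#' @export
metrics_bundle <- function(trace, gap_threshold = NULL, conga_lags = 1) {
  stopifnot(inherits(trace, "glucose_trace"))
  gaps <- detect_gaps(trace, gap_threshold)
  msc <- mean_sd_cv(trace)
  out <- tibble::tibble(
    mean = msc$mean, sd = msc$sd, cv = msc$cv,
    distance_traveled = distance_traveled(trace, gaps),
    mag = mag(trace, gaps)
  )
  for (lag in conga_lags) {
    out[[sprintf("conga_%gh", lag)]] <- conga(trace, lag)
  }
  out$mage <- mage(trace)
  out$gvp_percent <- gvp(trace, gap_threshold)$gvp_percent
  out
}
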