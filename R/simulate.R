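# Simulators: the square-wave frequency/amplitude experiment and a
# synthetic CGM cohort generator spanning the minimal-to-high
# variability range.

#' Simulated square-wave CGM trace
#'
#' Generates a square wave sampled on a regular grid: the value at time
#' `t` is `start_level` while `t mod full_period` is in the first half
#' period and the other level otherwise.  Samples lie at
#' `t = 0, s, ..., (N-1) s` with `N = floor(duration_h * 60 / sampling_min)`
#' (2016 samples for 7 days at 5 min), so the final half-period boundary at
#' `duration_h * 60` is never sampled.
#'
#' With the defaults (levels 40/400 mg/dL, 168 h) these are the canonical
#' profiles for demonstrating that SD and CV are blind to oscillation
#' frequency while GVP and MAG are not: all waves share mean 220 mg/dL and
#' SD 180.04, but shorter periods give proportionally larger GVP and MAG.
#'
#' @param full_period_h Full oscillation period in hours (low + high dwell).
#' @param low,high Low and high plateau levels in mg/dL (40 and 400).
#' @param duration_h Trace duration in hours (default 168 = 7 days).
#' @param sampling_min Sampling interval in minutes (default 5).
#' @param start_level `"low"` or `"high"`: plateau at `t = 0`.  All
#'   dwell-symmetric metrics are invariant to this choice.
#' @return A [glucose_trace()] in mg/dL.
#' @examples
#' w <- square_wave(full_period_h = 12)
#' length(w)        # 2016
#' mean(w$glucose)  # 220
#' @export
square_wave <- function(full_period_h, low = 40, high = 400,
                        duration_h = 168, sampling_min = 5,
                        start_level = c("low", "high")) {
  start_level <- match.arg(start_level)
  if (!is.numeric(full_period_h) || full_period_h <= 0 ||
      !is.numeric(duration_h) || duration_h <= 0 ||
      !is.numeric(sampling_min) || sampling_min <= 0) {
    stop("`full_period_h`, `duration_h` and `sampling_min` must be positive",
         call. = FALSE)
  }
  if (!(low < high)) stop("`low` must be less than `high`", call. = FALSE)
  n <- floor(duration_h * 60 / sampling_min)
  t <- (seq_len(n) - 1) * sampling_min
  half <- full_period_h * 60 / 2
  first_half <- (t %% (full_period_h * 60)) < half
  a <- if (start_level == "low") low else high
  b <- if (start_level == "low") high else low
  glucose_trace(t, ifelse(first_half, a, b), unit = "mg/dL",
                nominal_interval = sampling_min)
}

#' Square-wave frequency experiment
#'
#' Runs [square_wave()] for a set of full periods (default 12, 24, 56 and
#' 168 h over a 7-day window) and computes GVP, MAG, CONGA1, CV and SD for
#' each.  Rows are labelled by the half period (6, 12, 28, 84 h), the dwell
#' time at each level.  SD and CV are identical across rows; GVP and MAG
#' decrease as the period grows — the frequency component of variability
#' that dispersion metrics miss.
#'
#' @param full_periods_h Full periods in hours.
#' @param low,high,duration_h,sampling_min Passed to [square_wave()].
#' @return A [tibble::tibble()] with columns `half_period_h`,
#'   `gvp_percent`, `mag`, `conga1`, `cv`, `sd`.
#' @examples
#' square_wave_experiment()
#' @export
square_wave_experiment <- function(full_periods_h = c(12, 24, 56, 168),
                                   low = 40, high = 400, duration_h = 168,
                                   sampling_min = 5) {
  rows <- lapply(full_periods_h, function(p) {
    w <- square_wave(p, low = low, high = high, duration_h = duration_h,
                     sampling_min = sampling_min)
    msc <- mean_sd_cv(w)
    tibble::tibble(
      half_period_h = p / 2,
      gvp_percent = gvp(w)$gvp_percent,
      mag = mag(w),
      conga1 = conga(w, 1),
      cv = msc$cv,
      sd = msc$sd
    )
  })
  do.call(rbind, rows)
}

# run code with a private, restored RNG state so generators are
# deterministic without disturbing the caller's random stream
with_preserved_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Parameter presets for the synthetic cohort generator
#'
#' Five profiles emulating the clinical spectrum from non-diabetic adults
#' to high-variability pediatric type 1 diabetes.  Each is a list of
#' [synth_cohort()] arguments, chosen once so that a 50-subject cohort's
#' median GVP lands in the intended variability band (minimal for
#' `"nondiabetic"`, low for `"t2d_adult"`, moderate for `"t1d_adult"`,
#' high for `"t1d_adolescent"` and `"t1d_child"`), and frozen.
#'
#' @param name One of `"nondiabetic"`, `"t2d_adult"`, `"t1d_adult"`,
#'   `"t1d_adolescent"`, `"t1d_child"`.
#' @return Named list of generator parameters.
#' @examples
#' do.call(synth_cohort, c(list(n_subjects = 3, seed = 1),
#'                         cohort_preset("nondiabetic")))
#' @export
cohort_preset <- function(name) {
  presets <- list(
    nondiabetic = list(baseline = 95, excursion_rate = 3,
                       excursion_amplitude = c(45, 12), noise_sd = 3,
                       autocorrelation = 0.75),
    t2d_adult = list(baseline = 140, excursion_rate = 3.5,
                     excursion_amplitude = c(70, 20), noise_sd = 3.6,
                     autocorrelation = 0.75),
    t1d_adult = list(baseline = 150, excursion_rate = 4,
                     excursion_amplitude = c(90, 30), noise_sd = 4.8,
                     autocorrelation = 0.75),
    t1d_adolescent = list(baseline = 155, excursion_rate = 5,
                          excursion_amplitude = c(110, 35), noise_sd = 5,
                          autocorrelation = 0.7),
    t1d_child = list(baseline = 150, excursion_rate = 5,
                     excursion_amplitude = c(105, 35), noise_sd = 4.7,
                     autocorrelation = 0.7)
  )
  if (!name %in% names(presets)) {
    stop(sprintf("unknown preset '%s' (available: %s)", name,
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  }
  presets[[name]]
}

#' Synthetic CGM cohort generator
#'
#' Generates CGM-like traces as a baseline plus randomly timed meal-like
#' excursions (raised-cosine bumps spanning about 2 h) plus first-order
#' autocorrelated sensor/physiology noise, clipped to the 40-400 mg/dL CGM
#' reporting range.  Output is fully determined by `seed`.  The generator
#' is a test fixture standing in for clinical cohorts: its contract is to
#' produce traces whose GVP spans the minimal-to-high classification bands
#' reproducibly, not to be physiologically faithful.
#'
#' @param n_subjects Number of traces (0 returns an empty list).
#' @param duration_h Trace duration in hours (default 168).
#' @param sampling_min Sampling interval in minutes (default 5).
#' @param excursion_rate Mean number of excursion events per day.
#' @param excursion_amplitude Length-2 numeric `(mean, sd)` of the
#'   excursion peak height in mg/dL (negative draws are truncated to 0).
#' @param noise_sd Stationary SD of the AR(1) noise, mg/dL.
#' @param autocorrelation AR(1) coefficient of the noise, in `[0, 1)`.
#' @param baseline Baseline glucose, mg/dL.
#' @param seed Integer seed; identical parameters + seed give identical
#'   traces.
#' @return List of [glucose_trace()] objects.
#' @export
synth_cohort <- function(n_subjects, duration_h = 168, sampling_min = 5,
                         excursion_rate = 4, excursion_amplitude = c(100, 30),
                         noise_sd = 8, autocorrelation = 0.75,
                         baseline = 130, seed = 1L) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 0 ||
      n_subjects != round(n_subjects)) {
    stop("`n_subjects` must be a non-negative integer", call. = FALSE)
  }
  if (length(excursion_amplitude) != 2L || any(excursion_amplitude < 0)) {
    stop("`excursion_amplitude` must be (mean, sd), both non-negative",
         call. = FALSE)
  }
  if (excursion_rate < 0 || noise_sd < 0 || baseline <= 0 ||
      autocorrelation < 0 || autocorrelation >= 1) {
    stop("rates and amplitudes must be non-negative; `autocorrelation` in [0, 1)",
         call. = FALSE)
  }
  if (n_subjects == 0) return(list())
  n <- floor(duration_h * 60 / sampling_min)
  t <- (seq_len(n) - 1) * sampling_min
  total_min <- duration_h * 60
  half_span <- 60  # excursion half-width in minutes (~2 h rise-and-fall)
  phi <- autocorrelation
  with_preserved_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      g <- rep(baseline, n)
      k <- stats::rpois(1, excursion_rate * duration_h / 24)
      if (k > 0) {
        centers <- stats::runif(k, 0, total_min)
        amps <- pmax(0, stats::rnorm(k, excursion_amplitude[1],
                                     excursion_amplitude[2]))
        for (j in seq_len(k)) {
          w <- abs(t - centers[j]) < half_span
          g[w] <- g[w] + amps[j] *
            0.5 * (1 + cos(pi * (t[w] - centers[j]) / half_span))
        }
      }
      if (noise_sd > 0) {
        innov <- stats::rnorm(n, 0, noise_sd * sqrt(1 - phi^2))
        e <- stats::filter(innov, phi, method = "recursive")
        g <- g + as.numeric(e)
      }
      glucose_trace(t, pmin(400, pmax(40, g)), unit = "mg/dL",
                    nominal_interval = sampling_min)
    })
  })
}
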