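# Shared fixtures and independent brute-force oracles.  The oracles use
# plain loops and definitional formulas so they stay independent of the
# vectorized implementation paths they check.

make_regular_trace <- function(glucose, interval = 5, unit = "mg/dL") {
  glucose_trace((seq_along(glucose) - 1) * interval, glucose,
                unit = unit, nominal_interval = interval)
}

# random smooth-ish trace on a regular 5-min grid; n - 1 divisible by 6 by
# default so decimation by 2 and 3 preserves the final sample
random_walk_trace <- function(seed, n = 97, interval = 5, start = 150,
                              step_sd = 5) {
  set.seed(seed)
  g <- start + cumsum(rnorm(n, 0, step_sd))
  g <- pmin(400, pmax(40, g))
  make_regular_trace(g, interval)
}

# loop-wise arc length over a single contiguous run
brute_arc_length <- function(time, glucose) {
  total <- 0
  for (i in seq_len(length(time) - 1)) {
    total <- total + sqrt((time[i + 1] - time[i])^2 +
                          (glucose[i + 1] - glucose[i])^2)
  }
  total
}

# sort-based linear-interpolation percentile (definition, not quantile())
brute_percentile <- function(values, p) {
  x <- sort(values)
  n <- length(x)
  h <- (n - 1) * p / 100
  lo <- floor(h)
  if (lo >= n - 1) return(x[n])
  x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1])
}

# definitional CONGA: double loop over all pairs exactly lag apart
brute_conga <- function(trace, lag_hours, tol = trace$nominal_interval / 2) {
  d <- c()
  for (i in seq_along(trace$time)) {
    target <- trace$time[i] - lag_hours * 60
    j <- which(abs(trace$time - target) <= tol)
    if (length(j) >= 1) {
      j <- j[which.min(abs(trace$time[j] - target))]
      d <- c(d, trace$glucose[i] - trace$glucose[j])
    }
  }
  sd(d)
}

# independent turning-point MAGE: explicit state-machine scan
brute_mage <- function(trace) {
  g <- trace$glucose
  s <- sd(g)
  if (s == 0) return(0)
  v <- g[c(TRUE, diff(g) != 0)]
  if (length(v) < 2) return(0)
  tp <- v[1]
  for (i in 2:(length(v) - 1)) {
    if ((v[i] - v[i - 1]) * (v[i + 1] - v[i]) < 0) tp <- c(tp, v[i])
  }
  tp <- c(tp, v[length(v)])
  amps <- diff(tp)
  qual <- which(abs(amps) > s)
  if (length(qual) == 0) return(0)
  dir <- sign(amps[qual[1]])
  mean(abs(amps[qual][sign(amps[qual]) == dir]))
}

square_wave_closed_form_gvp <- function(k, amplitude, sampling, L0) {
  k * (sqrt(sampling^2 + amplitude^2) - sampling) / L0 * 100
}
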