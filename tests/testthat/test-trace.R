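test_that("read_trace maps timestamps to minutes, drops missing glucose, sorts", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,glucose",
               "2024-01-01T00:10:00Z,120",
               "2024-01-01T00:00:00Z,100",
               "2024-01-01T00:05:00Z,110"), path)
  tr <- read_trace(path)
  expect_equal(tr$time, c(0, 5, 10))
  expect_equal(tr$glucose, c(100, 110, 120))

  writeLines(c("timestamp,glucose",
               "2024-01-01T00:00:00Z,100",
               "2024-01-01T00:05:00Z,",
               "2024-01-01T00:10:00Z,120"), path)
  tr <- read_trace(path)
  expect_equal(tr$time, c(0, 10))

  # epoch-seconds timestamps are accepted too
  writeLines(c("timestamp,glucose", "0,100", "300,110", "600,120"), path)
  expect_equal(read_trace(path)$time, c(0, 5, 10))
})

test_that("read_trace errors name the failure mode", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,glucose",
               "2024-01-01T00:00:00Z,100",
               "2024-01-01T00:00:00Z,110"), path)
  expect_error(read_trace(path), "duplicate timestamp at 2024-01-01T00:00:00Z")

  writeLines(c("timestamp,glucose", "2024-01-01T00:00:00Z,100"), path)
  expect_error(read_trace(path), "insufficient data")

  writeLines(c("timestamp,glucose", "not-a-time,100", "also-bad,110"), path)
  expect_error(read_trace(path), "input-format error")

  writeLines(c("when,value", "2024-01-01T00:00:00Z,100"), path)
  expect_error(read_trace(path), "column 'timestamp' not found")
})

test_that("trace writer round-trips through the reader", {
  tr <- make_regular_trace(c(100.04, 110.22, 120.49, 115.31))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$time, tr$time)
  expect_equal(back$glucose, round(tr$glucose, 1))  # writer emits 1 decimal
})

test_that("unit conversion uses 18.016 and is invertible", {
  tr <- glucose_trace(c(0, 5), c(5, 10), unit = "mmol/L")
  expect_equal(convert_units(tr, "mg/dL")$glucose, c(90.08, 180.16))
  expect_equal(convert_units(tr, "mg/dL")$unit, "mg/dL")

  # identity when units already match
  mg <- glucose_trace(c(0, 5), c(180, 90))
  expect_identical(convert_units(mg, "mg/dL"), mg)

  # round trip within 1e-9 relative
  back <- convert_units(convert_units(mg, "mmol/L"), "mg/dL")
  expect_equal(back$glucose, mg$glucose, tolerance = 1e-9)

  expect_error(convert_units(mg, "furlongs"), "unknown glucose unit")
})

test_that("trace validation rejects malformed input", {
  expect_error(glucose_trace(c(0, 5, 5), c(1, 2, 3) * 100),
               "strictly increasing")
  expect_error(glucose_trace(c(0, 5), c(100, -3)), "strictly positive")
  expect_error(glucose_trace(c(0, 5), c(100, Inf)), "strictly positive")
  expect_error(glucose_trace(0, 100), "at least 2 samples")
  expect_error(glucose_trace(c(0, 5), c(100, 110), nominal_interval = 0),
               "positive")
})

test_that("gap detection decomposes runs and accounts for excluded time", {
  tr <- glucose_trace(c(0, 5, 10, 30, 35), c(100, 120, 110, 130, 125))
  gr <- detect_gaps(tr, 7.5)
  expect_equal(gr$runs, data.frame(start = c(1L, 4L), end = c(3L, 5L)))
  expect_equal(gr$gap_intervals$t_start, 10)
  expect_equal(gr$gap_intervals$t_end, 30)
  expect_equal(gr$excluded_minutes, 20)

  # no gaps below threshold; threshold dominating removes the gap
  expect_equal(detect_gaps(glucose_trace(c(0, 5, 10, 15), rep(100, 4)),
                           7.5)$excluded_minutes, 0)
  gr25 <- detect_gaps(tr, 25)
  expect_equal(nrow(gr25$runs), 1L)
  expect_equal(gr25$excluded_minutes, 0)
})

test_that("run decomposition partitions indices and gap accounting balances", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:60, 1)
    dt <- sample(c(5, 5, 5, 20, 45), n - 1, replace = TRUE)
    tr <- glucose_trace(cumsum(c(0, dt)), runif(n, 60, 300))
    thr <- sample(c(6, 7.5, 30), 1)
    gr <- detect_gaps(tr, thr)
    covered <- unlist(Map(seq, gr$runs$start, gr$runs$end))
    expect_identical(sort(covered), seq_len(n))        # exact partition
    within_run <- sum(tr$time[gr$runs$end] - tr$time[gr$runs$start])
    expect_equal(gr$excluded_minutes + within_run,
                 tr$time[n] - tr$time[1])              # time balance
  }
})

test_that("decimation keeps every k-th sample and scales the nominal interval", {
  tr <- make_regular_trace(rep(c(40, 400), 1008))  # 2016 samples at 5 min
  r2 <- resample_trace(tr, 2)
  expect_equal(length(r2), 1008L)
  expect_equal(unique(diff(r2$time)), 10)
  expect_equal(r2$nominal_interval, 10)
  expect_identical(resample_trace(tr, 1), tr)
  expect_error(resample_trace(tr, 0), "positive integer")
  expect_error(resample_trace(make_regular_trace(c(100, 110)), 2),
               "insufficient data")
})
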