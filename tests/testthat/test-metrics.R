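test_that("mean/SD/CV match hand-worked values (sample SD, n-1)", {
  expect_equal(mean_sd_cv(make_regular_trace(rep(100, 10)))$sd, 0)
  expect_equal(mean_sd_cv(make_regular_trace(rep(100, 10)))$cv, 0)

  two <- make_regular_trace(c(40, 400))
  expect_equal(mean_sd_cv(two)$sd, 180 * sqrt(2), tolerance = 1e-12)
  expect_equal(mean_sd_cv(two)$sd, 254.558, tolerance = 1e-4)

  # equal-dwell 40/400 wave, 2016 samples: SD = 180 * sqrt(2016/2015)
  wave <- square_wave(12)
  msc <- mean_sd_cv(wave)
  expect_equal(msc$sd, 180 * sqrt(2016 / 2015), tolerance = 1e-12)
  expect_equal(round(msc$sd, 2), 180.04)
  expect_equal(round(msc$cv, 4), 0.8184)
})

test_that("distance traveled sums |dy| within runs", {
  expect_equal(distance_traveled(make_regular_trace(rep(100, 5))), 0)
  expect_equal(distance_traveled(make_regular_trace(c(460, 100))), 360)

  # 12-h full cycle over 168 h: 27 sampled transitions of 360 mg/dL
  expect_equal(distance_traveled(square_wave(12)), 27 * 360)

  # segments across a gap do not contribute
  gappy <- glucose_trace(c(0, 5, 10, 60, 65), c(100, 150, 120, 300, 310))
  expect_equal(distance_traveled(gappy), 50 + 30 + 10)
})

test_that("MAG is distance traveled per within-run hour, exactly", {
  expect_equal(round(mag(square_wave(12)), 1), 57.9)
  expect_equal(round(mag(square_wave(168)), 1), 2.1)
  expect_equal(mag(make_regular_trace(rep(150, 10))), 0)

  for (seed in 1:10) {
    tr <- random_walk_trace(seed, n = 55)
    gaps <- detect_gaps(tr)
    seg <- decompose_segments(tr, gaps)
    hours <- sum(seg$dx) / 60
    expect_equal(mag(tr, gaps) * hours, distance_traveled(tr, gaps),
                 tolerance = 1e-15)  # exact up to one rounding of d/h * h
  }
})

test_that("CONGA matches its definition and the brute-force oracle", {
  expect_equal(conga(make_regular_trace(rep(100, 30))), 0)

  # exact linear ramp: all lagged differences equal, SD = 0
  ramp <- make_regular_trace(100 + (0:49) * 2)
  expect_equal(conga(ramp, 1), 0, tolerance = 1e-12)
  expect_equal(conga(ramp, 2), 0, tolerance = 1e-12)

  wave <- square_wave(12)
  expect_equal(conga(wave, 1), brute_conga(wave, 1), tolerance = 1e-9)

  for (seed in 1:5) {
    tr <- random_walk_trace(seed, n = 60)
    expect_equal(conga(tr, 1), brute_conga(tr, 1), tolerance = 1e-9)
  }

  short <- make_regular_trace(c(100, 110, 120))
  expect_error(conga(short, 1), "insufficient data")
})

test_that("MAGE follows the turning-point/1-SD rule", {
  expect_equal(mage(make_regular_trace(rep(100, 10))), 0)

  # square wave: every excursion has amplitude 360 > SD (180.04)
  expect_equal(mage(square_wave(12)), 360)
  expect_equal(mage(square_wave(24)), 360)

  # sinusoid sampled peak-to-trough: excursions 2A > SD (~A/sqrt(2))
  k <- 0:(2016 - 1)
  sine <- make_regular_trace(220 - 100 * cos(2 * pi * k / 72))
  expect_equal(mage(sine), 200, tolerance = 1e-9)

  for (seed in 1:10) {
    tr <- random_walk_trace(seed, n = 80, step_sd = 15)
    expect_equal(mage(tr), brute_mage(tr), tolerance = 1e-9)
    m <- mage(tr)
    expect_true(m == 0 || m > sd(tr$glucose))
  }
})

test_that("dispersion metrics ignore sample order; path metrics do not", {
  wave <- square_wave(12)
  set.seed(99)
  shuffled <- make_regular_trace(sample(wave$glucose))
  expect_equal(mean_sd_cv(shuffled)$sd, mean_sd_cv(wave)$sd)
  expect_equal(mean_sd_cv(shuffled)$cv, mean_sd_cv(wave)$cv)
  expect_false(isTRUE(all.equal(mag(shuffled), mag(wave))))
  expect_false(isTRUE(all.equal(gvp(shuffled)$gvp_percent,
                                gvp(wave)$gvp_percent)))
})

test_that("scaling deviations about the mean scales amplitude metrics", {
  tr <- random_walk_trace(11, n = 90, step_sd = 10)
  m <- mean(tr$glucose)
  c_ <- 2.5
  scaled <- make_regular_trace(m + c_ * (tr$glucose - m))
  expect_equal(mean_sd_cv(scaled)$sd, c_ * mean_sd_cv(tr)$sd)
  expect_equal(distance_traveled(scaled), c_ * distance_traveled(tr))
  expect_equal(mag(scaled), c_ * mag(tr))
  expect_equal(mage(scaled), c_ * mage(tr))
})

test_that("metrics_bundle assembles all metrics consistently", {
  wave <- square_wave(12)
  b <- metrics_bundle(wave)
  expect_equal(b$mean, 220)
  expect_equal(round(b$sd, 2), 180.04)
  expect_equal(b$mag, mag(wave))
  expect_equal(b$conga_1h, conga(wave, 1))
  expect_equal(b$mage, 360)
  expect_equal(b$gvp_percent, gvp(wave)$gvp_percent)
  expect_equal(b$distance_traveled, 9720)
})
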