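test_that("time-domain features reproduce hand-computed cases", {
  td <- hrv_time_domain(c(800, 800, 800))
  expect_equal(td$mean_nn, 800)
  expect_equal(td$sdnn, 0)
  expect_equal(td$rmssd, 0)
  expect_equal(td$pnn50, 0)

  td2 <- hrv_time_domain(c(700, 800, 900))
  expect_equal(td2$mean_nn, 800)
  expect_equal(td2$sdnn, sqrt(20000 / 3))
  expect_equal(td2$rmssd, 100)

  # pNN50 with the interval-count denominator: 3 of 4 diffs exceed 50 ms,
  # divided by the 5 intervals
  td3 <- hrv_time_domain(c(800, 860, 870, 1000, 940))
  expect_equal(td3$pnn50, 60)
  td3b <- hrv_time_domain(c(800, 860, 870, 1000, 940),
                          pnn50_denominator = "differences")
  expect_equal(td3b$pnn50, 75)

  expect_error(hrv_time_domain(800), class = "vf_insufficient_data")
})

test_that("time-domain and Poincare features match the naive-loop oracle", {
  set.seed(101)
  for (i in 1:100) {
    rr <- runif(150, 500, 1200)
    td <- hrv_time_domain(rr)
    or <- oracle_time_domain(rr)
    expect_equal(td$mean_nn, or$mean_nn, tolerance = 1e-9)
    expect_equal(td$sdnn, or$sdnn, tolerance = 1e-9)
    expect_equal(td$rmssd, or$rmssd, tolerance = 1e-9)
    expect_equal(td$pnn50, or$pnn50, tolerance = 1e-9)
    pc <- hrv_poincare(rr)
    op <- oracle_poincare(rr)
    expect_equal(pc$sd1, op$sd1, tolerance = 1e-9)
    expect_equal(pc$sd2, op$sd2, tolerance = 1e-9)
  }
})

test_that("offset invariance: dispersion features ignore a constant shift", {
  set.seed(7)
  rr <- runif(200, 600, 1000)
  a <- hrv_time_domain(rr)
  b <- hrv_time_domain(rr + 250)
  expect_equal(b$mean_nn, a$mean_nn + 250)
  expect_equal(b$sdnn, a$sdnn)
  expect_equal(b$rmssd, a$rmssd)
  expect_equal(b$pnn50, a$pnn50)
  expect_equal(hrv_poincare(rr + 250)$sd1, hrv_poincare(rr)$sd1)
})

test_that("Poincare dispersions: alternating series and the SDNN identity", {
  expect_warning(pc0 <- hrv_poincare(rep(800, 10)), "SD1/SD2 is undefined")
  expect_equal(pc0$sd1, 0)

  # long +/-25 ms alternation: SD1 -> 50/sqrt(2), SD2 -> 0 (clamped)
  x <- rep(c(800, 850), length.out = 999)
  pc <- suppressWarnings(hrv_poincare(x))
  expect_equal(pc$sd1, 50 / sqrt(2), tolerance = 1e-3)
  expect_lt(pc$sd2, 0.1)
  expect_true(is.na(suppressWarnings(hrv_poincare(rep(800, 5)))$sd1_sd2))

  # sd1^2 + sd2^2 = 2 sdnn^2 by construction, to 1e-9 relative
  set.seed(33)
  for (i in 1:50) {
    rr <- runif(120, 500, 1100)
    pc <- hrv_poincare(rr)
    sdnn <- hrv_time_domain(rr)$sdnn
    expect_equal(pc$sd1^2 + pc$sd2^2, 2 * sdnn^2,
                 tolerance = 1e-9)
  }
})

test_that("rmssd approaches sqrt(2) * sd1 for long stationary series", {
  rr <- generate_rr(group_params(mean_rr = 800, rr_noise_sd = 40),
                    duration = 8100, seed = 13)
  expect_gt(nrow(rr), 9900)
  r <- hrv_time_domain(rr)$rmssd
  s1 <- hrv_poincare(rr)$sd1
  n <- nrow(rr)
  expect_equal(r, 2 * s1 / sqrt(2 * (n - 1) / n), tolerance = 0.01)
})

test_that("band powers land in the band of the driving modulation", {
  # 0.10 Hz sinusoidal tachogram: power concentrates in LF
  rr_lf <- generate_rr(group_params(mean_rr = 800, lf_mod_amp = 30,
                                    lf_mod_freq = 0.10),
                       duration = 120, seed = 1)
  fd <- hrv_frequency_domain(rr_lf)
  expect_gte(fd$lf / (fd$vlf + fd$lf + fd$hf), 0.8)

  # 0.25 Hz modulation: HF dominates
  rr_hf <- generate_rr(group_params(mean_rr = 800, hf_mod_amp = 30,
                                    hf_mod_freq = 0.25),
                       duration = 120, seed = 1)
  fdh <- hrv_frequency_domain(rr_hf)
  expect_gt(fdh$hf, fdh$lf)
  expect_gt(fdh$hf, fdh$vlf)

  # constant tachogram: numerically zero power
  fdc <- suppressWarnings(
    hrv_frequency_domain(generate_rr(group_params(), 120, seed = 1)))
  expect_lt(fdc$vlf + fdc$lf + fdc$hf, 1e-6)
})

test_that("band powers are additive over (0, 0.4] and need 64 s of data", {
  rr <- generate_rr(group_params(mean_rr = 800, rr_noise_sd = 40,
                                 lf_mod_amp = 20, hf_mod_amp = 15),
                    duration = 180, seed = 21)
  fd <- hrv_frequency_domain(rr)
  t <- rr$t
  grid <- seq(t[1], t[length(t)], by = 1 / 4)
  tach <- spline(t, rr$rr, xout = grid)$y
  k <- seq_along(tach)
  fit <- lm(tach ~ k)
  psd <- welch_psd(resid(fit), fs = 4)
  total <- sum(psd$psd[psd$freq > 0 & psd$freq <= 0.4]) * 4 / 256
  expect_equal(fd$vlf + fd$lf + fd$hf, total, tolerance = 1e-9)

  short <- rr_series(rep(800, 50))
  expect_error(hrv_frequency_domain(short), class = "vf_insufficient_data")
})

test_that("Welch estimator recovers the power of a known sinusoid", {
  # cross-check against the analytic A^2/2 total power
  fs <- 4
  t <- seq(0, 300, by = 1 / fs)
  x <- 30 * sin(2 * pi * 0.1 * t)
  psd <- welch_psd(x, fs = fs)
  total <- sum(psd$psd) * fs / 256
  expect_equal(total, 30^2 / 2, tolerance = 0.05)
})

test_that("full HRV row has the 11 canonical columns", {
  rr <- generate_rr(group_params(mean_rr = 800, rr_noise_sd = 40,
                                 lf_mod_amp = 20, hf_mod_amp = 10),
                    duration = 120, seed = 5)
  row <- hrv_features(rr)
  expect_named(row, c("mean_nn", "sdnn", "rmssd", "pnn50", "vlf", "lf",
                      "hf", "lf_hf", "sd1", "sd2", "sd1_sd2"))
  expect_true(all(vapply(row, is.numeric, logical(1))))
})
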