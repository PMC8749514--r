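test_that("time-domain features match hand-computed values", {
  f <- hrv_time_features(c(800, 860, 870))
  # successive diffs 60, 10
  expect_equal(unname(f["meanNN"]), mean(c(800, 860, 870)))
  expect_equal(unname(f["NN50"]), 1)
  expect_equal(unname(f["RMSSD"]), sqrt((60^2 + 10^2) / 2), tolerance = 1e-12)
  expect_equal(unname(f["SDNN"]), sqrt(mean((c(800, 860, 870) - f["meanNN"])^2)))
  expect_equal(unname(f["total_power"]), unname(f["SDNN"])^2)
})

test_that("NN50 uses a strict > 50 ms boundary", {
  expect_equal(unname(hrv_time_features(c(750, 810))["NN50"]), 1)  # diff 60
  expect_equal(unname(hrv_time_features(c(750, 800))["NN50"]), 0)  # diff exactly 50
  expect_equal(unname(hrv_time_features(c(750, 800.001))["NN50"]), 1)
})

test_that("constant intervals give zero-variability features", {
  f <- hrv_time_features(rep(800, 20))
  expect_equal(unname(f), c(800, 0, 0, 0, 0))
  expect_error(hrv_time_features(800), "at least 2")
})

test_that("AR spectrum satisfies a Parseval-style power identity on white noise", {
  set.seed(101)
  x <- rnorm(2000, sd = 30)
  psd <- ar_psd(x, order = 10, interval = 1)
  total <- band_power(psd, 0, 0.5)
  expect_equal(total, mean((x - mean(x))^2), tolerance = 0.15)
})

test_that("AR spectrum locates a sinusoidal peak", {
  set.seed(102)
  tt <- 0:999
  x <- sin(2 * pi * 0.25 * tt) + rnorm(1000, sd = 0.05)
  psd <- ar_psd(x, order = 10)
  expect_lt(abs(psd$frequencies[which.max(psd$densities)] - 0.25), 0.02)
  expect_true(all(psd$densities >= 0))
})

test_that("AR fit rejects series shorter than the model order", {
  expect_error(ar_psd(rnorm(5), order = 10), "insufficient")
})

test_that("band powers integrate the spectrum consistently", {
  set.seed(103)
  psd <- ar_psd(rnorm(500), order = 10)
  total <- band_power(psd, 0, 0.5)
  lf <- band_power(psd, 0.04, 0.15)
  hf <- band_power(psd, 0.15, 0.40)
  expect_lte(lf + hf, total + 1e-9)
  # partition additivity
  parts <- band_power(psd, 0, 0.2) + band_power(psd, 0.2, 0.5)
  expect_equal(parts, total, tolerance = 1e-9)
  expect_error(band_power(psd, 0.3, 0.1), "invalid band")

  flat <- structure(list(frequencies = seq(0, 0.5, length.out = 512),
                         densities = rep(1, 512), model_order = 0),
                    class = "ar_psd")
  expect_equal(band_power(flat, 0.04, 0.15), 0.11, tolerance = 1e-12)
})

test_that("window feature vector has the eight named features in fixed order", {
  rri <- make_rri(duration = 300, noise_sd = 5)
  ends <- slide_windows(rri, 120, 1)
  f <- hrv_window_features(rri, ends[1], window = 120)
  expect_length(f, 8)
  expect_named(f, c("meanNN", "SDNN", "RMSSD", "total_power", "NN50",
                    "LF", "HF", "LF_HF"))
  df <- extract_hrv_features(rri, window = 120, slide = 30)
  expect_equal(names(df), c("t_end", names(f)))
  expect_equal(nrow(df), length(slide_windows(rri, 120, 30)))
})

test_that("a constant-RRI window has essentially no spectral power", {
  rri <- rri_series(cumsum(rep(0.8, 200)), rep(800, 200))
  f <- hrv_window_features(rri, end_time = 140, window = 120)
  expect_lt(unname(f["LF"]), 1e-6 * f["meanNN"]^2)
  expect_lt(unname(f["HF"]), 1e-6 * f["meanNN"]^2)
})

test_that("an LF-dominant rhythm yields LF > HF, cross-checked by periodogram", {
  # 25 ms at 0.10 Hz (LF band) vs 15 ms at 0.30 Hz (HF band)
  rri <- make_rri(duration = 300, lf = 25, hf = 15, noise_sd = 0)
  f <- hrv_window_features(rri, end_time = 200, window = 120)
  expect_gt(unname(f["LF"]), unname(f["HF"]))
  expect_gt(unname(f["LF_HF"]), 1)

  # independent oracle: raw periodogram of the resampled window
  rs <- resample_rri(rri)
  x <- as.numeric(window_payload(rs, 200, 120))
  pg <- spec.pgram(ts(x, frequency = 1), taper = 0, plot = FALSE, detrend = TRUE)
  lf_pg <- sum(pg$spec[pg$freq >= 0.04 & pg$freq <= 0.15])
  hf_pg <- sum(pg$spec[pg$freq > 0.15 & pg$freq <= 0.40])
  expect_gt(lf_pg, hf_pg)
})

test_that("spectral features are invariant to a constant RRI shift", {
  set.seed(104)
  x <- 800 + 20 * sin(2 * pi * 0.1 * (0:199)) + rnorm(200, sd = 5)
  p1 <- ar_psd(x, order = 10)
  p2 <- ar_psd(x + 150, order = 10)
  expect_equal(p1$densities, p2$densities, tolerance = 1e-8)
})

test_that("features scale correctly when all intervals are scaled", {
  iv <- c(820, 840, 790, 860, 810, 795, 830)
  f1 <- hrv_time_features(iv)
  f2 <- hrv_time_features(iv * 2)
  expect_equal(unname(f2[c("meanNN", "SDNN", "RMSSD")]),
               unname(2 * f1[c("meanNN", "SDNN", "RMSSD")]))
  expect_equal(unname(f2["total_power"]), unname(4 * f1["total_power"]))

  set.seed(105)
  x <- 800 + 20 * sin(2 * pi * 0.1 * (0:199)) + rnorm(200, sd = 5)
  p1 <- ar_psd(x, order = 10); p2 <- ar_psd(3 * x, order = 10)
  lf1 <- band_power(p1, 0.04, 0.15); hf1 <- band_power(p1, 0.15, 0.40)
  lf2 <- band_power(p2, 0.04, 0.15); hf2 <- band_power(p2, 0.15, 0.40)
  expect_equal(lf2, 9 * lf1, tolerance = 1e-6)
  expect_equal(lf2 / hf2, lf1 / hf1, tolerance = 1e-6)
})

test_that("NN50 is invariant to reversing the interval sequence", {
  set.seed(106)
  for (i in 1:10) {
    iv <- 800 + rnorm(30, sd = 40)
    expect_equal(unname(hrv_time_features(iv)["NN50"]),
                 unname(hrv_time_features(rev(iv))["NN50"]))
  }
})
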