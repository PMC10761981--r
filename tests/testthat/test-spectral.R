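test_that("preprocessing decimates and low-passes as specified", {
  fs_in <- 20000
  n <- fs_in * 4
  t <- (seq_len(n) - 1) / fs_in
  w <- sblfp:::with_seed(1, rnorm(n))
  out <- preprocess(w, fs_in)
  expect_equal(out$fs, 5000)
  expect_equal(length(out$x), n / 4)
  # 400 Hz attenuated by >= 20 dB relative to 100 Hz
  x100 <- preprocess(sin(2 * pi * 100 * t), fs_in)$x
  x400 <- preprocess(sin(2 * pi * 400 * t), fs_in)$x
  a100 <- tone_amplitude(x100, 5000, 100)
  a400 <- tone_amplitude(x400, 5000, 400)
  expect_gt(20 * log10(a100 / a400), 20)
  expect_gt(a100, 0.95)
  # DC passes unchanged
  dc <- preprocess(rep(2, n), fs_in)$x
  expect_equal(mean(dc), 2, tolerance = 1e-3)
  expect_error(preprocess(w, 1000), "below the target")
})

test_that("dpss tapers are orthonormal and spectrally concentrated", {
  for (n in c(500, 5000)) {
    v <- dpss_tapers(n, nw = 2, k = 3)
    expect_equal(crossprod(v), diag(3), tolerance = 1e-8,
                 ignore_attr = TRUE)
    conc <- vapply(1:3, function(j) dpss_concentration(v[, j], 2 / n),
                   numeric(1))
    expect_gt(conc[1], 0.999)
    expect_gt(conc[2], 0.99)
    expect_gt(conc[3], 0.9)
  }
})

test_that("spectrogram localizes tones and satisfies Parseval", {
  fs <- 500
  t <- (seq_len(fs * 60) - 1) / fs
  tf <- spectrogram(sin(2 * pi * 8 * t), fs)
  expect_equal(tf$freqs[2] - tf$freqs[1], 0.5)
  expect_equal(tf$time_bins[2] - tf$time_bins[1], 0.5)
  expect_equal(tf$freqs[which.max(rowMeans(tf$power))], 8)
  th <- band_power_series(tf, "theta")
  gm <- band_power_series(tf, "gamma")
  expect_gt(mean(th$values), 1000 * mean(gm$values))
  # Parseval within 5% on white noise
  x <- sblfp:::with_seed(2, rnorm(fs * 60, sd = 3))
  tfw <- spectrogram(x, fs, fmax = fs / 2)
  integral <- mean(colSums(tfw$power)) * (tfw$freqs[2] - tfw$freqs[1])
  expect_equal(integral / var(x), 1, tolerance = 0.05)
  # amplitude step x2 -> band power x4
  amp <- ifelse(t < 30, 1, 2)
  tfs <- spectrogram(amp * sin(2 * pi * 8 * t), fs)
  bs <- band_power_series(tfs, "theta")
  expect_equal(mean(bs$values[bs$time_bins > 32]) /
                 mean(bs$values[bs$time_bins < 28]), 4, tolerance = 0.05)
  expect_error(spectrogram(rnorm(100), fs), "shorter than one")
})

test_that("band power series averages and masks correctly", {
  # constructed flat spectrogram: band power equals the constant
  tf <- structure(list(power = matrix(3, 41, 20),
                       freqs = seq(0, 20, by = 0.5),
                       time_bins = seq(0.5, 10, by = 0.5), fs = 50,
                       window_s = 2, step_s = 0.5), class = "tf_power")
  bp <- band_power_series(tf, c(4, 12))
  expect_true(all(bp$values == 3))
  # masked bins excluded: period mean equals a direct average oracle
  bp2 <- bp
  bp2$values <- seq_along(bp$values)
  excl <- matrix(c(2, 4), 1)
  got <- period_band_mean(bp2, c(0, 10), excl)
  keep <- bp2$time_bins < 2 | bp2$time_bins >= 4
  expect_equal(got, mean(bp2$values[keep & bp2$time_bins < 10]))
})

test_that("encounter power gain is recovered in the right band only", {
  cfg <- sim_config(regions = c("AcbC", "BLA"), sampling_rate = 500,
                    baseline_s = 120, encounter_s = 120,
                    encounter_gain = list(theta = 1.5, gamma = 1))
  res <- simulate_session(cfg, "m01", "SP", 1, seed = 4)
  dth <- delta_band_power(res$session, "AcbC", "theta")
  dgm <- delta_band_power(res$session, "AcbC", "gamma")
  expect_gt(dth$delta, 0)
  expect_equal(dth$delta,
               dth$mean_encounter_power - dth$mean_baseline_power)
  # gamma unaffected: |relative change| well under the theta change
  rel_g <- abs(dgm$delta) / dgm$mean_baseline_power
  rel_t <- dth$delta / dth$mean_baseline_power
  expect_lt(rel_g, 0.2 * rel_t)
})

test_that("bout power averaging is duration-weighted with a baseline reference", {
  # hand-built series: three bouts with constant band power 4, 6, 8 and
  # empty-chamber baseline power 2 -> value = mean(4,6,8) - 2 = 4
  bp <- list(values = rep(2, 40), time_bins = seq(0.25, 10, by = 0.25))
  bout_bins <- list(`4` = 5:8, `6` = 13:16, `8` = 25:28)
  for (v in names(bout_bins)) bp$values[bout_bins[[v]]] <- as.numeric(v)
  bouts <- data.frame(start_s = c(1.1, 3.1, 6.1), end_s = c(2.1, 4.1, 7.1))
  got <- sblfp:::bout_series_mean(bp, bouts)
  expect_equal(got, 6)
  # duration weighting: a 2x longer high-power bout pulls the mean up
  bouts2 <- data.frame(start_s = c(1.1, 6.1), end_s = c(2.1, 8.1))
  bp$values[25:32] <- 8
  expect_equal(sblfp:::bout_series_mean(bp, bouts2), (4 * 4 + 8 * 8) / 12)
  expect_equal(sblfp:::bout_series_mean(bp, bouts2, per_bout = TRUE), 6)
  # full operation: bout-locked gamma gain for one stimulus only
  cfg <- sim_config(regions = c("AcbC", "BLA"), sampling_rate = 500,
                    baseline_s = 100, encounter_s = 100,
                    encounter_gain = list(theta = 1, gamma = 1),
                    bout_gain = list(gamma = c(social = 1.6)),
                    bout_gap_mean_s = 4)
  res <- simulate_session(cfg, "m01", "SP", 1, seed = 6)
  bbp <- bout_band_power(res$session, res$bouts, "AcbC", "gamma")
  v_soc <- bbp$value[bbp$stimulus == "social"]
  v_obj <- bbp$value[bbp$stimulus == "object"]
  expect_gt(v_soc, 0)
  if (is.finite(v_obj)) expect_gt(v_soc, abs(v_obj) * 2)
})

test_that("event z-scores use the pre-event window and average per event", {
  step <- 0.5
  bins <- seq(step / 2, 100, by = step)
  vals <- sblfp:::with_seed(11, rnorm(length(bins), mean = 10, sd = 0.5))
  # step x2 at t = 50
  vals[bins >= 50] <- vals[bins >= 50] + 10
  bp <- list(values = vals, time_bins = bins)
  ev <- data.frame(time_s = 50)
  z <- event_zscore(bp, ev)
  expect_equal(z$n_events, 1L)
  expect_equal(mean(z$z[z$rel_time < 0]), 0, tolerance = 0.5)
  expect_gt(mean(z$z[z$rel_time > 0]), 5)
  # zero pre-event SD drops the event
  bpc <- list(values = rep(1, length(bins)), time_bins = bins)
  z0 <- event_zscore(bpc, ev)
  expect_equal(z0$n_events, 0L)
  # averaging order matches a direct per-event oracle
  vals2 <- sblfp:::with_seed(12, rnorm(length(bins), 5, 1))
  bp2 <- list(values = vals2, time_bins = bins)
  evs <- data.frame(time_s = c(20, 40, 60))
  zm <- event_zscore(bp2, evs)
  oracle <- rowMeans(vapply(evs$time_s, function(t0) {
    k <- findInterval(t0 - 1e-9, bins)
    pre <- vals2[(k - 9):k]
    (vals2[(k - 9):(k + 10)] - mean(pre)) / sd(pre)
  }, numeric(20)))
  expect_equal(zm$z, oracle)
  # invariance to global rescaling of the power trace
  bp3 <- list(values = 7.3 * vals2, time_bins = bins)
  expect_equal(event_zscore(bp3, evs)$z, zm$z)
})

test_that("event-category comparison detects a constructed offset", {
  mkz <- function(offset, seed) {
    lapply(1:8, function(k) {
      z <- sblfp:::with_seed(seed + k, rnorm(20, offset, 0.2))
      list(z = z, rel_time = seq(-4.75, 4.75, by = 0.5), n_events = 10L)
    })
  }
  res <- compare_event_categories(mkz(1, 100), mkz(0, 200))
  expect_lt(res$p, 0.01)
  expect_gt(res$means[["A"]], res$means[["B"]])
  # identical session lists: difference exactly zero
  zA <- mkz(0.5, 300)
  res0 <- compare_event_categories(zA, zA)
  expect_equal(res0$p, 1)
  expect_error(compare_event_categories(zA[1], zA[1]), "two sessions")
})
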