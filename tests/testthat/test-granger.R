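test_that("GC-rate downsampling keeps the passband and kills aliases", {
  fs <- 5000
  t <- (seq_len(fs * 4) - 1) / fs
  y <- downsample_for_gc(rnorm(fs * 4), fs, 500)
  expect_length(y, ceiling(fs * 4 / 10))
  a8 <- tone_amplitude(downsample_for_gc(sin(2 * pi * 8 * t), fs), 500, 8)
  expect_equal(a8, 1, tolerance = 0.01)
  a240 <- tone_amplitude(downsample_for_gc(sin(2 * pi * 240 * t), fs), 500, 240)
  expect_gt(a240, 0.7)
  # 260 Hz folds to 240 Hz after decimation; it must arrive attenuated
  a260 <- tone_amplitude(downsample_for_gc(sin(2 * pi * 260 * t), fs), 500, 240)
  expect_gt(20 * log10(a240 / a260), 20)
  expect_error(downsample_for_gc(y, 750, 500), "integer multiple")
})

test_that("BIC selects the true order and LWR matches OLS", {
  # stable VAR(5) on 3 channels
  A <- lapply(1:5, function(k) matrix(0, 3, 3))
  A[[1]][1, 1] <- 0.4; A[[1]][2, 2] <- 0.3; A[[1]][3, 3] <- 0.35
  A[[5]][2, 1] <- 0.3; A[[5]][1, 3] <- -0.25; A[[5]][3, 2] <- 0.2
  m <- var_model(A, diag(3))
  x <- simulate_var_network(m, 50000, seed = 1)
  sel <- select_model_order(x, 10)
  expect_equal(sel$order, 5)
  # white noise: minimum order
  xw <- sblfp:::with_seed(2, matrix(rnorm(3 * 20000), 3))
  expect_equal(select_model_order(xw, 8)$order, 1)
  # constrained search warns at the boundary
  expect_warning(selb <- select_model_order(x, 3), "p_max")
  expect_equal(selb$order, 3)
  expect_true(selb$at_boundary)
  # coefficient recovery and estimator agreement
  fit_l <- fit_var(x, 5, method = "lwr")
  fit_o <- fit_var(x, 5, method = "ols")
  expect_lt(max(abs(fit_l$A[[5]] - A[[5]])), 0.02)
  for (k in 1:5)
    expect_equal(fit_l$A[[k]], fit_o$A[[k]], tolerance = 1e-2,
                 ignore_attr = TRUE)
  # white-noise fit: coefficients ~ 0, Sigma ~ sample covariance
  fw <- fit_var(xw, 2)
  expect_lt(max(abs(fw$A[[1]])), 0.05)
  expect_equal(fw$Sigma, cov(t(xw)), tolerance = 0.05, ignore_attr = TRUE)
})

test_that("spectral pairwise-conditional GC matches oracles", {
  # bivariate canonical system: frequency-average equals ln 2; reverse ~ 0
  m <- var_model(list(matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE)), diag(2))
  x <- simulate_var_network(m, 50000, seed = 3)
  fit <- fit_var(x, select_model_order(x, 8)$order)
  G <- var_to_autocov(fit)
  sp <- spectral_pairwise_conditional_gc(G, n_freqs = 256, fs = 500)
  gb <- band_gc(sp, "all")
  expect_equal(gb[2, 1], log(2), tolerance = 0.05)
  expect_lt(gb[1, 2], 0.01)
  expect_true(all(sp$f >= 0, na.rm = TRUE))
  # Geweke equality on a system with dynamics
  A2 <- list(matrix(c(0.5, 0, 0.4, 0.4), 2, 2, byrow = TRUE))
  m2 <- var_model(A2, diag(2))
  G2 <- var_to_autocov(m2, max_lags = 300, decay_tol = 1e-12)
  sp2 <- spectral_pairwise_conditional_gc(G2, n_freqs = 1024, fs = 500)
  expect_equal(band_gc(sp2, "all")[2, 1], time_domain_gc(G2, 2, 1),
               tolerance = 1e-3)
  # independent channels: all GC ~ 0
  m0 <- var_model(list(diag(c(0.3, 0.3, 0.3))), diag(3))
  x0 <- simulate_var_network(m0, 30000, seed = 4)
  G0 <- var_to_autocov(fit_var(x0, 2))
  g0 <- band_gc(spectral_pairwise_conditional_gc(G0, 128, 500), "all")
  expect_lt(max(g0, na.rm = TRUE), 0.01)
  # chain x -> y -> z: conditional GC(x -> z | y) suppressed while the
  # bivariate (unconditional) GC(x -> z) is clearly positive
  A3 <- matrix(0, 3, 3); diag(A3) <- 0.3; A3[2, 1] <- 0.8; A3[3, 2] <- 0.8
  mc <- var_model(list(A3), diag(3))
  xc <- simulate_var_network(mc, 100000, seed = 5)
  Gc <- var_to_autocov(fit_var(xc, select_model_order(xc, 8)$order))
  gc3 <- band_gc(spectral_pairwise_conditional_gc(Gc, 128, 500), "all")
  expect_lt(gc3[3, 1], 0.02)
  Gxz <- var_to_autocov(fit_var(xc[c(1, 3), ], 10))
  gxz <- band_gc(spectral_pairwise_conditional_gc(Gxz, 128, 500), "all")
  expect_gt(gxz[2, 1], 0.05)
})

test_that("band summaries of GC spectra behave as integrals", {
  # flat spectrum of value c -> band value c for any band
  f <- array(NA_real_, dim = c(2, 2, 101))
  f[1, 2, ] <- 0.4; f[2, 1, ] <- 0.4
  sp <- structure(list(f = f, freqs = seq(0, 250, length.out = 101), fs = 500),
                  class = "gc_spectra")
  expect_equal(band_gc(sp, "theta")[2, 1], 0.4)
  expect_equal(band_gc(sp, "all")[1, 2], 0.4)
  # band-confined spectrum: theta >> gamma
  f2 <- f
  f2[2, 1, ] <- ifelse(sp$freqs >= 4 & sp$freqs <= 12, 1, 0.001)
  sp2 <- structure(list(f = f2, freqs = sp$freqs, fs = 500),
                   class = "gc_spectra")
  expect_gt(band_gc(sp2, "theta")[2, 1], 50 * band_gc(sp2, "gamma")[2, 1])
})

test_that("encounter-only coupling is detected with correct direction", {
  # 6 sessions with a directed AcbC -> vDG theta coupling during encounter
  cfg <- sim_config(n_subjects = 2, regions = c("AcbC", "vDG"),
                    sampling_rate = 500, baseline_s = 120, encounter_s = 120,
                    encounter_gain = list(theta = 1, gamma = 1),
                    gc_couplings = list(list(from = "AcbC", to = "vDG",
                                             coef = 0.8, lag_s = 0.01,
                                             period = "encounter")))
  ds <- simulate_dataset(cfg, seed = 9, n_sessions = 3)
  ch <- gc_session_changes(ds, c("AcbC", "vDG"), "theta",
                           p_max = 12, n_freqs = 64)
  res <- gc_change_analysis(ch, min_sessions = 5)
  fwd <- res[res$from == "AcbC" & res$to == "vDG", ]
  bwd <- res[res$from == "vDG" & res$to == "AcbC", ]
  expect_gt(fwd$median_change, 0)
  expect_lt(fwd$p_adj, 0.05)
  expect_gt(fwd$median_change, 5 * abs(bwd$median_change))
  asym <- directional_asymmetry(ch, min_sessions = 5)
  expect_lt(asym$p_adj[1], 0.05)
  expect_gt(asym$median_d[1], 0)  # AcbC < vDG lexicographically: fw = AcbC->vDG
  # antisymmetry of the statistic under swapping the directions
  ch_sw <- ch
  ch_sw$from <- ch$to; ch_sw$to <- ch$from
  asym_sw <- directional_asymmetry(ch_sw, min_sessions = 5)
  expect_equal(asym_sw$median_d, -asym$median_d)
  expect_equal(asym_sw$p, asym$p)
})

test_that("no state change yields no GC rejections", {
  cfg <- sim_config(n_subjects = 2, regions = c("AcbC", "vDG"),
                    sampling_rate = 500, baseline_s = 120, encounter_s = 120,
                    encounter_gain = list(theta = 1, gamma = 1))
  ds <- simulate_dataset(cfg, seed = 13, n_sessions = 3)
  ch <- gc_session_changes(ds, c("AcbC", "vDG"), "theta",
                           p_max = 12, n_freqs = 64)
  res <- gc_change_analysis(ch, min_sessions = 5)
  expect_true(all(res$p_adj > 0.05))
})
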