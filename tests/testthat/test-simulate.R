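# Simulator: condition templates, spectral tachograms, noise injection and
# PQRST rendering.

test_that("condition templates carry the printed parameter sets", {
  det <- condition_params("DET")
  expect_equal(det$waves$theta_deg, c(-70, -15, 0, 15, 100))
  expect_equal(det$waves$a, c(1.2, -5, 30, -7.5, 0.75))
  expect_equal(det$waves$b, c(0.25, 0.1, 0.1, 0.1, 0.4))
  expect_equal(det$trace_noise_fraction, 0.01)
  expect_false(det$pq_noise)

  lqt <- condition_params("LQT")
  expect_equal(lqt$waves$b[lqt$waves$wave == "T"], 0.6)
  expect_equal(lqt$waves[lqt$waves$wave != "T", ],
               det$waves[det$waves$wave != "T", ])

  af <- condition_params("AF")
  expect_equal(af$waves$a[af$waves$wave == "P"], 0.2)
  expect_equal(af$waves$b[af$waves$wave == "P"], 0.125)
  expect_true(af$pq_noise)
  expect_equal(af$waves[af$waves$wave != "P", ],
               det$waves[det$waves$wave != "P", ])

  nse <- condition_params("NSE")
  expect_equal(nse$waves, det$waves)
  expect_equal(nse$trace_noise_fraction, 1.00)

  expect_error(condition_params("XYZ"), "unknown condition")
})

test_that("wave angles increase strictly P through T", {
  for (nm in c("DET", "AF", "LQT", "NSE")) {
    w <- condition_params(nm)$waves
    expect_false(is.unsorted(w$theta_deg, strictly = TRUE))
    expect_true(all(w$b > 0))
  }
})

test_that("zero-variance tachogram is exactly constant at 60000/mean_hr", {
  t <- build_tachogram(tachogram_spec(mean_hr = 350, sd_hr = 0,
                                      n_beats = 100))
  expect_equal(t$rr_ms, rep(60000 / 350, 100))
})

test_that("generated instantaneous HR recovers the requested mean and SD", {
  t <- build_tachogram(tachogram_spec(mean_hr = 350, sd_hr = 50,
                                      n_beats = 5000, seed = 11))
  hr <- 60000 / t$rr_ms
  expect_lt(abs(mean(hr) - 350) / 350, 0.01)
  expect_lt(abs(sd(hr) - 50) / 50, 0.02)
})

test_that("LF-dominated tachograms are more autocorrelated than HF-only", {
  ac1 <- function(x) cor(x[-1], x[-length(x)])
  for (seed in 1:5) {
    hf <- build_tachogram(tachogram_spec(lf_hf_ratio = 0, n_beats = 2000,
                                         seed = seed))
    lf <- build_tachogram(tachogram_spec(lf_hf_ratio = 1.5, n_beats = 2000,
                                         seed = seed))
    expect_lt(ac1(hf$rr_ms), ac1(lf$rr_ms))
  }
})

test_that("tachogram synthesis is reproducible under a fixed seed", {
  spec <- tachogram_spec(n_beats = 500, seed = 42)
  expect_identical(build_tachogram(spec), build_tachogram(spec))
  t <- build_tachogram(spec)
  expect_identical(add_tachogram_noise(t, 0.33, seed = 5),
                   add_tachogram_noise(t, 0.33, seed = 5))
})

test_that("noise level 0 returns the tachogram unchanged", {
  t <- build_tachogram(tachogram_spec(n_beats = 200, seed = 1))
  expect_equal(add_tachogram_noise(t, 0)$rr_ms, t$rr_ms)
})

test_that("tachogram noise inflates the RR spread monotonically", {
  levels <- c(0, 0.33, 0.66, 0.99)
  for (seed in 1:20) {
    t <- build_tachogram(tachogram_spec(n_beats = 400, seed = seed))
    sds <- vapply(levels, function(lv) {
      sd(add_tachogram_noise(t, lv, seed = 100 + seed)$rr_ms)
    }, numeric(1))
    expect_false(is.unsorted(sds))
    expect_gt(sds[4], sd(t$rr_ms))
  }
})

test_that("constant tachogram with noise falls back to the mean-scaled SD", {
  t <- build_tachogram(tachogram_spec(sd_hr = 0, n_beats = 300))
  expect_warning(out <- add_tachogram_noise(t, 0.99, seed = 1),
                 "constant tachogram")
  expect_gt(sd(out$rr_ms), 0)
  # fallback SD = level * mean(rr) * 0.01
  expect_lt(abs(sd(out$rr_ms) - 0.99 * mean(t$rr_ms) * 0.01) /
              (0.99 * mean(t$rr_ms) * 0.01), 0.2)
})

test_that("noised RR intervals never drop below the floor", {
  t <- build_tachogram(tachogram_spec(n_beats = 300, seed = 2))
  out <- add_tachogram_noise(t, 5, seed = 3)  # absurd level forces clipping
  expect_true(all(out$rr_ms >= 40))
})

test_that("zero-noise DET rendering is strictly periodic with n R peaks", {
  ecg <- make_det_ecg(n_beats = 8, fs = 1000)
  n_k <- diff(c(attr(ecg, "beat_start"), length(ecg$samples) + 1L))
  expect_true(all(n_k == n_k[1]))
  beats <- matrix(ecg$samples, nrow = n_k[1])
  for (k in 2:ncol(beats)) expect_equal(beats[, k], beats[, 1])
  expect_length(attr(ecg, "r_index"), 8)
})

test_that("rendered R amplitude matches the template R parameter", {
  for (nm in c("DET", "AF", "LQT")) {
    tac <- build_tachogram(tachogram_spec(sd_hr = 0, n_beats = 4))
    ecg <- synthesize_ecg(condition_params(nm), tac, fs = 1000,
                          trace_noise_fraction = 0, seed = 1)
    # sampling off-grid of theta = 0 and the Q/S tails shave a few percent
    expect_lt(abs(max(ecg$samples) - 30) / 30, 0.05)
  }
})

test_that("LQT T wave is wider at half maximum than DET's", {
  half_width_ms <- function(nm) {
    tac <- build_tachogram(tachogram_spec(sd_hr = 0, n_beats = 3))
    ecg <- synthesize_ecg(condition_params(nm), tac, fs = 1000,
                          trace_noise_fraction = 0, seed = 1)
    beat_len <- diff(attr(ecg, "beat_start"))[1]
    beat <- ecg$samples[1:beat_len]
    theta <- -pi + (0:(beat_len - 1)) * 2 * pi / beat_len
    t_win <- theta > 50 * pi / 180 & theta < 180 * pi / 180
    seg <- beat[t_win]
    above <- seg >= max(seg) / 2
    sum(above) / ecg$fs * 1000
  }
  expect_gt(half_width_ms("LQT"), half_width_ms("DET"))
})

test_that("AF P-window amplitude is below DET's", {
  p_window_max <- function(nm, seed) {
    tac <- build_tachogram(tachogram_spec(sd_hr = 0, n_beats = 6))
    ecg <- synthesize_ecg(condition_params(nm), tac, fs = 1000, seed = seed)
    beat_len <- diff(attr(ecg, "beat_start"))[1]
    theta <- -pi + (0:(beat_len - 1)) * 2 * pi / beat_len
    p_win <- theta > -80 * pi / 180 & theta < -60 * pi / 180
    mx <- 0
    for (k in 0:5) mx <- max(mx, abs(ecg$samples[k * beat_len + which(p_win)]))
    mx
  }
  for (seed in 1:5) {
    expect_lt(p_window_max("AF", seed), p_window_max("DET", seed))
  }
})

test_that("ECG synthesis is bit-reproducible under a fixed seed", {
  tac <- build_tachogram(tachogram_spec(n_beats = 50, seed = 9))
  a <- synthesize_ecg(condition_params("AF"), tac, fs = 500, seed = 4)
  b <- synthesize_ecg(condition_params("AF"), tac, fs = 500, seed = 4)
  expect_identical(a$samples, b$samples)
})

test_that("invalid tachogram specs are rejected", {
  expect_error(tachogram_spec(mean_hr = 0), "mean_hr")
  expect_error(tachogram_spec(sd_hr = -1), "sd_hr")
  expect_error(tachogram_spec(n_beats = 1), "n_beats")
  expect_error(as_tachogram(c(100, -5)), "positive")
})
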