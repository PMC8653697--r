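# Recurrence quantification: embedding parameter selection, recurrence
# plots, and factor equivalence with the brute-force oracle.

test_that("AMI of a constant series is zero at every lag", {
  ami <- average_mutual_information(rep(3, 200), 10)
  expect_equal(ami$ami, rep(0, 11))
})

test_that("AMI(0) equals the Shannon entropy of the binned series", {
  set.seed(4)
  x <- rnorm(2000)
  n <- length(x)
  bins <- ceiling(1 + log2(n))
  edges <- seq(min(x), max(x), length.out = bins + 1)
  b <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  p <- table(b) / n
  expect_equal(average_mutual_information(x, 5)$ami[1],
               -sum(p * log(p)))
})

test_that("AMI of iid noise is near zero for positive lags", {
  set.seed(10)
  ami <- average_mutual_information(runif(10000), 10)
  expect_lt(max(ami$ami[ami$lag > 0]), 0.05)
  expect_equal(select_tau(ami), 1L)
})

test_that("tau selection applies the first-1/e rule", {
  # synthetic AMI curves exercise the rule directly
  curve <- data.frame(lag = 0:5, ami = c(2.0, 1.5, 0.9, 0.7, 0.3, 0.2))
  expect_equal(select_tau(curve), 3L)  # 2/e = 0.7358: first <= at lag 3
  ramp <- data.frame(lag = 0:4, ami = c(1.0, 0.9, 0.8, 0.7, 0.6))
  expect_warning(tau <- select_tau(ramp), "never drops")
  expect_equal(tau, 4L)  # argmin fallback
})

test_that("tau for a noisy sine lies at the first 1/e crossing, below a quarter period", {
  set.seed(2)
  x <- sin(2 * pi * (0:1999) / 100) + rnorm(2000, 0, 0.05)
  ami <- average_mutual_information(x, 40)
  tau <- select_tau(ami)
  expected <- min(ami$lag[ami$lag >= 1 & ami$ami <= ami$ami[1] / exp(1)])
  expect_equal(tau, expected)
  expect_lt(tau, 25)
})

test_that("monotone ramp falls back to the AMI argmin with a warning", {
  expect_warning(tau <- select_tau(average_mutual_information(1:300, 20)),
                 "never drops")
  expect_gte(tau, 1L)
})

test_that("FNN identifies a sine as low-dimensional and noise as not", {
  x <- sin(2 * pi * (0:499) / 100)
  fnn_sine <- false_nearest_neighbors(x, tau = 25, m_max = 5)
  expect_true(all(fnn_sine >= 0 & fnn_sine <= 1))
  expect_lt(fnn_sine[2], 0.1)
  set.seed(6)
  fnn_noise <- false_nearest_neighbors(runif(400), tau = 1, m_max = 4)
  expect_gt(fnn_noise[1], 0.1)
})

test_that("constant series yields zero FNN with a warning", {
  expect_warning(f <- false_nearest_neighbors(rep(2, 100), 1, m_max = 3),
                 "constant")
  expect_equal(f, numeric(3))
})

test_that("dimension selection applies the first-below-0.1 rule", {
  expect_equal(select_m(c(0.9, 0.05, 0.01)), 2L)
  expect_equal(select_m(c(0.09, 0.5, 0.6)), 1L)
  expect_warning(m <- select_m(rep(0.5, 8)), "m_max")
  expect_equal(m, 8L)
})

test_that("phase-space embedding has the right shape and round-trips", {
  ps <- phase_space(1:10, tau = 2, m = 3)
  expect_equal(dim(ps), c(6, 3))
  expect_equal(ps[1, ], c(1, 3, 5))
  expect_equal(ps[6, ], c(6, 8, 10))
  x <- rnorm(50)
  expect_equal(phase_space(x, 1, 1)[, 1], x)  # identity embedding
  ps2 <- phase_space(x, 3, 4)
  for (i in c(1, 10, nrow(ps2))) {
    expect_equal(ps2[i, ], x[i + (0:3) * 3])
  }
})

test_that("distance matrix is normalised, symmetric, zero-diagonal", {
  dm <- distance_matrix(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_equal(dm, matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)
  set.seed(8)
  dm2 <- distance_matrix(matrix(rnorm(60), 20, 3))
  expect_equal(dm2, t(dm2))
  expect_equal(diag(dm2), rep(0, 20), ignore_attr = TRUE)
  expect_equal(max(dm2), 1)
  expect_warning(dz <- distance_matrix(matrix(1, 5, 2)), "coincide")
  expect_true(all(dz == 0))
})

test_that("epsilon limits saturate the recurrence plot as expected", {
  set.seed(9)
  dm <- distance_matrix(matrix(rnorm(40), 20, 2))
  expect_true(all(recurrence_plot(dm, 0.999999)$matrix[dm < 0.999999] == 1))
  tiny <- recurrence_plot(dm, 1e-12)
  expect_equal(tiny$matrix, diag(1L, 20), ignore_attr = TRUE)
})

test_that("periodic sine embedding shows diagonals at period multiples", {
  x <- sin(2 * pi * (0:299) / 50)
  rp <- recurrence_plot(distance_matrix(phase_space(x, 12, 2)), 0.09)
  N <- nrow(rp$matrix)
  off_density <- vapply(1:(N - 1), function(k) {
    i <- 1:(N - k)
    mean(rp$matrix[cbind(i, i + k)])
  }, numeric(1))
  hits <- which(off_density > 0.9)
  expect_true(all(abs((hits %% 50) - 0) <= 2 | abs((hits %% 50) - 50) <= 2))
  expect_true(any(abs(hits - 50) <= 2))
})

test_that("saturated and identity-only plots hit the factor limits", {
  N <- 12
  ones <- matrix(1L, N, N)
  f <- rqa_factors(as_recurrence_plot(ones))
  expect_equal(f[["recr"]], 1)
  # corner diagonals are shorter than l_min, so DTM saturates toward 1
  expect_equal(f[["dtm"]], 1, tolerance = 0.05)
  expect_equal(f[["lam"]], 1)
  expect_equal(f[["t1"]], 1)
  loi <- diag(1L, N)
  f0 <- rqa_factors(as_recurrence_plot(loi))
  expect_equal(f0[["recr"]], 0)
  expect_true(attr(f0, "undefined")[["dtm"]])
})

test_that("every factor matches the brute-force oracle on random plots", {
  set.seed(123)
  for (rep in 1:110) {
    N <- sample(5:40, 1)
    p <- runif(1, 0.05, 0.8)
    M <- random_symmetric_binary(N, p)
    f <- rqa_factors(as_recurrence_plot(M))
    o <- oracle_rqa_factors(M)
    expect_equal(unclass(f)[rqa_factor_names], o[rqa_factor_names],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("oracle equivalence also holds for asymmetric binary matrices", {
  set.seed(321)
  for (rep in 1:20) {
    N <- sample(5:30, 1)
    M <- matrix(rbinom(N * N, 1, runif(1, 0.1, 0.7)), N, N)
    f <- rqa_factors(as_recurrence_plot(M))
    o <- oracle_rqa_factors(M)
    expect_equal(unclass(f)[rqa_factor_names], o[rqa_factor_names],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("recurrence rate is monotone non-decreasing in epsilon", {
  set.seed(14)
  dm <- distance_matrix(phase_space(rnorm(150), 2, 2))
  eps <- c(0.02, 0.05, 0.09, 0.2, 0.5, 0.9)
  rr <- vapply(eps, function(e) {
    rqa_factors(recurrence_plot(dm, e))[["recr"]]
  }, numeric(1))
  expect_false(is.unsorted(rr))
})

test_that("ENTR is zero when one diagonal length class dominates", {
  # block with a single off-LOI diagonal line of length 5
  M <- diag(1L, 10)
  for (i in 1:5) M[i, i + 4] <- M[i + 4, i] <- 1L
  f <- rqa_factors(as_recurrence_plot(M))
  expect_equal(f[["entr"]], 0)
  expect_equal(f[["dmax"]], 5)
})

test_that("diagonal factors are invariant under time reversal", {
  set.seed(17)
  x <- as.numeric(arima.sim(list(ar = 0.9), 300))
  rp_f <- recurrence_plot(distance_matrix(phase_space(x, 2, 3)), 0.09)
  rp_r <- recurrence_plot(distance_matrix(phase_space(rev(x), 2, 3)), 0.09)
  f <- rqa_factors(rp_f); r <- rqa_factors(rp_r)
  for (nm in c("recr", "dtm", "mean_diag", "dmax", "entr")) {
    expect_equal(f[[nm]], r[[nm]], tolerance = 1e-12)
  }
})

test_that("zero-noise DET is more recurrent and deterministic than NSE", {
  tac <- build_tachogram(tachogram_spec(n_beats = 150, seed = 31))
  det <- synthesize_ecg(condition_params("DET"), tac, fs = 250, seed = 32,
                        trace_noise_fraction = 0)
  nse <- synthesize_ecg(condition_params("NSE"), tac, fs = 250, seed = 32)
  fd <- suppressWarnings(ecg_rqa(det, epoch_s = 2, n_epochs = 4, m_max = 6))
  fn <- suppressWarnings(ecg_rqa(nse, epoch_s = 2, n_epochs = 4, m_max = 6))
  expect_gt(mean(fd$recr), mean(fn$recr))
  expect_gt(mean(fd$dtm), mean(fn$dtm))
})

test_that("per-epoch factor table carries fixed embedding metadata", {
  ecg <- make_det_ecg(n_beats = 60, fs = 250, noise = 0.01, seed = 5)
  tab <- suppressWarnings(ecg_rqa(ecg, epoch_s = 1, n_epochs = 5,
                                  m_max = 5))
  expect_equal(nrow(tab), 5)
  expect_length(unique(tab$tau), 1)
  expect_length(unique(tab$m), 1)
  expect_true(all(rqa_factor_names %in% names(tab)))
  tab2 <- suppressWarnings(ecg_rqa(ecg, epoch_s = 1, n_epochs = 5,
                                   m_max = 5))
  expect_identical(tab, tab2)  # deterministic: no RNG in this module
})
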