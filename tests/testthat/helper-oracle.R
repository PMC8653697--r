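# Brute-force oracle for the recurrence factors: everything is computed by
# explicit cell-by-cell scans, independently of the package's vectorised
# run enumeration.  Used to pin down the factor definitions on random
# binary matrices.

oracle_diag_lengths <- function(M, theiler_window = 1) {
  N <- nrow(M)
  lens <- integer(0)
  for (k in -(N - 1):(N - 1)) {
    if (abs(k) < theiler_window) next
    run <- 0L
    for (i in 1:N) {
      j <- i + k
      if (j < 1 || j > N) next
      if (M[i, j] == 1) {
        run <- run + 1L
      } else {
        if (run > 0L) lens <- c(lens, run)
        run <- 0L
      }
    }
    if (run > 0L) lens <- c(lens, run)
  }
  lens
}

oracle_vert_lengths <- function(M) {
  N <- nrow(M)
  lens <- integer(0)
  for (j in 1:N) {
    run <- 0L
    for (i in 1:N) {
      if (M[i, j] == 1) {
        run <- run + 1L
      } else {
        if (run > 0L) lens <- c(lens, run)
        run <- 0L
      }
    }
    if (run > 0L) lens <- c(lens, run)
  }
  lens
}

oracle_rqa_factors <- function(M, theiler_window = 1, l_min = 3) {
  N <- nrow(M)
  off <- 0L
  for (i in 1:N) for (j in 1:N) if (i != j && M[i, j] == 1) off <- off + 1L
  recr <- off / (N^2 - N)

  dl <- oracle_diag_lengths(M, theiler_window)
  long_d <- dl[dl >= l_min]
  dtm <- if (sum(dl) > 0) sum(long_d) / sum(dl) else 0
  mean_diag <- if (length(long_d) > 0) mean(long_d) else 0
  dmax <- if (length(long_d) > 0) max(long_d) else 0
  entr <- if (length(long_d) > 0) {
    p <- table(long_d) / length(long_d)
    -sum(p * log(p))
  } else 0

  vl <- oracle_vert_lengths(M)
  long_v <- vl[vl >= l_min]
  lam <- if (sum(vl) > 0) sum(long_v) / sum(vl) else 0
  tt <- if (length(long_v) > 0) mean(long_v) else 0
  vmax <- if (length(long_v) > 0) max(long_v) else 0

  g1 <- numeric(0); g2 <- numeric(0)
  for (j in 1:N) {
    rows <- integer(0)
    for (i in 1:N) if (M[i, j] == 1) rows <- c(rows, i)
    if (length(rows) >= 2) g1 <- c(g1, diff(rows))
    firsts <- integer(0)
    for (idx in seq_along(rows)) {
      if (idx == 1 || rows[idx] - rows[idx - 1] > 1) {
        firsts <- c(firsts, rows[idx])
      }
    }
    if (length(firsts) >= 2) g2 <- c(g2, diff(firsts))
  }
  t1 <- if (length(g1) > 0) mean(g1) else 0
  t2 <- if (length(g2) > 0) mean(g2) else 0

  c(recr = recr, dtm = dtm, mean_diag = mean_diag, dmax = dmax,
    entr = entr, lam = lam, tt = tt, vmax = vmax, t1 = t1, t2 = t2)
}

random_symmetric_binary <- function(N, p) {
  M <- matrix(0L, N, N)
  up <- upper.tri(M)
  M[up] <- rbinom(sum(up), 1L, p)
  M <- M + t(M)
  diag(M) <- rbinom(N, 1L, p)
  M
}

# Convenience: clean constant-RR DET trace for waveform tests.
make_det_ecg <- function(n_beats = 10, fs = 1000, noise = 0, seed = NULL) {
  tac <- build_tachogram(tachogram_spec(sd_hr = 0, n_beats = n_beats))
  synthesize_ecg(condition_params("DET"), tac, fs = fs, seed = seed,
                 trace_noise_fraction = noise)
}
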