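# Per-recording RQA pipeline: embedding-parameter selection over epoch
# windows, per-epoch factor vectors, and the pooled multi-condition factor
# study that feeds the cohort-level PCA.

#' Select embedding delay and dimension for a recording
#'
#' Splits the series into up to `n_windows` consecutive non-overlapping
#' windows of `window_len` samples, selects in each the delay (first drop of
#' the average mutual information below `AMI(0)/e`) and the dimension (first
#' false-nearest-neighbour fraction below 0.1 at the recording delay), and
#' aggregates each as the median over windows (rounded up).  The delay is
#' capped so the largest tested dimension remains embeddable in one window.
#'
#' @param x Numeric series or [ecg_signal()].
#' @param window_len Window length in samples.
#' @param n_windows Maximum number of selection windows (default 10).
#' @param max_lag Largest delay examined by the AMI scan.
#' @param m_max Largest embedding dimension tested.
#' @param r_tol,a_tol Kennel FNN tolerances.
#' @return List with integer `tau` and `m`.
#' @export
select_embedding <- function(x, window_len, n_windows = 10, max_lag = 40,
                             m_max = 8, r_tol = 10, a_tol = 2) {
  if (inherits(x, "ecg_signal")) x <- x$samples
  x <- as.numeric(x)
  check_scalar_number(window_len, "window_len", 2)
  window_len <- as.integer(window_len)
  k <- min(as.integer(n_windows), length(x) %/% window_len)
  if (k < 1L) stop_input("series shorter than one selection window")
  max_lag <- min(as.integer(max_lag), window_len - 2L)
  taus <- integer(k)
  for (w in seq_len(k)) {
    seg <- x[((w - 1L) * window_len + 1L):(w * window_len)]
    taus[w] <- select_tau(average_mutual_information(seg, max_lag))
  }
  tau <- as.integer(ceiling(stats::median(taus)))
  tau <- max(1L, min(tau, (window_len - 2L) %/% max(1L, m_max)))
  ms <- integer(k)
  for (w in seq_len(k)) {
    seg <- x[((w - 1L) * window_len + 1L):(w * window_len)]
    ms[w] <- select_m(false_nearest_neighbors(seg, tau, m_max = m_max,
                                              r_tol = r_tol, a_tol = a_tol))
  }
  list(tau = tau, m = as.integer(ceiling(stats::median(ms))))
}

#' Per-epoch recurrence factors of an ECG recording
#'
#' Segments the recording into consecutive non-overlapping epochs of
#' `epoch_s` seconds and computes the ten recurrence factors per epoch.
#' Unless `tau` and `m` are supplied, they are selected once per recording
#' with [select_embedding()] on the first `selection_windows` epochs and
#' held fixed across epochs, so epochs of one recording are directly
#' comparable.
#'
#' @param ecg An [ecg_signal()].
#' @param epoch_s Epoch length in seconds.
#' @param n_epochs Number of epochs to analyse (default: all that fit).
#' @param epsilon_fraction Recurrence threshold as a fraction of each
#'   epoch's maximum phase-space diameter (default 0.09).
#' @param theiler_window,l_min See [recurrence_plot()].
#' @param max_lag,m_max,selection_windows Embedding-selection controls.
#' @param tau,m Optional fixed embedding parameters (both or neither).
#' @return Data frame with one row per epoch: `epoch`, `tau`, `m`,
#'   `epsilon` and the ten factor columns of [rqa_factor_names].
#' @export
ecg_rqa <- function(ecg, epoch_s = 2, n_epochs = NULL,
                    epsilon_fraction = 0.09, theiler_window = 1, l_min = 3,
                    max_lag = 40, m_max = 8, selection_windows = 10,
                    tau = NULL, m = NULL) {
  stopifnot(inherits(ecg, "ecg_signal"))
  check_scalar_number(epoch_s, "epoch_s", 0, strict_min = TRUE)
  epoch_len <- as.integer(round(epoch_s * ecg$fs))
  total <- length(ecg$samples) %/% epoch_len
  if (total < 1L) stop_input("recording shorter than one epoch")
  if (is.null(n_epochs)) n_epochs <- total
  n_epochs <- min(as.integer(n_epochs), total)
  if (is.null(tau) != is.null(m)) {
    stop_input("supply both `tau` and `m`, or neither")
  }
  if (is.null(tau)) {
    sel <- select_embedding(ecg$samples, epoch_len,
                            n_windows = selection_windows, max_lag = max_lag,
                            m_max = m_max)
    tau <- sel$tau
    m <- sel$m
  }
  rows <- vector("list", n_epochs)
  for (e in seq_len(n_epochs)) {
    seg <- ecg$samples[((e - 1L) * epoch_len + 1L):(e * epoch_len)]
    ps <- phase_space(seg, tau, m)
    dm <- suppressWarnings(distance_matrix(ps))
    rp <- recurrence_plot(dm, epsilon_fraction = epsilon_fraction,
                          theiler_window = theiler_window, l_min = l_min)
    f <- rqa_factors(rp)
    rows[[e]] <- data.frame(epoch = e, tau = tau, m = m,
                            epsilon = epsilon_fraction,
                            as.list(unclass(f)[rqa_factor_names]))
  }
  do.call(rbind, rows)
}

#' Per-epoch factor study over the simulated condition grid
#'
#' Runs the full simulation-to-factors pipeline for every combination of
#' condition, tachogram-noise level and LF/HF ratio: builds a tachogram,
#' noises it, renders the condition's ECG, and computes per-epoch recurrence
#' factors with data-driven embedding parameters.  The result is the pooled
#' per-epoch factor matrix used for cohort PCA and cluster scoring.
#'
#' Defaults reproduce the simulated study conditions: all four conditions,
#' noise levels 0/0.33/0.66/0.99, LF/HF ratios 0/0.5/1/1.5 and rat
#' heart-rate settings 350 +- 50 bpm.
#'
#' @param conditions Character vector of condition names.
#' @param noise_levels Tachogram noise levels (fractions of RR range).
#' @param lf_hf_ratios LF/HF spectral weights.
#' @param n_epochs Epochs analysed per recording.
#' @param epoch_s Epoch length in seconds.
#' @param fs Sampling rate of the rendered ECG (Hz).
#' @param mean_hr,sd_hr Instantaneous heart-rate mean and SD (bpm).
#' @param seed Integer seed; every grid cell derives its own child seed.
#' @param epsilon_fraction,max_lag,m_max,selection_windows Passed to
#'   [ecg_rqa()].
#' @return Data frame: `condition`, `noise`, `lf_hf`, `epoch`, `tau`, `m`,
#'   `epsilon` and the ten factor columns.
#' @export
aecg_factor_study <- function(conditions = c("DET", "AF", "LQT", "NSE"),
                              noise_levels = c(0, 0.33, 0.66, 0.99),
                              lf_hf_ratios = c(0, 0.5, 1, 1.5),
                              n_epochs = 20, epoch_s = 2, fs = 250,
                              mean_hr = 350, sd_hr = 50, seed = 1,
                              epsilon_fraction = 0.09, max_lag = 40,
                              m_max = 6, selection_windows = 10) {
  grid <- expand.grid(condition = conditions, noise = noise_levels,
                      lf_hf = lf_hf_ratios, stringsAsFactors = FALSE)
  duration_s <- n_epochs * epoch_s
  n_beats <- as.integer(ceiling(duration_s * mean_hr / 60 * 1.4) + 10)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    tac <- build_tachogram(tachogram_spec(
      mean_hr = mean_hr, sd_hr = sd_hr, lf_hf_ratio = g$lf_hf,
      n_beats = n_beats, seed = child_seed(seed, 3L * i)))
    tac <- add_tachogram_noise(tac, g$noise,
                               seed = child_seed(seed, 3L * i + 1L))
    ecg <- suppressWarnings(synthesize_ecg(
      condition_params(g$condition), tac, fs = fs,
      seed = child_seed(seed, 3L * i + 2L)))
    f <- suppressWarnings(ecg_rqa(
      ecg, epoch_s = epoch_s, n_epochs = n_epochs,
      epsilon_fraction = epsilon_fraction, max_lag = max_lag, m_max = m_max,
      selection_windows = selection_windows))
    out[[i]] <- cbind(condition = g$condition, noise = g$noise,
                      lf_hf = g$lf_hf, f)
  }
  do.call(rbind, out)
}

#' Extract the numeric factor matrix from a factor study table
#'
#' @param df Data frame containing the ten factor columns (e.g. from
#'   [aecg_factor_study()] or [ecg_rqa()]).
#' @return Numeric matrix with the ten factor columns in canonical order.
#' @export
factor_matrix <- function(df) {
  missing_cols <- setdiff(rqa_factor_names, names(df))
  if (length(missing_cols)) {
    stop_input("missing factor columns: %s",
               paste(missing_cols, collapse = ", "))
  }
  as.matrix(df[, rqa_factor_names])
}
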