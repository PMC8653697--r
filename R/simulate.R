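# Synthetic rat ECG generator: spectrally synthesised tachograms and
# Gaussian-sum PQRST templates for four cardiac/autonomic conditions.

#' Gaussian PQRST template parameters for a simulated cardiac condition
#'
#' Returns the wave-template parameter set for one of the four simulated
#' conditions.  Each beat is modelled as a sum of five Gaussian bumps (P, Q,
#' R, S, T) placed on a cycle angle \eqn{\theta \in [-\pi, \pi)}: the angular
#' position `theta_deg` (degrees), amplitude `a` (dimensionless template
#' units) and angular width `b` of each wave.
#'
#' The conditions are:
#' \describe{
#'   \item{DET}{Regular deterministic rat ECG, the reference morphology.}
#'   \item{AF}{Atrial-fibrillation-like: strongly reduced P wave
#'     (`a_P = 0.2`, `b_P = 0.125`) and the PQ segment overwritten with
#'     white noise during synthesis.}
#'   \item{LQT}{Long-QT-like: widened T wave (`b_T = 0.6`).}
#'   \item{NSE}{DET morphology buried in heavy additive noise
#'     (`trace_noise_fraction = 1`).}
#' }
#'
#' @param name Condition name, one of `"DET"`, `"AF"`, `"LQT"`, `"NSE"`.
#' @return An object of class `condition_params`: a list with `name`,
#'   `waves` (data frame with columns `wave`, `theta_deg`, `a`, `b`),
#'   `pq_noise` (logical; replace PQ segment with white noise),
#'   `pq_noise_sd` (template units), `pq_window_deg` (angular window of the
#'   PQ segment) and `trace_noise_fraction` (additive trace-noise SD as a
#'   fraction of the maximum absolute clean amplitude).
#' @examples
#' condition_params("DET")$waves
#' condition_params("LQT")$waves$b[5]  # widened T wave
#' @export
condition_params <- function(name = c("DET", "AF", "LQT", "NSE")) {
  if (!is.character(name) || length(name) != 1L ||
      !(name %in% c("DET", "AF", "LQT", "NSE"))) {
    stop_input("unknown condition '%s': must be one of DET, AF, LQT, NSE",
               paste(as.character(name), collapse = ","))
  }
  waves <- data.frame(
    wave      = c("P", "Q", "R", "S", "T"),
    theta_deg = c(-70, -15, 0, 15, 100),
    a         = c(1.2, -5, 30, -7.5, 0.75),
    b         = c(0.25, 0.1, 0.1, 0.1, 0.4),
    stringsAsFactors = FALSE
  )
  pq_noise <- FALSE
  trace_noise_fraction <- 0.01
  if (name == "AF") {
    waves$a[waves$wave == "P"] <- 0.2
    waves$b[waves$wave == "P"] <- 0.125
    pq_noise <- TRUE
  } else if (name == "LQT") {
    waves$b[waves$wave == "T"] <- 0.6
  } else if (name == "NSE") {
    trace_noise_fraction <- 1.00
  }
  structure(
    list(
      name = name,
      waves = waves,
      pq_noise = pq_noise,
      pq_noise_sd = 0.2,
      pq_window_deg = c(-90, -30),  # covers P and the PQ baseline, ends before Q onset
      trace_noise_fraction = trace_noise_fraction
    ),
    class = "condition_params"
  )
}

#' Specification of a synthetic tachogram
#'
#' Bundles the parameters governing tachogram synthesis: target mean and
#' standard deviation of the instantaneous heart rate, the low/high-frequency
#' spectral balance, and the number of beats.  Defaults reproduce standard
#' rat heartbeat dynamics (350 bpm mean, 50 bpm SD) with conventional rat
#' spectral bands (LF centred at 0.35 Hz, HF at 1.5 Hz).
#'
#' @param mean_hr Mean instantaneous heart rate, beats/min.
#' @param sd_hr Standard deviation of the instantaneous heart rate,
#'   beats/min.
#' @param lf_hf_ratio Multiplicative weight of the low-frequency spectral
#'   peak relative to the high-frequency peak (HF weight fixed at 1);
#'   any value `>= 0`.
#' @param lf_center,lf_width Centre and width (Hz) of the LF Gaussian peak.
#' @param hf_center,hf_width Centre and width (Hz) of the HF Gaussian peak.
#' @param n_beats Number of RR intervals to generate (`>= 2`).
#' @param seed Optional integer seed for the random spectral phases.
#' @return An object of class `tachogram_spec`.
#' @seealso [build_tachogram()]
#' @export
tachogram_spec <- function(mean_hr = 350, sd_hr = 50, lf_hf_ratio = 1,
                           lf_center = 0.35, lf_width = 0.1,
                           hf_center = 1.5, hf_width = 0.3,
                           n_beats = 300, seed = NULL) {
  check_scalar_number(mean_hr, "mean_hr", 0, strict_min = TRUE)
  check_scalar_number(sd_hr, "sd_hr", 0)
  check_scalar_number(lf_hf_ratio, "lf_hf_ratio", 0)
  for (nm in c("lf_center", "lf_width", "hf_center", "hf_width")) {
    check_scalar_number(get(nm), nm, 0, strict_min = TRUE)
  }
  check_scalar_number(n_beats, "n_beats", 2)
  structure(
    list(mean_hr = mean_hr, sd_hr = sd_hr, lf_hf_ratio = lf_hf_ratio,
         lf_center = lf_center, lf_width = lf_width,
         hf_center = hf_center, hf_width = hf_width,
         n_beats = as.integer(n_beats), seed = seed),
    class = "tachogram_spec"
  )
}

#' Construct a tachogram object from RR intervals
#'
#' @param rr_ms Numeric vector of RR intervals in milliseconds; all finite
#'   and positive.
#' @param origin `"synthetic"` for simulator output, `"detected"` for
#'   intervals derived from R-peak detection on a recording.
#' @return An object of class `tachogram` with fields `rr_ms` and `origin`.
#' @export
as_tachogram <- function(rr_ms, origin = c("synthetic", "detected")) {
  origin <- match.arg(origin)
  rr_ms <- as.numeric(rr_ms)
  if (length(rr_ms) < 1L || any(!is.finite(rr_ms)) || any(rr_ms <= 0)) {
    stop_input("`rr_ms` must be a non-empty vector of finite positive values")
  }
  structure(list(rr_ms = rr_ms, origin = origin), class = "tachogram")
}

#' @export
print.tachogram <- function(x, ...) {
  cat(sprintf("<tachogram: %d beats, origin %s, mean RR %.2f ms>\n",
              length(x$rr_ms), x$origin, mean(x$rr_ms)))
  invisible(x)
}

# Coerce a tachogram or bare numeric vector to RR intervals (ms).
as_rr <- function(t) {
  if (inherits(t, "tachogram")) return(t$rr_ms)
  if (is.numeric(t)) return(as.numeric(t))
  stop_input("expected a `tachogram` object or a numeric RR vector")
}

#' Synthesise a tachogram from a bimodal LF/HF power spectrum
#'
#' Builds the RR-interval series by inverse-Fourier synthesis: a bimodal
#' target power spectrum
#' \deqn{S(f) = r\,e^{-(f-f_{LF})^2 / 2\sigma_{LF}^2} +
#'              e^{-(f-f_{HF})^2 / 2\sigma_{HF}^2}}
#' (with `r = lf_hf_ratio`) is sampled on the beat-frequency grid, random
#' phases are drawn for each spectral line, the inverse FFT yields a real
#' heart-rate modulation, and the series is affinely rescaled so the
#' instantaneous heart rate has exactly the requested sample mean and SD.
#' RR intervals are then `60000 / HR` in milliseconds.
#'
#' The beat series is treated as sampled at the mean beat rate
#' (`mean_hr / 60` Hz), which sets the Nyquist frequency available to the
#' spectral peaks.  With `sd_hr = 0` the tachogram is exactly constant.
#' RR values that would fall below `rr_floor_ms` (possible for very large
#' `sd_hr`) are clipped there, with a warning reporting how many beats were
#' affected.
#'
#' @param spec A [tachogram_spec()].
#' @param rr_floor_ms Minimum admissible RR interval in ms; default 40 ms,
#'   far below physiological rat RR.
#' @return A [as_tachogram()] object of `spec$n_beats` intervals with origin
#'   `"synthetic"`.
#' @examples
#' t <- build_tachogram(tachogram_spec(n_beats = 500, seed = 1))
#' mean(60000 / t$rr_ms)  # ~350 bpm
#' @export
build_tachogram <- function(spec, rr_floor_ms = 40) {
  stopifnot(inherits(spec, "tachogram_spec"))
  n <- spec$n_beats
  rr_const <- 60000 / spec$mean_hr
  if (spec$sd_hr == 0) {
    return(as_tachogram(rep(rr_const, n), origin = "synthetic"))
  }
  dt <- 60 / spec$mean_hr                 # seconds per beat
  nf <- floor(n / 2)
  f <- (1:nf) / (n * dt)                  # positive frequency grid, Hz
  S <- spec$lf_hf_ratio *
    exp(-(f - spec$lf_center)^2 / (2 * spec$lf_width^2)) +
    exp(-(f - spec$hf_center)^2 / (2 * spec$hf_width^2))
  amp <- sqrt(S)
  phases <- with_seed(spec$seed, stats::runif(nf, 0, 2 * pi))
  half <- amp * exp(1i * phases)
  if (n %% 2 == 0) half[nf] <- complex(real = Re(half[nf]))  # Nyquist bin real
  X <- complex(length.out = n)
  X[1L] <- 0
  X[2:(nf + 1L)] <- half
  if (n - nf - 1L >= 1L) {
    lower <- Conj(half[seq_len(n - nf - 1L)])
    X[n:(nf + 2L)] <- lower
  }
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  if (stats::sd(x) < .Machine$double.eps * max(1, abs(mean(x)))) {
    warning("spectral mass is numerically zero on the beat-frequency grid; ",
            "returning a constant tachogram", call. = FALSE)
    return(as_tachogram(rep(rr_const, n), origin = "synthetic"))
  }
  hr <- spec$mean_hr + spec$sd_hr * (x - mean(x)) / stats::sd(x)
  rr <- ifelse(hr > 0, 60000 / hr, -1)
  n_clip <- sum(rr < rr_floor_ms)
  if (n_clip > 0) {
    warning(sprintf("%d of %d RR intervals clipped at the %g ms floor",
                    n_clip, n, rr_floor_ms), call. = FALSE)
    rr <- pmax(rr, rr_floor_ms)
  }
  as_tachogram(rr, origin = "synthetic")
}

#' Add white noise to a tachogram
#'
#' Adds zero-mean Gaussian noise whose SD is `level` times the peak-to-peak
#' range of the clean RR series, emulating measurement/dysautonomia noise at
#' 0, 33, 66 or 99 percent of maximum amplitude (any `level >= 0` is
#' accepted).  For a constant input tachogram the range is zero; the noise
#' SD then degenerates and the function falls back to
#' `level * mean(rr) * 0.01` with a warning.  Noised intervals are floored
#' at `rr_floor_ms` to stay positive.
#'
#' @param t A tachogram (or numeric RR vector in ms).
#' @param level Noise level as a fraction of the RR peak-to-peak range.
#' @param seed Optional integer seed.
#' @param rr_floor_ms Minimum admissible RR after noising (ms).
#' @return A `tachogram` of the same length.
#' @export
add_tachogram_noise <- function(t, level, seed = NULL, rr_floor_ms = 40) {
  rr <- as_rr(t)
  check_scalar_number(level, "level", 0)
  if (level == 0) {
    return(as_tachogram(rr, origin = "synthetic"))
  }
  rng <- max(rr) - min(rr)
  if (rng == 0) {
    warning("constant tachogram: noise SD from peak-to-peak range is 0; ",
            "falling back to SD = level * mean(rr) * 0.01", call. = FALSE)
    noise_sd <- level * mean(rr) * 0.01
  } else {
    noise_sd <- level * rng
  }
  noise <- with_seed(seed, stats::rnorm(length(rr), 0, noise_sd))
  as_tachogram(pmax(rr + noise, rr_floor_ms), origin = "synthetic")
}

#' Construct an ECG signal object
#'
#' @param samples Numeric voltage series (arbitrary mV-scale units).
#' @param fs Sampling rate in Hz.
#' @param condition_label Optional label (e.g. a simulated condition name).
#' @return An object of class `ecg_signal` with fields `fs`, `samples` and
#'   `condition_label`.
#' @export
ecg_signal <- function(samples, fs, condition_label = NULL) {
  check_scalar_number(fs, "fs", 0, strict_min = TRUE)
  samples <- as.numeric(samples)
  if (length(samples) < 2L || any(!is.finite(samples))) {
    stop_input("`samples` must be a finite numeric vector of length >= 2")
  }
  structure(list(fs = fs, samples = samples,
                 condition_label = condition_label),
            class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal: %d samples @ %g Hz (%.1f s)%s>\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (is.null(x$condition_label)) ""
              else paste0(", ", x$condition_label)))
  invisible(x)
}

# Evaluate the Gaussian-sum PQRST template at cycle angles theta (radians).
pqrst_template <- function(theta, waves) {
  v <- numeric(length(theta))
  th_w <- waves$theta_deg * pi / 180
  for (w in seq_len(nrow(waves))) {
    v <- v + waves$a[w] * exp(-(theta - th_w[w])^2 / (2 * waves$b[w]^2))
  }
  v
}

#' Synthesise an ECG trace from a tachogram and a condition template
#'
#' Renders one PQRST complex per RR interval by sequencing the Gaussian-sum
#' template: beat \eqn{k} spans a cycle angle \eqn{\theta \in [-\pi, \pi)}
#' sampled at `round(fs * RR_k / 1000)` points, with voltage
#' \deqn{v(\theta) = \sum_w a_w \exp\{-(\theta - \theta_w)^2 / 2 b_w^2\}.}
#' Beats are concatenated, then (for AF-type parameters) the PQ angular
#' segment of every beat is overwritten with white noise, and finally
#' zero-mean Gaussian trace noise with SD
#' `trace_noise_fraction * max(abs(clean signal))` is added (1 percent by
#' default; 100 percent for the NSE condition).
#'
#' @param params A [condition_params()] object.
#' @param t A tachogram (or numeric RR vector in ms).
#' @param fs Sampling rate in Hz (`>= 250`; default 1000, the usual rodent
#'   acquisition rate).
#' @param seed Optional integer seed for PQ and trace noise.
#' @param trace_noise_fraction Override of the template's trace-noise
#'   fraction (use 0 for a noise-free trace).
#' @return An [ecg_signal()] carrying attributes `r_index` (ground-truth R
#'   sample index of every rendered beat) and `beat_start` (first sample of
#'   each beat), useful for validating peak detectors.
#' @examples
#' tac <- build_tachogram(tachogram_spec(sd_hr = 0, n_beats = 10))
#' ecg <- synthesize_ecg(condition_params("DET"), tac, fs = 1000,
#'                       trace_noise_fraction = 0)
#' length(attr(ecg, "r_index"))  # 10 beats
#' @export
synthesize_ecg <- function(params, t, fs = 1000, seed = NULL,
                           trace_noise_fraction = NULL) {
  stopifnot(inherits(params, "condition_params"))
  check_scalar_number(fs, "fs", 250)
  rr <- as_rr(t)
  if (is.null(trace_noise_fraction)) {
    trace_noise_fraction <- params$trace_noise_fraction
  }
  check_scalar_number(trace_noise_fraction, "trace_noise_fraction", 0)

  n_samp <- pmax(2L, as.integer(round(fs * rr / 1000)))
  if (any(n_samp < 8L)) {
    warning(sprintf(
      "%d beats rendered with < 8 samples (RR shorter than the template support)",
      sum(n_samp < 8L)), call. = FALSE)
  }
  beat_start <- cumsum(c(1L, n_samp[-length(n_samp)]))
  total <- sum(n_samp)
  samples <- numeric(total)
  r_index <- integer(length(rr))
  pq_idx <- integer(0)
  pq_lo <- params$pq_window_deg[1] * pi / 180
  pq_hi <- params$pq_window_deg[2] * pi / 180
  for (k in seq_along(rr)) {
    nk <- n_samp[k]
    theta <- -pi + (0:(nk - 1L)) * (2 * pi / nk)
    idx <- beat_start[k]:(beat_start[k] + nk - 1L)
    samples[idx] <- pqrst_template(theta, params$waves)
    r_index[k] <- idx[which.min(abs(theta))]
    if (params$pq_noise) {
      pq_idx <- c(pq_idx, idx[theta >= pq_lo & theta <= pq_hi])
    }
  }
  peak <- max(abs(samples))
  samples <- with_seed(seed, {
    if (length(pq_idx) > 0) {
      samples[pq_idx] <- stats::rnorm(length(pq_idx), 0, params$pq_noise_sd)
    }
    if (trace_noise_fraction > 0) {
      samples <- samples +
        stats::rnorm(total, 0, trace_noise_fraction * peak)
    }
    samples
  })
  out <- ecg_signal(samples, fs, condition_label = params$name)
  attr(out, "r_index") <- r_index
  attr(out, "beat_start") <- beat_start
  out
}
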