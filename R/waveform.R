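# R-peak detection and R-aligned PQRST complex extraction.

#' Detect R peaks in a single-lead ECG
#'
#' Amplitude-based detector: candidate samples are strict local maxima above
#' an adaptive threshold, then a refractory rule removes peaks closer than
#' `refractory_ms`, keeping the larger of any competing pair.  The default
#' threshold sits halfway between the signal mean and its maximum, which is
#' robust for R-dominated rodent traces; a different policy can be injected
#' through `threshold_policy`.
#'
#' @param ecg An [ecg_signal()].
#' @param refractory_ms Minimum peak-to-peak distance in ms (default 60 ms,
#'   shorter than the RR of a rat at 500 bpm or above).
#' @param threshold_policy Optional function `f(samples) -> scalar`
#'   returning the detection threshold.
#' @return Strictly increasing integer vector of sample indices; empty for a
#'   flat trace.
#' @export
detect_r_peaks <- function(ecg, refractory_ms = 60, threshold_policy = NULL) {
  stopifnot(inherits(ecg, "ecg_signal"))
  check_scalar_number(refractory_ms, "refractory_ms", 0, strict_min = TRUE)
  x <- ecg$samples
  n <- length(x)
  refractory <- max(1L, as.integer(round(refractory_ms * ecg$fs / 1000)))
  if (n <= refractory) {
    stop_input("signal shorter than one refractory period")
  }
  if (diff(range(x)) == 0) return(integer(0))
  thr <- if (is.null(threshold_policy)) {
    mean(x) + 0.5 * (max(x) - mean(x))
  } else {
    threshold_policy(x)
  }
  i <- 2:(n - 1L)
  cand <- i[x[i] > x[i - 1L] & x[i] >= x[i + 1L] & x[i] > thr]
  if (length(cand) == 0) return(integer(0))
  keep <- cand[1L]
  for (p in cand[-1L]) {
    last <- keep[length(keep)]
    if (p - last >= refractory) {
      keep <- c(keep, p)
    } else if (x[p] > x[last]) {
      keep[length(keep)] <- p
    }
  }
  keep
}

#' Extract R-aligned PQRST complexes
#'
#' Cuts a symmetric window of `window_half_ms` on each side of every R peak
#' (18 ms per side by default, so 37 columns at 1000 Hz) and stacks the
#' complexes as rows of a matrix.  Peaks whose window would cross a signal
#' boundary are dropped; interior rows are unaffected by that dropping.
#'
#' @param ecg An [ecg_signal()].
#' @param peaks Integer vector of R-peak sample indices (from
#'   [detect_r_peaks()] or ground truth).
#' @param window_half_ms Half window in ms; converted to samples by
#'   truncation (`trunc(window_half_ms * fs / 1000)`).
#' @return An object of class `complex_matrix`: list with `matrix` (rows =
#'   complexes), `r_indices` (retained peaks), `window_half_ms` and `fs`.
#'   The matrix has zero rows when no peak window fits.
#' @export
extract_complexes <- function(ecg, peaks, window_half_ms = 18) {
  stopifnot(inherits(ecg, "ecg_signal"))
  check_scalar_number(window_half_ms, "window_half_ms", 0, strict_min = TRUE)
  peaks <- as.integer(peaks)
  if (is.unsorted(peaks, strictly = TRUE)) {
    stop_input("`peaks` must be strictly increasing")
  }
  half <- trunc(window_half_ms * ecg$fs / 1000)
  n <- length(ecg$samples)
  keep <- peaks[peaks - half >= 1L & peaks + half <= n]
  ncol_out <- 2L * half + 1L
  m <- matrix(numeric(0), nrow = 0L, ncol = ncol_out)
  if (length(keep) > 0) {
    m <- t(vapply(keep, function(p) ecg$samples[(p - half):(p + half)],
                  numeric(ncol_out)))
  }
  colnames(m) <- sprintf("s%+d", -half:half)
  structure(list(matrix = m, r_indices = keep,
                 window_half_ms = window_half_ms, fs = ecg$fs),
            class = "complex_matrix")
}

#' @export
print.complex_matrix <- function(x, ...) {
  cat(sprintf("<complex_matrix: %d complexes x %d samples (+-%g ms @ %g Hz)>\n",
              nrow(x$matrix), ncol(x$matrix), x$window_half_ms, x$fs))
  invisible(x)
}

#' Tachogram from detected R peaks
#'
#' @param peaks Strictly increasing R-peak sample indices.
#' @param fs Sampling rate in Hz.
#' @return A `tachogram` with origin `"detected"`.
#' @export
peaks_to_tachogram <- function(peaks, fs) {
  check_scalar_number(fs, "fs", 0, strict_min = TRUE)
  if (length(peaks) < 2L) stop_input("need at least 2 peaks for a tachogram")
  as_tachogram(diff(as.numeric(peaks)) / fs * 1000, origin = "detected")
}
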