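# Time-domain heart rate variability statistics and Poincare-map
# descriptors.  All statistics use the sample (n-1) convention, so the
# SD1/RMSSD and ellipse identities hold to O(1/n) rather than exactly.

#' Standard deviation of NN intervals (SDNN)
#'
#' Sample standard deviation of the RR series, the classical long-period
#' autonomic-balance index.  No NN filtering (ectopy removal) is applied:
#' an artifact filter can be run on the tachogram beforehand.
#'
#' @param t A `tachogram` or numeric RR vector (ms).
#' @return SDNN in ms.
#' @examples
#' sdnn(c(150, 160, 150, 160))  # sqrt(100/3)
#' @export
sdnn <- function(t) {
  rr <- as_rr(t)
  if (length(rr) < 2L) stop_input("SDNN needs at least 2 intervals")
  stats::sd(rr)
}

#' Root mean square of successive differences (RMSSD)
#'
#' Short-period vagally-mediated variability index:
#' \eqn{\sqrt{\mathrm{mean}((RR_{k+1}-RR_k)^2)}}.
#'
#' @inheritParams sdnn
#' @return RMSSD in ms.
#' @examples
#' rmssd(c(150, 160, 150, 160))  # 10
#' @export
rmssd <- function(t) {
  rr <- as_rr(t)
  if (length(rr) < 2L) stop_input("RMSSD needs at least 2 intervals")
  sqrt(mean(diff(rr)^2))
}

#' Poincare-map descriptors SD1 and SD2
#'
#' The Poincare (first-return) map scatters each RR interval against the
#' interval `lag` beats earlier.  SD1 is the dispersion perpendicular to the
#' line of identity (short-term variability); SD2 the dispersion along it
#' (long-term variability).  With `x = RR[1..n-lag]`, `y = RR[1+lag..n]`:
#' `sd1 = sd((x - y)/sqrt(2))`, `sd2 = sd((x + y)/sqrt(2))`.
#'
#' @inheritParams sdnn
#' @param lag Return-map lag in beats (default 1).
#' @return An object of class `poincare_summary`: list with `sd1`, `sd2`
#'   (ms), `centroid` (mean x, mean y in ms) and `lag`.
#' @export
poincare <- function(t, lag = 1) {
  rr <- as_rr(t)
  check_scalar_number(lag, "lag", 1)
  lag <- as.integer(lag)
  if (length(rr) < lag + 2L) {
    stop_input("Poincare map needs at least lag + 2 intervals")
  }
  n <- length(rr)
  x <- rr[1:(n - lag)]
  y <- rr[(1 + lag):n]
  structure(
    list(sd1 = stats::sd((x - y) / sqrt(2)),
         sd2 = stats::sd((x + y) / sqrt(2)),
         centroid = c(mean(x), mean(y)),
         lag = lag),
    class = "poincare_summary"
  )
}

#' @export
print.poincare_summary <- function(x, ...) {
  cat(sprintf(
    "<poincare_summary: SD1 %.3f ms, SD2 %.3f ms, centroid (%.1f, %.1f) ms, lag %d>\n",
    x$sd1, x$sd2, x$centroid[1], x$centroid[2], x$lag))
  invisible(x)
}

#' One-row summary of the standard HRV coefficients
#'
#' @inheritParams sdnn
#' @return A one-row data frame with columns `sdnn`, `rmssd`, `sd1`, `sd2`
#'   (all ms).
#' @export
hrv_summary <- function(t) {
  pm <- poincare(t)
  data.frame(sdnn = sdnn(t), rmssd = rmssd(t), sd1 = pm$sd1, sd2 = pm$sd2)
}
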