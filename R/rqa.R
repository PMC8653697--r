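# Recurrence quantification analysis: data-driven embedding parameters
# (average mutual information for the delay, false nearest neighbours for
# the dimension), thresholded recurrence plots, and the ten recurrence
# factors.  This module is deterministic: all stochasticity lives upstream
# in the simulator.

#' Names of the ten recurrence factors, in canonical order
#'
#' `recr` recurrence rate, `dtm` determinism, `mean_diag` mean diagonal
#' length, `dmax` maximum diagonal length, `entr` diagonal-length Shannon
#' entropy (nats), `lam` laminarity, `tt` trapping time, `vmax` maximum
#' vertical length, `t1`/`t2` type-1/type-2 mean recurrence return times.
#'
#' @export
rqa_factor_names <- c("recr", "dtm", "mean_diag", "dmax", "entr",
                      "lam", "tt", "vmax", "t1", "t2")

#' Average mutual information curve
#'
#' Computes the average mutual information (AMI, in nats) between the series
#' and its lagged copy for lags `0..max_lag`, from a joint histogram whose
#' per-axis bin count follows the Sturges rule,
#' \eqn{\lceil 1 + \log_2 n \rceil}, with identical bin edges on both axes.
#' `AMI(0)` equals the Shannon entropy of the binned series.  A constant
#' series has zero AMI at every lag.
#'
#' @param x Numeric series.
#' @param max_lag Largest lag (samples); requires `length(x) > max_lag + 1`.
#' @return Data frame with columns `lag` and `ami`.
#' @export
average_mutual_information <- function(x, max_lag) {
  x <- as.numeric(x)
  n <- length(x)
  check_scalar_number(max_lag, "max_lag", 0)
  max_lag <- as.integer(max_lag)
  if (n <= max_lag + 1L) {
    stop_input("series length (%d) must exceed max_lag + 1 (%d)", n,
               max_lag + 1L)
  }
  if (any(!is.finite(x))) stop_input("`x` must be finite")
  lags <- 0:max_lag
  if (diff(range(x)) == 0) {
    return(data.frame(lag = lags, ami = numeric(length(lags))))
  }
  bins <- ceiling(1 + log2(n))
  edges <- seq(min(x), max(x), length.out = bins + 1L)
  bx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  ami <- vapply(lags, function(tau) {
    a <- bx[1:(n - tau)]
    b <- bx[(1 + tau):n]
    joint <- tabulate((a - 1L) * bins + b, nbins = bins * bins)
    m <- length(a)
    p <- joint / m
    px <- tabulate(a, nbins = bins) / m
    py <- tabulate(b, nbins = bins) / m
    nz <- p > 0
    # cell (a-1)*bins + b runs b fastest, so flatten px[a]*py[b] to match
    pp <- as.vector(t(outer(px, py)))
    sum(p[nz] * log(p[nz] / pp[nz]))
  }, numeric(1))
  data.frame(lag = lags, ami = ami)
}

#' Select the embedding delay from an AMI curve
#'
#' Returns the smallest lag `tau >= 1` whose AMI has dropped to or below
#' `AMI(0)/e`, the conventional first-1/e criterion.  If the curve never
#' crosses the threshold the lag minimising AMI is returned with a warning.
#'
#' @param ami Data frame from [average_mutual_information()].
#' @return Integer delay in samples (`>= 1`).
#' @export
select_tau <- function(ami) {
  if (!is.data.frame(ami) || nrow(ami) == 0 ||
      !all(c("lag", "ami") %in% names(ami))) {
    stop_input("`ami` must be a non-empty data frame with columns lag, ami")
  }
  a0 <- ami$ami[ami$lag == 0]
  if (length(a0) != 1L) stop_input("AMI curve must contain lag 0")
  pos <- ami[ami$lag >= 1, , drop = FALSE]
  if (nrow(pos) == 0) stop_input("AMI curve must contain lags >= 1")
  hit <- pos$lag[pos$ami <= a0 / exp(1)]
  if (length(hit) > 0) return(as.integer(min(hit)))
  warning("AMI never drops below AMI(0)/e; returning the lag minimising AMI",
          call. = FALSE)
  as.integer(pos$lag[which.min(pos$ami)])
}

#' Delay-coordinate phase-space reconstruction
#'
#' Takens embedding: point \eqn{i} is
#' \eqn{(x_i, x_{i+\tau}, \ldots, x_{i+(m-1)\tau})}, giving
#' `n - (m-1)*tau` points in \eqn{m} dimensions.
#'
#' @param x Numeric series.
#' @param tau Delay in samples (`>= 1`).
#' @param m Embedding dimension (`>= 1`).
#' @return Numeric matrix with one embedded point per row.
#' @export
phase_space <- function(x, tau, m) {
  x <- as.numeric(x)
  check_scalar_number(tau, "tau", 1)
  check_scalar_number(m, "m", 1)
  tau <- as.integer(tau); m <- as.integer(m)
  np <- length(x) - (m - 1L) * tau
  if (np < 1L) stop_input("series too short for tau = %d, m = %d", tau, m)
  idx <- outer(0:(np - 1L), (0:(m - 1L)) * tau, "+") + 1L
  matrix(x[idx], nrow = np, ncol = m)
}

#' False nearest neighbours fraction per embedding dimension
#'
#' Kennel criterion: for each candidate dimension `m`, the nearest neighbour
#' of every point in the `m`-dimensional embedding is tested when the
#' `(m+1)`-th coordinate is appended.  A neighbour is false if the extra
#' coordinate stretches the pair by more than `r_tol` times its distance, or
#' moves the pair beyond `a_tol` times the series SD.
#'
#' @param x Numeric series.
#' @param tau Embedding delay (samples).
#' @param m_max Largest dimension tested.
#' @param r_tol,a_tol Kennel tolerances (defaults 10 and 2).
#' @return Numeric vector of length `m_max`: FNN fraction for
#'   `m = 1..m_max`, each in `[0, 1]`.
#' @export
false_nearest_neighbors <- function(x, tau, m_max = 8, r_tol = 10, a_tol = 2) {
  x <- as.numeric(x)
  check_scalar_number(tau, "tau", 1); tau <- as.integer(tau)
  check_scalar_number(m_max, "m_max", 1); m_max <- as.integer(m_max)
  n <- length(x)
  if (n - m_max * tau < 2L) {
    stop_input("series too short to test dimensions up to m_max = %d", m_max)
  }
  sdx <- stats::sd(x)
  if (sdx == 0) {
    warning("constant series: FNN fraction is 0 for every dimension",
            call. = FALSE)
    return(numeric(m_max))
  }
  vapply(seq_len(m_max), function(m) {
    np <- n - m * tau            # points that can also be extended to m+1
    ps <- phase_space(x[seq_len(n - tau)], tau, m)[seq_len(np), , drop = FALSE]
    extra <- x[(0:(np - 1L)) + m * tau + 1L]
    d <- as.matrix(stats::dist(ps))
    diag(d) <- Inf
    nn <- apply(d, 1L, which.min)
    rnn <- d[cbind(seq_len(np), nn)]
    stretch <- abs(extra - extra[nn])
    r1 <- ifelse(rnn > 0, stretch / rnn, ifelse(stretch > 0, Inf, 0))
    d_new <- sqrt(rnn^2 + stretch^2)
    mean(r1 > r_tol | d_new / sdx > a_tol)
  }, numeric(1))
}

#' Select the embedding dimension from FNN fractions
#'
#' Smallest dimension whose false-nearest-neighbour fraction falls below
#' `threshold` (0.1 by default).  If no dimension qualifies, the largest
#' tested dimension is returned with a warning.
#'
#' @param fnn Numeric vector of FNN fractions for `m = 1..length(fnn)`.
#' @param threshold Qualifying FNN fraction.
#' @return Integer embedding dimension.
#' @export
select_m <- function(fnn, threshold = 0.1) {
  if (!is.numeric(fnn) || length(fnn) == 0) {
    stop_input("`fnn` must be a non-empty numeric vector")
  }
  hit <- which(fnn < threshold)
  if (length(hit) > 0) return(as.integer(hit[1L]))
  warning(sprintf(
    "no dimension reaches FNN < %g; returning m_max = %d", threshold,
    length(fnn)), call. = FALSE)
  as.integer(length(fnn))
}

#' Normalised phase-space distance matrix
#'
#' Pairwise Euclidean distances between embedded points, divided by the
#' maximum phase-space diameter so all signals live on the same `[0, 1]`
#' scale and the recurrence threshold can be stated as a diameter fraction.
#'
#' @param ps Embedded point matrix from [phase_space()].
#' @return Symmetric matrix in `[0, 1]` with zero diagonal and (for at
#'   least two distinct points) maximum exactly 1.  If all points coincide
#'   the zero matrix is returned with attribute `degenerate = TRUE` and a
#'   warning.
#' @export
distance_matrix <- function(ps) {
  ps <- as.matrix(ps)
  if (nrow(ps) < 2L) stop_input("need at least 2 phase-space points")
  d <- as.matrix(stats::dist(ps))
  mx <- max(d)
  if (mx == 0) {
    warning("all phase-space points coincide: maximum diameter is 0",
            call. = FALSE)
    attr(d, "degenerate") <- TRUE
    return(d)
  }
  d / mx
}

# Lengths of maximal runs of ones along one logical/0-1 vector.
run_lengths <- function(v) {
  r <- rle(as.logical(v))
  r$lengths[r$values]
}

# Histogram (counts indexed by length 1..N) of maximal diagonal lines,
# excluding diagonals with |i - j| < theiler_window, and of maximal vertical
# lines over all columns.
line_histograms <- function(M, theiler_window) {
  N <- nrow(M)
  dlen <- integer(0)
  offsets <- setdiff(-(N - 1L):(N - 1L),
                     (-(theiler_window - 1L)):(theiler_window - 1L))
  if (theiler_window == 0L) offsets <- -(N - 1L):(N - 1L)
  for (k in offsets) {
    i <- if (k >= 0) 1L:(N - k) else (1L - k):N
    j <- i + k
    dlen <- c(dlen, run_lengths(M[cbind(i, j)]))
  }
  vlen <- unlist(lapply(seq_len(N), function(j) run_lengths(M[, j])),
                 use.names = FALSE)
  list(diag_hist = tabulate(dlen, nbins = N),
       vert_hist = tabulate(if (length(vlen)) vlen else integer(0),
                            nbins = N))
}

#' Recurrence plot from a normalised distance matrix
#'
#' Thresholds the distance matrix at `epsilon_fraction` of the maximum
#' phase-space diameter (9 percent by default): entry \eqn{(i, j)} is 1 iff
#' `dm[i, j] < epsilon_fraction`.  Maximal diagonal and vertical line-length
#' histograms are enumerated on the binary matrix; diagonals within
#' `theiler_window` of the line of identity are excluded from the diagonal
#' histogram (but remain in the stored matrix).
#'
#' @param dm Normalised distance matrix from [distance_matrix()].
#' @param epsilon_fraction Recurrence threshold as a fraction of the maximum
#'   diameter, in `(0, 1)`.
#' @param theiler_window Number of diagonals around the line of identity
#'   excluded from diagonal statistics (default 1: exclude only the LOI).
#' @param l_min Minimum line length counted as structure (default 3).
#' @return An object of class `recurrence_plot`: list with the binary
#'   `matrix`, `diag_hist` and `vert_hist` (counts indexed by line length),
#'   `epsilon_fraction`, `theiler_window` and `l_min`.
#' @export
recurrence_plot <- function(dm, epsilon_fraction = 0.09, theiler_window = 1,
                            l_min = 3) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm)) stop_input("`dm` must be square")
  if (!is.numeric(epsilon_fraction) || epsilon_fraction <= 0 ||
      epsilon_fraction >= 1) {
    stop_input("`epsilon_fraction` must lie in (0, 1)")
  }
  as_recurrence_plot((dm < epsilon_fraction) * 1L,
                     epsilon_fraction = epsilon_fraction,
                     theiler_window = theiler_window, l_min = l_min)
}

#' Build a recurrence-plot object from a binary matrix
#'
#' Computes the line-length histograms for an already-thresholded binary
#' matrix.  Useful for testing and for importing recurrence matrices
#' produced elsewhere.
#'
#' @param M Square 0/1 matrix.
#' @param epsilon_fraction Threshold recorded with the object (metadata
#'   only).
#' @param theiler_window,l_min See [recurrence_plot()].
#' @return A `recurrence_plot` object.
#' @export
as_recurrence_plot <- function(M, epsilon_fraction = NA_real_,
                               theiler_window = 1, l_min = 3) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop_input("`M` must be square")
  if (nrow(M) < 1L) stop_input("`M` must be non-empty")
  if (!all(M %in% c(0, 1))) stop_input("`M` must be binary")
  check_scalar_number(theiler_window, "theiler_window", 0)
  check_scalar_number(l_min, "l_min", 1)
  storage.mode(M) <- "integer"
  h <- line_histograms(M, as.integer(theiler_window))
  structure(
    list(matrix = M, diag_hist = h$diag_hist, vert_hist = h$vert_hist,
         epsilon_fraction = epsilon_fraction,
         theiler_window = as.integer(theiler_window),
         l_min = as.integer(l_min)),
    class = "recurrence_plot"
  )
}

#' @export
print.recurrence_plot <- function(x, ...) {
  N <- nrow(x$matrix)
  cat(sprintf(
    "<recurrence_plot: %d x %d, eps %s, density %.3f, theiler %d, l_min %d>\n",
    N, N, format(x$epsilon_fraction), mean(x$matrix), x$theiler_window,
    x$l_min))
  invisible(x)
}

#' The ten recurrence factors of a recurrence plot
#'
#' Computes, in canonical order ([rqa_factor_names]):
#' \describe{
#'   \item{recr}{Recurrence rate: density of recurrences over the
#'     off-diagonal cells, \eqn{\sum_{i \ne j} RP_{ij} / (N^2 - N)}.}
#'   \item{dtm}{Determinism: fraction of recurrence mass on diagonal lines
#'     of length `>= l_min`, \eqn{\sum_{d \ge l_{min}} d P_d(d) /
#'     \sum_{d \ge 1} d P_d(d)}, with the line of identity excluded by the
#'     Theiler window.}
#'   \item{mean_diag}{Weighted mean diagonal line length over
#'     `d >= l_min`.}
#'   \item{dmax}{Longest diagonal line of length `>= l_min`.}
#'   \item{entr}{Shannon entropy (nats) of the diagonal length distribution
#'     over `d >= l_min`.}
#'   \item{lam}{Laminarity: fraction of recurrence mass on vertical lines
#'     of length `>= l_min`.}
#'   \item{tt}{Trapping time: mean vertical line length over
#'     `v >= l_min`.}
#'   \item{vmax}{Longest vertical line of length `>= l_min`.}
#'   \item{t1}{Type-1 mean return time: mean gap between successive
#'     recurrence rows within each column (sojourn points included).}
#'   \item{t2}{Type-2 mean return time: as `t1` after collapsing each
#'     consecutive recurrence run to its first point.}
#' }
#'
#' Factors whose qualifying structure is absent (for example no diagonal of
#' length `>= l_min`) are reported as 0 and flagged in the `undefined`
#' attribute; downstream analyses can treat the flag as missingness.
#'
#' @param rp A [recurrence_plot()] object.
#' @return Named numeric vector of length 10 (class `rqa_factors`) with a
#'   logical `undefined` attribute of the same names.
#' @export
rqa_factors <- function(rp) {
  if (!inherits(rp, "recurrence_plot")) {
    stop_input("`rp` must be a recurrence_plot object")
  }
  M <- rp$matrix
  N <- nrow(M)
  if (N < 2L) stop_input("recurrence plot too small (N >= 2 required)")
  l_min <- rp$l_min
  undef <- stats::setNames(logical(10L), rqa_factor_names)

  recr <- (sum(M) - sum(diag(M))) / (N^2 - N)

  dh <- rp$diag_hist
  d <- seq_along(dh)
  long_d <- d >= l_min
  den_d <- sum(d * dh)
  dtm <- if (den_d > 0) sum(d[long_d] * dh[long_d]) / den_d else {
    undef["dtm"] <- TRUE; 0
  }
  n_long_d <- sum(dh[long_d])
  if (n_long_d > 0) {
    mean_diag <- sum(d[long_d] * dh[long_d]) / n_long_d
    dmax <- max(d[long_d & dh > 0])
    p <- dh[long_d][dh[long_d] > 0] / n_long_d
    entr <- -sum(p * log(p))
  } else {
    undef[c("mean_diag", "dmax", "entr")] <- TRUE
    mean_diag <- 0; dmax <- 0; entr <- 0
  }

  vh <- rp$vert_hist
  v <- seq_along(vh)
  long_v <- v >= l_min
  den_v <- sum(v * vh)
  lam <- if (den_v > 0) sum(v[long_v] * vh[long_v]) / den_v else {
    undef["lam"] <- TRUE; 0
  }
  n_long_v <- sum(vh[long_v])
  if (n_long_v > 0) {
    tt <- sum(v[long_v] * vh[long_v]) / n_long_v
    vmax <- max(v[long_v & vh > 0])
  } else {
    undef[c("tt", "vmax")] <- TRUE
    tt <- 0; vmax <- 0
  }

  gaps1 <- vector("list", N)
  gaps2 <- vector("list", N)
  for (j in seq_len(N)) {
    rows <- which(M[, j] == 1L)
    if (length(rows) >= 2L) gaps1[[j]] <- diff(rows)
    first <- rows[c(TRUE, diff(rows) > 1L)]
    if (length(first) >= 2L) gaps2[[j]] <- diff(first)
  }
  g1 <- unlist(gaps1, use.names = FALSE)
  g2 <- unlist(gaps2, use.names = FALSE)
  t1 <- if (length(g1)) mean(g1) else { undef["t1"] <- TRUE; 0 }
  t2 <- if (length(g2)) mean(g2) else { undef["t2"] <- TRUE; 0 }

  out <- stats::setNames(
    c(recr, dtm, mean_diag, dmax, entr, lam, tt, vmax, t1, t2),
    rqa_factor_names)
  attr(out, "undefined") <- undef
  class(out) <- "rqa_factors"
  out
}

#' @export
print.rqa_factors <- function(x, ...) {
  v <- unclass(x)
  attr(v, "undefined") <- NULL
  print(round(v, 4))
  und <- attr(x, "undefined")
  if (any(und)) {
    cat("undefined (no qualifying structure):",
        paste(names(und)[und], collapse = ", "), "\n")
  }
  invisible(x)
}
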