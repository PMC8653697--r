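# Readers and writers for ECG traces (CSV and WFDB-style text records) and
# RR-interval files.  CSV dialect: comma-separated, header row, '.' decimal.
# RR files carry one interval in ms per line, the lingua franca of HRV
# tools.

#' Write an ECG trace as CSV
#'
#' Columns `time_s,voltage`, full precision, so a write/read round trip
#' preserves the samples bit-exactly.
#'
#' @param ecg An [ecg_signal()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(ecg, path) {
  stopifnot(inherits(ecg, "ecg_signal"))
  time_s <- (seq_along(ecg$samples) - 1L) / ecg$fs
  df <- data.frame(time_s = sprintf("%.17g", time_s),
                   voltage = sprintf("%.17g", ecg$samples))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = c("time_s", "voltage"))
  invisible(path)
}

#' Write an ECG trace as a WFDB-style text record
#'
#' Writes `<record>.hea` with the usual header line
#' `record-name n-signals fs n-samples` plus one signal line, and the
#' samples (full precision, one per line) in `<record>.txt`.  This is a
#' plain-text sibling of the WFDB format: the header is WFDB-compatible,
#' the signal file is ASCII rather than binary.
#'
#' @param ecg An [ecg_signal()].
#' @param record Record path without extension.
#' @return The header path, invisibly.
#' @export
write_ecg_wfdb <- function(ecg, record) {
  stopifnot(inherits(ecg, "ecg_signal"))
  name <- basename(record)
  hea <- paste0(record, ".hea")
  dat <- paste0(record, ".txt")
  writeLines(c(
    sprintf("%s 1 %.10g %d", name, ecg$fs, length(ecg$samples)),
    sprintf("%s.txt ascii 1 0 0 0 0 0 ECG", name)
  ), hea)
  writeLines(sprintf("%.17g", ecg$samples), dat)
  invisible(hea)
}

#' Read a single-lead ECG from CSV or a WFDB-style text record
#'
#' For CSV input the file must have a `time_s,voltage` header; the sampling
#' rate is recovered from the timestamp spacing, which must be uniform to
#' within `tolerance` (relative).  For WFDB input, `path` is the `.hea`
#' header (or the record path without extension); the sampling rate is read
#' from the header and the samples from the ASCII signal file next to it.
#'
#' @param path Input file path.
#' @param format `"csv"` or `"wfdb"`.
#' @param tolerance Maximum relative deviation of timestamp spacing from
#'   uniformity.
#' @return An [ecg_signal()].
#' @export
read_ecg <- function(path, format = c("csv", "wfdb"), tolerance = 1e-6) {
  format <- match.arg(format)
  if (format == "wfdb") return(read_ecg_wfdb(path))
  if (!file.exists(path)) stop_input("file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 3L) stop_input("CSV must have a header and >= 2 rows")
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (length(header) < 2L) stop_input("expected 'time_s,voltage' header")
  parts <- strsplit(lines[-1L], ",", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad)) {
    stop_input("malformed row at line %d: '%s'", bad[1L] + 1L,
               lines[bad[1L] + 1L])
  }
  time_s <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  voltage <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  bad <- which(!is.finite(time_s) | !is.finite(voltage))
  if (length(bad)) {
    stop_input("malformed row at line %d: '%s'", bad[1L] + 1L,
               lines[bad[1L] + 1L])
  }
  dt <- diff(time_s)
  if (any(dt <= 0)) stop_input("timestamps must be strictly increasing")
  dt0 <- stats::median(dt)
  if (max(abs(dt - dt0)) > tolerance * dt0) {
    stop_input("non-uniform sampling: timestamp spacing varies by more than %g (relative)",
               tolerance)
  }
  ecg_signal(voltage, fs = 1 / dt0)
}

read_ecg_wfdb <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop_input("header not found: %s", hea)
  lines <- readLines(hea)
  fields <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(fields) < 3L) {
    stop_input("WFDB header must carry 'name n-signals fs'")
  }
  fs <- suppressWarnings(as.numeric(fields[3L]))
  if (!is.finite(fs) || fs <= 0) stop_input("invalid fs in WFDB header")
  dat <- file.path(dirname(hea), paste0(fields[1L], ".txt"))
  if (!file.exists(dat)) stop_input("signal file not found: %s", dat)
  samples <- as.numeric(readLines(dat))
  if (any(!is.finite(samples))) stop_input("non-numeric sample in %s", dat)
  ecg_signal(samples, fs = fs)
}

#' Write RR intervals to a text file
#'
#' One interval (ms, full precision) per line.
#'
#' @param t A `tachogram` or numeric RR vector (ms).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rr <- function(t, path) {
  writeLines(sprintf("%.17g", as_rr(t)), path)
  invisible(path)
}

#' Read RR intervals from a text file
#'
#' @param path File with one RR interval (ms) per line.
#' @param origin Origin recorded in the tachogram (default `"detected"`).
#' @return A `tachogram`.
#' @export
read_rr <- function(path, origin = "detected") {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  rr <- suppressWarnings(as.numeric(lines))
  bad <- which(!is.finite(rr))
  if (length(bad)) {
    stop_input("malformed RR value at line %d: '%s'", bad[1L], lines[bad[1L]])
  }
  as_tachogram(rr, origin = origin)
}
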