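#' Construct a SweepSet
#'
#' One subject's epoched multi-sweep EEG: a numeric matrix (rows = sweeps,
#' columns = samples, amplitudes in microvolts) with per-sweep stimulus
#' polarity labels and the epoch time base.
#'
#' @param sweeps numeric matrix, rows = sweeps, columns = samples (microvolts).
#' @param polarity character vector (one of `"A"`, `"B"` per sweep).
#' @param sampling_rate_hz sampling rate (Hz).
#' @param epoch_window_ms epoch interval (ms), typically `c(-30, 230)`.
#' @param subject_id,group optional metadata carried through the pipeline.
#' @param n_rejected count of sweeps already removed by artifact rejection.
#' @return An object of class `ffr_sweepset`.
#' @export
sweep_set <- function(sweeps, polarity, sampling_rate_hz,
                      epoch_window_ms = c(-30, 230),
                      subject_id = NA_character_, group = NA_character_,
                      n_rejected = 0L) {
  if (!is.matrix(sweeps) || !is.numeric(sweeps))
    stopf("sweeps must be a numeric matrix (rows = sweeps)")
  polarity <- as.character(polarity)
  if (length(polarity) != nrow(sweeps))
    stopf("polarity must have one label per sweep row")
  if (!all(polarity %in% c("A", "B")))
    stopf("polarity labels must be 'A' or 'B'")
  check_interval(epoch_window_ms, "epoch_window_ms")
  expected <- (epoch_window_ms[2] - epoch_window_ms[1]) * sampling_rate_hz / 1000
  if (abs(ncol(sweeps) - expected) > 1)
    stopf("epoch window (%g..%g ms at %g Hz) implies %g samples, matrix has %d",
          epoch_window_ms[1], epoch_window_ms[2], sampling_rate_hz,
          expected, ncol(sweeps))
  structure(list(
    sweeps = sweeps, polarity = polarity,
    sampling_rate_hz = sampling_rate_hz,
    epoch_window_ms = as.numeric(epoch_window_ms),
    subject_id = subject_id, group = group,
    n_rejected = as.integer(n_rejected)
  ), class = "ffr_sweepset")
}

#' @export
print.ffr_sweepset <- function(x, ...) {
  cat(sprintf("FFR sweep set%s: %d sweeps (A: %d, B: %d) x %d samples at %g Hz, epoch %g..%g ms\n",
              if (is.na(x$subject_id)) "" else paste0(" [", x$subject_id, "]"),
              nrow(x$sweeps), sum(x$polarity == "A"), sum(x$polarity == "B"),
              ncol(x$sweeps), x$sampling_rate_hz,
              x$epoch_window_ms[1], x$epoch_window_ms[2]))
  if (x$n_rejected > 0) cat(sprintf("  %d sweeps rejected upstream\n", x$n_rejected))
  invisible(x)
}

# epoch sample times in ms (sample k sits at epoch_start + (k-1)/fs)
epoch_times_ms <- function(x) {
  x$epoch_window_ms[1] + (seq_len(ncol(x$sweeps)) - 1) * 1000 / x$sampling_rate_hz
}

#' Write a SweepSet to a delimited text file
#'
#' Format: `#`-prefixed `key: value` header lines (subject id, group, sampling
#' rate, epoch window, polarity label string), followed by a tab-separated
#' numeric matrix, one sweep per row.
#'
#' @param x an `ffr_sweepset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sweepset <- function(x, path) {
  stopifnot(inherits(x, "ffr_sweepset"))
  header <- c(
    "# ffrpipe sweepset v1",
    sprintf("# subject_id: %s", x$subject_id),
    sprintf("# group: %s", x$group),
    sprintf("# sampling_rate_hz: %.10g", x$sampling_rate_hz),
    sprintf("# epoch_window_ms: %.10g %.10g", x$epoch_window_ms[1], x$epoch_window_ms[2]),
    sprintf("# n_rejected: %d", x$n_rejected),
    sprintf("# polarity: %s", paste(x$polarity, collapse = ""))
  )
  writeLines(header, path)
  data.table::fwrite(data.table::as.data.table(x$sweeps), path,
                     append = TRUE, sep = "\t", col.names = FALSE)
  invisible(path)
}

read_header_lines <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  out <- character()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0 || !startsWith(ln, "#")) break
    out <- c(out, ln)
  }
  out
}

header_field <- function(header, key) {
  pat <- paste0("^# ", key, ": ?")
  ln <- grep(pat, header, value = TRUE)
  if (length(ln) != 1) stopf("missing header field '%s'", key)
  sub(pat, "", ln)
}

#' Read a SweepSet written by [write_sweepset()]
#'
#' @param path file path.
#' @return An `ffr_sweepset`.
#' @export
read_sweepset <- function(path) {
  if (!file.exists(path)) stopf("sweep file not found: %s", path)
  header <- read_header_lines(path)
  if (length(header) == 0 || !grepl("ffrpipe sweepset", header[1]))
    stopf("%s is not an ffrpipe sweepset file", path)
  mat <- as.matrix(data.table::fread(path, skip = length(header),
                                     sep = "\t", header = FALSE))
  dimnames(mat) <- NULL
  pol <- strsplit(header_field(header, "polarity"), "")[[1]]
  sweep_set(
    sweeps = mat, polarity = pol,
    sampling_rate_hz = as.numeric(header_field(header, "sampling_rate_hz")),
    epoch_window_ms = as.numeric(strsplit(header_field(header, "epoch_window_ms"), " ")[[1]]),
    subject_id = header_field(header, "subject_id"),
    group = header_field(header, "group"),
    n_rejected = as.integer(header_field(header, "n_rejected"))
  )
}

#' Averaged response container
#'
#' A subject's polarity-subtracted average waveform on the epoch time base,
#' with bookkeeping of sweep counts.
#'
#' @param samples numeric vector (microvolts).
#' @param sampling_rate_hz sampling rate (Hz).
#' @param epoch_window_ms epoch interval (ms).
#' @param n_sweeps_used integer vector `c(A = .., B = ..)`.
#' @param n_rejected rejected sweep count.
#' @param subject_id,group optional metadata.
#' @return An object of class `ffr_avg_response`.
#' @export
avg_response <- function(samples, sampling_rate_hz, epoch_window_ms,
                         n_sweeps_used, n_rejected = 0L,
                         subject_id = NA_character_, group = NA_character_) {
  structure(list(
    samples = as.numeric(samples), sampling_rate_hz = sampling_rate_hz,
    epoch_window_ms = as.numeric(epoch_window_ms),
    n_sweeps_used = stats::setNames(as.integer(n_sweeps_used), c("A", "B")),
    n_rejected = as.integer(n_rejected),
    subject_id = subject_id, group = group
  ), class = "ffr_avg_response")
}

#' @export
print.ffr_avg_response <- function(x, ...) {
  cat(sprintf("FFR averaged response%s: %d samples at %g Hz, epoch %g..%g ms\n",
              if (is.na(x$subject_id)) "" else paste0(" [", x$subject_id, "]"),
              length(x$samples), x$sampling_rate_hz,
              x$epoch_window_ms[1], x$epoch_window_ms[2]))
  cat(sprintf("  sweeps used A/B: %d/%d; rejected: %d\n",
              x$n_sweeps_used[1], x$n_sweeps_used[2], x$n_rejected))
  invisible(x)
}

#' Write an averaged response to a delimited text file
#' @param x an `ffr_avg_response`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_avg_response <- function(x, path) {
  stopifnot(inherits(x, "ffr_avg_response"))
  header <- c(
    "# ffrpipe avg_response v1",
    sprintf("# subject_id: %s", x$subject_id),
    sprintf("# group: %s", x$group),
    sprintf("# sampling_rate_hz: %.10g", x$sampling_rate_hz),
    sprintf("# epoch_window_ms: %.10g %.10g", x$epoch_window_ms[1], x$epoch_window_ms[2]),
    sprintf("# n_sweeps_used: %d %d", x$n_sweeps_used[1], x$n_sweeps_used[2]),
    sprintf("# n_rejected: %d", x$n_rejected)
  )
  writeLines(header, path)
  data.table::fwrite(list(x$samples), path, append = TRUE, col.names = FALSE)
  invisible(path)
}

#' Read an averaged response written by [write_avg_response()]
#' @param path file path.
#' @return An `ffr_avg_response`.
#' @export
read_avg_response <- function(path) {
  if (!file.exists(path)) stopf("averaged-response file not found: %s", path)
  header <- read_header_lines(path)
  if (length(header) == 0 || !grepl("ffrpipe avg_response", header[1]))
    stopf("%s is not an ffrpipe averaged-response file", path)
  samples <- data.table::fread(path, skip = length(header), header = FALSE)[[1]]
  avg_response(
    samples = samples,
    sampling_rate_hz = as.numeric(header_field(header, "sampling_rate_hz")),
    epoch_window_ms = as.numeric(strsplit(header_field(header, "epoch_window_ms"), " ")[[1]]),
    n_sweeps_used = as.integer(strsplit(header_field(header, "n_sweeps_used"), " ")[[1]]),
    n_rejected = as.integer(header_field(header, "n_rejected")),
    subject_id = header_field(header, "subject_id"),
    group = header_field(header, "group")
  )
}
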