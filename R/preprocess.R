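# Preprocessing: bandpass filter -> artifact rejection -> baseline correction
# -> polarity-subtracted averaging, in that order.

# Second-order (12 dB/octave) digital Butterworth sections via the bilinear
# transform with frequency prewarping (RBJ biquad formulation, Q = 1/sqrt(2)).
biquad_butter <- function(fc, fs, type = c("high", "low")) {
  type <- match.arg(type)
  w0 <- 2 * pi * fc / fs
  alpha <- sin(w0) / (2 * (1 / sqrt(2)))
  cw <- cos(w0)
  if (type == "high") {
    b <- c((1 + cw) / 2, -(1 + cw), (1 + cw) / 2)
  } else {
    b <- c((1 - cw) / 2, (1 - cw), (1 - cw) / 2)
  }
  a <- c(1 + alpha, -2 * cw, 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Design the FFR bandpass filter
#'
#' Cascade of a second-order Butterworth highpass and lowpass, giving the
#' classic 12 dB/octave asymptotic roll-off beyond each corner.
#'
#' @param low_hz highpass corner (Hz).
#' @param high_hz lowpass corner (Hz).
#' @param sampling_rate_hz sampling rate (Hz).
#' @return An object of class `ffr_filter` (list of biquad sections).
#' @export
design_bandpass <- function(low_hz, high_hz, sampling_rate_hz) {
  nyq <- sampling_rate_hz / 2
  if (!is_number(low_hz) || !is_number(high_hz) || low_hz <= 0)
    stopf("filter corners must be positive numbers")
  if (low_hz >= high_hz)
    stopf("filter low corner (%g Hz) must be below the high corner (%g Hz)",
          low_hz, high_hz)
  if (high_hz >= nyq)
    stopf("filter corner %g Hz is at/above the Nyquist frequency (%g Hz)",
          high_hz, nyq)
  structure(list(
    sections = list(biquad_butter(low_hz, sampling_rate_hz, "high"),
                    biquad_butter(high_hz, sampling_rate_hz, "low")),
    low_hz = low_hz, high_hz = high_hz, sampling_rate_hz = sampling_rate_hz
  ), class = "ffr_filter")
}

#' Magnitude response of a designed filter
#'
#' Evaluates the filter's frequency response on the unit circle
#' (the analytic magnitude of the realized digital filter).
#'
#' @param flt an `ffr_filter` from [design_bandpass()].
#' @param freq_hz frequencies (Hz) at which to evaluate.
#' @return numeric vector of linear magnitude gains.
#' @export
filter_response <- function(flt, freq_hz) {
  stopifnot(inherits(flt, "ffr_filter"))
  w <- 2 * pi * freq_hz / flt$sampling_rate_hz
  z1 <- exp(-1i * w)
  h <- rep(1 + 0i, length(w))
  for (s in flt$sections) {
    num <- s$b[1] + s$b[2] * z1 + s$b[3] * z1^2
    den <- s$a[1] + s$a[2] * z1 + s$a[3] * z1^2
    h <- h * num / den
  }
  Mod(h)
}

# Reference implementation of causal IIR filtering of a samples x series
# matrix via stats::filter (FIR numerator as one-sided convolution with zero
# initial conditions, then the recursive denominator). The fast path is the
# compiled biquad cascade; this version is kept as an independent check.
iir_filter_matrix <- function(X, b, a) {
  nc <- ncol(X)
  pad <- matrix(0, length(b) - 1L, nc)
  V <- stats::filter(rbind(pad, X), b, method = "convolution", sides = 1)
  V <- V[-seq_len(nrow(pad)), , drop = FALSE]
  Y <- stats::filter(V, -a[-1], method = "recursive")
  Y <- matrix(as.numeric(Y), nrow(X), nc)
  Y
}

apply_filter_samples <- function(X, flt, zero_phase = FALSE) {
  # X: samples x series
  X <- biquad_cascade(X, flt$sections)
  if (zero_phase) {
    X <- X[nrow(X):1, , drop = FALSE]
    X <- biquad_cascade(X, flt$sections)
    X <- X[nrow(X):1, , drop = FALSE]
  }
  X
}

#' Bandpass-filter all sweeps of a SweepSet
#'
#' Butterworth bandpass with 12 dB/octave asymptotic roll-off beyond each
#' corner; removes DC. Applied causally (forward only) by default so the
#' realized roll-off equals the nominal slope; `zero_phase = TRUE` runs the
#' filter forward and backward, which removes phase distortion but doubles
#' the effective roll-off.
#'
#' @param sweeps an `ffr_sweepset`.
#' @param low_hz,high_hz corner frequencies (Hz).
#' @param zero_phase logical; forward-backward filtering (default FALSE).
#' @return The filtered `ffr_sweepset`.
#' @export
bandpass_filter <- function(sweeps, low_hz = 70, high_hz = 2000,
                            zero_phase = FALSE) {
  stopifnot(inherits(sweeps, "ffr_sweepset"))
  flt <- design_bandpass(low_hz, high_hz, sweeps$sampling_rate_hz)
  sweeps$sweeps <- t(apply_filter_samples(t(sweeps$sweeps), flt, zero_phase))
  sweeps
}

#' Filter a single waveform
#'
#' Convenience wrapper around the matrix path for vectors (used e.g. to build
#' reference waveforms comparable to filtered sweeps).
#'
#' @param x numeric vector.
#' @param flt an `ffr_filter`.
#' @param zero_phase logical.
#' @return filtered numeric vector.
#' @export
filter_waveform <- function(x, flt, zero_phase = FALSE) {
  as.numeric(apply_filter_samples(matrix(x, ncol = 1), flt, zero_phase))
}

#' Reject artifact sweeps
#'
#' Removes sweeps with any sample strictly exceeding the threshold
#' (`|x| > threshold_uv`); a sample exactly at the threshold is retained.
#' Survivor order is preserved.
#'
#' @param sweeps an `ffr_sweepset`.
#' @param threshold_uv rejection threshold (microvolts), default 30.
#' @return list with `sweeps` (surviving `ffr_sweepset`, its `n_rejected`
#'   field incremented) and `n_rejected` (count removed by this call).
#' @export
reject_artifacts <- function(sweeps, threshold_uv = 30) {
  stopifnot(inherits(sweeps, "ffr_sweepset"))
  if (!is_number(threshold_uv) || threshold_uv <= 0)
    stopf("threshold_uv must be > 0")
  peak <- apply(abs(sweeps$sweeps), 1, max)
  keep <- peak <= threshold_uv
  n_rejected <- sum(!keep)
  if (!any(keep))
    stopf("all %d sweeps exceed +/- %g microvolts; nothing left to average",
          length(keep), threshold_uv)
  sweeps$sweeps <- sweeps$sweeps[keep, , drop = FALSE]
  sweeps$polarity <- sweeps$polarity[keep]
  sweeps$n_rejected <- sweeps$n_rejected + as.integer(n_rejected)
  list(sweeps = sweeps, n_rejected = as.integer(n_rejected))
}

#' Baseline-correct each sweep
#'
#' Subtracts, per sweep, its mean over the pre-stimulus baseline window from
#' every sample.
#'
#' @param sweeps an `ffr_sweepset`.
#' @param baseline_window_ms baseline interval (ms), default `c(-30, 0)`.
#' @return The corrected `ffr_sweepset`.
#' @export
baseline_correct <- function(sweeps, baseline_window_ms = c(-30, 0)) {
  stopifnot(inherits(sweeps, "ffr_sweepset"))
  check_interval(baseline_window_ms, "baseline_window_ms")
  ep <- sweeps$epoch_window_ms
  if (baseline_window_ms[1] < ep[1] - 1e-9 || baseline_window_ms[2] > ep[2] + 1e-9)
    stopf("baseline window %g..%g ms lies outside the epoch window %g..%g ms",
          baseline_window_ms[1], baseline_window_ms[2], ep[1], ep[2])
  t_ms <- epoch_times_ms(sweeps)
  idx <- which(t_ms >= baseline_window_ms[1] & t_ms < baseline_window_ms[2])
  if (length(idx) == 0) stopf("baseline window contains no samples")
  bl <- rowMeans(sweeps$sweeps[, idx, drop = FALSE])
  sweeps$sweeps <- sweeps$sweeps - bl
  sweeps
}

#' Polarity-subtracted average
#'
#' Averages the two stimulus polarities separately and returns half their
#' difference, `(avgA - avgB) / 2`. Subtraction doubles the polarity-inverting
#' fine-structure component and cancels polarity-invariant components
#' (envelope-following response, stimulus artifact, cochlear microphonic);
#' the division by 2 keeps amplitudes on the scale of a single-polarity
#' average. Each polarity is averaged over its own surviving sweeps.
#'
#' @param sweeps an `ffr_sweepset`; both polarities must be present.
#' @return An `ffr_avg_response`.
#' @export
average_and_subtract <- function(sweeps) {
  stopifnot(inherits(sweeps, "ffr_sweepset"))
  ia <- sweeps$polarity == "A"
  ib <- sweeps$polarity == "B"
  if (!any(ia) || !any(ib))
    stopf("both stimulus polarities must be present (have A: %d, B: %d)",
          sum(ia), sum(ib))
  avg_a <- colMeans(sweeps$sweeps[ia, , drop = FALSE])
  avg_b <- colMeans(sweeps$sweeps[ib, , drop = FALSE])
  avg_response(
    samples = (avg_a - avg_b) / 2,
    sampling_rate_hz = sweeps$sampling_rate_hz,
    epoch_window_ms = sweeps$epoch_window_ms,
    n_sweeps_used = c(A = sum(ia), B = sum(ib)),
    n_rejected = sweeps$n_rejected,
    subject_id = sweeps$subject_id, group = sweeps$group
  )
}

#' Full preprocessing pipeline for one subject
#'
#' Filter, reject artifacts, baseline-correct, then average with polarity
#' subtraction, in that order.
#'
#' @param sweeps an `ffr_sweepset`.
#' @param low_hz,high_hz bandpass corners (Hz).
#' @param threshold_uv artifact rejection threshold (microvolts).
#' @param baseline_window_ms baseline interval (ms).
#' @param zero_phase passed to [bandpass_filter()].
#' @return An `ffr_avg_response`.
#' @export
preprocess_sweeps <- function(sweeps, low_hz = 70, high_hz = 2000,
                              threshold_uv = 30,
                              baseline_window_ms = c(-30, 0),
                              zero_phase = FALSE) {
  x <- bandpass_filter(sweeps, low_hz, high_hz, zero_phase)
  x <- reject_artifacts(x, threshold_uv)$sweeps
  x <- baseline_correct(x, baseline_window_ms)
  average_and_subtract(x)
}
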