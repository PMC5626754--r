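# Region-wise amplitude spectra and stimulus-anchored peak extraction.

# Single-sided amplitude spectrum of a segment: rectangular window, zero-padded
# so the bin width is <= resolution_hz, amplitude = 2|X|/N_unpadded.
amplitude_spectrum <- function(segment, sampling_rate_hz, resolution_hz = 1,
                               region_label = "whole") {
  n <- length(segment)
  if (n < 2) stopf("segment must contain at least 2 samples")
  nfft <- max(next_pow2(sampling_rate_hz / resolution_hz), next_pow2(n))
  x <- c(segment, numeric(nfft - n))
  sp <- stats::fft(x)[seq_len(nfft / 2 + 1)]
  structure(list(
    freqs_hz = (0:(nfft / 2)) * sampling_rate_hz / nfft,
    amplitude = 2 * Mod(sp) / n,
    region_label = region_label,
    resolution_hz = sampling_rate_hz / nfft,
    n_samples = n
  ), class = "ffr_spectrum")
}

#' @export
print.ffr_spectrum <- function(x, ...) {
  cat(sprintf("FFR spectrum [%s]: %d bins, 0..%g Hz, resolution %.4g Hz (from %d samples)\n",
              x$region_label, length(x$freqs_hz), max(x$freqs_hz),
              x$resolution_hz, x$n_samples))
  invisible(x)
}

#' Amplitude spectrum of one time region of an averaged response
#'
#' Extracts the segment by closed-open sample indexing, applies a rectangular
#' window, and zero-pads the FFT so the bin width is at most `resolution_hz`
#' (default 1 Hz). Amplitudes follow the single-sided convention
#' `2 |X| / N_unpadded`, so a unit sinusoid spanning the window reads 1.
#'
#' @param response an `ffr_avg_response`.
#' @param window_ms time interval (ms) inside the epoch window.
#' @param resolution_hz maximum FFT bin width (Hz).
#' @param region_label label stored on the spectrum.
#' @return An object of class `ffr_spectrum`.
#' @export
region_spectrum <- function(response, window_ms, resolution_hz = 1,
                            region_label = "whole") {
  stopifnot(inherits(response, "ffr_avg_response"))
  check_interval(window_ms, "window_ms")
  ep <- response$epoch_window_ms
  if (window_ms[1] < ep[1] - 1e-9 || window_ms[2] > ep[2] + 1e-9)
    stopf("window %g..%g ms lies outside the epoch window %g..%g ms",
          window_ms[1], window_ms[2], ep[1], ep[2])
  fs <- response$sampling_rate_hz
  i0 <- round((window_ms[1] - ep[1]) * fs / 1000) + 1
  nseg <- round((window_ms[2] - window_ms[1]) * fs / 1000)
  if (nseg < 2) stopf("window shorter than 2 samples")
  seg <- response$samples[i0:(i0 + nseg - 1)]
  amplitude_spectrum(seg, fs, resolution_hz, region_label)
}

# Indices of interior local maxima of `amp` restricted to `idx`
# (plateaus count once, at their first bin).
local_maxima_in <- function(amp, idx) {
  idx <- idx[idx > 1 & idx < length(amp)]
  idx[amp[idx] >= amp[idx - 1] & amp[idx] >= amp[idx + 1] &
        (amp[idx] > amp[idx - 1] | amp[idx] > amp[idx + 1])]
}

# Refined peak near a nominal frequency: frequency of the highest interior
# local maximum within +/- search_hz (ties resolve to the lowest frequency).
refine_peak <- function(freqs, amp, nominal_hz, search_hz) {
  idx <- which(freqs >= nominal_hz - search_hz & freqs <= nominal_hz + search_hz)
  cand <- local_maxima_in(amp, idx)
  if (length(cand) == 0)
    stopf("no spectral local maximum within +/- %g Hz of %g Hz",
          search_hz, nominal_hz)
  best <- cand[amp[cand] == max(amp[cand])]
  freqs[min(best)]
}

#' Refine band peak frequencies from the stimulus spectrum
#'
#' Computes the whole-stimulus amplitude spectrum and, for each nominal band
#' frequency (F0, H2-H6), returns the frequency of the local spectral maximum
#' within `search_hz` of the nominal value. These refined frequencies anchor
#' the response peak-window extraction in both time regions.
#'
#' @param stimulus an `ffr_stimulus`.
#' @param spec a [stimulus_spec()].
#' @param search_hz half-width (Hz) of the search interval around each nominal
#'   frequency.
#' @param resolution_hz maximum FFT bin width (Hz).
#' @return named numeric vector (`f0, h2, ..., h6`) of refined frequencies.
#' @export
stimulus_peak_frequencies <- function(stimulus, spec, search_hz = 30,
                                      resolution_hz = 1) {
  stopifnot(inherits(stimulus, "ffr_stimulus"),
            inherits(spec, "ffr_stimulus_spec"))
  if (length(stimulus$samples) < stimulus$sampling_rate_hz / spec$f0_hz)
    stopf("stimulus is shorter than one F0 period")
  sp <- amplitude_spectrum(stimulus$samples, stimulus$sampling_rate_hz,
                           resolution_hz, "stimulus")
  vapply(band_frequencies(spec), function(f)
    refine_peak(sp$freqs_hz, sp$amplitude, f, search_hz), numeric(1))
}

#' Closed peak-extraction window around a center frequency
#'
#' The extraction rule uses a total bandwidth around the peak: a 20 Hz
#' bandwidth at a 118 Hz peak searches the closed interval 108 to 128 Hz.
#'
#' @param center_hz peak frequency (Hz).
#' @param bandwidth_hz total window width (Hz).
#' @return numeric `c(lo, hi)`.
#' @export
peak_window <- function(center_hz, bandwidth_hz = 20) {
  c(center_hz - bandwidth_hz / 2, center_hz + bandwidth_hz / 2)
}

#' Maximum spectral amplitude in a peak window
#'
#' Maximum amplitude over all bins whose frequency lies in the closed interval
#' `[center - bandwidth/2, center + bandwidth/2]`. The DC bin is never
#' eligible.
#'
#' @param spectrum an `ffr_spectrum`.
#' @param center_hz window center (Hz).
#' @param bandwidth_hz total window width (Hz).
#' @return amplitude (microvolts).
#' @export
extract_peak_amplitude <- function(spectrum, center_hz, bandwidth_hz = 20) {
  stopifnot(inherits(spectrum, "ffr_spectrum"))
  win <- peak_window(center_hz, bandwidth_hz)
  if (win[1] < 0 || win[2] > max(spectrum$freqs_hz))
    stopf("peak window %g..%g Hz exceeds the spectrum range (0..%g Hz)",
          win[1], win[2], max(spectrum$freqs_hz))
  sel <- spectrum$freqs_hz >= win[1] & spectrum$freqs_hz <= win[2] &
    spectrum$freqs_hz > 0
  if (!any(sel))
    stopf("no spectral bins inside the window %g..%g Hz", win[1], win[2])
  max(spectrum$amplitude[sel])
}

#' Partition harmonics into formant and non-formant sets
#'
#' Harmonic h is classified in-formant iff its refined frequency lies in the
#' closed interval `[f1_low - margin, f1_high + margin]`.
#'
#' @param peak_freqs named vector of refined harmonic frequencies
#'   (`h2, ..., h6`); an `f0` entry, if present, is ignored.
#' @param f1_range closed interval (Hz) of the first formant.
#' @param margin_hz tolerance (Hz) added to each side.
#' @return list with character vectors `f1_members` and `non_f1_members`
#'   (possibly empty).
#' @export
classify_f1_harmonics <- function(peak_freqs, f1_range, margin_hz = 20) {
  check_interval(f1_range, "f1_range")
  if (!is_number(margin_hz) || margin_hz < 0) stopf("margin_hz must be >= 0")
  h <- peak_freqs[setdiff(names(peak_freqs), "f0")]
  if (length(h) != 5)
    stopf("expected refined frequencies for the 5 harmonics h2..h6")
  inside <- h >= f1_range[1] - margin_hz & h <= f1_range[2] + margin_hz
  list(f1_members = names(h)[inside], non_f1_members = names(h)[!inside])
}

#' Extract spectral features of one averaged response
#'
#' For each time region (consonant, vowel): computes the region amplitude
#' spectrum and extracts, at the refined stimulus peak frequencies, the F0 and
#' H2-H6 peak-window amplitudes; then forms the mean over all harmonics
#' (`mean_h`), the mean over harmonics inside the formant range (`f1_mean`),
#' and the mean over harmonics outside it (`non_f1_mean`).
#'
#' @param response an `ffr_avg_response`.
#' @param spec a [stimulus_spec()].
#' @param peak_freqs named vector from [stimulus_peak_frequencies()].
#' @param regions named list of region windows (ms); defaults to the spec's
#'   consonant and vowel windows.
#' @param resolution_hz maximum FFT bin width (Hz).
#' @return data frame, one row per region, with columns `subject_id`, `group`,
#'   `region`, `f0_amp`, `h2 ... h6`, `mean_h`, `f1_mean`, `non_f1_mean`;
#'   attribute `f1_members` records the harmonic partition.
#' @export
compute_features <- function(response, spec, peak_freqs,
                             regions = NULL, resolution_hz = 1) {
  stopifnot(inherits(response, "ffr_avg_response"),
            inherits(spec, "ffr_stimulus_spec"))
  if (is.null(names(peak_freqs)) || !all(ffr_bands() %in% names(peak_freqs)))
    stopf("peak_freqs must be named with bands f0, h2..h6")
  if (is.null(regions))
    regions <- list(consonant = spec$consonant_window_ms,
                    vowel = spec$vowel_window_ms)
  cls <- classify_f1_harmonics(peak_freqs, spec$f1_range_hz, spec$f1_margin_hz)
  bw <- spec$extraction_bandwidth_hz
  harm <- setdiff(ffr_bands(), "f0")
  rows <- lapply(names(regions), function(rg) {
    sp <- region_spectrum(response, regions[[rg]], resolution_hz, rg)
    amps <- vapply(ffr_bands(), function(b) {
      tryCatch(extract_peak_amplitude(sp, peak_freqs[[b]], bw),
               error = function(e) stopf("region '%s', band '%s': %s",
                                         rg, b, conditionMessage(e)))
    }, numeric(1))
    h_amps <- amps[harm]
    data.frame(
      subject_id = response$subject_id, group = response$group, region = rg,
      f0_amp = amps[["f0"]],
      as.list(h_amps),
      mean_h = mean(h_amps),
      f1_mean = if (length(cls$f1_members)) mean(h_amps[cls$f1_members]) else NA_real_,
      non_f1_mean = if (length(cls$non_f1_members)) mean(h_amps[cls$non_f1_members]) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "f1_members") <- cls$f1_members
  out
}

#' Extract features for a whole cohort of averaged responses
#'
#' @param responses list of `ffr_avg_response` objects.
#' @param spec a [stimulus_spec()].
#' @param peak_freqs named vector from [stimulus_peak_frequencies()].
#' @param ... passed to [compute_features()].
#' @return data frame of stacked per-subject features (class
#'   `ffr_features`), two rows (regions) per subject.
#' @export
compute_cohort_features <- function(responses, spec, peak_freqs, ...) {
  out <- do.call(rbind, lapply(responses, compute_features,
                               spec = spec, peak_freqs = peak_freqs, ...))
  rownames(out) <- NULL
  class(out) <- c("ffr_features", class(out))
  out
}
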