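#' Stimulus specification
#'
#' The frequency/time plan of the speech-like stimulus that anchors all
#' spectral feature extraction: fundamental frequency, harmonic peak
#' frequencies, first-formant range, region boundaries, and extraction
#' parameters. Defaults describe a 209 ms syllable with F0 at 129 Hz,
#' harmonics H2-H6 at 261, 393, 531, 665 and 787 Hz, and a first formant
#' spanning 400-700 Hz; response time regions are consonant 20-67 ms and
#' vowel 67-220 ms (stimulus time plus a 10 ms neural delay allowance).
#'
#' @param f0_hz fundamental frequency (Hz).
#' @param harmonic_hz ordered vector of 5 harmonic peak frequencies (Hz), H2-H6.
#' @param f1_range_hz closed interval (Hz) of the first formant.
#' @param total_duration_ms stimulus duration (ms).
#' @param consonant_window_ms response-time window (ms) of the consonant region.
#' @param vowel_window_ms response-time window (ms) of the vowel region.
#' @param sampling_rate_hz sampling rate (Hz).
#' @param extraction_bandwidth_hz total width (Hz) of the spectral peak search
#'   window (a 20 Hz bandwidth around a peak at 118 Hz searches 108-128 Hz).
#' @param f1_margin_hz tolerance (Hz) added to each side of `f1_range_hz` when
#'   classifying harmonics as formant vs non-formant.
#' @param neural_delay_allowance_ms latency allowance (ms) between stimulus and
#'   response time; region windows may extend this far past stimulus offset.
#' @return An object of class `ffr_stimulus_spec` (a validated list).
#' @examples
#' spec <- stimulus_spec()
#' spec$harmonic_hz
#' @export
stimulus_spec <- function(f0_hz = 129,
                          harmonic_hz = c(261, 393, 531, 665, 787),
                          f1_range_hz = c(400, 700),
                          total_duration_ms = 209,
                          consonant_window_ms = c(20, 67),
                          vowel_window_ms = c(67, 220),
                          sampling_rate_hz = 30000,
                          extraction_bandwidth_hz = 20,
                          f1_margin_hz = 20,
                          neural_delay_allowance_ms = 10) {
  if (!is_number(f0_hz) || f0_hz <= 0) stopf("f0_hz must be a positive number")
  if (!is.numeric(harmonic_hz) || length(harmonic_hz) != 5L)
    stopf("harmonic_hz must hold the 5 harmonic frequencies H2-H6")
  if (any(diff(harmonic_hz) <= 0)) stopf("harmonic_hz must be strictly increasing")
  if (any(harmonic_hz <= f0_hz)) stopf("all harmonics must lie above f0_hz")
  check_interval(f1_range_hz, "f1_range_hz")
  if (!is_number(total_duration_ms) || total_duration_ms <= 0)
    stopf("total_duration_ms must be positive")
  check_interval(consonant_window_ms, "consonant_window_ms")
  check_interval(vowel_window_ms, "vowel_window_ms")
  if (consonant_window_ms[2] > vowel_window_ms[1] &&
      vowel_window_ms[2] > consonant_window_ms[1] &&
      !(consonant_window_ms[2] <= vowel_window_ms[1] ||
        vowel_window_ms[2] <= consonant_window_ms[1]))
    stopf("consonant and vowel windows may share only a boundary")
  # 1 ms grace: the canonical vowel window (67-220 ms) overruns stimulus
  # offset + neural delay (209 + 10 ms) by a single millisecond.
  hi <- total_duration_ms + neural_delay_allowance_ms + 1 + 1e-9
  if (consonant_window_ms[1] < 0 || vowel_window_ms[2] > hi)
    stopf("region windows must lie within [0, total_duration_ms + neural delay allowance]")
  if (!is_number(sampling_rate_hz) || sampling_rate_hz <= 0)
    stopf("sampling_rate_hz must be positive")
  if (!is_number(extraction_bandwidth_hz) || extraction_bandwidth_hz <= 0)
    stopf("extraction_bandwidth_hz must be positive")
  if (!is_number(f1_margin_hz) || f1_margin_hz < 0)
    stopf("f1_margin_hz must be >= 0")
  structure(list(
    f0_hz = f0_hz,
    harmonic_hz = as.numeric(harmonic_hz),
    f1_range_hz = as.numeric(f1_range_hz),
    total_duration_ms = total_duration_ms,
    consonant_window_ms = as.numeric(consonant_window_ms),
    vowel_window_ms = as.numeric(vowel_window_ms),
    sampling_rate_hz = sampling_rate_hz,
    extraction_bandwidth_hz = extraction_bandwidth_hz,
    f1_margin_hz = f1_margin_hz,
    neural_delay_allowance_ms = neural_delay_allowance_ms
  ), class = "ffr_stimulus_spec")
}

#' @export
print.ffr_stimulus_spec <- function(x, ...) {
  cat("FFR stimulus spec\n")
  cat(sprintf("  F0: %g Hz; H2-H6: %s Hz\n", x$f0_hz,
              paste(x$harmonic_hz, collapse = ", ")))
  cat(sprintf("  F1 range: %g-%g Hz (margin %g Hz)\n",
              x$f1_range_hz[1], x$f1_range_hz[2], x$f1_margin_hz))
  cat(sprintf("  duration: %g ms at %g Hz; regions: consonant %g-%g ms, vowel %g-%g ms\n",
              x$total_duration_ms, x$sampling_rate_hz,
              x$consonant_window_ms[1], x$consonant_window_ms[2],
              x$vowel_window_ms[1], x$vowel_window_ms[2]))
  invisible(x)
}

# Names of the spectral bands, in fixed order used throughout the package.
ffr_bands <- function() c("f0", "h2", "h3", "h4", "h5", "h6")

band_frequencies <- function(spec) {
  stats::setNames(c(spec$f0_hz, spec$harmonic_hz), ffr_bands())
}

# raised-cosine on/off ramp, length nr samples each side
apply_ramp <- function(x, nr) {
  n <- length(x)
  if (nr < 1 || 2 * nr >= n) return(x)
  r <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
  x[seq_len(nr)] <- x[seq_len(nr)] * r
  x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(r)
  x
}

#' Synthesize a speech-like harmonic stimulus
#'
#' Builds a synthetic surrogate of a consonant-vowel syllable as a harmonic
#' complex: sinusoidal partials at `f0_hz` and the configured harmonic
#' frequencies. The consonant segment has reduced harmonic amplitude plus
#' added broadband noise (fricative-like); the vowel segment boosts partials
#' that fall inside the first-formant range. The waveform is peak-normalized
#' to 1. This is a surrogate sharing only the frequency/time plan of a natural
#' recording, not its waveform.
#'
#' @param spec a [stimulus_spec()].
#' @param gains named numeric vector of linear gains for bands
#'   `f0, h2, ..., h6` (default all 1).
#' @param consonant_end_ms boundary (ms, stimulus time) between the
#'   consonant-like and vowel-like segments. Defaults to the end of the
#'   consonant response window minus the neural delay allowance.
#' @param consonant_harmonic_scale harmonic gain multiplier in the consonant
#'   segment.
#' @param consonant_noise_sd standard deviation of the broadband noise added to
#'   the consonant segment (relative to unit partial amplitude).
#' @param f1_boost multiplier applied, in the vowel segment, to partials inside
#'   `f1_range_hz`.
#' @param noise_seed seed for the fricative noise (fixed default keeps the
#'   waveform deterministic).
#' @return An object of class `ffr_stimulus`: list with `samples` (normalized
#'   amplitude), `sampling_rate_hz`, and the `spec`.
#' @examples
#' stim <- synthesize_stimulus(stimulus_spec())
#' length(stim$samples) # 0.209 s * 30000 Hz = 6270
#' @export
synthesize_stimulus <- function(spec,
                                gains = NULL,
                                consonant_end_ms = NULL,
                                consonant_harmonic_scale = 0.35,
                                consonant_noise_sd = 0.3,
                                f1_boost = 2,
                                noise_seed = 1L) {
  stopifnot(inherits(spec, "ffr_stimulus_spec"))
  fs <- spec$sampling_rate_hz
  freqs <- band_frequencies(spec)
  if (any(freqs >= fs / 2))
    stopf("partial at %g Hz is at/above the Nyquist frequency (%g Hz)",
          max(freqs), fs / 2)
  if (is.null(gains)) gains <- stats::setNames(rep(1, 6), ffr_bands())
  if (is.null(names(gains))) names(gains) <- ffr_bands()
  gains <- gains[ffr_bands()]
  if (any(is.na(gains)) || any(!is.finite(gains)) || any(gains < 0))
    stopf("gains must be finite, non-negative, named by band (f0, h2..h6)")
  if (is.null(consonant_end_ms))
    consonant_end_ms <- spec$consonant_window_ms[2] - spec$neural_delay_allowance_ms

  n <- round(spec$total_duration_ms * fs / 1000)
  t <- (seq_len(n) - 1) / fs
  cons <- t < consonant_end_ms / 1000
  in_f1 <- freqs >= spec$f1_range_hz[1] & freqs <= spec$f1_range_hz[2]

  x <- numeric(n)
  for (b in ffr_bands()) {
    g <- rep(gains[[b]], n)
    if (b != "f0") {
      g[cons] <- g[cons] * consonant_harmonic_scale
      if (in_f1[[b]]) g[!cons] <- g[!cons] * f1_boost
    }
    x <- x + g * sin(2 * pi * freqs[[b]] * t)
  }
  if (any(cons) && consonant_noise_sd > 0 && any(gains > 0)) {
    noise <- with_seed(noise_seed, stats::rnorm(sum(cons), 0, consonant_noise_sd))
    x[cons] <- x[cons] + noise * mean(gains)
  }
  x <- apply_ramp(x, round(0.005 * fs))
  pk <- max(abs(x))
  if (pk > 0) x <- x / pk
  structure(list(samples = x, sampling_rate_hz = fs, spec = spec),
            class = "ffr_stimulus")
}

#' @export
print.ffr_stimulus <- function(x, ...) {
  cat(sprintf("FFR stimulus: %d samples at %g Hz (%.1f ms), peak %g\n",
              length(x$samples), x$sampling_rate_hz,
              1000 * length(x$samples) / x$sampling_rate_hz,
              max(abs(x$samples))))
  invisible(x)
}

#' Write a mono waveform as a WAV file
#'
#' Minimal RIFF/WAVE writer (mono, 32-bit IEEE float or 16-bit PCM).
#'
#' @param samples numeric vector, expected within `[-1, 1]`.
#' @param sampling_rate_hz sampling rate (Hz).
#' @param path output file path.
#' @param format `"float32"` or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sampling_rate_hz, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  fs <- as.integer(round(sampling_rate_hz))
  n <- length(samples)
  bits <- if (format == "float32") 32L else 16L
  bytes <- bits / 8L
  data_size <- n * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (format == "float32") 3L else 1L, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")             # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes), con, size = 4, endian = "little")
  writeBin(as.integer(bytes), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(pmax(-1, pmin(1, samples)) * 32767)),
             con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file written by [write_wav()]
#'
#' @param path WAV file path.
#' @return list with `samples` and `sampling_rate_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stopf("%s is not a RIFF/WAVE file", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stopf("%s is not a RIFF/WAVE file", path)
  fmt <- NULL; fs <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stopf("no data chunk found in %s", path)
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), size = 2, endian = "little")
      nch <- readBin(con, integer(), size = 2, endian = "little")
      if (nch != 1L) stopf("only mono WAV supported")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16) readBin(con, raw(), n = sz - 16)
    } else if (id == "data") {
      n <- sz / (bits / 8)
      samples <- if (fmt == 3L) {
        readBin(con, numeric(), n = n, size = 4, endian = "little")
      } else {
        readBin(con, integer(), n = n, size = 2, endian = "little") / 32767
      }
      return(list(samples = samples, sampling_rate_hz = fs))
    } else {
      readBin(con, raw(), n = sz)
    }
  }
}
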