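# Pipeline configuration: a flat key-value text format (TOML-style scalars
# and comma-separated numeric lists), with units embedded in key names.

#' Default pipeline configuration
#'
#' All analysis defaults are the canonical protocol values: 70-2000 Hz
#' Butterworth bandpass (12 dB/octave), +/- 30 microvolt artifact rejection,
#' -30..0 ms baseline, -30..230 ms epoch, consonant 20-67 ms and vowel
#' 67-220 ms regions, 20 Hz extraction bandwidth, formant range 400-700 Hz
#' with a 20 Hz margin, and the full cohort (14/18/10 subjects, 3000 sweeps
#' per polarity at 30 kHz).
#'
#' @return named list of class `ffr_config`.
#' @export
default_pipeline_config <- function() {
  structure(list(
    # stimulus plan
    f0_hz = 129,
    harmonic_hz = c(261, 393, 531, 665, 787),
    f1_range_hz = c(400, 700),
    total_duration_ms = 209,
    consonant_window_ms = c(20, 67),
    vowel_window_ms = c(67, 220),
    sampling_rate_hz = 30000,
    extraction_bandwidth_hz = 20,
    f1_margin_hz = 20,
    neural_delay_ms = 10,
    # preprocessing
    filter_low_hz = 70,
    filter_high_hz = 2000,
    rejection_threshold_uv = 30,
    baseline_window_ms = c(-30, 0),
    epoch_window_ms = c(-30, 230),
    spectral_resolution_hz = 1,
    # cohort simulation
    group_names = c("native", "nonnative_nonmus", "nonnative_mus"),
    group_sizes = c(14, 18, 10),
    sweeps_per_polarity = 3000,
    noise_sd_uv = 1,
    artifact_rate = 0.02,
    envelope_gain = 0.25,
    base_gains = c(0.30, 0.15, 0.12, 0.12, 0.10, 0.08),
    gain_cv = 0.2,
    gain_shared_var = 0.5,
    f1_effect_native = 0.9,
    f1_effect_nonnative_nonmus = 0,
    f1_effect_nonnative_mus = 0.9,
    master_seed = 1234
  ), class = "ffr_config")
}

#' A reduced cohort configuration for quick runs and tests
#'
#' Same analysis parameters as [default_pipeline_config()] but a small cohort
#' (`subjects_per_group` per group, fewer sweeps) so the full pipeline runs in
#' seconds.
#'
#' @param subjects_per_group subjects in each of the three groups.
#' @param sweeps_per_polarity sweeps per stimulus polarity.
#' @param sampling_rate_hz sampling rate (Hz).
#' @return named list of class `ffr_config`.
#' @export
small_pipeline_config <- function(subjects_per_group = 4,
                                  sweeps_per_polarity = 500,
                                  sampling_rate_hz = 30000) {
  cfg <- default_pipeline_config()
  cfg$group_sizes <- rep(subjects_per_group, 3)
  cfg$sweeps_per_polarity <- sweeps_per_polarity
  cfg$sampling_rate_hz <- sampling_rate_hz
  cfg
}

config_checks <- list(
  f0_hz = function(v) v > 0,
  sampling_rate_hz = function(v) v > 0,
  extraction_bandwidth_hz = function(v) v > 0,
  f1_margin_hz = function(v) v >= 0,
  filter_low_hz = function(v) v > 0,
  filter_high_hz = function(v) v > 0,
  rejection_threshold_uv = function(v) v > 0,
  sweeps_per_polarity = function(v) v >= 1,
  noise_sd_uv = function(v) v > 0,
  artifact_rate = function(v) v >= 0 && v <= 1,
  envelope_gain = function(v) v >= 0,
  gain_cv = function(v) v >= 0,
  gain_shared_var = function(v) v >= 0 && v <= 1,
  neural_delay_ms = function(v) v >= 0,
  spectral_resolution_hz = function(v) v > 0,
  group_sizes = function(v) all(v >= 1),
  base_gains = function(v) all(v >= 0)
)

#' Validate a pipeline configuration
#'
#' Checks every key against its valid range and cross-field consistency;
#' errors name the offending key.
#'
#' @param cfg an `ffr_config` list.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  ref <- default_pipeline_config()
  miss <- setdiff(names(ref), names(cfg))
  if (length(miss))
    stopf("config is missing key(s): %s", paste(miss, collapse = ", "))
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  for (k in names(config_checks)) {
    v <- cfg[[k]]
    if (!is.numeric(v) || any(!is.finite(v)) || !config_checks[[k]](v))
      stopf("config key '%s' has an invalid value (%s)",
            k, paste(format(v), collapse = ", "))
  }
  for (k in c("f1_range_hz", "consonant_window_ms", "vowel_window_ms",
              "baseline_window_ms", "epoch_window_ms"))
    tryCatch(check_interval(cfg[[k]], k),
             error = function(e) stopf("config key '%s': %s", k, conditionMessage(e)))
  if (cfg$filter_low_hz >= cfg$filter_high_hz)
    stopf("config key 'filter_low_hz' must be below 'filter_high_hz'")
  if (cfg$filter_high_hz >= cfg$sampling_rate_hz / 2)
    stopf("config key 'filter_high_hz' is at/above Nyquist")
  if (length(cfg$group_sizes) != length(cfg$group_names))
    stopf("config key 'group_sizes' must match 'group_names' in length")
  if (length(cfg$harmonic_hz) != 5)
    stopf("config key 'harmonic_hz' must list the 5 harmonics H2-H6")
  if (length(cfg$base_gains) != 6)
    stopf("config key 'base_gains' must list 6 gains (f0, h2..h6)")
  invisible(cfg)
}

#' Write a configuration to a flat key-value text file
#' @param cfg an `ffr_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  fmt <- function(v) {
    if (is.character(v)) paste(v, collapse = ", ")
    else paste(sub("\\.?0+$", "", sprintf("%.10f", v)), collapse = ", ")
  }
  lines <- c("# ffrpipe pipeline configuration",
             vapply(names(cfg), function(k) sprintf("%s = %s", k, fmt(cfg[[k]])),
                    character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a configuration from a flat key-value text file
#'
#' Lines look like `key = value` or `key = v1, v2, v3`; `#` starts a comment.
#' Keys absent from the file keep their default values.
#'
#' @param path file path.
#' @return validated `ffr_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- default_pipeline_config()
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stopf("malformed config line: '%s'", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(cfg)) stopf("unknown config key '%s'", key)
    parts <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    cfg[[key]] <- if (is.character(cfg[[key]])) parts else {
      if (any(is.na(num))) stopf("config key '%s' must be numeric", key)
      num
    }
  }
  validate_config(cfg)
  cfg
}

#' Apply `key=value` overrides to a configuration
#' @param cfg an `ffr_config`.
#' @param sets character vector of `key=value` strings (comma-separated lists
#'   allowed).
#' @return updated, validated `ffr_config`.
#' @export
apply_config_overrides <- function(cfg, sets) {
  for (s in sets) {
    if (!grepl("=", s, fixed = TRUE)) stopf("override must look like key=value: '%s'", s)
    key <- trimws(sub("=.*$", "", s))
    val <- trimws(sub("^[^=]*=", "", s))
    if (!key %in% names(cfg)) stopf("unknown config key '%s'", key)
    parts <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    cfg[[key]] <- if (is.character(cfg[[key]])) parts else {
      if (any(is.na(num))) stopf("config key '%s' must be numeric", key)
      num
    }
  }
  validate_config(cfg)
  cfg
}

# Derived objects from a config
config_spec <- function(cfg) {
  stimulus_spec(
    f0_hz = cfg$f0_hz, harmonic_hz = cfg$harmonic_hz,
    f1_range_hz = cfg$f1_range_hz, total_duration_ms = cfg$total_duration_ms,
    consonant_window_ms = cfg$consonant_window_ms,
    vowel_window_ms = cfg$vowel_window_ms,
    sampling_rate_hz = cfg$sampling_rate_hz,
    extraction_bandwidth_hz = cfg$extraction_bandwidth_hz,
    f1_margin_hz = cfg$f1_margin_hz,
    neural_delay_allowance_ms = cfg$neural_delay_ms
  )
}

config_cohort <- function(cfg) {
  sizes <- stats::setNames(as.integer(cfg$group_sizes), cfg$group_names)
  plan_rows <- list()
  for (g in cfg$group_names) {
    key <- paste0("f1_effect_", g)
    off <- if (key %in% names(cfg)) cfg[[key]] else 0
    if (is.numeric(off) && length(off) == 1 && off != 0)
      plan_rows[[g]] <- data.frame(group = g, band = c("h3", "h4", "h5"),
                                   offset = off, stringsAsFactors = FALSE)
  }
  plan <- if (length(plan_rows)) do.call(rbind, plan_rows) else
    data.frame(group = character(), band = character(), offset = numeric())
  cohort_config(
    group_sizes = sizes,
    sweeps_per_polarity = cfg$sweeps_per_polarity,
    effect_plan = plan,
    base_gains = stats::setNames(cfg$base_gains, ffr_bands()),
    gain_cv = cfg$gain_cv, gain_shared_var = cfg$gain_shared_var,
    envelope_gain = cfg$envelope_gain, noise_sd_uv = cfg$noise_sd_uv,
    artifact_rate = cfg$artifact_rate, neural_delay_ms = cfg$neural_delay_ms,
    master_seed = cfg$master_seed
  )
}
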