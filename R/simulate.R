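#' Per-subject simulation parameters
#'
#' Describes one simulated subject: linear gains (microvolts) of the
#' temporal-fine-structure component in each spectral band, the gain of the
#' non-inverting envelope-following component, single-sweep noise level,
#' artifact probability, neural response delay, and the subject's RNG seed.
#'
#' @param group_label group membership label.
#' @param component_gains named numeric vector of band gains in microvolts
#'   (`f0, h2, ..., h6`).
#' @param envelope_gain gain (microvolts) of the envelope-following component
#'   at F0 (does not invert with stimulus polarity).
#' @param noise_sd_uv single-sweep Gaussian noise standard deviation
#'   (microvolts); must be positive.
#' @param artifact_rate per-sweep probability of an added large deflection
#'   exceeding +/- 30 microvolts.
#' @param neural_delay_ms latency (ms) of the response relative to stimulus
#'   onset.
#' @param seed integer RNG seed for this subject.
#' @param subject_id optional identifier.
#' @return An object of class `ffr_subject_params`.
#' @export
subject_params <- function(group_label = "A",
                           component_gains = c(f0 = 0.30, h2 = 0.15, h3 = 0.12,
                                               h4 = 0.12, h5 = 0.10, h6 = 0.08),
                           envelope_gain = 0.25,
                           noise_sd_uv = 1,
                           artifact_rate = 0.02,
                           neural_delay_ms = 10,
                           seed = 1L,
                           subject_id = NA_character_) {
  if (is.null(names(component_gains))) names(component_gains) <- ffr_bands()
  component_gains <- component_gains[ffr_bands()]
  if (any(is.na(component_gains)) || any(!is.finite(component_gains)))
    stopf("component_gains must be finite and named by band (f0, h2..h6)")
  if (any(component_gains < 0)) stopf("component_gains must be >= 0")
  if (!is_number(envelope_gain) || envelope_gain < 0)
    stopf("envelope_gain must be a finite number >= 0")
  if (!is_number(noise_sd_uv) || noise_sd_uv <= 0)
    stopf("noise_sd_uv must be > 0")
  if (!is_number(artifact_rate) || artifact_rate < 0 || artifact_rate > 1)
    stopf("artifact_rate must be in [0, 1]")
  if (!is_number(neural_delay_ms) || neural_delay_ms < 0)
    stopf("neural_delay_ms must be >= 0")
  structure(list(
    group_label = group_label, component_gains = component_gains,
    envelope_gain = envelope_gain, noise_sd_uv = noise_sd_uv,
    artifact_rate = artifact_rate, neural_delay_ms = neural_delay_ms,
    seed = as.integer(seed), subject_id = subject_id
  ), class = "ffr_subject_params")
}

# Deterministic signal components of one subject's response on the epoch time
# base. The fine-structure component inverts with stimulus polarity; the
# envelope component does not. Harmonic (but not F0) fine structure is
# attenuated during the consonant segment, mirroring the stimulus synthesis.
# Returned as a list(fine, envelope) of vectors in microvolts.
ffr_signal_components <- function(params, spec,
                                  epoch_window_ms = c(-30, 230),
                                  consonant_harmonic_scale = 0.5) {
  fs <- spec$sampling_rate_hz
  n <- round((epoch_window_ms[2] - epoch_window_ms[1]) * fs / 1000)
  t_ms <- epoch_window_ms[1] + (seq_len(n) - 1) * 1000 / fs
  d <- params$neural_delay_ms
  on_ms <- d
  off_ms <- d + spec$total_duration_ms
  if (on_ms < epoch_window_ms[1] || off_ms > epoch_window_ms[2])
    stopf("epoch window %g..%g ms does not cover stimulus + neural delay (%g..%g ms)",
          epoch_window_ms[1], epoch_window_ms[2], on_ms, off_ms)
  active <- t_ms >= on_ms & t_ms < off_ms
  # support mask with 5 ms raised-cosine onset/offset inside the active span
  mask <- numeric(n)
  mask[active] <- apply_ramp(rep(1, sum(active)), round(0.005 * fs))
  cons_end <- d + (spec$consonant_window_ms[2] - spec$neural_delay_allowance_ms)
  freqs <- band_frequencies(spec)
  g <- params$component_gains
  ts <- (t_ms - d) / 1000
  fine <- numeric(n)
  for (b in ffr_bands()) {
    scale <- rep(1, n)
    if (b != "f0") scale[t_ms < cons_end] <- consonant_harmonic_scale
    fine <- fine + g[[b]] * scale * sin(2 * pi * freqs[[b]] * ts) * mask
  }
  envelope <- params$envelope_gain * cos(2 * pi * spec$f0_hz * ts) * mask
  list(fine = fine, envelope = envelope, t_ms = t_ms)
}

#' Simulate one subject's multi-sweep FFR recording
#'
#' Each sweep is the sum of (a) a temporal-fine-structure component that
#' inverts sign when the stimulus polarity inverts, (b) an envelope-following
#' component at F0 that does not invert, (c) white Gaussian noise, and (d),
#' with probability `artifact_rate`, a square-pulse deflection of 50-100
#' microvolts. Polarity labels alternate sweep-to-sweep (A, B, A, B, ...).
#' Fully reproducible from `params$seed`.
#'
#' @param stimulus an `ffr_stimulus` consistent with `spec` (used to validate
#'   the timing contract; the neural components are built from the spec's
#'   frequency plan).
#' @param params a [subject_params()].
#' @param spec a [stimulus_spec()].
#' @param n_sweeps_per_polarity sweeps per stimulus polarity.
#' @param epoch_window_ms epoch interval (ms); must cover stimulus + delay.
#' @return An `ffr_sweepset`.
#' @export
simulate_subject_sweeps <- function(stimulus, params, spec,
                                    n_sweeps_per_polarity = 3000,
                                    epoch_window_ms = c(-30, 230)) {
  stopifnot(inherits(params, "ffr_subject_params"),
            inherits(spec, "ffr_stimulus_spec"))
  if (!is.null(stimulus)) {
    stopifnot(inherits(stimulus, "ffr_stimulus"))
    if (stimulus$sampling_rate_hz != spec$sampling_rate_hz)
      stopf("stimulus sampling rate (%g) does not match spec (%g)",
            stimulus$sampling_rate_hz, spec$sampling_rate_hz)
    n_stim <- round(spec$total_duration_ms * spec$sampling_rate_hz / 1000)
    if (abs(length(stimulus$samples) - n_stim) > 1)
      stopf("stimulus length inconsistent with spec duration")
  }
  fs <- spec$sampling_rate_hz
  comp <- ffr_signal_components(params, spec, epoch_window_ms)
  n_samp <- length(comp$fine)
  n_tot <- 2L * n_sweeps_per_polarity
  polarity <- rep(c("A", "B"), n_sweeps_per_polarity)
  sign_vec <- ifelse(polarity == "A", 1, -1)

  sweeps <- with_seed(params$seed, {
    m <- outer(sign_vec, comp$fine) +
      matrix(comp$envelope, n_tot, n_samp, byrow = TRUE) +
      matrix(stats::rnorm(n_tot * n_samp, 0, params$noise_sd_uv), n_tot, n_samp)
    if (params$artifact_rate > 0) {
      hit <- which(stats::runif(n_tot) < params$artifact_rate)
      w <- max(2L, round(0.010 * fs)) # 10 ms square pulse
      for (i in hit) {
        amp <- stats::runif(1, 50, 100) * sample(c(-1, 1), 1)
        start <- sample.int(n_samp - w + 1L, 1)
        m[i, start:(start + w - 1L)] <- m[i, start:(start + w - 1L)] + amp
      }
    }
    m
  })
  sweep_set(sweeps, polarity, fs, epoch_window_ms,
            subject_id = params$subject_id, group = params$group_label)
}

#' Cohort configuration for the synthetic-data generator
#'
#' Describes a simulated study cohort: group sizes, sweeps per polarity,
#' the per-(group, band) standardized gain offsets (the effect plan), and the
#' between-subject variability model. Defaults mirror a three-group study of
#' 14 native nonmusicians, 18 non-native nonmusicians and 10 non-native
#' musicians, 3000 sweeps per polarity at 30 kHz, with the first-formant
#' harmonic bands (H3-H5) elevated by 0.9 between-subject standard deviations
#' in the native and non-native-musician groups.
#'
#' Subject-to-subject gain variability: each subject draws a scalar deviate
#' `z_sb = sqrt(w) u_s + sqrt(1 - w) v_sb` per band, where `u_s` is shared
#' across bands (overall response strength), `v_sb` is band-specific, and
#' `w = gain_shared_var`. Band gains are
#' `base_gain_b * max(0, 1 + gain_cv * (z_sb + offset_gb))`, so an effect-plan
#' offset is a standardized (per-band, between-subject SD units) mean shift.
#'
#' @param group_sizes named integer vector of subjects per group.
#' @param sweeps_per_polarity sweeps per stimulus polarity per subject.
#' @param effect_plan data frame with columns `group`, `band`, `offset`
#'   (standardized gain offsets); an empty data frame means a null cohort.
#' @param base_gains named vector of population mean band gains (microvolts).
#' @param gain_cv between-subject coefficient of variation of band gains.
#' @param gain_shared_var fraction of between-subject gain variance shared
#'   across bands (0 = independent bands, 1 = perfectly correlated).
#' @param envelope_gain,noise_sd_uv,artifact_rate,neural_delay_ms passed to
#'   [subject_params()].
#' @param master_seed integer; subject seeds are derived deterministically
#'   from it.
#' @return An object of class `ffr_cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(native = 14, nonnative_nonmus = 18,
                                          nonnative_mus = 10),
                          sweeps_per_polarity = 3000,
                          effect_plan = default_effect_plan(),
                          base_gains = c(f0 = 0.30, h2 = 0.15, h3 = 0.12,
                                         h4 = 0.12, h5 = 0.10, h6 = 0.08),
                          gain_cv = 0.2,
                          gain_shared_var = 0.5,
                          envelope_gain = 0.25,
                          noise_sd_uv = 1,
                          artifact_rate = 0.02,
                          neural_delay_ms = 10,
                          master_seed = 1234L) {
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes))))
    stopf("group_sizes must be a named vector")
  if (any(group_sizes < 1)) stopf("group sizes must be positive")
  effect_plan <- as.data.frame(effect_plan)
  if (nrow(effect_plan) > 0) {
    need <- c("group", "band", "offset")
    if (!all(need %in% names(effect_plan)))
      stopf("effect_plan needs columns group, band, offset")
    bad <- setdiff(unique(effect_plan$group), names(group_sizes))
    if (length(bad))
      stopf("effect_plan references unknown group(s): %s",
            paste(bad, collapse = ", "))
    badb <- setdiff(unique(effect_plan$band), ffr_bands())
    if (length(badb))
      stopf("effect_plan references unknown band(s): %s",
            paste(badb, collapse = ", "))
  }
  if (is.null(names(base_gains))) names(base_gains) <- ffr_bands()
  base_gains <- base_gains[ffr_bands()]
  if (any(is.na(base_gains)) || any(base_gains < 0))
    stopf("base_gains must be non-negative and named by band")
  if (!is_number(gain_cv) || gain_cv < 0) stopf("gain_cv must be >= 0")
  if (!is_number(gain_shared_var) || gain_shared_var < 0 || gain_shared_var > 1)
    stopf("gain_shared_var must be in [0, 1]")
  structure(list(
    group_sizes = group_sizes, sweeps_per_polarity = sweeps_per_polarity,
    effect_plan = effect_plan, base_gains = base_gains,
    gain_cv = gain_cv, gain_shared_var = gain_shared_var,
    envelope_gain = envelope_gain, noise_sd_uv = noise_sd_uv,
    artifact_rate = artifact_rate, neural_delay_ms = neural_delay_ms,
    master_seed = as.integer(master_seed)
  ), class = "ffr_cohort_config")
}

#' Default effect plan: formant-band gains elevated in two groups
#'
#' Standardized (between-subject SD units) offsets of +0.9 on the harmonics
#' inside the first-formant range (H3-H5) for the `native` and
#' `nonnative_mus` groups, relative to `nonnative_nonmus`.
#'
#' @param offset standardized gain offset applied to the F1 bands.
#' @param groups groups receiving the offset.
#' @param bands bands receiving the offset.
#' @return data frame with columns `group`, `band`, `offset`.
#' @export
default_effect_plan <- function(offset = 0.9,
                                groups = c("native", "nonnative_mus"),
                                bands = c("h3", "h4", "h5")) {
  plan <- expand.grid(group = groups, band = bands, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  plan$offset <- offset
  plan
}

#' Tabulate per-subject simulation parameters for a cohort
#'
#' Draws the subject-level random gain structure (deterministically from
#' `master_seed`) and returns one row per subject without simulating sweeps.
#' Columns: `subject_id`, `group`, `seed`, `u` (shared deviate), one gain
#' column per band, and `envelope_gain`.
#'
#' @param config an [cohort_config()].
#' @return data frame, one row per subject.
#' @export
cohort_subject_table <- function(config) {
  stopifnot(inherits(config, "ffr_cohort_config"))
  groups <- rep(names(config$group_sizes), config$group_sizes)
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  bands <- ffr_bands()
  offs <- matrix(0, n, length(bands), dimnames = list(NULL, bands))
  if (nrow(config$effect_plan) > 0) {
    for (r in seq_len(nrow(config$effect_plan))) {
      sel <- groups == config$effect_plan$group[r]
      offs[sel, config$effect_plan$band[r]] <-
        offs[sel, config$effect_plan$band[r]] + config$effect_plan$offset[r]
    }
  }
  w <- config$gain_shared_var
  draws <- with_seed(config$master_seed, {
    u <- stats::rnorm(n)
    v <- matrix(stats::rnorm(n * length(bands)), n, length(bands))
    list(u = u, v = v)
  })
  z <- sqrt(w) * draws$u + sqrt(1 - w) * draws$v
  gains <- sapply(seq_along(bands), function(j) {
    config$base_gains[[j]] * pmax(0, 1 + config$gain_cv * (z[, j] + offs[, j]))
  })
  colnames(gains) <- bands
  env <- config$envelope_gain * pmax(0, 1 + config$gain_cv * draws$u)
  out <- data.frame(subject_id = ids, group = groups,
                    seed = vapply(seq_len(n), function(i)
                      derive_subject_seed(config$master_seed, i), integer(1)),
                    u = draws$u, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(gains), envelope_gain = env)
}

subject_params_from_row <- function(row, config) {
  subject_params(
    group_label = row$group,
    component_gains = unlist(row[ffr_bands()]),
    envelope_gain = row$envelope_gain,
    noise_sd_uv = config$noise_sd_uv,
    artifact_rate = config$artifact_rate,
    neural_delay_ms = config$neural_delay_ms,
    seed = row$seed,
    subject_id = row$subject_id
  )
}

#' Simulate a full cohort of FFR recordings
#'
#' One [simulate_subject_sweeps()] call per subject, with group-level gains
#' following the cohort's effect plan. Byte-identical under rerun with the
#' same `master_seed`. If `out_dir` is given, each subject's sweeps are
#' written to `<out_dir>/sweeps_<id>.txt` and dropped from memory, and the
#' returned manifest gains a `file` column.
#'
#' @param config a [cohort_config()].
#' @param spec a [stimulus_spec()].
#' @param stimulus optional `ffr_stimulus` (synthesized from `spec` if NULL).
#' @param out_dir optional directory for per-subject sweep files.
#' @param epoch_window_ms epoch interval (ms).
#' @return list with `manifest` (data frame: subject_id, group, seed[, file])
#'   and, when `out_dir` is NULL, `sweepsets` (named list of `ffr_sweepset`).
#' @export
simulate_cohort <- function(config, spec, stimulus = NULL, out_dir = NULL,
                            epoch_window_ms = c(-30, 230)) {
  stopifnot(inherits(config, "ffr_cohort_config"),
            inherits(spec, "ffr_stimulus_spec"))
  if (is.null(stimulus)) stimulus <- synthesize_stimulus(spec)
  tab <- cohort_subject_table(config)
  keep <- is.null(out_dir)
  if (!keep && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sweepsets <- if (keep) vector("list", nrow(tab))
  files <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    params <- subject_params_from_row(tab[i, ], config)
    ss <- simulate_subject_sweeps(stimulus, params, spec,
                                  n_sweeps_per_polarity = config$sweeps_per_polarity,
                                  epoch_window_ms = epoch_window_ms)
    if (keep) {
      sweepsets[[i]] <- ss
    } else {
      files[i] <- file.path(out_dir, paste0("sweeps_", tab$subject_id[i], ".txt"))
      write_sweepset(ss, files[i])
    }
  }
  manifest <- tab[, c("subject_id", "group", "seed")]
  if (!keep) manifest$file <- files
  if (keep) names(sweepsets) <- tab$subject_id
  out <- list(manifest = manifest)
  if (keep) out$sweepsets <- sweepsets
  out
}
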