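# Shared fixtures. Tests that do not need the full 30 kHz rate use 8 kHz to
# keep the suite fast; spectral identities are rate-independent.

fast_spec <- function(fs = 8000) stimulus_spec(sampling_rate_hz = fs)

# tiny deterministic sweep set: pure fine-structure subject, low noise
quiet_params <- function(seed = 1, noise = 1e-9, env = 0, rate = 0,
                         gains = c(f0 = 0.30, h2 = 0.15, h3 = 0.12,
                                   h4 = 0.12, h5 = 0.10, h6 = 0.08)) {
  subject_params(component_gains = gains, envelope_gain = env,
                 noise_sd_uv = noise, artifact_rate = rate, seed = seed)
}

# raw sweep_set from an explicit matrix on a simple time base starting at t ms
raw_sweepset <- function(mat, polarity = NULL, fs = 1000, t0 = -30) {
  n <- ncol(mat)
  if (is.null(polarity)) polarity <- rep(c("A", "B"), length.out = nrow(mat))
  sweep_set(mat, polarity, fs, c(t0, t0 + n * 1000 / fs))
}

# spectrum object with arbitrary bins (for extraction tests)
make_spectrum <- function(freqs, amp, label = "whole") {
  structure(list(freqs_hz = freqs, amplitude = amp, region_label = label,
                 resolution_hz = diff(freqs[1:2]), n_samples = length(freqs)),
            class = "ffr_spectrum")
}

# small cohort config used by workflow tests
tiny_config <- function(fs = 8000, spg = 2, sweeps = 30, seed = 42) {
  cfg <- small_pipeline_config(subjects_per_group = spg,
                               sweeps_per_polarity = sweeps,
                               sampling_rate_hz = fs)
  cfg$master_seed <- seed
  cfg
}

# calibration configuration (see the methods vignette: runtime-scaled sweep
# counts; the statistical contract under test is rate-invariant)
calibration_config <- function(sweeps, effect = 0) {
  cfg <- small_pipeline_config(sampling_rate_hz = 8000,
                               sweeps_per_polarity = sweeps)
  cfg$group_sizes <- c(14, 18, 10)
  cfg$artifact_rate <- 0
  cfg$f1_effect_native <- effect
  cfg$f1_effect_nonnative_mus <- effect
  cfg$f1_effect_nonnative_nonmus <- 0
  cfg
}

# one replicate of the vowel formant-band group test: real pipeline
# operations (simulate -> filter/reject/baseline/average -> vowel spectrum ->
# F1-band peak extraction) then the one-way group ANOVA p-value. The
# stimulus synthesis and peak anchoring are deterministic given cfg, so the
# caller hoists them out of the replicate loop via make_calibration_world().
make_calibration_world <- function(cfg) {
  spec <- ffrpipe:::config_spec(cfg)
  stim <- synthesize_stimulus(spec)
  peaks <- stimulus_peak_frequencies(stim, spec)
  cls <- classify_f1_harmonics(peaks, spec$f1_range_hz, spec$f1_margin_hz)
  list(cfg = cfg, spec = spec, stim = stim,
       f1_centers = peaks[cls$f1_members])
}

vowel_group_pvalue <- function(world, seed) {
  cfg <- world$cfg
  cfg$master_seed <- seed
  cohort <- ffrpipe:::config_cohort(cfg)
  tab <- cohort_subject_table(cohort)
  f1 <- vapply(seq_len(nrow(tab)), function(i) {
    params <- ffrpipe:::subject_params_from_row(tab[i, ], cohort)
    ss <- simulate_subject_sweeps(world$stim, params, world$spec,
                                  n_sweeps_per_polarity = cfg$sweeps_per_polarity,
                                  epoch_window_ms = cfg$epoch_window_ms)
    avg <- preprocess_sweeps(ss, low_hz = cfg$filter_low_hz,
                             high_hz = cfg$filter_high_hz,
                             threshold_uv = cfg$rejection_threshold_uv,
                             baseline_window_ms = cfg$baseline_window_ms)
    sp <- region_spectrum(avg, cfg$vowel_window_ms, region_label = "vowel")
    mean(vapply(world$f1_centers, function(fc)
      extract_peak_amplitude(sp, fc, cfg$extraction_bandwidth_hz), numeric(1)))
  }, numeric(1))
  an <- mixed_anova(data.frame(subject_id = tab$subject_id, group = tab$group,
                               amplitude = f1),
                    within = character(0))
  as.data.frame(an)$p[1]
}

# synthetic feature table with a specified group shift on vowel f1_mean
fake_features <- function(n_per_group = c(6, 6, 6), f1_shift = c(0, 0, 0),
                          seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  groups <- rep(c("g1", "g2", "g3"), n_per_group)
  n <- length(groups)
  withr_seed({
    base <- rnorm(n, 0.5, 0.1)
    rows <- lapply(c("consonant", "vowel"), function(rg) {
      f1 <- base + rnorm(n, 0, 0.05) +
        if (rg == "vowel") f1_shift[match(groups, c("g1", "g2", "g3"))] else 0
      data.frame(subject_id = sprintf("S%02d", seq_len(n)), group = groups,
                 region = rg,
                 f0_amp = base + rnorm(n, 0, 0.05),
                 h2 = base, h3 = base, h4 = base, h5 = base, h6 = base,
                 mean_h = base + rnorm(n, 0, 0.05),
                 f1_mean = f1,
                 non_f1_mean = base + rnorm(n, 0, 0.05),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
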