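# Pipeline stages tying simulation, preprocessing, extraction, statistics and
# reporting into a reproducible file-based workflow with a run manifest.

#' Canonical file layout of a pipeline output directory
#'
#' @param out_dir output directory.
#' @return named list of file paths used by the pipeline stages.
#' @export
pipeline_paths <- function(out_dir) {
  list(
    config = file.path(out_dir, "config.txt"),
    manifest = file.path(out_dir, "manifest.json"),
    stimulus = file.path(out_dir, "stimulus.wav"),
    sweep_dir = file.path(out_dir, "sweeps"),
    cohort_manifest = file.path(out_dir, "cohort_manifest.csv"),
    avg_dir = file.path(out_dir, "averaged"),
    peaks = file.path(out_dir, "stimulus_peaks.csv"),
    features = file.path(out_dir, "features.csv"),
    features_wide = file.path(out_dir, "features_wide.csv"),
    results = file.path(out_dir, "results.json"),
    fig_global = file.path(out_dir, "fig_global_bands.png"),
    fig_regions = file.path(out_dir, "fig_region_spectra.png"),
    summary = file.path(out_dir, "summary.txt")
  )
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

read_manifest <- function(path) {
  if (file.exists(path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else list(stages = list())
}

update_manifest <- function(out_dir, stage, files, extra = list()) {
  p <- pipeline_paths(out_dir)
  man <- read_manifest(p$manifest)
  man$package_version <- as.character(utils::packageVersion("ffrpipe"))
  files <- files[file.exists(files)]
  entry <- c(list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  checksums = as.list(tools::md5sum(files))), extra)
  if (is.null(man$stages)) man$stages <- list()
  man$stages[[stage]] <- entry
  jsonlite::write_json(man, p$manifest, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(man)
}

check_inputs_exist <- function(files, stage) {
  miss <- files[!file.exists(files)]
  if (length(miss))
    stopf("stage '%s': missing input file(s): %s", stage,
          paste(miss, collapse = ", "))
  invisible(TRUE)
}

log_stage <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
  invisible(NULL)
}

#' Pipeline stage: simulate the cohort
#'
#' Writes the stimulus WAV, per-subject sweep files, the cohort manifest
#' (subject, group, file) and the config snapshot, and updates the run
#' manifest with checksums.
#'
#' @param cfg validated `ffr_config`.
#' @param out_dir output directory (created if needed).
#' @param verbose print per-stage progress.
#' @return the cohort manifest data frame, invisibly.
#' @export
stage_simulate <- function(cfg, out_dir, verbose = TRUE) {
  validate_config(cfg)
  p <- pipeline_paths(out_dir)
  dir.create(p$sweep_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- config_spec(cfg)
  stim <- synthesize_stimulus(spec)
  write_wav(stim$samples, spec$sampling_rate_hz, p$stimulus)
  log_stage(verbose, "[simulate] stimulus written (%d samples)", length(stim$samples))
  cohort <- config_cohort(cfg)
  res <- simulate_cohort(cohort, spec, stimulus = stim, out_dir = p$sweep_dir,
                         epoch_window_ms = cfg$epoch_window_ms)
  man <- res$manifest
  data.table::fwrite(man, p$cohort_manifest)
  write_config(cfg, p$config)
  update_manifest(out_dir, "simulate",
                  c(p$stimulus, p$cohort_manifest, p$config, man$file),
                  list(config_hash = config_hash(cfg),
                       n_subjects = nrow(man),
                       sweeps_per_subject = 2 * cfg$sweeps_per_polarity))
  log_stage(verbose, "[simulate] %d subjects, %d sweeps each",
            nrow(man), 2 * cfg$sweeps_per_polarity)
  invisible(man)
}

#' Pipeline stage: preprocess every subject
#'
#' Reads each sweep file, runs filter -> artifact rejection -> baseline ->
#' polarity-subtracted averaging, and writes one averaged-response file per
#' subject; per-subject sweep counts go into the run manifest.
#'
#' @inheritParams stage_simulate
#' @return data frame of per-subject rejection counts, invisibly.
#' @export
stage_preprocess <- function(cfg, out_dir, verbose = TRUE) {
  validate_config(cfg)
  p <- pipeline_paths(out_dir)
  check_inputs_exist(p$cohort_manifest, "preprocess")
  man <- data.table::fread(p$cohort_manifest, data.table = FALSE)
  check_inputs_exist(man$file, "preprocess")
  dir.create(p$avg_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- lapply(seq_len(nrow(man)), function(i) {
    ss <- read_sweepset(man$file[i])
    n_in <- nrow(ss$sweeps)
    avg <- preprocess_sweeps(ss, low_hz = cfg$filter_low_hz,
                             high_hz = cfg$filter_high_hz,
                             threshold_uv = cfg$rejection_threshold_uv,
                             baseline_window_ms = cfg$baseline_window_ms)
    out <- file.path(p$avg_dir, paste0("avg_", man$subject_id[i], ".txt"))
    write_avg_response(avg, out)
    log_stage(verbose, "[preprocess] %s: %d sweeps read, %d rejected, %d averaged",
              man$subject_id[i], n_in, avg$n_rejected, sum(avg$n_sweeps_used))
    data.frame(subject_id = man$subject_id[i], n_read = n_in,
               n_rejected = avg$n_rejected,
               n_used_a = avg$n_sweeps_used[1], n_used_b = avg$n_sweeps_used[2],
               file = out, stringsAsFactors = FALSE)
  })
  counts <- do.call(rbind, counts)
  update_manifest(out_dir, "preprocess", counts$file,
                  list(rejections = stats::setNames(as.list(counts$n_rejected),
                                                    counts$subject_id)))
  invisible(counts)
}

#' Pipeline stage: extract spectral features
#'
#' Refines band peak frequencies from the stimulus FFT, extracts per-subject,
#' per-region features, and writes the long and wide feature tables plus the
#' stimulus-peak table.
#'
#' @inheritParams stage_simulate
#' @return the feature data frame, invisibly.
#' @export
stage_extract <- function(cfg, out_dir, verbose = TRUE) {
  validate_config(cfg)
  p <- pipeline_paths(out_dir)
  check_inputs_exist(c(p$stimulus, p$cohort_manifest), "extract")
  spec <- config_spec(cfg)
  wav <- read_wav(p$stimulus)
  stim <- structure(list(samples = wav$samples,
                         sampling_rate_hz = wav$sampling_rate_hz, spec = spec),
                    class = "ffr_stimulus")
  peaks <- stimulus_peak_frequencies(stim, spec,
                                     resolution_hz = cfg$spectral_resolution_hz)
  data.table::fwrite(data.frame(band = names(peaks), freq_hz = as.numeric(peaks)),
                     p$peaks)
  man <- data.table::fread(p$cohort_manifest, data.table = FALSE)
  avg_files <- file.path(p$avg_dir, paste0("avg_", man$subject_id, ".txt"))
  check_inputs_exist(avg_files, "extract")
  responses <- lapply(avg_files, read_avg_response)
  feats <- compute_cohort_features(responses, spec, peaks,
                                   resolution_hz = cfg$spectral_resolution_hz)
  long <- do.call(rbind, lapply(c("f0_amp", "h2", "h3", "h4", "h5", "h6",
                                  "mean_h", "f1_mean", "non_f1_mean"),
                                function(b)
                                  data.frame(subject_id = feats$subject_id,
                                             group = feats$group,
                                             region = feats$region, band = b,
                                             amplitude_uv = feats[[b]])))
  data.table::fwrite(long[order(long$subject_id, long$region, long$band), ],
                     p$features)
  data.table::fwrite(as.data.frame(feats), p$features_wide)
  update_manifest(out_dir, "extract", c(p$peaks, p$features, p$features_wide),
                  list(n_feature_rows = nrow(feats)))
  log_stage(verbose, "[extract] features for %d subjects x 2 regions",
            length(responses))
  invisible(feats)
}

#' Pipeline stage: group statistics
#'
#' Runs the global, per-region and per-feature ANOVAs with Fisher LSD
#' post-hocs on the extracted feature table and writes the JSON results
#' bundle.
#'
#' @inheritParams stage_simulate
#' @return the `ffr_results` bundle, invisibly.
#' @export
stage_stats <- function(cfg, out_dir, verbose = TRUE) {
  validate_config(cfg)
  p <- pipeline_paths(out_dir)
  check_inputs_exist(p$features_wide, "stats")
  feats <- data.table::fread(p$features_wide, data.table = FALSE)
  results <- run_group_analysis(feats)
  results_to_json(results, p$results)
  update_manifest(out_dir, "stats", p$results)
  log_stage(verbose, "[stats] results written to %s", p$results)
  invisible(results)
}

#' Pipeline stage: summary figures and report
#'
#' Writes a grouped-bar figure of band amplitudes per group (with +/- 1
#' standard-error bars), overlaid mean region spectra per group, and a plain
#' text summary of the fitted models.
#'
#' @inheritParams stage_simulate
#' @param format figure device, `"png"` or `"pdf"`.
#' @return invisibly, the paths of the written files.
#' @export
stage_report <- function(cfg, out_dir, verbose = TRUE, format = c("png", "pdf")) {
  format <- match.arg(format)
  validate_config(cfg)
  p <- pipeline_paths(out_dir)
  check_inputs_exist(c(p$features_wide, p$results), "report")
  feats <- data.table::fread(p$features_wide, data.table = FALSE)
  if (format == "pdf") {
    p$fig_global <- sub("\\.png$", ".pdf", p$fig_global)
    p$fig_regions <- sub("\\.png$", ".pdf", p$fig_regions)
  }
  plot_global_bands(feats, p$fig_global, format)
  plot_region_spectra(cfg, out_dir, p$fig_regions, format)
  res_json <- readLines(p$results)
  writeLines(c("ffrpipe run summary", "===================", "",
               sprintf("subjects: %d", length(unique(feats$subject_id))),
               sprintf("groups: %s", paste(unique(feats$group), collapse = ", ")),
               "", "Model results (JSON):", res_json), p$summary)
  update_manifest(out_dir, "report", c(p$fig_global, p$fig_regions, p$summary))
  log_stage(verbose, "[report] figures and summary written")
  invisible(c(p$fig_global, p$fig_regions, p$summary))
}

open_device <- function(path, format, width = 9, height = 5) {
  if (format == "pdf") grDevices::pdf(path, width = width, height = height)
  else grDevices::png(path, width = width * 110, height = height * 110)
}

# Grouped bars of band amplitudes (mean across regions) per group,
# +/- 1 standard error of the mean.
plot_global_bands <- function(feats, path, format = "png") {
  bands <- c("f0_amp", "f1_mean", "non_f1_mean", "mean_h")
  labels <- c("F0", "F1", "Non-F1", "Harmonics")
  groups <- unique(feats$group)
  agg <- stats::aggregate(feats[bands], by = feats[c("subject_id", "group")], mean)
  m <- sapply(bands, function(b) tapply(agg[[b]], agg$group, mean))[groups, , drop = FALSE]
  se <- sapply(bands, function(b) tapply(agg[[b]], agg$group,
                                         function(v) stats::sd(v) / sqrt(length(v))))[groups, , drop = FALSE]
  open_device(path, format)
  on.exit(grDevices::dev.off())
  cols <- grDevices::hcl.colors(length(groups), "Dark 3")
  bp <- graphics::barplot(m, beside = TRUE, names.arg = labels, col = cols,
                          ylim = c(0, max(m + se) * 1.25),
                          ylab = "Amplitude (µV)",
                          main = "Spectral representation by band and group")
  graphics::arrows(bp, m - se, bp, m + se, angle = 90, code = 3, length = 0.03)
  graphics::legend("topright", legend = groups, fill = cols, bty = "n")
  invisible(path)
}

# Mean region spectra per group, consonant and vowel panels.
plot_region_spectra <- function(cfg, out_dir, path, format = "png") {
  p <- pipeline_paths(out_dir)
  man <- data.table::fread(p$cohort_manifest, data.table = FALSE)
  avg_files <- file.path(p$avg_dir, paste0("avg_", man$subject_id, ".txt"))
  check_inputs_exist(avg_files, "report")
  responses <- lapply(avg_files, read_avg_response)
  regions <- list(consonant = cfg$consonant_window_ms,
                  vowel = cfg$vowel_window_ms)
  groups <- unique(man$group)
  cols <- grDevices::hcl.colors(length(groups), "Dark 3")
  open_device(path, format, width = 10, height = 4.5)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  for (rg in names(regions)) {
    specs <- lapply(responses, region_spectrum, window_ms = regions[[rg]],
                    resolution_hz = cfg$spectral_resolution_hz, region_label = rg)
    freqs <- specs[[1]]$freqs_hz
    keep <- freqs <= 1000
    graphics::plot(NA, xlim = c(0, 1000),
                   ylim = c(0, max(vapply(specs, function(s) max(s$amplitude[keep]),
                                          numeric(1))) * 1.05),
                   xlab = "Frequency (Hz)", ylab = "Amplitude (µV)",
                   main = sprintf("%s region", rg))
    for (gi in seq_along(groups)) {
      sel <- man$group == groups[gi]
      mean_amp <- rowMeans(vapply(specs[sel], function(s) s$amplitude,
                                  numeric(length(freqs))))
      graphics::lines(freqs[keep], mean_amp[keep], col = cols[gi], lwd = 1.4)
    }
    graphics::legend("topright", legend = groups, col = cols, lwd = 1.4, bty = "n")
  }
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes the requested stages in order (simulate, preprocess, extract,
#' stats, report). Each stage reads its inputs from `out_dir`, so any stage
#' can be re-run independently after its inputs exist.
#'
#' @param cfg validated `ffr_config`.
#' @param out_dir output directory.
#' @param stages character vector of stages to run.
#' @param verbose print progress.
#' @param report_format figure device for the report stage.
#' @return invisibly, the path list of pipeline outputs.
#' @export
run_pipeline <- function(cfg, out_dir,
                         stages = c("simulate", "preprocess", "extract",
                                    "stats", "report"),
                         verbose = TRUE, report_format = "png") {
  validate_config(cfg)
  all_stages <- c("simulate", "preprocess", "extract", "stats", "report")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (st in all_stages[all_stages %in% stages]) {
    switch(st,
           simulate = stage_simulate(cfg, out_dir, verbose),
           preprocess = stage_preprocess(cfg, out_dir, verbose),
           extract = stage_extract(cfg, out_dir, verbose),
           stats = stage_stats(cfg, out_dir, verbose),
           report = stage_report(cfg, out_dir, verbose, report_format))
  }
  invisible(pipeline_paths(out_dir))
}

#' In-memory pipeline: config to feature table
#'
#' Runs simulate -> preprocess -> extract without touching the file system.
#' Used by the statistical calibration simulations and tests, and convenient
#' interactively for small cohorts.
#'
#' @param cfg validated `ffr_config`.
#' @param regions `"both"` or `"vowel"` (restrict extraction to the vowel
#'   region, halving FFT work when only vowel features are needed).
#' @return `ffr_features` data frame.
#' @export
pipeline_features <- function(cfg, regions = c("both", "vowel")) {
  regions <- match.arg(regions)
  validate_config(cfg)
  spec <- config_spec(cfg)
  stim <- synthesize_stimulus(spec)
  peaks <- stimulus_peak_frequencies(stim, spec,
                                     resolution_hz = cfg$spectral_resolution_hz)
  cohort <- config_cohort(cfg)
  tab <- cohort_subject_table(cohort)
  reg <- if (regions == "vowel") list(vowel = cfg$vowel_window_ms) else NULL
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    params <- subject_params_from_row(tab[i, ], cohort)
    ss <- simulate_subject_sweeps(stim, params, spec,
                                  n_sweeps_per_polarity = cfg$sweeps_per_polarity,
                                  epoch_window_ms = cfg$epoch_window_ms)
    avg <- preprocess_sweeps(ss, low_hz = cfg$filter_low_hz,
                             high_hz = cfg$filter_high_hz,
                             threshold_uv = cfg$rejection_threshold_uv,
                             baseline_window_ms = cfg$baseline_window_ms)
    compute_features(avg, spec, peaks, regions = reg,
                     resolution_hz = cfg$spectral_resolution_hz)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ffr_features", class(out))
  out
}
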