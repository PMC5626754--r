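# Filtering, artifact rejection, baseline correction, averaging.

sinusoid_sweep <- function(freq, fs, dur_s = 1, amp = 1) {
  t <- (0:(dur_s * fs - 1)) / fs
  amp * sin(2 * pi * freq * t)
}

measured_attenuation_db <- function(freq, fs = 30000, lo = 70, hi = 2000) {
  x <- sinusoid_sweep(freq, fs)
  flt <- design_bandpass(lo, hi, fs)
  y <- filter_waveform(x, flt)
  # steady-state amplitude after the transient
  tail_amp <- max(abs(y[(length(y) / 2):length(y)]))
  -20 * log10(tail_amp)
}

test_that("bandpass passes mid-band and rolls off at 12 dB/octave", {
  # < 3 dB at 1 kHz (mid passband)
  expect_lt(measured_attenuation_db(1000), 3)
  # two octaves below the 70 Hz corner: 24 +/- 3 dB
  att_175 <- measured_attenuation_db(17.5)
  expect_gt(att_175, 21)
  expect_lt(att_175, 27)
  # measured sinusoid attenuation agrees with the analytic magnitude response
  flt <- design_bandpass(70, 2000, 30000)
  expect_lt(abs(att_175 - (-20 * log10(filter_response(flt, 17.5)))), 0.5)
  expect_lt(abs(measured_attenuation_db(1000) -
                  (-20 * log10(filter_response(flt, 1000)))), 0.5)
})

test_that("DC input decays to ~0 after the filter transient", {
  fs <- 30000
  x <- rep(5, fs)
  y <- filter_waveform(x, design_bandpass(70, 2000, fs))
  expect_lt(max(abs(y[(fs / 2):fs])), 1e-3)
})

test_that("corner frequencies at/above Nyquist are rejected", {
  expect_error(design_bandpass(70, 16000, 30000), "Nyquist")
  expect_error(design_bandpass(2000, 70, 30000), "below")
  expect_error(design_bandpass(-5, 2000, 30000), "positive")
})

test_that("compiled filter matches the stats::filter reference implementation", {
  set.seed(4)
  X <- matrix(rnorm(5 * 3000), 3000, 5)
  flt <- design_bandpass(70, 2000, 30000)
  ref <- X
  for (s in flt$sections) ref <- ffrpipe:::iir_filter_matrix(ref, s$b, s$a)
  expect_equal(ffrpipe:::apply_filter_samples(X, flt), ref, tolerance = 1e-12)
})

test_that("zero-phase filtering doubles the effective roll-off", {
  fs <- 30000
  x <- sinusoid_sweep(17.5, fs)
  flt <- design_bandpass(70, 2000, fs)
  y <- ffrpipe:::apply_filter_samples(matrix(x, ncol = 1), flt, zero_phase = TRUE)
  mid <- abs(y[(fs / 4):(3 * fs / 4), 1])
  expect_gt(-20 * log10(max(mid)), 40)
})

test_that("artifact rejection uses strict exceedance over the whole epoch", {
  set.seed(11)
  mat <- matrix(rnorm(10 * 100, 0, 3), 10, 100)
  mat[abs(mat) > 29] <- 0
  mat[2, 50] <- 50; mat[5, 10] <- -50; mat[9, 99] <- 31
  ss <- raw_sweepset(mat)
  out <- reject_artifacts(ss, 30)
  expect_identical(out$n_rejected, 3L)
  expect_identical(nrow(out$sweeps$sweeps), 7L)
  # survivors keep their order
  expect_identical(out$sweeps$sweeps[1, ], mat[1, ])
  # exactly at the threshold is retained
  mat2 <- matrix(0, 2, 100); mat2[1, 5] <- 30.0
  expect_identical(reject_artifacts(raw_sweepset(mat2), 30)$n_rejected, 0L)
  # all rejected -> error
  mat3 <- matrix(100, 2, 100)
  expect_error(reject_artifacts(raw_sweepset(mat3), 30), "all 2 sweeps")
  expect_error(reject_artifacts(ss, -3), "threshold")
})

test_that("baseline correction subtracts the per-sweep baseline mean", {
  # constant sweep -> zero
  const <- raw_sweepset(matrix(5, 2, 100))
  expect_equal(max(abs(baseline_correct(const)$sweeps)), 0)
  # random sweeps: direct-summation oracle
  set.seed(2)
  mat <- matrix(rnorm(4 * 260), 4, 260)
  ss <- raw_sweepset(mat, fs = 1000, t0 = -30)
  out <- baseline_correct(ss, c(-30, 0))
  for (i in 1:4) {
    m <- sum(mat[i, 1:30]) / 30
    expect_equal(out$sweeps[i, ], mat[i, ] - m)
  }
  # idempotent
  out2 <- baseline_correct(out, c(-30, 0))
  expect_equal(out2$sweeps, out$sweeps)
  # window outside epoch
  expect_error(baseline_correct(ss, c(-60, 0)), "outside")
})

test_that("polarity-subtracted averaging matches the direct-summation oracle", {
  set.seed(3)
  mat <- matrix(rnorm(6 * 100), 6, 100)
  pol <- c("A", "A", "B", "A", "B", "B")
  ss <- raw_sweepset(mat, polarity = pol)
  avg <- average_and_subtract(ss)
  brute <- (colMeans(mat[pol == "A", ]) - colMeans(mat[pol == "B", ])) / 2
  expect_equal(avg$samples, brute)
  expect_identical(avg$n_sweeps_used, c(A = 3L, B = 3L))
  # pure inversion: recover the component at its single-polarity amplitude
  s <- sin(2 * pi * 10 * (0:99) / 1000)
  inv <- raw_sweepset(rbind(s, -s), polarity = c("A", "B"))
  expect_equal(average_and_subtract(inv)$samples, s)
  # identical polarities cancel
  same <- raw_sweepset(rbind(s, s), polarity = c("A", "B"))
  expect_lt(max(abs(average_and_subtract(same)$samples)), 1e-12)
  # one polarity absent
  only_a <- raw_sweepset(mat, polarity = rep("A", 6))
  expect_error(average_and_subtract(only_a), "both")
})

test_that("preprocessing is linear when no sweeps are rejected", {
  set.seed(8)
  x <- matrix(rnorm(4 * 520), 4, 520)
  y <- matrix(rnorm(4 * 520), 4, 520)
  pol <- c("A", "B", "A", "B")
  run <- function(m) preprocess_sweeps(raw_sweepset(m, pol, fs = 2000),
                                       low_hz = 70, high_hz = 900)$samples
  expect_equal(run(x + y), run(x) + run(y), tolerance = 1e-10)
})

test_that("subtraction favors harmonic fine structure over envelope by >= 20 dB", {
  spec <- fast_spec()
  stim <- synthesize_stimulus(spec)
  p <- subject_params(envelope_gain = 0.25, noise_sd_uv = 0.3,
                      artifact_rate = 0, seed = 5)
  ss <- simulate_subject_sweeps(stim, p, spec, n_sweeps_per_polarity = 200)
  ss <- bandpass_filter(ss)
  ss <- baseline_correct(ss)
  sub <- average_and_subtract(ss)
  # polarity-ADDED average (envelope survives, fine structure cancels)
  add <- ss
  add$sweeps[add$polarity == "B", ] <- -add$sweeps[add$polarity == "B", ]
  added <- average_and_subtract(add)
  vow <- spec$vowel_window_ms
  sp_sub <- region_spectrum(sub, vow)
  sp_add <- region_spectrum(added, vow)
  e_sub <- sum(sapply(spec$harmonic_hz, function(f)
    extract_peak_amplitude(sp_sub, f, 20)^2))
  e_add <- sum(sapply(spec$harmonic_hz, function(f)
    extract_peak_amplitude(sp_add, f, 20)^2))
  expect_gt(10 * log10(e_sub / e_add), 20)
})
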