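---
title: "Methods: speech-evoked FFR analysis with ffrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speech-evoked FFR analysis with ffrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffrpipe)
```

## What the pipeline computes

The frequency-following response (FFR) is scalp-recorded neural activity
that phase-locks to the periodicity and spectral fine structure of a sound,
dominated by subcortical generators. `ffrpipe` implements a complete
analysis chain for speech-evoked FFRs to a consonant-vowel syllable with
fundamental frequency F0 = 129 Hz, harmonics H2-H6 anchored at stimulus
spectral peaks (261, 393, 531, 665, 787 Hz), and a first formant (F1)
spanning 400-700 Hz:

1. **Preprocessing** of multi-sweep EEG epochs (-30..230 ms at 30 kHz):
   Butterworth bandpass 70-2000 Hz at 12 dB/octave, rejection of sweeps with
   activity exceeding ±30 µV, baseline correction to the -30..0 ms
   pre-stimulus mean, then per-polarity averaging and polarity subtraction
   `(avgA - avgB)/2`.
2. **Spectral feature extraction** on two response regions — consonant
   (20-67 ms) and vowel (67-220 ms) — via rectangular-window FFTs
   zero-padded to ≤ 1 Hz bins. For each band, the maximum single-sided
   amplitude in a closed 20 Hz window centred on the *stimulus* FFT peak is
   extracted (a peak at 118 Hz is searched in [108, 128] Hz). Harmonics
   whose refined frequencies fall inside F1 ± 20 Hz form the formant-band
   mean (H3-H5 for the canonical plan); the others (H2, H6) form the
   non-formant mean; all five form the harmonics mean.
3. **Split-plot statistics**: a global mixed ANOVA with group (3 levels)
   between subjects and time region (2) × spectral component (4) within
   subjects; separate consonant (2 components) and vowel (3 components)
   models; per-feature one-way group ANOVAs; Fisher LSD post-hoc t-tests
   with Cohen's d, gated on an omnibus group effect with p < 0.05.
4. A **synthetic-cohort generator** standing in for unreleased human EEG, so
   every stage is testable end to end without any external data.

## The split-plot model

For subject $s$ in group $g$ with within-cell response $y_{gsjk}$ (region
$j$, component $k$), the classical univariate split-plot decomposition is
used. The group effect is tested against subjects-within-groups; each within
effect and its group interaction against its own effect × subject-within-
group stratum. With $a$ groups, $N$ subjects, $r$ regions and $c$
components, the degrees of freedom are exact integers: for example the
region × component interaction has
$\big((r-1)(c-1),\ (r-1)(c-1)(N-a)\big)$ — with $N - a = 37$, $r = 2$,
$c = 4$ this is $(3, 111)$. No sphericity correction is applied, matching
the integer df convention of the reporting style this package mirrors.

Mechanically, each subject's cell vector is projected onto orthonormal
(normalized Helmert) within-subject contrasts, which reduces every stratum
to a one-way decomposition over subjects; the test suite verifies every F
and df against an independent brute-force sums-of-squares oracle written
with explicit loops (relative error < 1e-8 on 200 random designs), and the
one-within-cell reduction against the closed-form one-way F.

Unbalanced groups are handled with each group's own n in all mean
computations and weighted grand means — the classical weighted-means
split-plot treatment (identical to `aov` with an
`Error(subject/(region*component))` stratum specification). Fisher LSD for
a group effect operates on per-subject mean scores with the subject-stratum
error mean square rescaled to that level; Cohen's d uses the pooled
(n-1)-weighted standard deviation with no small-sample correction.

The 4-level "spectral component" factor of the global model is built for
*both* regions as {F0, F1-band mean, non-F1 mean, harmonics mean} so the
design is fully crossed; the source protocol does not state its exact
composition per region, and this choice keeps the global model structurally
reproducible. Per-region models then use the per-region component sets
({F0, harmonics mean} for the consonant; {F0, F1 mean, non-F1 mean} for the
vowel).

## Numerical choices

* **Filter**: second-order Butterworth highpass (70 Hz) and lowpass
  (2000 Hz) biquads via the bilinear transform with frequency prewarping,
  cascaded — the asymptotic roll-off is 12 dB/octave beyond each corner.
  The filter is applied **causally (forward only)** by default: zero-phase
  forward-backward filtering would double the realized roll-off to
  24 dB/octave and silently break the stated slope. A `zero_phase` option
  exists and is documented as doing exactly that. Expected attenuation two
  octaves below the low corner is $10\log_{10}(1+4^4) \approx 24.1$ dB,
  which the tests verify against both a measured sinusoid and the analytic
  magnitude response of the realized digital filter.
* **Rejection** uses strict exceedance: a sample exactly at ±30 µV is
  retained. Rejection is evaluated over the entire epoch, after filtering
  (the pipeline applies the stages in their documented order:
  filter → reject → baseline → average).
* **Polarity subtraction is halved**: `(avgA - avgB)/2` keeps amplitudes on
  the scale of a single-polarity average. This is a pure rescaling; it
  cannot change any F, p, or d downstream. Unequal surviving sweep counts
  per polarity are allowed; each polarity averages over its own survivors.
* **Spectra** use a rectangular window and zero-padding to ≤ 1 Hz bins.
  The rectangular window keeps the amplitude calibration exact (a unit
  sinusoid filling a region reads 1.0 ± 2% at any padding factor) and the
  padding makes a 20 Hz search window meaningful for the 47 ms consonant
  segment, whose native resolution is only ~21 Hz. Amplitudes are
  single-sided, `2|X|/N` with N the unpadded segment length; a power
  spectral density is deliberately not the default because the extracted
  quantities are amplitudes in µV.
* **Peak anchoring**: one whole-stimulus FFT supplies the refined band
  frequencies for both response regions. Within ±30 Hz of each nominal
  frequency, the highest interior local maximum wins; exact ties resolve to
  the lowest frequency (deterministic and oracle-testable). The 20 Hz
  extraction bandwidth is interpreted as total width (peak ± 10 Hz), fixed
  by the worked example mapping 118 Hz to [108, 128] Hz.
* **Degenerate inputs** error early with the offending context: corners at
  or above Nyquist, all sweeps rejected, one polarity absent, incomplete
  within-cells, singleton groups, zero pooled SD.
* The canonical vowel window (67-220 ms) overruns stimulus offset plus the
  10 ms neural delay (219 ms) by 1 ms; the stimulus-spec validator grants
  exactly that 1 ms of grace rather than silently truncating the window.

## The synthetic cohort: what it emulates, and what a green test means

The generator emulates the acquisition protocol of a three-group
cross-sectional study — 14 native nonmusicians, 18 non-native nonmusicians,
10 non-native musicians; 3000 sweeps per stimulus polarity per subject at
30 kHz — with this generative model per sweep:

* a **temporal-fine-structure component**: sinusoids at F0 and H2-H6 with
  per-subject, per-band gains (µV), which **invert** with stimulus
  polarity; harmonic (not F0) fine structure is attenuated ×0.5 during the
  consonant segment, mirroring the fricative-like consonant acoustics;
* an **envelope-following component** at F0 (default 0.25 µV) which does
  **not** invert — so polarity subtraction cancels it while doubling the
  fine structure, exactly the property the alternating-polarity protocol
  exploits against cochlear-microphonic and stimulus artifact;
* white Gaussian noise (default SD 1 µV per sweep);
* with probability 0.02 per sweep, a 10 ms square-pulse artifact of
  50-100 µV — only its exceedance of the ±30 µV threshold matters
  downstream, so no richer artifact morphology is modelled.

Between-subject gain variability uses a 20% coefficient of variation with
half the variance shared across bands
($z_{sb} = \sqrt{w}\,u_s + \sqrt{1-w}\,v_{sb}$, $w = 0.5$): spectral
amplitudes correlate strongly within subject (overall response strength,
head geometry) but retain band-specific variability. Perfect correlation
($w = 1$) would be unrealistic and would also make a 3-band composite no
more reliable than a single band; full independence ($w = 0$) is equally
implausible. Group effects are standardized per-band gain offsets (the
"effect plan"), so an offset of 0.9 means a 0.9-between-subject-SD shift of
each targeted band's gain; the default plan elevates the F1 bands (H3-H5)
by 0.9 in the native and non-native-musician groups. A consequence worth
stating explicitly: because bands are only partially correlated, the
*composite* F1 mean realizes a larger standardized difference (~1.1-1.2
here) than any single band (0.9) — averaging partially independent measures
is exactly why the protocol forms band means.

Amplitude scales (0.08-0.30 µV component gains, 1 µV sweep noise) are
chosen for testability: no single-sweep SNR is published for this protocol,
so these values make the averaged response clean at full sweep counts while
leaving single sweeps realistically noise-dominated. Subject seeds derive
deterministically from the master seed, so cohorts are byte-identical under
rerun.

What the generator does **not** model: cochlear mechanics or
inferior-colliculus physiology, 1/f or non-Gaussian EEG background,
latency jitter across sweeps, drifting electrode impedance, or a natural
speech waveform (the stimulus is a harmonic-complex surrogate sharing only
the frequency/time plan). A green acceptance suite therefore establishes
that the *pipeline* is correct and calibrated — filters meet their stated
response, extraction equals its oracle, the ANOVA matches brute-force sums
of squares, type-I error is nominal and the designed effect is recovered —
not that any scientific claim about human listeners is reproduced.

## Statistical calibration and runtime scaling

Two simulation-based checks calibrate the full chain
(simulate → preprocess → extract → test on the vowel F1-band mean):

* **Type-I error**: 2000 null cohorts (effect plan all zeros) must reject
  at 3-7%. Under the null the one-way F test on extracted features is
  exact, so the rejection rate is insensitive to sweep count; these
  replicates run at 4 sweeps per polarity and 8 kHz to fit the test-time
  budget.
* **Power**: 500 cohorts at the designed 0.9 standardized F1-band offset
  (n = 14/18/10) must reject at ≥ 80%. These run at 16 sweeps per polarity
  (8 kHz): fewer sweeps raise the spectral noise floor and *dilute* the
  realized effect relative to the full 3000-sweep protocol, so this scaled
  run is conservative with respect to the stated world, not optimistic.

The scaling knobs here are runtime concessions only; generator defaults,
effect sizes and acceptance bands are fixed by the stated study design and
were not adjusted against test outcomes.

## Known limitations

* The epoch and region windows assume the canonical 260 ms epoch; other
  paradigms would need new region definitions, not just new parameters.
* The causal filter introduces a frequency-dependent group delay
  (~0.4-4 ms over the passband edges); features are extracted from
  amplitude spectra, which are delay-invariant, but time-domain latency
  analyses are out of scope.
* Second-formant analysis is intentionally absent: F2 of this stimulus
  exceeds the phase-locking limit of the auditory brainstem.
* The plain-text sweep format trades size for transparency; at the full
  6000 × 7800 protocol scale a binary container would be preferable (the
  format adapter interface is left open).
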