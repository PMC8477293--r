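---
title: "Methods: test-retest reliability and longitudinal stability of smartphone digital biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: test-retest reliability and longitudinal stability of smartphone digital biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Smartphone-based assessments of Parkinson disease (PD) — short gait and
balance recordings from the phone's accelerometer, sustained-/a/
phonations from the microphone, and rapid alternating two-finger tapping
on the screen — yield *digital biomarkers*: numeric features intended to
track motor and phonatory impairment in daily life. Before such features
can be used in longitudinal studies they must (a) differentiate patients
from controls, (b) be reliable from one self-administered session to the
next, and (c) be robust to learning, motivation, elapsed time and
medication state. `dbstability` implements that full evaluation battery
over a synthetic cohort whose ground truth is known, so every stage of
the battery can be validated by parameter recovery rather than by
inspection.

The pipeline stages mirror the standard design of such studies:

1. **Simulate** a PD/HC cohort with repeated task recordings on a
   realistic self-administration schedule.
2. **Preprocess**: demographic inclusion rules (age 35-75, complete
   age/sex/diagnosis), removal of corrupted payloads, per-task analysis
   windows, chronological repetition indexing.
3. **Extract** a curated set of ~60 features spanning the families used
   in this literature (band powers, spectral summaries, freeze index,
   stride timing, moments; shimmer/jitter/F0/MFCC; inter-tap interval,
   drift, accuracy).
4. **Screen** features at baseline with Mann-Whitney U tests and Cohen
   *d*, after redundancy filtering (Spearman rho > 0.95 collapses to one
   random representative).
5. **Reliability**: ICC(1,1) per feature, group and pairing scheme;
   top-10 selection by median ICC per group; PD / HC / common labels.
6. **Longitudinal models**: mixed between/within repeated-measures
   ANOVAs for repetition, repetition adjusted for age and sex, elapsed
   time, and (within PD) medication state.

## The reliability model

Test-retest reliability uses the one-way random-effects,
single-measurement intraclass correlation, ICC(1,1). For paired
measurements per subject (k = 2),

$$\mathrm{ICC}(1,1) = \frac{MS_B - MS_W}{MS_B + (k - 1)\,MS_W},$$

where \(MS_B\) and \(MS_W\) are the between- and within-subject mean
squares of a one-way ANOVA with subject as the random factor. This form
is appropriate when raters/devices are not crossed with subjects — every
participant uses their own phone — and when a single measurement (not a
mean of repeats) is the unit whose reliability matters. Because the
one-way model absorbs *any* systematic difference between baseline and
retest into \(MS_W\), a learning or motivation drift lowers ICC(1,1);
this is a property, not a bug, and the package's simulator exposes it
(see the drift test in `test-pipeline.R`).

Interpretation bands follow the usual convention: below 0.40 poor,
0.40-0.59 fair, 0.60-0.74 good, 0.75-1.00 excellent.

**Pairing schemes.** Eight schemes pair each subject's baseline with one
retest: four repetition schemes (baseline vs repetitions 2-5) and four
time-lag schemes. The time lags are operationalized as disjoint
half-open windows of elapsed hours from baseline — hour (0, 6], day
(6, 36], week (36 h, 8 d], month (8 d, 45 d] — taking the subject's
*first* qualifying record in each window. Disjointness guarantees each
retest enters exactly one scheme; the "first qualifying" rule makes the
pairing deterministic. Calendar-anchored definitions ("same calendar
day") were considered and rejected because they make the pairing depend
on the local time of day of the baseline, which the data do not record
reliably.

## The longitudinal models

All four designs are computed by an explicit two-stratum sums-of-squares
partition:

* **Between-subject stratum** — subject means, one per subject, modelled
  by diagnosis (plus optional age and sex covariates). Effects are
  tested against subjects-within-groups. With covariates, each term's
  sum of squares is partial (Type-II style): the increment over the
  model containing all other between-subject terms. Unequal group sizes
  are the norm in such cohorts, so nothing assumes balance.
* **Within-subject stratum** — deviations from each subject's mean,
  modelled by the within factor (repetition, or centered elapsed time)
  and its interaction with diagnosis, tested against the
  within-by-subjects residual.

For the repetition designs a complete five-repetition profile per
subject is required (subjects with fewer are dropped and logged);
duplicate observations in a cell are aggregated by their median. The
medication design is a one-within-factor repeated-measures ANOVA over
the three PD medication states (before, after, at best), with each
subject contributing the median of their records per state.

Greenhouse-Geisser epsilon is computed from the pooled within-group
covariance of the level profiles and reported as a corrected p-value
(`p_gg`) alongside the uncorrected one; the uncorrected p is primary
since the generating model of the simulator is compound-symmetric, where
the correction is unnecessary. The engine is validated against
`stats::aov()` error-stratum output and an independent cell-means
decomposition to 1e-8 relative, and its null rejection rates are checked
by Monte Carlo (about 0.05 for every effect).

Elapsed time enters as a *continuous* within-subject regressor (centered
within subject) rather than binned; the data's irregular schedules make
bins arbitrary, while the continuous slope preserves the single-df
interpretation of a time trend.

## The synthetic cohort

The simulator has two tiers with one configuration object
(`sim_config()`).

**Feature-table tier.** Values follow the additive variance-component
model

$$y_{ijk} = \mu + \delta\,[\text{PD}] + b_i + \lambda_g (k-1) + m_{s} +
\varepsilon_{ijk}, \qquad b_i \sim N(0, \sigma^2_b),\;
\varepsilon \sim N(0, \sigma^2_w),$$

so the generating ICC is \(\sigma^2_b / (\sigma^2_b + \sigma^2_w)\), the
generating baseline Cohen *d* is \(\delta\) when
\(\sigma^2_b + \sigma^2_w = 1\), a group-specific repetition slope
\(\lambda_g\) injects a diagnosis-by-repetition interaction, and
\(m_s\) shifts the PD medication states. Session times follow a
log-normal inter-session gap (default mean 24 h, sdlog 1.5), chosen so
that hour-, day-, week- and month-scale retest lags are all populated
within six sessions. PD records cycle deterministically through the
before/after/best states by repetition index, which keeps the
medication design balanced; with the default zero drift this cycling is
harmless, and analyses that combine non-zero drift with medication
effects should treat the two as partially confounded by construction.

**Recording tier.** Signal archetypes drive the real extractors:

* *gait* — gravity-offset sinusoid at the subject's cadence (defaults:
  HC 1.8 Hz, PD 1.6 Hz) with a second harmonic and white noise, 12 s at
  100 Hz;
* *balance* — low-frequency sway plus a 4-7 Hz tremor component whose
  amplitude is group-scaled (defaults: PD 0.05 g, HC 0.01 g), 30 s;
* *voice* — cycle-by-cycle synthesis of a harmonic source at the
  subject's F0 with per-cycle amplitude and period perturbation; the
  injected shimmer/jitter values are the expected mean absolute
  consecutive relative differences, so the extractor's estimates are
  directly comparable to the knobs (defaults: shimmer 3% HC / 6% PD),
  10 s at 16 kHz;
* *tapping* — alternating-button events with subject-level inter-tap
  interval (defaults 0.20 s HC / 0.35 s PD), per-tap timing noise,
  spatial scatter, and a miss probability whose misses land clear of
  both buttons.

Subject-level parameters are drawn with between-subject dispersion and
per-session jitter, so downstream feature ICCs sit strictly between 0
and 1. Sampling rates (100 Hz motion, 16 kHz audio) are fixed well above
every analysis band. The archetypes are deliberately *not*
physiologically realistic — no gait dynamics, no vocal-tract model;
they exist to give the extractors signals whose feature statistics are
controllable. Consequently, green end-to-end tests demonstrate that the
pipeline measures what the generator injects; they do not certify
performance on real phone data, where device heterogeneity, artifacts
and non-stationarity dominate.

Identical seed and configuration give bit-identical output at both
tiers, including serialized WAV bytes.

## Numerical choices

* **PSD**: Welch's method, Hann window, 5 s segments, 50% overlap; the
  full-length rectangular periodogram is used only as a test oracle.
  Band powers integrate the one-sided density over half-open bands
  `(lo, hi]`, so adjacent bands partition the spectrum (Parseval checks
  hold within 2%).
* **F50** is the first frequency bin at which the cumulative PSD reaches
  half the total — with symmetric leakage around a line spectrum this
  lands on the line instead of interpolating away from it.
* **Freeze index bands**: locomotor 0.5-3 Hz, freezing 3-8 Hz — the
  common convention; the exact limits are configurable arguments.
* **Step detection**: 0.5-3 Hz band-pass of the magnitude signal, peaks
  at least 0.3 s apart and above a quarter of the filtered SD; a stride
  is two successive steps (alternate step events).
* **Double integration** to position applies a linear detrend and a
  0.3 Hz high-pass between integration steps to bound drift.
* **F0 tracking**: normalized autocorrelation peak in 75-500 Hz, 40 ms
  frames, 20 ms hop, voicing threshold 0.45; cycle peaks are refined by
  parabolic interpolation so periods are not quantized to the sample
  grid (without this, sample quantization alone mimics ~0.7% jitter at
  220 Hz / 16 kHz).
* **MFCC**: 13 coefficients, 25 ms frames, 10 ms hop, 26 mel filters —
  a fixed, standard configuration.
* **Glottis-quotient proxy** (`voice.gqc_proxy`): fraction of each cycle
  with |waveform| below 10% of the cycle peak. A true closed quotient
  needs glottal inverse filtering, which is out of scope; the name and
  docs flag the proxy status.
* **Mann-Whitney**: exact enumeration of the U distribution (valid under
  ties) when both groups have at most 8 observations, tie-corrected
  continuity-corrected normal approximation otherwise. Screening
  p-values are uncorrected by default (a `p_adjust_method` argument
  exists), matching the battery's screening role.
* **Degenerate inputs** yield missing values, not errors: all-zero
  spectra, constant series (skew/kurtosis), fewer than 10 voice cycles,
  fewer than 4 steps, fewer than 3 ICC pairs, fewer than 2 same-button
  taps.

## Problem sizes

The shipped tests validate at sizes chosen to keep the whole suite
within a coffee break on one core while leaving Monte-Carlo noise well
below the asserted tolerances: ICC recovery at 500 pairs x 200
replicates per true value; Mann-Whitney calibration over 5000 simulated
null features at 50 per group; ANOVA calibration at 5000 null
replicates of a 40-subject design; the end-to-end demo at 60 + 60
subjects with 6 sessions each across all four tasks. The acceptance
script (`scripts/acceptance.R`) recomputes the same quantities from
scratch under a caller-supplied seed.

## Known limitations

* The feature inventory is a curated ~60-feature subset of the families
  named in this literature, not the full several-hundred-feature
  battery of any specific study.
* ICC confidence intervals and ICC types (2,1)/(3,1) are not
  implemented; the battery is about type (1,1) point estimates.
* The longitudinal engine is a fixed-effects ANOVA decomposition, not a
  random-slope mixed model; that is the analysis the battery specifies,
  and `lme4` remains the right tool when shrinkage estimates are
  wanted.
* Real-data ingestion is limited to the package's own on-disk layout
  (JSON-lines + WAV + CSV); adapters for proprietary study exports are
  out of scope.
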