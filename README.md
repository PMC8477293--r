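# dbstability

Test-retest reliability and longitudinal stability of smartphone digital
biomarkers for Parkinson disease — as a reusable, fully tested pipeline
over a synthetic cohort with known ground truth.

Remote smartphone studies collect repeated gait, balance,
sustained-phonation and finger-tapping recordings from self-reported
patients with Parkinson disease (PD) and healthy controls (HC). Features
computed from those recordings are candidate *digital biomarkers*, but
they are only useful if they (a) separate PD from HC, (b) give similar
values when the same person repeats the task, and (c) stay stable — or
change interpretably — across repetitions, elapsed time and medication
states. `dbstability` implements the whole evaluation battery:

* a **synthetic cohort generator** at two tiers — long-format feature
  tables with explicit variance components, and raw sensor recordings
  (tri-axial accelerometry, phonation audio, tap event streams) with
  controllable group shifts, subject-level dispersion and schedules;
* **preprocessing**: demographic inclusion (ages 35-75, complete
  age/sex/diagnosis), corrupted-payload removal, per-task analysis
  windows (gait first 10 s; balance seconds 5-20 of 30; voice seconds
  2-8 of 10; tapping untrimmed 20 s), chronological repetition indexing;
* **feature extraction** (~60 features): band powers and spectral
  summaries (F50, CFREQ, FRQD, RHL, peak energy), freeze index, stride
  timing, signal moments; shimmer, jitter, F0, MFCC summaries; inter-tap
  interval statistics, tap drift, X-Y correlation, miss frequency;
* **reliability statistics**: Mann-Whitney baseline screening with Cohen
  *d*, Spearman-correlation redundancy filtering, and ICC(1,1)

  `ICC = (MSB − MSW) / (MSB + (k−1) MSW)`

  across eight pairing schemes (baseline vs repetitions 2-5; baseline vs
  first retest within an hour / day / week / month), top-10 selection by
  median ICC per group, PD / HC / common labelling;
* **longitudinal models**: mixed between/within repeated-measures ANOVAs
  (diagnosis × repetition; the same adjusted for age and sex; elapsed
  time as a continuous within-subject regressor; PD-only medication
  state model), with Greenhouse-Geisser-corrected p-values alongside.

The methods vignette (`vignettes/reliability-methods.Rmd`) documents the
models, the simulator's design and its limitations.

## Worked example

```r
library(dbstability)

cfg <- sim_config(n_pd = 12, n_hc = 12, recordings_per_subject = 6,
                  tasks = c("gait", "tapping"), seed = 42)
res <- run_pipeline(cfg)

dplyr::arrange(res$screen, p_value)[1:5, ]
#>   feature              U   p_value cohen_d significant
#> 1 tap.DriftLeft      144 0.0000366    6.95 TRUE
#> 2 tap.DriftRight     144 0.0000366    7.56 TRUE
#> 3 tap.TapDist.sd     144 0.0000366    4.03 TRUE
#> 4 tap.TapInter.iqr   144 0.0000366    5.44 TRUE
#> 5 tap.TapInter.p95   144 0.0000366    3.86 TRUE
```

U = 144 is complete separation of 12 vs 12 at baseline; the simulator's
default PD group taps more slowly and scatters more, and the tapping
features recover that with very large effect sizes. The reliability and
longitudinal summaries land in the run report:

```r
cat(res$report, sep = "\n")
#> - gait: 5 out of 17 features significant at baseline (P<.05)
#> - tap: 10 out of 13 features significant at baseline (P<.05)
#> ...
#> - gait / time family: mean ICC 0.65 at hour vs 0.48 at month
#> ...
#> - diagnosis main effect: 11 out of 11 features
#> - repetition main effect: 0 out of 11 features
```

Mean ICC of the top features declines from hour-scale to month-scale
retests (0.65 to 0.48 for gait here) purely through the generator's
session-to-session parameter jitter; with a configured repetition drift
(`drift_slope`) the repetition-family ICCs decay too, because ICC(1,1)
charges systematic baseline-to-retest shifts to the within-subject mean
square. With the default configuration no drift or medication effect is
injected, and the corresponding effects stay at their nominal 5% rate.

Every stage is also exposed individually (`simulate_recordings()`,
`clean_cohort()`, `window_records()`, `extract_features()`,
`screen_features()`, `icc_by_scheme()`, `select_top_features()`,
`rm_anova()`, `medication_model()`, ...), and a thin CLI wraps the
stages for shell use:

```sh
Rscript inst/cli/dbstability.R all --config cfg.yaml --out out/
```

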