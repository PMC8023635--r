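# eegprog

Resting-state EEG network features and outcome prognosis for acute
post-traumatic unresponsive states.

After a severe traumatic brain injury, patients who do not follow commands
once sedation is withdrawn pose the hardest prognostic question in the
intensive care unit. `eegprog` implements a complete analysis pipeline for
the standard clinical EEG recorded at the bedside (19-electrode 10/20
montage): it quantifies the oscillatory brain networks in those recordings
and relates them to the clinical picture and to functional outcome (Extended
Glasgow Outcome Scale, GOSE) months later. It is aimed at clinical
neurophysiology researchers who want a tested, fully reproducible
re-implementation of this analysis rather than an interactive toolbox.

## What it computes

From each recording — band-pass filtered 0.5–45 Hz, segmented into 10-s
epochs, artifact-cleaned, average-referenced — eight features:

* **Relative band power** (alpha 8–13 Hz, delta 0.5–4 Hz): band power over
  total power, mean over channels.
* **Connectivity**: debiased weighted phase lag index (dwPLI) between all
  channel pairs. With `I_k = Im(Z_k)` the imaginary cross-spectrum over
  `K` epochs, `dwPLI = ((Σ I_k)² − Σ I_k²) / ((Σ|I_k|)² − Σ I_k²)` —
  insensitive to zero-lag (volume-conduction) coupling. Feature: median
  over pairs, per band.
* **Graph metrics** on density-thresholded weighted networks, averaged over
  connection densities 90–10 %: Newman modularity `Q`, mean Onnela weighted
  clustering coefficient, population SD of participation coefficients
  `P_i = 1 − Σ_m (κ_im/κ_i)²`, and modular span (weight-weighted mean
  intra-module electrode distance, in head-radius units). Communities via
  seeded weighted Louvain with restarts.

On top of the features:

* **Cross-montage validation** — features computed from 91-channel
  high-density recordings versus the 19-channel subset taken *before*
  preprocessing, associated per feature (Pearson, or Spearman when
  Shapiro–Wilk flags non-normality); the same machinery checks 10- versus
  5-minute recording-length reliability.
* **Canonical correlation analysis** between the clinical picture (age,
  total GCS, CT grade, days since injury) and the EEG features, with a
  2000-permutation max-correlation randomization test and variate loadings.
* **Prognostic stepwise regression** (entry p = 0.05, removal p = 0.10) on
  rank-based inverse-normal transformed GOSE, with standardized betas,
  adjusted R² and R²-change against nested models.
* **Synthetic data**: multichannel EEG with controllable band power,
  phase-lagged modular coupling, zero-lag mixing and 1/f background, plus
  cohorts whose outcome depends on GCS and alpha power with tunable effect
  sizes — so every stage is testable without patient data.

## Worked example

```r
library(eegprog)

# a synthetic 5-minute recording with a phase-lagged alpha network
m  <- load_montage("ld1020")
ma <- setNames(rep(1L, 19), m$labels)          # all channels coupled
rec <- simulate_eeg(eeg_sim_spec(duration_s = 300, module_assignment = ma,
                                 coupling = 0.8, lag_deg = 45, seed = 7))
ep <- preprocess(rec)            # filter -> 10-s epochs -> reject -> avg ref
round(extract_features(ep, m, seed = 1), 4)
#>        alpha_rel_power     alpha_median_dwpli     alpha_modular_span
#>                 0.4265                 0.8216                 1.2862
#> alpha_participation_sd        delta_rel_power     delta_median_dwpli
#>                 0.0527                 0.3049                -0.0015
#>  delta_clustering_mean       delta_modularity
#>                 0.0728                 0.2840
```

Alpha power dominates (the imposed 0.35 band weight against a 0.25 delta
weight and 1/f background), the median alpha dwPLI (0.82) is far above
chance because of the planted phase-lagged coupling — while delta, which has
no imposed coupling, stays at its null value near 0 — and the graph features
summarize the density-thresholded alpha and delta networks.

A full cohort analysis, from EDF files on disk to a prognostic model:

```r
cfg <- default_config()
cfg$paths$output_dir <- "run1"; cfg$paths$input_dir <- "run1"
run_simulate(cfg)                                  # writes EDFs + cohort.csv
cfg$paths$cohort_csv <- "run1/cohort.csv"
run_features(cfg)                                  # eight features per patient
cfg$paths$cohort_csv <- "run1/cohort_features.csv"
run_cca(cfg)                                       # CCA + permutation test
run_prognose(cfg)                                  # stepwise GOSE model
```

The same stages are available from a shell via the thin front-end
`inst/cli/eegprog` (subcommands `simulate | features | validate-montage |
cca | prognose`).

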