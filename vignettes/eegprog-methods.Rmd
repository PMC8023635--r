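---
title: "Resting-state EEG network features and outcome prognosis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state EEG network features and outcome prognosis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`eegprog` analyses resting-state EEG from patients in acute post-traumatic
unresponsive states — patients in intensive care who do not follow commands
after sedation hold — and asks two questions: which oscillatory-network
features of a standard low-density (19-channel, 10/20) clinical EEG can be
trusted as estimates of the corresponding high-density features, and do those
features carry information about the clinical picture at the time of the EEG
and about functional outcome (GOSE) three and six months after injury.

The pipeline is: EDF in, band-pass filter, 10-s epochs, automated artifact
rejection, average reference; then eight features per recording; then
cross-montage validation, canonical correlation against the clinical picture
with a max-statistic permutation test, and stepwise prognostic regression on
rank-inverse-normal transformed outcomes. A synthetic-EEG and
synthetic-cohort generator makes all of it testable without patient data.

## Preprocessing

Recordings are band-pass filtered between 0.5 and 45 Hz, cut into
consecutive non-overlapping 10-s epochs (trailing remainder dropped),
cleaned, and re-referenced to the channel average — in that fixed order.

**Filter.** The filter applies the squared magnitude response of a
Butterworth band-pass in the frequency domain, which is exactly zero-phase
(the frequency-domain analogue of a forward–backward IIR pass). A 4th-order
design — the common clinical-EEG default — attenuates a 50 Hz mains tone only
to about 0.55 of its amplitude per pass (0.30 after the squared response),
which leaks mains artifact into the analysed range. We therefore use order 12
per edge: the passband (e.g. the 8–13 Hz alpha band) is flat to well within
1 dB while 50 Hz is reduced by more than a factor of 13 and anything an
octave outside the edges by far more than 20 dB. There is no notch filter;
the 45 Hz edge is the mains defence.

**Artifact rejection.** Interactive ICA-based cleaning is not reproducible
programmatically, so rejection is deterministic and two-stage: (1) drop
channels whose within-epoch variance z-score (computed across channels) is
above `z_var = 3` in more than half of the epochs; (2) drop epochs in which
any remaining channel has a peak-to-peak amplitude above `ptp_uV = 200`
microvolts. Both thresholds are exposed in the YAML config and the CLI. No
channel interpolation is performed afterwards: interpolation would inject
synthetic signal into connectivity estimates, and all downstream metrics
tolerate reduced channel counts.

## Features

Eight scalar features per recording, chosen for their track record in
disorders-of-consciousness work:

| key | definition |
|---|---|
| `alpha_rel_power` | mean over channels of alpha (8–13 Hz) power / total (0.5–45 Hz) power |
| `alpha_median_dwpli` | median over channel pairs of alpha dwPLI |
| `alpha_modular_span` | density-averaged mean intra-module electrode distance |
| `alpha_participation_sd` | density-averaged population SD of participation coefficients |
| `delta_rel_power` | mean relative delta (0.5–4 Hz) power |
| `delta_median_dwpli` | median delta dwPLI |
| `delta_clustering_mean` | density-averaged mean Onnela clustering |
| `delta_modularity` | density-averaged Newman modularity |

**Spectra.** Welch estimates: 2-s Hamming segments, 50 % overlap, averaged
within and across epochs, 0.5 Hz resolution, restricted to 0.5–45 Hz. Band
power uses trapezoidal integration; bands are half-open at the top
(delta [0.5, 4), theta [4, 8)) except alpha [8, 13], so shared edge bins are
never counted twice. The delta floor is 0.5 Hz, not 0: bins below the
high-pass cut-off hold filter roll-off, not signal. Relative power is
normalized by the full analysed range (0.5–45 Hz) rather than by the three
bands only; the alternative would change absolute values but not the ranks
the analyses rely on.

**Connectivity.** The debiased weighted phase lag index (dwPLI) is built
from the imaginary part of the cross-spectrum, so any zero-lag coupling —
volume conduction, common reference — contributes nothing. Per epoch, each
channel is Hanning-tapered and Fourier transformed over the whole epoch
(0.1 Hz resolution); one observation is one epoch at one in-band bin. With
`I_k = Im(Z_k)` over the `K` epochs of a pair and bin,

$$\mathrm{dwPLI} = \frac{(\sum_k I_k)^2 - \sum_k I_k^2}
                       {(\sum_k |I_k|)^2 - \sum_k I_k^2},$$

defined as 0 when the denominator vanishes, then averaged over the band's
bins. The debiasing removes the small-sample positive bias of squared WPLI,
at the price of slightly negative values under the null; negative entries
are retained in the connectivity matrix but clipped to zero when the matrix
is used as a graph.

**Graphs.** For each connection density from 90 % down to 10 % in 10 % steps
(the density grid is a package choice; only the range is canonical), the
strongest `round(density * n(n-1)/2)` pairs are kept with their weights,
ties broken by lexicographic pair order. Communities come from weighted
Louvain with 100 seeded restarts from shuffled node orders, keeping the
highest-modularity partition; given a seed the result is fully
deterministic, and features are invariant to input channel order because
channels are first sorted by label. Metrics per density, then averaged over
the nine densities:

* **Modularity** `Q = (1/2m) * sum_ij (w_ij - s_i s_j / 2m) [c_i = c_j]`.
* **Participation coefficient** `P_i = 1 - sum_m (k_im / k_i)^2`; isolated
  nodes get 0; the feature is the *population* SD over nodes (a fixed
  convention — the sample SD would differ by a factor
  `sqrt(n/(n-1))` and change nothing downstream).
* **Onnela clustering** with weights normalized by the network maximum;
  degree-<2 nodes get 0; feature is the mean.
* **Modular span**: for each module with at least one internal edge, the
  weight-weighted mean Euclidean distance between its connected electrodes,
  averaged over such modules. Electrode coordinates sit on a unit sphere, so
  spans are in head-radius units. The prose notion "average topographical
  distance spanned by a module" admits several formalizations (e.g. module
  diameter); this weight-weighted form is isolated in one function
  (`modular_span`) so it can be substituted without touching anything else.

## Montages

`ld1020` is the 19-electrode clinical 10/20 set. `hd91` is an idealized
91-site high-density layout following 10-10/10-5 naming, constructed on an
azimuthal-equidistant disc and projected to the unit sphere. It is a
synthetic stand-in: real high-density caps differ in their exact site lists,
but any fixed superset of the 10/20 sites supports the cross-montage
validation design, which only needs the two processing paths to share the
19 channels. Old temporal-chain names (T3/T4/T5/T6) are mapped to their
modern equivalents (T7/T8/P7/P8) on EDF read; mastoid channels are read but
fall out at montage subsetting.

## Cross-montage and segment reliability

Features are computed twice per healthy subject: from all high-density
channels, and from the 19-channel subset taken *before* preprocessing, so
the low-density path (in particular its average reference) is processed
exactly like clinical data. Per feature, estimates are associated across
subjects: Shapiro–Wilk is applied to each marginal, and if either p < 0.05
the association is Spearman's rho, otherwise Pearson's r ("bivariate
normality" via an OR-gate on the marginals — a conservative reading, since
the exact multivariate test is not canonical). Features with p < 0.05 are
selected; no multiple-comparison correction is applied across the eight
features, deliberately mirroring the selection-at-raw-p design this package
reimplements. The same machinery compares features from the first 10 versus
the first 5 minutes of a recording (segment reliability).

## Statistical inference

**CCA.** Clinical variables (age, total GCS, CT grade, days since injury)
versus the validated EEG features. Columns are standardized; weights come
from the QR/SVD solution; variates have unit sample variance. Significance
uses a max-statistic randomization test: 2000 row shuffles of the clinical
set, each recording the *largest* canonical correlation, and the p-value of
observed pair *i* is the plain proportion of null maxima strictly exceeding
its correlation. Using the maximum makes the test valid for every pair
without step-down corrections (p-values are automatically non-decreasing
across pairs). The plain proportion (not `(b+1)/(P+1)`) is used
deliberately; with 2000 permutations the difference is at most 5e-4.
Loadings are Pearson correlations of each variable with the opposite set's
first variate.

**Prognosis.** GOSE (1–8) is rank-inverse-normal transformed with the Blom
constant, `z_i = qnorm((r_i - 3/8)/(n + 1/4))` (the constant is an argument;
Blom is the common default among rank-INT variants). Stepwise linear
regression with entry p = 0.05 and removal p = 0.10: forward-add the
candidate with the smallest partial-F p-value, backward-remove anything at
or above the removal threshold, iterate to a fixed point. Candidates are the
EEG features plus five clinical variables — the four CCA variables and sex
coded 0/1 (the fifth regression candidate; configurable). Cases with missing
outcome or predictors are removed listwise and logged. Reported:
standardized betas (z-scored outcome and predictors), raw coefficients,
adjusted R², the model F with its df pair, a per-step log, and R² change
against any nested reduced model refit on the identical case set.

## The synthetic generator

`simulate_eeg` builds, per band, narrowband Gaussian sources (white noise
through a zero-phase 4th-order Butterworth band-pass). In the coupled band,
the k-th channel of a module (0-based, sorted labels) receives
`sqrt(c) * rotate(driver, k * lag_deg) + sqrt(1-c) * independent noise`,
where `rotate` multiplies the driver's analytic signal by `exp(i*theta)` —
a pure non-zero lag, exactly what a phase-lag index is designed to detect.
Channel signals are weight-summed with a 1/f background (white noise shaped
to amplitude slope −1), then mixed with zero lag:
`x <- (1-m) x + m W x` with Gaussian spatial weights — the volume-conduction
confound that dwPLI must ignore, and demonstrably does (mixing at m = 0.5
changes median dwPLI by well under 0.05).

What the generator does *not* emulate: a forward head model with
sub-cortical sources, non-stationarity, real artifact morphology (only a
spike-injection helper exists, to test rejection), heteroscedastic channel
noise. Passing tests therefore show that the estimators recover the imposed
statistical structure, not that clinical recordings satisfy that structure.

One generator-specific finding is documented rather than hidden: with this
contract, a cleanly segregated two-module alpha network yields a *lower*
participation-coefficient SD than a single module whose channels form one
long phase ring (uniformly low participation versus heterogeneous hubs).
The test suite asserts this consistent, explainable contrast; the intuition
that "more modules mean more participation spread" does not hold under a
pure phase-lag generator.

`simulate_cohort` draws age ~ U{18..90}, total GCS ~ U{3..11} (all patients
below command-following), CT grade ~ U{1..6}, days since injury ~ U{3..24},
sex male with probability 0.8 (matching the bundled cohort's imbalance), and
a latent alpha level `alpha_target ~ N(0,1)`. Latent health is
`effect_gcs * z(gcs) + effect_alpha * z(alpha_target) + N(0, noise_sd)`,
cut at seven thresholds (defaults: equal-probability normal quantiles of
the latent scale) to give GOSE 1–8; the 6-month outcome re-thresholds the
latent value plus extra noise at half the residual SD. Each patient's EEG
gets alpha weight `plogis(alpha_target)` scaled into the weight budget left
by the other bands, so extracted relative alpha power increases
monotonically with the latent level (empirically r > 0.95 at 30-s
recordings).

### Synthetic healthy cohorts for the reliability experiments

The two reliability experiments need 20 high-density subjects whose features
genuinely vary between subjects (a correlation across subjects is
meaningless otherwise). Two designs are used, both with a per-subject alpha
level (band weight 0.15–0.65) and coupling strength, both coupling alpha
and delta:

* **Ring** (cross-montage validation): one global module whose channel
  copies step around a phase ring (k × 45°). Every channel pair carries a
  non-zero lag, so band power and the median dwPLI are strong and highly
  reliable across montages — the graph features, by contrast, have no
  unique partition (a phase ring can be cut anywhere) and validate poorly,
  which mirrors the empirical finding that power and median connectivity
  survive the montage reduction much better than the graph summaries.
* **Wedge** (10-vs-5-minute reliability): 2–5 spatially contiguous
  azimuthal wedge modules per subject, so the *true* modular geometry —
  and with it modular span, participation spread, clustering and
  modularity — differs across subjects and is stably recoverable from
  either recording length.

## Problem sizes and numerical choices

Simulated experiments use sizes chosen to exercise every code path at
desk scale: 128 Hz sampling for synthetic data (the band ceiling of 45 Hz
needs only a 96 Hz rate; clinical EDFs at 256/512 Hz are of course read as
recorded), 5-minute default recordings (matching the typical usable length
of acute clinical recordings), 30-second recordings inside the 20-cohort
parameter-recovery experiment, and 30 Louvain restarts per density inside
the 20-subject reliability experiments (the exported default is 100
restarts; at 91 nodes the best-of-30 modularity is already stable to ~1e-3).
Permutation-test calibration uses 500 null cohorts of n = 40 with 3 + 3
variables at 200 permutations each.

Other numerical conventions: dwPLI denominator 0 maps to estimate 0;
density thresholding breaks weight ties by lexicographic pair order;
community detection derives one sub-seed per density from the caller's
seed; `fit_cca` refuses rank-deficient sets naming the collinear columns;
`rank_inverse_normal` refuses all-equal input (no ordering information);
stepwise regression refuses nothing but reports an explicit `empty` flag
when no candidate enters.

## Known limitations

* The modular-span formula and the 10 %-step density grid are package
  choices behind prose-level descriptions; other implementations of the
  same prose may differ numerically.
* The high-density montage is idealized; real cap geometry will change
  modular span values (but not the validation design).
* The stepwise procedure inherits all the usual caveats of p-value-driven
  selection at n = 18; it is reimplemented here because it is the procedure
  under study, not because it is recommended.
* Six-month models use whatever cases have a 6-month outcome; the case
  count is logged rather than forced to match any external report.
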