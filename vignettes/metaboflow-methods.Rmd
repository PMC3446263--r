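---
title: "Post-deconvolution untargeted LC-MS metabolomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-deconvolution untargeted LC-MS metabolomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboflow)
```

## Scope

`metaboflow` implements the computational stages that follow peak
deconvolution in an untargeted LC-MS serum metabolomics experiment with a
pooled-QC design: signal correction, quality assurance, exploratory PCA,
non-parametric differential testing with cross-study replication, and a
bootstrapped differential-correlation ("reversal") analysis designed to
detect treatment-associated restoration of metabolite-metabolite
correlations. Raw-file conversion, peak picking and retention-time
alignment are upstream of this package: the pipeline starts at a
feature-by-injection peak-area table.

The intended experimental frame is a rodent model of insulin-deficient
(streptozotocin-induced) diabetes treated with the copper(II)-selective
chelator triethylenetetramine (TETA), with four biological groups —
non-diabetic untreated (`ND_UT`), non-diabetic treated (`ND_TETA`),
diabetic untreated (`DM_UT`) and diabetic treated (`DM_TETA`) — measured
in two independent studies. Nothing in the code is specific to that frame
beyond the group labels.

## Data model and missingness

A `feature_table` couples feature metadata (m/z, retention time, ion
mode), a non-negative peak-area matrix and an injection manifest. Missing
measurements are stored as `NA` and never conflated with zero peak areas.
Downstream stages then apply the conventions of this analysis style
explicitly: rank-based statistics exclude missing values pairwise, while
PCA replaces them by 0. The zero-for-PCA convention slightly biases
feature variances, but missingness in these tables is predominantly
left-censoring at the detection limit, for which zero is the natural
bound; it is kept as a deliberate fidelity choice rather than replaced by
model-based imputation.

## QC-RLSC signal correction

Instrument response in an LC-MS run drifts slowly with injection order.
Because every pooled-QC injection is chemically identical, a feature's QC
intensities trace the drift. `fit_qc_trend()` fits a robust
(iteratively-reweighted, `family = "symmetric"`) loess of QC intensity on
injection order and evaluates it at every injection;
`qc_rlsc_correct()` divides each measurement by the trend and rescales to
the feature's median raw QC intensity. The contract is
QC-anchored-smooth-trend, divide and rescale; the loess internals are
configurable because no single span is canonical:

* `span` defaults to 0.6 of the QC points; local degree defaults to 2.
  With fewer than 8 usable QC points the degree drops to 1 and the span
  widens so each local window still determines the fit. Fewer than 4
  usable QC points is treated as uncorrectable and the feature is dropped
  with a reason.
* Outside the QC-anchored order range the trend is held at its boundary
  value: extrapolating a polynomial beyond the anchors is less defensible
  than assuming the drift freezes.
* Fitted trends are clipped to be strictly positive, since a trend
  crossing zero would flip the sign of corrected intensities.

Correction is applied per (study, ion mode) run; runs are never
normalized against each other, because cross-study agreement is assessed
by replication of *results*, not by pooling data.

The QA filter then retains a feature only if it is detected (non-missing,
positive) in more than 60% of QC injections from injection 8 onward
(earlier QC injections condition the column) and its QC relative standard
deviation is below 20%. Both inequalities are strict.

## Univariate stage

Group comparisons use the Mann-Whitney U test on per-feature intensities,
with U computed from midrank sums. For combined samples of at most 20
observations the two-sided p-value is exact: the permutation null of U is
enumerated over all C(n1+n2, n1) group assignments of the pooled
midranks, which handles ties exactly. The two-sided p is defined as
P(|U − n1·n2/2| ≥ |u_obs − n1·n2/2|) under that enumeration. Beyond 20
observations the normal approximation with tie and continuity correction
(`stats::wilcox.test`) takes over. Enumerated null distributions are
cached by midrank multiset, so a 2,000-feature comparison with tie-free
data pays the enumeration cost once.

Fold-changes are ratios of group medians (consistent with a rank test;
means are one flag away). No multiple-testing adjustment is applied by
default: the design controls false positives by requiring a feature to be
significant (p < 0.05) in **both** independent studies with the same
direction of change (`replication_filter()`). Under two independent null
studies this replication criterion has an expected pass rate of roughly
alpha squared over two, which the acceptance checks verify by simulation.
Benjamini-Hochberg adjustment is available behind a flag.

## PCA and outlier flagging

`pca_scores()` centres and scales every feature to unit variance (after
the zero-for-missing substitution, dropping zero-variance features) and
returns scores, orthonormal loadings and explained-variance fractions of
the leading components. Signs are fixed by making each loading's
largest-magnitude entry positive so results are reproducible across
feature orderings.

The one subjective step in this analysis style — spotting a failed
injection on a score plot — is made reproducible by `flag_outliers()`: an
injection whose total non-missing peak area lies more than 5 MADs below
the median biological total is flagged. Flagging is advisory; removal
happens only when the pipeline is configured to act on it
(`act_on_outliers = TRUE`), since such removals should be deliberate and
visible.

## Bootstrapped Spearman reversal cascade

For each of the three groups of interest (untreated controls, untreated
diabetics, treated diabetics) and every unordered feature pair with at
least 6 complete observation pairs, `bootstrap_rho()` resamples the
complete pairs with replacement 100 times, computes the Spearman
coefficient of each resample (degenerate resamples with fewer than 3
distinct pairs or zero rank variance are redrawn) and aggregates by the
median. The median was chosen as the aggregate because it is robust to
the occasional wild resample at n = 10; the mean gives nearly identical
results. Note that resampling with replacement induces rank ties, which
attenuates the aggregate slightly toward zero relative to the single
full-sample coefficient; this is a property of any bootstrap of a
rank statistic at small n.

A pair shows the reversal pattern when

1. |rho| > 0.5 in untreated controls,
2. the coefficient changes by more than 0.5 between untreated controls
   and untreated diabetics, and
3. |rho| > 0.5 again in treated diabetics.

Pairs whose two features are assigned to the same metabolite are removed
(adduct/isotopologue siblings of one metabolite are trivially correlated),
and a feature is reported only when it shows the pattern with at least 10
*different partner metabolites* — degree counts metabolites, not features.
The full pairwise analysis is O(F²): for F = 3,610 and F = 1,983 eligible
features the candidate pair counts are 6,514,245 and 1,965,153; desk-scale
runs should cap the feature set (≤ ~2,000) before this stage.

## Putative annotation

Annotation is deliberately simple and confers putative
(Metabolomics Standards Initiative level-2) status only. Charge states
are assigned from isotopologue m/z spacings: z is the integer (up to 4)
minimizing |spacing − 1.003355/z| Da, unknown if the best residual
exceeds 0.01 Da. Neutral masses are reconstructed per adduct hypothesis
([M+H]⁺, [M+Na]⁺, [M+NH₄]⁺ in positive mode; [M−H]⁻, [M+formate]⁻ in
negative mode; configurable) and matched against a user-supplied
reference table within ±5 ppm, with optional retention-time windows; all
surviving isomers are reported. Features sharing a unique top candidate
and co-eluting within 5 s (a declared default; co-elution tolerances are
instrument-dependent) are grouped under one metabolite, which feeds the
same-metabolite pair-removal rule above. When the synthetic generator is
used, the ground-truth feature-to-metabolite map can be passed directly
so correlation-stage results are not hostage to annotation accuracy.

## The synthetic-data generator

`generate_study()` emulates the study design the pipeline targets, and
its defaults are the study conditions, not tuning knobs:

* Group sizes: study 1 = 9/6/9/6, study 2 = 10 per group; pooled-QC
  schedule of ten conditioning QCs, a QC every fifth injection, and two
  closing QCs, with biological samples randomized over the remaining
  slots.
* Metabolite baselines are log-normal (median 1e5 arbitrary area units,
  log-sd 1); between-animal biological variation is log-normal with
  log-sd 0.3.
* Each metabolite emits 1-3 features with probabilities (0.5, 0.3, 0.2)
  and proportional response factors, emulating adduct redundancy.
* Diabetes effects multiply the two diabetic groups of selected
  metabolites by fold-changes drawn from [1.5, 5] (inverted with
  probability one half).
* Reversal blocks receive a shared per-sample latent factor (log-sd 0.5)
  in `ND_UT`, `ND_TETA` and `DM_TETA`, and independent per-metabolite
  variation of the same magnitude in `DM_UT`. `within_block_rho` is the
  target *observable feature-level rank correlation*: the latent Pearson
  correlation is set to 2·sin(π·rho/6) (the rank-to-Pearson conversion
  for Gaussian copulas) inflated by (1 + σ²_noise/σ²_latent) to undo
  measurement-noise attenuation, capped at 0.999.
* Drift is a per-feature random cubic in normalized injection order,
  rescaled to a maximum fractional deviation of `drift_amplitude`
  (default 0.2) — smoothness is the only drift property QC-RLSC assumes,
  so a low-order polynomial is the least-committal choice. Measurement
  noise is multiplicative log-normal with CV 0.1. The magnitudes of
  drift and missingness in the motivating experiments are unreported;
  these defaults are declared free parameters of the emulation, not
  calibrated claims.
* Missingness is left-censoring: values below the `missing_rate` quantile
  (default 0.05) of the run's intensities become missing, reflecting
  detection limits.
* QC injections carry the feature-wise mean of the biological signal
  (a pooled sample), subject to the same drift and noise.

What the generator does **not** emulate: chromatographic peak shape,
isotope envelopes as signals, correlated (matrix-effect) noise across
features, retention-time drift, or batch effects beyond the smooth
within-run drift. Tests passing on synthetic data therefore validate the
statistical machinery and its contracts, not robustness to every artefact
of real spectra.

## Numerical choices and degenerate inputs

* Exact-test cutoff at combined n = 20; above it the approximation's
  error is far below analytic relevance at these sample sizes.
* Spearman coefficients are undefined below 3 complete pairs, and pairs
  below 6 complete observations are excluded from the correlation stage
  entirely (the "minimum 6 versus 6" rule, binding for the smallest
  groups).
* Ratio direction is "none" when a group median is zero or undefined.
* QA detection treats zero peak areas as non-detection; storage keeps
  zero and missing distinct so this remains an explicit rule.
* All stochastic stages take explicit seeds; the pipeline derives stage
  seeds deterministically from one master seed, so a run is reproducible
  bit for bit while QA verdicts on fixed input are seed-invariant.

## Validation problem sizes

The packaged checks run the null calibration at 2,000 features with 10
animals per group, the drift benchmark at ~85 features with drift
amplitude 0.3 and noise CV 0.05, and the reversal recovery at a single
12-metabolite block (target rank correlation 0.9, 10 animals per group,
10 seeds) against a 50-feature global null. These sizes were chosen to
make the statistical contracts measurable with Monte-Carlo error well
below the asserted margins while remaining desk-scale.

One recovery property deserves honesty: with 10 animals per group, the
sampling spread of a null Spearman coefficient is ≈ 1/3, so the
|rho_ND − rho_DM| > 0.5 cascade condition fails by chance for a
noticeable fraction of truly reversed pairs. A feature of a 12-metabolite
block must pass with 10 of its 11 partner metabolites to reach the degree
threshold, so per-dataset recall of block features is ~0.6-0.9, not 1 —
a small-sample property of the cascade itself, not an implementation
artefact. Larger blocks (more partners than the degree threshold needs)
or larger groups push recall toward 1. Partner *purity* — the fraction of
a recovered feature's partners that are genuinely within-block — is
consistently above 0.9 at these sizes.
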