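---
title: "Methods: multimodal brain-behavior association with PLS correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal brain-behavior association with PLS correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plsbrain)
```

## The scientific problem

Lesional therapies for Parkinson's disease — here, unilateral
focused-ultrasound subthalamotomy — produce motor improvements that vary
widely between patients. Two questions drive the analysis this package
implements: can multimodal brain imaging *before* treatment predict who
will respond, and which *treatment-induced* brain changes travel with the
clinical outcome? Both are questions about the joint covariance of two
blocks measured on the same subjects:

* an **imaging block** `X` (n subjects × p features): four regional
  measures — fALFF and ReHo from resting-state fMRI, and gray-matter
  density and Jacobian-determinant atrophy from structural MRI — over 104
  brain regions (70 cortical, 16 subcortical, 18 cerebellar), with
  hemispheres relabeled *treated side* (TS) / *untreated side* (US) so
  that left- and right-treated patients are comparable;
* a **clinical block** `Y` (n × 5): percent changes, baseline to month 4,
  of the MDS-UPDRS III total, treated-side total, rigidity, akinesia and
  tremor scores. Negative values are improvements.

## The model

PLS correlation finds paired unit vectors ("saliences") `u` (imaging) and
`v` (clinical) maximizing `cov(X u, Y v)`. With both blocks residualized
on covariates (age, gender as 0/1, disease duration) and standardized
column-wise (unbiased n−1 SD), every pair is given at once by the SVD of
the cross-block matrix

```
R = Y' X / (n - 1),    R = V S U'.
```

Each paired column of `U`, `V` is a latent variable (LV); its singular
value `s_k` is the covariance it captures and `s_k² / Σ_j s_j²` the
fraction of explained covariance. The per-subject latent scores are
`X u_k` and `Y v_k`. With 5 outcomes the decomposition has at most 5
components. Sign indeterminacy is resolved deterministically by making
the largest-magnitude clinical salience of each component positive.

We deliberately implement the correlation (symmetric) flavor of PLS, not
regression PLS: the scientific claim is about shared covariance, not
out-of-sample prediction, and no cross-validated prediction is offered.

### Covariate handling

Covariates are regressed out of *both* blocks before standardization —
the conservative symmetric choice when the nuisance structure may touch
imaging and outcomes alike. Residualization uses ordinary least squares
against `[1, age, gender, duration]`; a rank-deficient design is an error
naming the collinear columns.

## Inference

### Permutation family-wise p-values

Significance of the LVs uses a permutation null with the **max-statistic**
family-wise correction: for each of P permutations the clinical block is
permuted against the fixed imaging block, the decomposition re-run, and
the maximum singular value recorded;

```
fwe_p(k) = (1 + #{perm : max_j s_j^perm >= s_k}) / (1 + P)
```

(the add-one estimator keeps p ≥ 1/(P+1)). Because `s_k` is non-increasing
in `k`, these p-values are automatically monotone across components.

A numerical subtlety decides *where* rows are shuffled. After
residualization the observed residuals of both blocks lie in the same
(n − 1 − c)-dimensional subspace orthogonal to the covariate columns;
naively shuffling residual rows in subject space produces permuted vectors
outside that subspace, whose cross-covariance with the imaging residuals
is systematically smaller than the observed one. In our null simulations
that scheme rejected LV1 at rate 0.17 instead of 0.05. The default
(`permute = "residual"`) therefore rotates both processed blocks into an
orthonormal basis of the covariate orthocomplement — which leaves the
observed statistic unchanged — and shuffles the reduced clinical rows,
which *are* exchangeable under the null (exact under rotationally
invariant noise). Measured empirical FWE under the null is 0.053. A
`permute = "raw"` switch re-runs the whole chain on shuffled raw clinical
rows instead.

### Bootstrap salience ratios

Feature reliability uses subject-level bootstrap (resampling rows with
replacement, re-running the full chain). Resampled saliences are aligned
to the original fit by orthogonal Procrustes rotation of the
5-dimensional clinical basis, with the same rotation applied to the
imaging side — without alignment, sign and axis flips between resamples
inflate the spread. Per element we report

* the bootstrap SE and the **bootstrap ratio** (original salience / SE), a
  pseudo-z importance measure;
* the percentile 95% CI and a robustness flag (CI excludes zero).

Resamples in which a column becomes constant are handled by centering that
column to zero; the count of such events is reported. The **top 5%** of
features by |bootstrap ratio| (ceiling rule: 21 of 416; ties broken by
column order) are reported as most influential, by default intersected
with the robustness flags. **Modality contributions** are the per-modality
sums of |bootstrap ratio| over selected features, normalized to sum to 1
(a modality with no selected feature is exactly 0); a `"mean"` switch
normalizes per-modality means instead — the two differ only when selected
counts differ across modalities.

### Defaults

| parameter | default | why |
|---|---|---|
| `n_permutations` | 1000 | conventional resolution, p down to ~0.001 |
| `n_bootstrap` | 1000 | SE stable to a few percent |
| `alpha` | 0.05 | FWE level for calling LVs significant |
| `top_fraction` | 0.05 | "top 5%" reporting convention |
| band | 0.01–0.08 Hz | canonical resting-state band |
| `drop_initial` | 10 volumes | scanner equilibration |

One master seed drives the fit; permutation and bootstrap use independent
child seeds derived from it, so changing one stage's count does not
perturb the other.

## Regional fMRI metrics

**fALFF** is the fraction of a series' spectral amplitude inside
0.01–0.08 Hz: square roots of periodogram power summed over in-band
frequency bins, divided by the sum over all positive-frequency bins. It is
computed on detrended, confound-regressed but **not** band-pass filtered
series — on band-limited data the ratio is identically 1, so the band-pass
step of the conditioning chain is opt-in and feeds only
connectivity-style metrics such as ReHo. An identically-zero series
returns 0 by convention. For a white-noise series the expected value is
the in-band bin fraction, (0.08 − 0.01)/0.25 ≈ 0.28 at TR = 2 s.

**ReHo** is Kendall's coefficient of concordance among the time-series of
a voxel's 3×3×3 neighborhood (27 voxels in the interior, clipped at the
boundary), with the standard tie correction:
`W = 12 S / (K²(t³ − t) − K T)`. Regional ReHo is the mean of voxel-wise
`W` within the region (the alternative — one `W` over all regional voxels
jointly — is not implemented; the voxel-wise mean is the common choice in
the ReHo literature). `W = 1` for identical series; `E[W] = 1/K` under
independence; all-constant neighborhoods return the degenerate sentinel 1
with a warning.

**Gray-matter density and atrophy** enter as caller-supplied voxel maps
(modulated segmentations, Jacobian determinants) summarized by per-region
means over a label volume; the package performs no registration,
segmentation or deformation estimation, and assumes index-aligned arrays.
Atrophy values are, by the field's convention, mostly negative (volume
loss).

**Side flipping** swaps homologous L/R column pairs for right-treated
subjects and relabels all columns TS/US. Midline regions (e.g. cerebellar
vermis) have no homologue and pass through unswapped with side label
`mid`. Flipping is a column permutation per subject, so per-subject value
multisets are preserved.

## Clinical statistics

Percent change is `(score_month4 − score_baseline)/score_baseline × 100`,
computed **per subject and then averaged** (the mean-of-ratios
convention; the ratio of group means is a different number and is not
used). A zero baseline makes the cell undefined: it is flagged missing
with a warning, the subject retained, and summary means computed pairwise
with an explicit n column. Before/after comparisons are classical paired
t-tests (df = n − 1); zero-variance differences are flagged degenerate
rather than producing a spurious statistic.

## The synthetic cohort generator

Real trial data of this kind are confidential, so validation runs on
synthetic cohorts with a *planted* latent association — the exact
generative model under which PLS-SVD is the natural estimator:

```
X = Σ_k s_k t_k u_k' + C B_x + E_x
Y = Σ_k s_k t_k v_k' + C B_y + E_y
```

with standard-normal latent scores `t_k` per subject, unit salience
vectors `u_k` (sparse by default, 30 of 416 features), `v_k`, standardized
covariates `C` with Gaussian random coefficients, and isotropic Gaussian
noise. The latent-scale imaging block is mapped affinely onto raw feature
values per modality with offsets ~10 SD from zero, then clamped, so sign
conventions hold (atrophy ≤ 0, the rest ≥ 0) while the linear structure is
essentially untouched. The continuous clinical outcome block is mapped
onto percent changes with the per-score means and SDs of the emulated
trial's descriptive table (e.g. total −40.0 ± 18.0, tremor −74.0 ± 30.5),
combined with integer baseline scores (37.6 ± 8.0 total, etc., clipped to
plausible MDS-UPDRS ranges with a floor of 1 so percent change is defined)
to yield the month-4 table. Month-4 imaging features drift from baseline
by a latent-linked component on its own salience vector (coupling 0.5)
plus small noise (SD 0.25), reflecting the small longitudinal imaging
variances such trials show. Demographics are drawn from the emulated
cohort's profile (age 56.6 ± 9.5, 22/13 male/female, duration
7.2 ± 2.8 y, 16/35 right-treated).

The default effect size (`singular_strength = 6`) makes the leading LV
carry roughly 80% of the sample cross-covariance at n = 35 — the regime
the emulated analysis reports. Everything is reproducible from the config
seed.

What the generator does **not** emulate: spatial autocorrelation between
regions, non-Gaussian and heteroscedastic imaging noise, site/scanner
effects, registration error, lesion geometry, and item-level clinical
scoring. Passing tests therefore validate the statistical machinery under
its own model assumptions, not the behavior of the pipeline on real MRI
data.

### Validation scenarios and numerical choices

* **SVD correctness** is checked against independent dense
  eigendecompositions (tolerance 1e−8); salience orthonormality to 1e−10;
  explained-covariance fractions sum to 1.
* **Calibration** uses 200 null cohorts (no planted signal) at the study
  size with 200 permutations each; the empirical rate of
  `fwe_p(LV1) ≤ 0.05` must fall in the exact binomial 95% envelope
  [0.022, 0.089].
* **Recovery** uses 50 planted rank-1 cohorts at n = 200 with strength 5,
  which places the observed `s₁` at ≥3× the null 95th percentile (the
  null percentile is re-estimated by simulation inside the test).
  Validation scenarios plant *equal-magnitude* support weights: column
  standardization rescales each feature by its own SD, so the estimand is
  the standardized-model salience — for unequal planted weights the two
  directions differ, and recovery would be measured against the wrong
  target. With flat weights the planted direction is invariant under
  standardization. Cosines ≥ 0.9 on both blocks are required in ≥ 90% of
  replicates, and planted-zero features' bootstrap CIs must cross zero.
* Simulation sizes throughout (200 × 200 calibration, 50 × B = 200
  recovery, 2000 white-noise fALFF series, 60 ReHo null replicates) were
  chosen to keep Monte-Carlo error comfortably below the asserted
  tolerances at a few minutes of single-core compute.
* Degenerate inputs have defined behavior rather than silent output:
  constant columns error in `zscore_columns` (and are recentered with a
  count in bootstrap resamples), zero baselines flag missing outcomes,
  all-constant ReHo neighborhoods return the sentinel 1 with a warning,
  zero series give fALFF 0, band edges at or above Nyquist error naming
  the TR.

## Worked example

```{r example, fig.width = 5, fig.height = 4}
coh <- generate_cohort(cohort_config(seed = 7))
analysis <- run_analysis(coh, "baseline", n_permutations = 200,
                         n_bootstrap = 200, seed = 7)
analysis
summary(analysis$fit)$contribution
plot(analysis$fit)
```

The printed table lists, per LV, the singular value, explained covariance
fraction and FWE p-value; the contribution vector splits the selected
top-5% features' total |bootstrap ratio| across the four modalities; the
plot is the per-subject latent-score scatter of LV1.

## Known limitations

* In-sample association only; latent scores on new subjects via
  `predict()` reuse training centering/scaling and covariate coefficients
  but no predictive performance claims are made.
* The reduced-basis permutation scheme is exact under rotationally
  invariant residual noise; heavy-tailed noise makes it approximate.
* Regional ReHo and the fALFF-before-filtering choice follow one reading
  of common practice; both are surfaced as explicit arguments rather than
  hidden defaults.
* Bootstrap SEs at n = 35 with 416 features are noisy; the bootstrap
  ratio is a ranking device, not a calibrated z-statistic.
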