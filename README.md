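# plsbrain

Brain–behavior association analysis for treatment studies: links
multimodal regional brain-imaging profiles to clinical outcomes with
**partial least squares correlation (PLS-SVD)**, permutation-based
family-wise inference and bootstrap salience ratios. The package was
built around the analysis design of unilateral focused-ultrasound
subthalamotomy trials in Parkinson's disease — four imaging modalities
(fALFF, ReHo, gray-matter density, gray-matter atrophy) over 104 brain
regions, five treated-side motor outcomes — but the machinery is generic
for any two-block subjects × features design.

It is aimed at neuroimaging statisticians who want a tested, scriptable
re-implementation of this analysis family: regional resting-state metrics,
treated-side flipping, clinical percent-change statistics, the PLS
inference engine, and a synthetic-cohort generator with a planted latent
association for validating the whole chain (the original patient data of
such trials are confidential).

## The model

With imaging block `X` (n × p) and clinical block `Y` (n × q), both
residualized on covariates (age, gender, disease duration) and
standardized column-wise, PLS correlation decomposes the cross-block
matrix

    R = Yᵀ X / (n − 1),   R = V S Uᵀ

Each paired column of `U` (imaging saliences) and `V` (clinical
saliences) is a latent variable; its singular value `s_k` measures the
imaging–clinical covariance it captures, `s_k² / Σ s_j²` the fraction of
explained covariance, and `X u_k`, `Y v_k` are per-subject latent scores.
Component significance is a permutation FWE p-value under the
max-singular-value null; feature reliability is the bootstrap ratio
(salience / bootstrap SE) with percentile CIs, Procrustes-aligned across
resamples. The top 5% of features by |bootstrap ratio| and their
per-modality contribution fractions summarize each significant component.

## Worked example

```r
library(plsbrain)

coh <- generate_cohort(cohort_config(seed = 7))   # 35 subjects, 416 features
analysis <- run_analysis(coh, "baseline", n_permutations = 200,
                         n_bootstrap = 200, seed = 7)
analysis
```

```
Analysis (baseline features vs clinical outcomes)

PLS correlation: 416 imaging features x 5 clinical outcomes, n = 35
    singular_value covariance_explained    fwe_p
LV1         9.4309               0.8826 0.004975
LV2         2.1890               0.0475 1.000000
LV3         1.8899               0.0354 1.000000
LV4         1.6025               0.0255 1.000000
LV5         0.9509               0.0090 1.000000
```

One latent variable dominates: it explains 88% of the imaging–clinical
cross-covariance and no permutation produced a larger leading singular
value (p = 1/201, the minimum at 200 permutations). Its modality split
over the selected top-5% features:

```r
summary(analysis$fit)$contribution
```

```
     fALFF       ReHo GM_atrophy GM_density
 0.3061651  0.2141701  0.2245099  0.2551549
```

i.e. 31% of the selected importance sits in fALFF features and 26% in
gray-matter density, mirroring how such contribution tables are read.
`plot(analysis$fit)` draws the LV1 latent-score scatter;
`summary(analysis$fit)$top_features` lists the selected features with
region, side (treated/untreated), bootstrap ratio and CI;
`write_results(analysis, "results/")` writes every table (saliences,
bootstrap ratios, CIs, permutation null, contributions, latent scores,
clinical descriptives) as round-trippable CSV plus a run manifest.

Clinical descriptives and paired before/after t-tests:

```r
analysis$clinical$summary   # mean ± SD per score and visit, % changes
analysis$clinical$paired    # paired t, df, p per score
```

A thin command-line front end ships in `inst/scripts/plsbrain`
(`simulate | features | analyze`).

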