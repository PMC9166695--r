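Package: plsbrain
Title: Brain-Behavior Association by Partial Least Squares Correlation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate association analysis between multimodal regional
    brain-imaging features and clinical treatment outcomes, as used in
    neuroimaging studies of focused-ultrasound subthalamotomy for
    Parkinson's disease. Implements partial least squares correlation
    (PLS-SVD) on the imaging-clinical cross-covariance with covariate
    residualization, permutation-based family-wise-error inference on the
    latent variables, bootstrap salience ratios with percentile confidence
    intervals, top-fraction predictor selection and per-modality
    contribution summaries. Also provides regional resting-state fMRI
    metrics (fractional amplitude of low-frequency fluctuation, regional
    homogeneity via Kendall's coefficient of concordance), gray-matter
    summaries, treated-side flipping, clinical percent-change statistics,
    and a synthetic-cohort generator with a planted low-rank latent
    association for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
Config/testthat/edition: 3
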