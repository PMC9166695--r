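#' Run a full brain-behavior association analysis on a cohort
#'
#' Orchestrates the two study designs on a two-visit cohort:
#' * `mode = "baseline"` — regional imaging features at baseline as
#'   predictors of the clinical percent-change outcomes;
#' * `mode = "changes"` — month-4 minus baseline feature changes against
#'   the same outcomes.
#'
#' Features of right-treated subjects are mirrored onto a common
#' treated/untreated-side orientation ([flip_sides()]), outcomes are the
#' per-subject percent changes ([percent_change()]), and the association is
#' fitted with [plsc()] (covariate residualization, standardization,
#' cross-covariance SVD, permutation FWE inference, bootstrap salience
#' ratios, top-fraction selection and modality contributions).
#'
#' @param cohort a `synthetic_cohort` (from [generate_cohort()] or
#'   [read_cohort()]) or a list with the same table fields.
#' @param mode `"baseline"` or `"changes"`.
#' @param n_permutations,n_bootstrap,alpha,top_fraction,seed,permute,contribution
#'   passed to [plsc()].
#' @param flip mirror right-treated subjects' features (default TRUE).
#' @return List of class `plsc_analysis`: `fit` (the [plsc] object),
#'   `clinical` (paired tests and [cohort_summary()]), `outcomes`, `mode`,
#'   `features` (the analyzed, possibly flipped, feature table).
#' @export
run_analysis <- function(cohort, mode = c("baseline", "changes"),
                         n_permutations = 1000, n_bootstrap = 1000,
                         alpha = 0.05, top_fraction = 0.05, seed = NULL,
                         permute = "residual", contribution = "sum",
                         flip = TRUE) {
  mode <- match.arg(mode)
  fb <- cohort$features_baseline
  fm <- cohort$features_month4
  if (flip && !is.null(cohort$treated_side)) {
    fb <- flip_sides(fb, cohort$treated_side)
    if (!is.null(fm)) fm <- flip_sides(fm, cohort$treated_side)
  }
  features <- if (mode == "baseline") fb else {
    if (is.null(fm)) stop("mode = 'changes' needs month-4 features")
    compute_changes(fb, fm)
  }
  outcomes <- percent_change(cohort$clinical_baseline, cohort$clinical_month4)
  if (anyNA(outcomes)) {
    drop <- apply(unclass(outcomes), 1, anyNA)
    warning("dropping ", sum(drop),
            " subject(s) with undefined percent change (zero baseline)")
    keep <- !drop
    outcomes <- structure(unclass(outcomes)[keep, , drop = FALSE],
                          class = "outcome_table")
    features <- feature_table(as.matrix(features)[keep, , drop = FALSE],
                              annotations(features))
    cohort$covariates <- cohort$covariates[keep, , drop = FALSE]
  }
  fit <- plsc(features, outcomes, cohort$covariates,
              n_permutations = n_permutations, n_bootstrap = n_bootstrap,
              alpha = alpha, top_fraction = top_fraction, seed = seed,
              permute = permute, contribution = contribution)
  clinical <- list(
    paired = paired_tests(cohort$clinical_baseline, cohort$clinical_month4),
    summary = cohort_summary(cohort$clinical_baseline, cohort$clinical_month4,
                             cohort$covariates, cohort$treated_side))
  structure(list(fit = fit, clinical = clinical, outcomes = outcomes,
                 mode = mode, features = features),
            class = "plsc_analysis")
}

#' @export
print.plsc_analysis <- function(x, ...) {
  cat("Analysis (", x$mode, " features vs clinical outcomes)\n\n", sep = "")
  print(x$fit)
  invisible(x)
}

#' Write all result tables of an analysis to a directory
#'
#' Emits `saliences_imaging.csv`, `saliences_clinical.csv`,
#' `bootstrap_ratios.csv`, `ci.csv`, `permutation.csv` (null distribution
#' plus p-values), `contributions.csv`, `latent_scores.csv`,
#' `clinical_summary.csv`, `paired_tests.csv`, a plain-text `summary.txt`
#' and a JSON `manifest.json` (configuration, seed, package version). All
#' numeric tables are written in full precision and round-trippable.
#'
#' @param analysis a [run_analysis()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_results <- function(analysis, dir) {
  stopifnot(inherits(analysis, "plsc_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fit <- analysis$fit
  m <- fit$model
  wcsv <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                           row.names = FALSE, quote = FALSE)
  fnum <- function(x) format(x, digits = 15, trim = TRUE)
  ann <- fit$annotations
  lvn <- paste0("LV", seq_along(m$singular_values))

  si <- data.frame(feature = rownames(m$imaging_saliences),
                   fnum(m$imaging_saliences), check.names = FALSE)
  colnames(si)[-1] <- lvn
  if (!is.null(ann)) si <- cbind(ann[c("modality", "region", "side")], si[-1])
  wcsv(si, "saliences_imaging.csv")
  sc <- data.frame(outcome = rownames(m$clinical_saliences),
                   fnum(m$clinical_saliences), check.names = FALSE)
  colnames(sc)[-1] <- lvn
  wcsv(sc, "saliences_clinical.csv")

  if (!is.null(fit$bootstrap)) {
    br <- data.frame(feature = rownames(m$imaging_saliences),
                     fnum(fit$bootstrap$imaging$ratio), check.names = FALSE)
    colnames(br)[-1] <- lvn
    wcsv(br, "bootstrap_ratios.csv")
    ci <- data.frame(feature = rownames(m$imaging_saliences),
                     ci_low = fnum(fit$bootstrap$imaging$ci_low[, 1]),
                     ci_high = fnum(fit$bootstrap$imaging$ci_high[, 1]),
                     robust = fit$bootstrap$imaging$robust[, 1])
    wcsv(ci, "ci.csv")
  }
  if (!is.null(fit$permutation)) {
    pm <- data.frame(permutation = seq_len(nrow(fit$permutation$null_singular_values)),
                     fnum(fit$permutation$null_singular_values),
                     check.names = FALSE)
    colnames(pm)[-1] <- lvn
    wcsv(pm, "permutation.csv")
    wcsv(data.frame(component = lvn,
                    singular_value = fnum(m$singular_values),
                    covariance_explained = fnum(m$covariance_explained),
                    fwe_p = fnum(fit$permutation$fwe_p)),
         "components.csv")
  }
  if (!is.null(fit$contribution))
    wcsv(data.frame(modality = names(fit$contribution),
                    contribution = fnum(fit$contribution)),
         "contributions.csv")
  ls <- data.frame(subject = rownames(m$scores_imaging),
                   fnum(m$scores_imaging), fnum(m$scores_clinical),
                   check.names = FALSE)
  colnames(ls)[-1] <- c(paste0("imaging_", lvn), paste0("clinical_", lvn))
  wcsv(ls, "latent_scores.csv")

  wcsv(analysis$clinical$summary$scores, "clinical_summary.csv")
  pt <- analysis$clinical$paired
  wcsv(cbind(score = rownames(pt), pt), "paired_tests.csv")

  con <- file(file.path(dir, "summary.txt"), "w")
  sink(con)
  print(analysis)
  cat("\n")
  print(summary(fit))
  cat("\n")
  print(analysis$clinical$summary)
  sink()
  close(con)

  jsonlite::write_json(
    list(mode = analysis$mode, seed = fit$seed,
         n_permutations = if (is.null(fit$permutation)) 0 else
           fit$permutation$n_permutations,
         n_bootstrap = if (is.null(fit$bootstrap)) 0 else
           fit$bootstrap$n_bootstrap,
         alpha = fit$alpha, top_fraction = fit$top_fraction,
         permute = fit$permute,
         package = "plsbrain",
         version = as.character(utils::packageVersion("plsbrain"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
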