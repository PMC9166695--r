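#' Regress covariates out of every column of a block
#'
#' Replaces each column by its least-squares residual on an intercept plus
#' the covariates, so the returned columns are orthogonal to the covariate
#' space. Gender factors are encoded 0/1.
#'
#' @param block subjects x columns numeric matrix.
#' @param covariates subjects x covariates matrix or data frame (may be
#'   `NULL` for centering only).
#' @return Residual matrix of the same shape. The fitted coefficient matrix
#'   (covariates + intercept) x columns is attached as attribute `coef` so
#'   new subjects can be residualized consistently.
#' @export
residualize <- function(block, covariates = NULL) {
  block <- as.matrix(block)
  design <- covariate_design(covariates, nrow(block))
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    drop <- colnames(design)[-(qrd$pivot[seq_len(qrd$rank)])]
    stop("covariate design is rank-deficient; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  fit <- stats::lm.fit(design, block)
  res <- as.matrix(fit$residuals)
  dimnames(res) <- dimnames(block)
  attr(res, "coef") <- fit$coefficients
  res
}

covariate_design <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  if (is.data.frame(covariates)) {
    covariates <- do.call(cbind, lapply(covariates, function(x) {
      if (is.factor(x) || is.character(x)) as.numeric(factor(x)) - 1
      else as.numeric(x)
    }))
  }
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != n)
    stop("covariates have ", nrow(covariates), " rows; expected ", n)
  cbind(intercept = rep(1, n), covariates)
}

#' Standardize block columns to zero mean and unit SD
#'
#' Uses the unbiased (n - 1) SD convention.
#'
#' @param block subjects x columns numeric matrix.
#' @return Standardized matrix with `center`/`scale` attributes; a constant
#'   column is an error (degenerate feature).
#' @export
zscore_columns <- function(block) {
  block <- as.matrix(block)
  ctr <- colMeans(block)
  sds <- apply(block, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    nm <- if (!is.null(colnames(block))) colnames(block)[bad] else bad
    stop("constant column(s), cannot standardize: ",
         paste(utils::head(nm, 10), collapse = ", "))
  }
  out <- sweep(sweep(block, 2, ctr), 2, sds, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- sds
  out
}

# tolerant variant for bootstrap resamples: degenerate columns are centered
# to zero and counted instead of erroring
zscore_columns_safe <- function(block) {
  block <- as.matrix(block)
  ctr <- colMeans(block)
  sds <- apply(block, 2, stats::sd)
  bad <- sds == 0
  sds[bad] <- 1
  out <- sweep(sweep(block, 2, ctr), 2, sds, "/")
  attr(out, "n_degenerate") <- sum(bad)
  out
}

#' Joint SVD of the imaging-clinical cross-covariance
#'
#' Decomposes the cross-block matrix `R = Y' X / (n - 1)` (clinical block
#' `Y` on the left, imaging block `X` on the right, both already
#' residualized and standardized) as `R = V S U'`. Each paired column of
#' `U` (imaging saliences) and `V` (clinical saliences) is a latent
#' variable (LV); its singular value measures the imaging-clinical
#' covariance it captures and `s_k^2 / sum s^2` the fraction of total
#' explained covariance. Sign convention: the largest-magnitude clinical
#' salience of every component is made positive.
#'
#' @param X subjects x features imaging matrix (residualized, z-scored).
#' @param Y subjects x outcomes clinical matrix (same subjects).
#' @return A list of class `plsc_model`: `imaging_saliences` (features x
#'   components, unit orthonormal columns), `clinical_saliences`,
#'   `singular_values` (non-increasing), `covariance_explained`,
#'   `scores_imaging` and `scores_clinical` (per-subject latent scores
#'   `X u_k`, `Y v_k`), `n`.
#' @export
pls_svd <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must share the subject index")
  n <- nrow(X)
  if (n < 3) stop("need at least 3 subjects")
  if (all(X == 0) || all(Y == 0)) stop("all-zero block")
  R <- crossprod(Y, X) / (n - 1)
  k <- min(dim(R))
  sv <- svd(R, nu = k, nv = k)
  V <- sv$u[, seq_len(k), drop = FALSE]  # clinical side (rows of R)
  U <- sv$v[, seq_len(k), drop = FALSE]  # imaging side (columns of R)
  d <- sv$d[seq_len(k)]
  # deterministic sign: dominant clinical salience positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  rownames(U) <- colnames(X)
  rownames(V) <- colnames(Y)
  structure(list(imaging_saliences = U, clinical_saliences = V,
                 singular_values = d,
                 covariance_explained = d^2 / sum(d^2),
                 scores_imaging = X %*% U, scores_clinical = Y %*% V,
                 n = n),
            class = "plsc_model")
}

#' Partial least squares correlation of imaging and clinical blocks
#'
#' The central fitting function: runs the full chain
#' residualize -> standardize -> cross-covariance SVD, then (optionally)
#' permutation-based family-wise-error p-values for the latent variables,
#' bootstrap salience ratios with percentile confidence intervals,
#' top-fraction predictor selection and per-modality contributions.
#'
#' Covariates are regressed out of both blocks before standardization.
#' Permutations shuffle the subject rows of the processed clinical block
#' with the imaging block fixed (`permute = "residual"`, the default) or
#' shuffle the raw clinical rows and re-run the whole chain
#' (`permute = "raw"`). The family-wise p-value of component `k` compares
#' `s_k` against the permutation distribution of the maximum singular
#' value, with the add-one estimator `(1 + #exceedances) / (1 + P)`.
#' Bootstrap resamples subjects with replacement, re-runs the chain, aligns
#' each resampled clinical salience basis to the original by orthogonal
#' Procrustes rotation, and reports `original salience / bootstrap SE` as a
#' pseudo-z bootstrap ratio.
#'
#' @param X imaging block: [feature_table] or subjects x features matrix.
#' @param Y clinical outcome block: `outcome_table` or subjects x outcomes
#'   matrix.
#' @param covariates data frame or matrix of nuisance covariates (age,
#'   gender, disease duration), or `NULL`.
#' @param n_permutations permutation count (default 1000; 0 skips).
#' @param n_bootstrap bootstrap count (default 1000; 0 skips).
#' @param alpha family-wise error level used by [summary.plsc()] (default
#'   0.05).
#' @param top_fraction fraction of features reported as most influential
#'   (default 0.05, i.e. the top 5 percent).
#' @param seed master RNG seed; permutation and bootstrap use independent
#'   child seeds derived from it, so changing one count does not perturb
#'   the other stage.
#' @param permute `"residual"` (default) or `"raw"`, see Details.
#' @param contribution `"sum"` (default) or `"mean"` normalization for
#'   [modality_contribution()].
#' @param modality optional per-feature modality labels (taken from the
#'   [feature_table] annotations when available).
#' @return An object of class `plsc`: the fitted `model` ([pls_svd()]
#'   output) plus `permutation`, `bootstrap`, `selection`, `contribution`,
#'   the processing parameters, and `call`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 20, seed = 5))
#' out <- suppressWarnings(percent_change(coh$clinical_baseline,
#'                                        coh$clinical_month4))
#' fit <- plsc(coh$features_baseline, out, coh$covariates,
#'             n_permutations = 50, n_bootstrap = 50, seed = 1)
#' fit
#' @export
plsc <- function(X, Y, covariates = NULL, n_permutations = 1000,
                 n_bootstrap = 1000, alpha = 0.05, top_fraction = 0.05,
                 seed = NULL, permute = c("residual", "raw"),
                 contribution = c("sum", "mean"), modality = NULL) {
  permute <- match.arg(permute)
  contribution <- match.arg(contribution)
  cl <- match.call()
  if (is.null(modality) && inherits(X, "feature_table"))
    modality <- annotations(X)$modality
  ann <- if (inherits(X, "feature_table")) annotations(X) else NULL
  Xr <- as.matrix(X); Yr <- as.matrix(Y)
  if (anyNA(Xr) || anyNA(Yr))
    stop("blocks contain missing values; handle undefined cells first")

  Xres <- residualize(Xr, covariates)
  Yres <- residualize(Yr, covariates)
  Xz <- zscore_columns(Xres)
  Yz <- zscore_columns(Yres)
  model <- pls_svd(Xz, Yz)

  if (!is.null(seed)) set.seed(seed)
  perm_seed <- sample.int(.Machine$integer.max, 1)
  boot_seed <- sample.int(.Machine$integer.max, 1)

  permutation <- if (n_permutations > 0)
    permutation_test(Xr, Yr, covariates, n_permutations = n_permutations,
                     seed = perm_seed, permute = permute,
                     processed = list(X = Xz, Y = Yz), model = model)
  boot <- if (n_bootstrap > 0)
    bootstrap_saliences(Xr, Yr, covariates, model,
                        n_bootstrap = n_bootstrap, seed = boot_seed)
  selection <- contrib <- NULL
  if (!is.null(boot)) {
    selection <- select_top(boot, fraction = top_fraction, component = 1)
    if (!is.null(modality))
      contrib <- modality_contribution(boot, selection, modality,
                                       method = contribution)
  }
  structure(list(model = model, permutation = permutation, bootstrap = boot,
                 selection = selection, contribution = contrib,
                 annotations = ann, modality = modality,
                 alpha = alpha, top_fraction = top_fraction,
                 permute = permute, seed = seed,
                 center_x = attr(Xz, "center"), scale_x = attr(Xz, "scale"),
                 center_y = attr(Yz, "center"), scale_y = attr(Yz, "scale"),
                 coef_x = attr(Xres, "coef"), coef_y = attr(Yres, "coef"),
                 call = cl),
            class = "plsc")
}

#' @export
print.plsc <- function(x, ...) {
  m <- x$model
  cat("PLS correlation: ", nrow(m$imaging_saliences), " imaging features x ",
      nrow(m$clinical_saliences), " clinical outcomes, n = ", m$n, "\n",
      sep = "")
  df <- data.frame(singular_value = round(m$singular_values, 4),
                   covariance_explained = round(m$covariance_explained, 4))
  if (!is.null(x$permutation)) df$fwe_p <- signif(x$permutation$fwe_p, 4)
  rownames(df) <- paste0("LV", seq_along(m$singular_values))
  print(df)
  invisible(x)
}

#' @export
summary.plsc <- function(object, component = 1, ...) {
  m <- object$model
  out <- list(fit = object, component = component)
  if (!is.null(object$permutation))
    out$significant <- which(object$permutation$fwe_p <= object$alpha)
  if (!is.null(object$selection)) {
    sel <- object$selection
    tab <- data.frame(feature = rownames(m$imaging_saliences)[sel$index],
                      salience = m$imaging_saliences[sel$index, component],
                      bootstrap_ratio = sel$ratio,
                      ci_low = object$bootstrap$imaging$ci_low[sel$index, component],
                      ci_high = object$bootstrap$imaging$ci_high[sel$index, component],
                      robust = object$bootstrap$imaging$robust[sel$index, component])
    if (!is.null(object$annotations))
      tab <- cbind(object$annotations[sel$index, c("modality", "region", "side")],
                   tab[-1])
    out$top_features <- tab
  }
  out$contribution <- object$contribution
  structure(out, class = "summary.plsc")
}

#' @export
print.summary.plsc <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$significant))
    cat("\nSignificant LVs at FWE alpha = ", x$fit$alpha, ": ",
        if (length(x$significant)) paste0("LV", x$significant, collapse = ", ")
        else "none", "\n", sep = "")
  if (!is.null(x$top_features)) {
    cat("\nTop ", 100 * x$fit$top_fraction, "% features (component ",
        x$component, "):\n", sep = "")
    print(utils::head(x$top_features, 25), digits = 3, row.names = FALSE)
  }
  if (!is.null(x$contribution)) {
    cat("\nModality contributions:\n")
    print(round(x$contribution, 3))
  }
  invisible(x)
}

#' @export
coef.plsc <- function(object, block = c("imaging", "clinical"), ...) {
  block <- match.arg(block)
  if (block == "imaging") object$model$imaging_saliences
  else object$model$clinical_saliences
}

#' Latent score scatter of a fitted PLS correlation
#'
#' Plots per-subject imaging vs clinical latent scores of one component
#' (the standard LV scatter figure); the Pearson correlation of the scores
#' is shown in the title.
#'
#' @param x a [plsc] fit.
#' @param component which LV (default 1).
#' @param ... passed to [graphics::plot()].
#' @export
plot.plsc <- function(x, component = 1, ...) {
  si <- x$model$scores_imaging[, component]
  sc <- x$model$scores_clinical[, component]
  graphics::plot(si, sc, xlab = "imaging latent score",
                 ylab = "clinical latent score",
                 main = sprintf("LV%d: r = %.2f, %.1f%% covariance%s",
                                component, stats::cor(si, sc),
                                100 * x$model$covariance_explained[component],
                                if (!is.null(x$permutation))
                                  sprintf(", FWE p = %.3g",
                                          x$permutation$fwe_p[component])
                                else ""),
                 pch = 19, ...)
  graphics::abline(stats::lm(sc ~ si), lty = 2)
  invisible(x)
}

#' Project new subjects onto fitted saliences
#'
#' Applies the training-set covariate regression (fitted coefficients),
#' centering and scaling to new data, then projects onto the fitted
#' saliences to obtain latent scores.
#'
#' @param object a [plsc] fit.
#' @param X new imaging block (same columns as training).
#' @param Y optional new clinical block.
#' @param covariates covariates of the new subjects (same layout as
#'   training); `NULL` applies intercept-only adjustment.
#' @param ... unused.
#' @return List with `scores_imaging` and (if `Y` given) `scores_clinical`.
#' @export
predict.plsc <- function(object, X, Y = NULL, covariates = NULL, ...) {
  proj <- function(block, coefs, ctr, scl, sal) {
    block <- as.matrix(block)
    design <- covariate_design(covariates, nrow(block))
    keep <- intersect(rownames(coefs), colnames(design))
    res <- block - design[, keep, drop = FALSE] %*% coefs[keep, , drop = FALSE]
    z <- sweep(sweep(res, 2, ctr), 2, scl, "/")
    z %*% sal
  }
  out <- list(scores_imaging = proj(X, object$coef_x, object$center_x,
                                    object$scale_x,
                                    object$model$imaging_saliences))
  if (!is.null(Y))
    out$scores_clinical <- proj(Y, object$coef_y, object$center_y,
                                object$scale_y,
                                object$model$clinical_saliences)
  out
}
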