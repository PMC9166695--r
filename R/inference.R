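#' Permutation test of the PLS latent variables
#'
#' Builds a null distribution of singular values by permuting the clinical
#' block against the fixed imaging block, and reports family-wise-error
#' corrected p-values under the max-statistic rule:
#' `fwe_p(k) = (1 + #{perm : max_j s_j^perm >= s_k}) / (1 + P)`.
#'
#' With `permute = "residual"` (default) the residualized, standardized
#' blocks are first rotated into an orthonormal basis of the covariate
#' orthocomplement, where the residual rows are exchangeable under the
#' null, and the reduced clinical rows are shuffled; the observed
#' statistic is unchanged by the rotation. Shuffling residual rows in the
#' original subject space instead is anticonservative, because the
#' observed residuals of both blocks are confined to the same
#' covariate-orthogonal subspace while shuffled rows are not. With
#' `permute = "raw"` the raw clinical rows are shuffled against the
#' unpermuted covariates and the whole residualize/standardize/SVD chain
#' is re-run per permutation.
#'
#' @param X,Y raw subject x column blocks (matrices or tables).
#' @param covariates covariates as in [plsc()].
#' @param n_permutations number of permutations (>= 100 for reported
#'   p-values).
#' @param seed RNG seed for the permutation stream.
#' @param permute `"residual"` or `"raw"`.
#' @param processed,model internal fast path: pre-processed blocks and
#'   fitted model (used by [plsc()]).
#' @return List of class `plsc_permutation`: `null_singular_values`
#'   (permutations x components), `fwe_p`, `observed`, `n_permutations`.
#' @export
permutation_test <- function(X, Y, covariates = NULL, n_permutations = 1000,
                             seed = NULL, permute = c("residual", "raw"),
                             processed = NULL, model = NULL) {
  permute <- match.arg(permute)
  Xr <- as.matrix(X); Yr <- as.matrix(Y)
  if (is.null(processed)) {
    Xz <- zscore_columns(residualize(Xr, covariates))
    Yz <- zscore_columns(residualize(Yr, covariates))
  } else {
    Xz <- processed$X; Yz <- processed$Y
  }
  if (is.null(model)) model <- pls_svd(Xz, Yz)
  obs <- model$singular_values
  k <- length(obs)
  n <- nrow(Xz)
  if (permute == "residual") {
    # exchangeable reduced space: orthonormal basis of the covariate
    # orthocomplement; crossprod(Yred, Xred) == crossprod(Yz, Xz)
    qrd <- qr(covariate_design(covariates, n))
    Bfull <- qr.Q(qrd, complete = TRUE)
    B <- Bfull[, seq.int(qrd$rank + 1, n), drop = FALSE]
    Xred <- crossprod(B, Xz)
    Yred <- crossprod(B, Yz)
    m <- nrow(Xred)
  }
  if (!is.null(seed)) set.seed(seed)
  null_sv <- matrix(NA_real_, n_permutations, k)
  for (p in seq_len(n_permutations)) {
    if (permute == "residual") {
      Rp <- crossprod(Yred[sample.int(m), , drop = FALSE], Xred) / (n - 1)
    } else {
      idx <- sample.int(n)
      Yp <- zscore_columns_safe(residualize(Yr[idx, , drop = FALSE], covariates))
      Rp <- crossprod(Yp, Xz) / (n - 1)
    }
    null_sv[p, ] <- svd(Rp, nu = 0, nv = 0)$d[seq_len(k)]
  }
  maxima <- apply(null_sv, 1, max)
  fwe_p <- vapply(obs, function(s) (1 + sum(maxima >= s)) /
                    (1 + n_permutations), numeric(1))
  structure(list(null_singular_values = null_sv, fwe_p = fwe_p,
                 observed = obs, n_permutations = n_permutations,
                 permute = permute),
            class = "plsc_permutation")
}

#' Bootstrap salience ratios and confidence intervals
#'
#' Resamples subjects with replacement, re-runs the
#' residualize/standardize/SVD chain on each resample, aligns the
#' resampled saliences to the original fit by orthogonal Procrustes
#' rotation of the (low-dimensional) clinical basis — the rotation is then
#' applied to the imaging side too, preventing axis- and sign-flips from
#' inflating the spread — and summarizes, per salience element:
#' the bootstrap standard error, the pseudo-z bootstrap ratio
#' (original salience / SE), the percentile 95% confidence interval, and a
#' robustness flag (CI excludes zero). Resamples in which columns become
#' constant are handled by centering those columns to zero; their count is
#' reported.
#'
#' @param X,Y raw blocks as given to [plsc()].
#' @param covariates covariates as in [plsc()].
#' @param model the fitted [pls_svd()] model on the same data.
#' @param n_bootstrap number of resamples.
#' @param seed RNG seed for the bootstrap stream.
#' @param conf confidence level (default 0.95).
#' @return List of class `plsc_bootstrap` with elements `imaging` and
#'   `clinical`, each containing matrices (features x components) `se`,
#'   `ratio`, `ci_low`, `ci_high`, `robust`; plus `n_bootstrap` and
#'   `n_degenerate` (count of recentered degenerate columns over all
#'   resamples).
#' @export
bootstrap_saliences <- function(X, Y, covariates = NULL, model,
                                n_bootstrap = 1000, seed = NULL,
                                conf = 0.95) {
  stopifnot(inherits(model, "plsc_model"))
  Xr <- as.matrix(X); Yr <- as.matrix(Y)
  n <- nrow(Xr)
  k <- length(model$singular_values)
  U0 <- model$imaging_saliences
  V0 <- model$clinical_saliences
  if (!is.null(seed)) set.seed(seed)
  Ub <- array(NA_real_, c(nrow(U0), k, n_bootstrap))
  Vb <- array(NA_real_, c(nrow(V0), k, n_bootstrap))
  n_degenerate <- 0L
  cov_mat <- if (is.null(covariates)) NULL else covariates
  for (b in seq_len(n_bootstrap)) {
    idx <- sample.int(n, replace = TRUE)
    cb <- if (is.null(cov_mat)) NULL else
      if (is.data.frame(cov_mat)) cov_mat[idx, , drop = FALSE] else
        cov_mat[idx, , drop = FALSE]
    Xb <- tryCatch(residualize(Xr[idx, , drop = FALSE], cb),
                   error = function(e) NULL)
    if (is.null(Xb)) next  # degenerate covariate draw; skip resample
    Yb <- residualize(Yr[idx, , drop = FALSE], cb)
    Xz <- zscore_columns_safe(Xb)
    Yz <- zscore_columns_safe(Yb)
    n_degenerate <- n_degenerate + attr(Xz, "n_degenerate") +
      attr(Yz, "n_degenerate")
    fit <- pls_svd(Xz, Yz)
    rot <- procrustes_rotation(fit$clinical_saliences, V0)
    Ub[, , b] <- fit$imaging_saliences %*% rot
    Vb[, , b] <- fit$clinical_saliences %*% rot
  }
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  summarize <- function(orig, arr) {
    se <- apply(arr, c(1, 2), stats::sd, na.rm = TRUE)
    ratio <- orig / se
    ci <- apply(arr, c(1, 2), stats::quantile, probs = probs, na.rm = TRUE)
    ci_low <- ci[1, , , drop = TRUE]
    ci_high <- ci[2, , , drop = TRUE]
    dim(ci_low) <- dim(ci_high) <- dim(orig)
    dimnames(se) <- dimnames(ratio) <- dimnames(ci_low) <-
      dimnames(ci_high) <- dimnames(orig)
    list(se = se, ratio = ratio, ci_low = ci_low, ci_high = ci_high,
         robust = ci_low * ci_high > 0)
  }
  structure(list(imaging = summarize(U0, Ub), clinical = summarize(V0, Vb),
                 n_bootstrap = n_bootstrap, n_degenerate = n_degenerate,
                 conf = conf),
            class = "plsc_bootstrap")
}

# orthogonal Procrustes: rotation Q minimizing || A Q - B ||_F
procrustes_rotation <- function(A, B) {
  s <- svd(crossprod(A, B))
  s$u %*% t(s$v)
}

#' Select the most influential imaging features
#'
#' Ranks features by the magnitude of their bootstrap ratio on one
#' component and returns the top `ceiling(fraction * n_features)` of them;
#' ties are broken deterministically by column order (with a warning). By
#' default the selection is intersected with the robustness flags (95% CI
#' not crossing zero).
#'
#' @param boot a [bootstrap_saliences()] result.
#' @param fraction selection fraction in (0, 1] (default 0.05).
#' @param component LV index (default 1).
#' @param robust_only keep only features whose CI excludes zero (default
#'   TRUE).
#' @return List of class `plsc_selection`: `index` (column indices in rank
#'   order), `ratio`, `component`, `fraction`, `n_candidates`.
#' @export
select_top <- function(boot, fraction = 0.05, component = 1,
                       robust_only = TRUE) {
  stopifnot(inherits(boot, "plsc_bootstrap"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  ratio <- boot$imaging$ratio[, component]
  p <- length(ratio)
  n_top <- ceiling(fraction * p)
  if (n_top < 1) stop("fraction selects no features")
  ord <- order(-abs(ratio), seq_len(p))
  picked <- ord[seq_len(n_top)]
  if (n_top < p &&
      isTRUE(abs(ratio[ord[n_top]]) == abs(ratio[ord[n_top + 1]])))
    warning("tied bootstrap ratios at the selection boundary; ",
            "ties broken by column order")
  if (robust_only) {
    keep <- boot$imaging$robust[picked, component]
    picked <- picked[keep]
  }
  structure(list(index = picked, ratio = ratio[picked],
                 component = component, fraction = fraction,
                 n_candidates = n_top),
            class = "plsc_selection")
}

#' Per-modality contribution to a latent variable
#'
#' Fraction of the total selected-feature importance carried by each
#' imaging modality: by default (`method = "sum"`) the per-modality sum of
#' `|bootstrap ratio|` over selected features, normalized to sum to 1
#' across modalities (equivalently mean |ratio| weighted by the selected
#' count). `method = "mean"` normalizes the per-modality means instead.
#' Modalities with no selected feature get exactly 0.
#'
#' @param boot a [bootstrap_saliences()] result.
#' @param selection a [select_top()] result (or integer feature indices).
#' @param modality character vector of per-feature modality labels.
#' @param method `"sum"` (default) or `"mean"`.
#' @param component LV index (default: the selection's component).
#' @return Named numeric vector over `unique(modality)` (input order)
#'   summing to 1.
#' @export
modality_contribution <- function(boot, selection, modality,
                                  method = c("sum", "mean"),
                                  component = NULL) {
  method <- match.arg(method)
  if (inherits(selection, "plsc_selection")) {
    idx <- selection$index
    if (is.null(component)) component <- selection$component
  } else {
    idx <- as.integer(selection)
    if (is.null(component)) component <- 1
  }
  if (!length(idx)) stop("selection is empty")
  ratio <- boot$imaging$ratio[, component]
  mods <- unique(modality)
  per <- vapply(mods, function(m) {
    sel_m <- idx[modality[idx] == m]
    if (!length(sel_m)) return(0)
    if (method == "sum") sum(abs(ratio[sel_m])) else mean(abs(ratio[sel_m]))
  }, numeric(1))
  names(per) <- mods
  per / sum(per)
}
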