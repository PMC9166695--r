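# shared fixtures, built in code

# minimal lateralized feature table: 2 modalities x (2 paired regions + 1 midline)
toy_feature_table <- function(values = NULL, n = 3) {
  ann <- data.frame(
    modality = rep(c("fALFF", "GM_density"), each = 5),
    region = rep(c("ctx_01", "ctx_01", "ctx_02", "ctx_02", "cbl_vermis_1"), 2),
    side = rep(c("L", "R", "L", "R", "mid"), 2),
    class = rep(c(rep("cortical", 4), "cerebellar"), 2))
  if (is.null(values)) {
    set.seed(7)
    values <- matrix(rnorm(n * nrow(ann)), n, nrow(ann),
                     dimnames = list(sprintf("s%d", seq_len(n)), NULL))
  }
  feature_table(values, ann)
}

toy_clinical <- function(values, visit = "baseline") {
  clinical_table(matrix(values, ncol = 5, byrow = TRUE,
                        dimnames = list(sprintf("s%d",
                                                seq_len(length(values) / 5)),
                                        clinical_score_names())),
                 visit)
}

# equal-magnitude sparse unit salience: standardization leaves its
# direction invariant, so it is both the planted truth and the estimand
flat_salience <- function(p, support, seed) {
  set.seed(seed)
  u <- numeric(p)
  idx <- sample(p, support)
  u[idx] <- sample(c(-1, 1), support, replace = TRUE) / sqrt(support)
  u
}

# cohort -> (flipped features, outcomes, covariates) for fitting
cohort_inputs <- function(coh, flip = TRUE) {
  fb <- coh$features_baseline
  if (flip) fb <- flip_sides(fb, coh$treated_side)
  out <- suppressWarnings(percent_change(coh$clinical_baseline,
                                         coh$clinical_month4))
  list(X = fb, Y = out, covariates = coh$covariates)
}

# independent concordance oracle: Kendall's W from mean pairwise Spearman
# correlation (valid without ties): W = (1 + (K-1) * mean rho) / K
oracle_W_spearman <- function(m) {
  k <- nrow(m)
  rho <- stats::cor(t(m), method = "spearman")
  (1 + (k - 1) * mean(rho[upper.tri(rho)])) / k
}

# brute-force W: ranks by explicit enumeration (counting), mid-ranks for ties
oracle_W_enumerate <- function(m) {
  k <- nrow(m); nt <- ncol(m)
  ranks <- t(apply(m, 1, function(x)
    vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))))
  rs <- colSums(ranks)
  s <- sum((rs - mean(rs))^2)
  ties <- sum(apply(m, 1, function(x) {
    tl <- as.vector(table(x)); sum(tl^3 - tl)
  }))
  12 * s / (k^2 * (nt^3 - nt) - k * ties)
}
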