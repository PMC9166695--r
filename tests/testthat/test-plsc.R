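test_that("residualize matches the explicit hat-matrix projection", {
  set.seed(11)
  n <- 35
  block <- matrix(rnorm(n * 4), n, 4)
  cov <- data.frame(age = rnorm(n, 55, 9),
                    gender = factor(sample(c("f", "m"), n, TRUE)),
                    duration = rnorm(n, 7, 3))
  res <- residualize(block, cov)
  D <- cbind(1, cov$age, as.numeric(cov$gender) - 1, cov$duration)
  H <- D %*% solve(crossprod(D)) %*% t(D)
  expect_equal(unname(res), unname((diag(n) - H) %*% block),
               tolerance = 1e-10, ignore_attr = TRUE)
  # residuals orthogonal to the covariate space
  expect_lt(max(abs(crossprod(D, res))), 1e-8)
  # a column equal to a covariate residualizes to zero
  res2 <- residualize(cbind(cov$age), cov)
  expect_lt(max(abs(res2)), 1e-10)
})

test_that("residualize rejects collinear covariates naming them", {
  set.seed(12)
  cov <- data.frame(age = rnorm(10), double_age = NA, duration = rnorm(10))
  cov$double_age <- 2 * cov$age
  expect_error(residualize(matrix(rnorm(10), 10, 1), cov), "collinear")
})

test_that("a column orthogonal to centered covariates is only centered", {
  n <- 8
  cov <- data.frame(age = rep(c(1, 2), each = 4))
  x <- rep(c(-1, 1), 4) + 5   # orthogonal to age after centering
  res <- residualize(cbind(x), cov)
  expect_equal(unname(res[, 1]), x - mean(x), ignore_attr = TRUE)
})

test_that("zscore uses the n-1 convention and flags constants", {
  z <- zscore_columns(cbind(a = c(1, 2, 3)))
  expect_equal(unname(z[, 1]), c(-1, 0, 1))
  zz <- zscore_columns(z)
  expect_equal(unclass(zz), unclass(z), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(zscore_columns(cbind(ok = 1:3, flat = rep(2, 3))), "flat")
})

test_that("pls_svd recovers a constructed diagonal cross-covariance", {
  n <- 21
  set.seed(13)
  Q <- qr.Q(qr(matrix(rnorm(n * 2), n, 2)))
  Y <- Q * sqrt(n - 1)
  X <- Q %*% diag(c(3, 1)) * sqrt(n - 1)
  m <- pls_svd(X, Y)
  expect_equal(m$singular_values, c(3, 1))
  expect_equal(m$covariance_explained, c(0.9, 0.1))
})

test_that("identical blocks give equal latent scores per component", {
  set.seed(14)
  Q <- qr.Q(qr(matrix(rnorm(30 * 5), 30, 5)))
  m <- pls_svd(Q, Q)
  expect_equal(m$scores_imaging, m$scores_clinical, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("singular structure matches an independent eigendecomposition", {
  set.seed(15)
  for (i in 1:5) {
    X <- scale(matrix(rnorm(35 * 40), 35, 40))
    Y <- scale(matrix(rnorm(35 * 5), 35, 5))
    m <- pls_svd(X, Y)
    R <- t(Y) %*% X / 34
    ev <- eigen(R %*% t(R), symmetric = TRUE)
    expect_equal(m$singular_values, sqrt(pmax(ev$values, 0)),
                 tolerance = 1e-8)
    expect_equal(sum(m$covariance_explained), 1, tolerance = 1e-12)
    # orthonormal saliences within each block
    expect_equal(crossprod(m$imaging_saliences), diag(5),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(crossprod(m$clinical_saliences), diag(5),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("saliences are invariant to raw column rescaling", {
  coh <- generate_cohort(cohort_config(n_subjects = 25, seed = 16))
  inp <- cohort_inputs(coh)
  f1 <- plsc(inp$X, inp$Y, inp$covariates, n_permutations = 0, n_bootstrap = 0)
  Xs <- as.matrix(inp$X)
  Xs[, 1:100] <- Xs[, 1:100] * 37
  f2 <- plsc(Xs, unclass(inp$Y), inp$covariates, n_permutations = 0,
             n_bootstrap = 0)
  expect_equal(f1$model$imaging_saliences, f2$model$imaging_saliences,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(f1$model$singular_values, f2$model$singular_values,
               tolerance = 1e-10)
})

test_that("flipping one clinical column flips only its salience", {
  set.seed(17)
  X <- matrix(rnorm(40 * 12), 40, 12)
  Y <- matrix(rnorm(40 * 5), 40, 5)
  m1 <- pls_svd(scale(X), scale(Y))
  Y2 <- Y; Y2[, 3] <- -Y2[, 3]
  m2 <- pls_svd(scale(X), scale(Y2))
  expect_equal(m1$singular_values, m2$singular_values, tolerance = 1e-10)
  for (k in 1:5) {
    v1 <- m1$clinical_saliences[, k]
    v2 <- m2$clinical_saliences[, k]
    v2[3] <- -v2[3]
    sgn <- sign(sum(v1 * v2))
    expect_equal(v1, sgn * v2, tolerance = 1e-8)
    expect_equal(m1$imaging_saliences[, k], sgn * m2$imaging_saliences[, k],
                 tolerance = 1e-8)
  }
})

test_that("permutation p-values are deterministic and bounded", {
  coh <- generate_cohort(cohort_config(n_subjects = 20, seed = 18))
  inp <- cohort_inputs(coh)
  p1 <- permutation_test(as.matrix(inp$X), unclass(inp$Y), inp$covariates,
                         n_permutations = 100, seed = 5)
  p2 <- permutation_test(as.matrix(inp$X), unclass(inp$Y), inp$covariates,
                         n_permutations = 100, seed = 5)
  expect_identical(p1$fwe_p, p2$fwe_p)
  expect_true(all(p1$fwe_p >= 1 / 101 & p1$fwe_p <= 1))
  # max-statistic rule makes p-values monotone across components
  expect_true(all(diff(p1$fwe_p) >= 0))
})

test_that("a perfect association attains the minimum permutation p", {
  set.seed(19)
  X <- matrix(rnorm(30 * 20), 30, 20)
  Y <- X[, 1:5]
  p <- permutation_test(X, Y, NULL, n_permutations = 200, seed = 7)
  expect_equal(p$fwe_p[1], 1 / 201)
})

test_that("bootstrap flags planted strong features and spares null ones", {
  u <- flat_salience(416, 30, seed = 23)
  coh <- generate_cohort(cohort_config(
    n_subjects = 60, singular_strength = 6,
    imaging_saliences = matrix(u, ncol = 1),
    covariate_effect_sd = c(imaging = 0, clinical = 0), seed = 23))
  inp <- cohort_inputs(coh, flip = FALSE)
  fit <- plsc(inp$X, inp$Y, inp$covariates, n_permutations = 0,
              n_bootstrap = 200, seed = 3)
  bt <- fit$bootstrap$imaging
  strong <- which(abs(u) > 0)
  expect_gt(mean(bt$robust[strong, 1]), 0.8)
  expect_gt(mean(abs(bt$ratio[strong, 1])), 2)
  # robustness flag is exactly "CI excludes zero"
  expect_identical(bt$robust, bt$ci_low * bt$ci_high > 0)
  expect_true(all(bt$se[is.finite(bt$se)] >= 0))
})

test_that("doubling the bootstrap leaves standard errors stable", {
  coh <- generate_cohort(cohort_config(n_subjects = 30, seed = 24))
  inp <- cohort_inputs(coh)
  fit <- plsc(inp$X, inp$Y, inp$covariates, n_permutations = 0, n_bootstrap = 0)
  b1 <- bootstrap_saliences(as.matrix(inp$X), unclass(inp$Y), inp$covariates,
                            fit$model, n_bootstrap = 150, seed = 1)
  b2 <- bootstrap_saliences(as.matrix(inp$X), unclass(inp$Y), inp$covariates,
                            fit$model, n_bootstrap = 300, seed = 2)
  m1 <- mean(b1$imaging$se[, 1]); m2 <- mean(b2$imaging$se[, 1])
  expect_lt(abs(m1 - m2) / m2, 0.25)
})

test_that("top-fraction selection counts, ties and bounds are deterministic", {
  ratio <- matrix(seq(416, 1), 416, 1)
  boot <- structure(list(imaging = list(ratio = ratio,
                                        robust = ratio > 0)),
                    class = "plsc_bootstrap")
  sel <- select_top(boot, fraction = 0.05, robust_only = FALSE)
  expect_equal(length(sel$index), 21)   # ceiling(0.05 * 416)
  expect_equal(sel$index, 1:21)
  # all ratios equal: first-k by column order with a tie warning
  boot2 <- structure(list(imaging = list(ratio = matrix(1, 10, 1),
                                         robust = matrix(TRUE, 10, 1))),
                     class = "plsc_bootstrap")
  expect_warning(sel2 <- select_top(boot2, fraction = 0.3), "tie")
  expect_equal(sel2$index, 1:3)
  sel3 <- select_top(boot, fraction = 1, robust_only = FALSE)
  expect_equal(length(sel3$index), 416)
  expect_error(select_top(boot, fraction = 0), "fraction")
  # robust intersection removes non-robust picks
  boot3 <- structure(list(imaging = list(
    ratio = ratio, robust = matrix(c(FALSE, rep(TRUE, 415)), 416, 1))),
    class = "plsc_bootstrap")
  sel4 <- select_top(boot3, fraction = 0.05)
  expect_equal(sel4$index, 2:21)
})

test_that("modality contributions normalize hand-set ratios", {
  ratio <- matrix(c(6, 0.01, 2.1, 1.8), 4, 1)
  boot <- structure(list(imaging = list(ratio = ratio,
                                        robust = matrix(TRUE, 4, 1))),
                    class = "plsc_bootstrap")
  mods <- c("fALFF", "ReHo", "GM_atrophy", "GM_density")
  contrib <- modality_contribution(boot, selection = c(1, 3, 4), mods)
  expect_equal(unname(contrib), c(6, 0, 2.1, 1.8) / 9.9, tolerance = 1e-12)
  expect_equal(sum(contrib), 1)
  expect_equal(round(unname(contrib), 2), c(0.61, 0, 0.21, 0.18))
  # single-modality selection: 1 for it, 0 for all others
  c2 <- modality_contribution(boot, selection = 1, mods)
  expect_equal(unname(c2), c(1, 0, 0, 0))
  # equal totals split 50/50
  boot3 <- structure(list(imaging = list(ratio = matrix(c(2, 2), 2, 1),
                                         robust = matrix(TRUE, 2, 1))),
                     class = "plsc_bootstrap")
  c3 <- modality_contribution(boot3, selection = 1:2, c("A", "B"))
  expect_equal(unname(c3), c(0.5, 0.5))
  expect_error(modality_contribution(boot, integer(0), mods), "empty")
})

test_that("an identical-visit changes analysis raises the degeneracy error", {
  coh <- generate_cohort(cohort_config(n_subjects = 15, seed = 26))
  coh$features_month4 <- coh$features_baseline
  expect_error(run_analysis(coh, "changes", n_permutations = 10,
                            n_bootstrap = 10, seed = 1),
               "constant column")
})

test_that("plsc integrates selection and contribution on a planted cohort", {
  coh <- generate_cohort(cohort_config(n_subjects = 35, seed = 27))
  inp <- cohort_inputs(coh)
  fit <- plsc(inp$X, inp$Y, inp$covariates, n_permutations = 100,
              n_bootstrap = 100, seed = 9)
  expect_s3_class(fit, "plsc")
  expect_lte(fit$permutation$fwe_p[1], 0.05)
  expect_equal(sum(fit$contribution), 1)
  expect_lte(length(fit$selection$index), 21)
  s <- summary(fit)
  expect_true(all(c("modality", "region", "side", "bootstrap_ratio")
                  %in% names(s$top_features)))
  expect_output(print(s), "Significant LVs")
  # latent scores are projections of the processed blocks
  expect_equal(ncol(fit$model$scores_imaging), 5)
})

test_that("predict reproduces training latent scores", {
  coh <- generate_cohort(cohort_config(n_subjects = 25, seed = 28))
  inp <- cohort_inputs(coh)
  fit <- plsc(inp$X, inp$Y, inp$covariates, n_permutations = 0,
              n_bootstrap = 0)
  pr <- predict(fit, X = as.matrix(inp$X), Y = unclass(inp$Y),
                covariates = inp$covariates)
  expect_equal(pr$scores_imaging, fit$model$scores_imaging,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(pr$scores_clinical, fit$model$scores_clinical,
               tolerance = 1e-8, ignore_attr = TRUE)
})
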