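#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a two-visit cohort
#' of Parkinson's disease patients with four regional imaging modalities
#' over 104 brain regions, five treated-side motor outcomes, three
#' covariates, and a planted low-rank latent association between the
#' imaging and clinical blocks. Defaults reproduce the dimensions and
#' descriptive statistics of a 35-patient focused-ultrasound subthalamotomy
#' trial cohort.
#'
#' @param n_subjects number of subjects (default 35).
#' @param region_counts named counts of cortical / subcortical / cerebellar
#'   regions (defaults 70/16/18, summing to 104). Cortical and subcortical
#'   counts must be even (left/right pairs); cerebellar regions are pairs
#'   plus 2 midline (vermis-like) regions.
#' @param modalities ordered modality names.
#' @param latent_rank number of planted latent components.
#' @param singular_strength per-component effect size (length
#'   `latent_rank`); 0 plants no association. The default 6 makes the
#'   leading latent variable dominate the sample cross-covariance at the
#'   default cohort size (around 80 percent of explained covariance), the
#'   regime the emulated trial analysis operates in.
#' @param imaging_saliences optional p x rank matrix of planted imaging
#'   saliences (unit columns); default: sparse random unit vectors with
#'   `salience_support` nonzero entries.
#' @param clinical_saliences optional 5 x rank matrix of planted clinical
#'   saliences (unit columns); default random unit vectors.
#' @param salience_support number of imaging features carrying each default
#'   planted component.
#' @param noise_sd_imaging,noise_sd_clinical Gaussian noise SDs of the two
#'   latent-scale blocks.
#' @param covariate_effect_sd SD of the random age/gender/duration
#'   regression coefficients on the imaging and clinical blocks (named
#'   vector, set to 0 for no confounding).
#' @param treated_side_fraction probability a subject is right-treated.
#' @param change_model list with `coupling` (fraction of
#'   `singular_strength` linking month-4 feature drift to the latent) and
#'   `drift_sd` (SD of the drift noise; small, matching the small month-4
#'   imaging variances the design assumes).
#' @param clinical_baseline_mean,clinical_baseline_sd means/SDs used to draw
#'   integer baseline scores for the five outcomes.
#' @param clinical_change_mean,clinical_change_sd means/SDs (percent) onto
#'   which the latent-linked continuous outcome block is mapped.
#' @param score_max per-score plausible MDS-UPDRS caps for clipping.
#' @param min_baseline_score lower clip for baseline scores (default 1 so
#'   percent change is defined everywhere).
#' @param discretize_clinical round clinical scores to integers (default
#'   TRUE).
#' @param seed integer RNG seed; the whole cohort is reproducible from it.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 35,
                          region_counts = c(cortical = 70, subcortical = 16,
                                            cerebellar = 18),
                          modalities = c("fALFF", "ReHo", "GM_atrophy",
                                         "GM_density"),
                          latent_rank = 1,
                          singular_strength = 6,
                          imaging_saliences = NULL,
                          clinical_saliences = NULL,
                          salience_support = 30,
                          noise_sd_imaging = 1,
                          noise_sd_clinical = 1,
                          covariate_effect_sd = c(imaging = 0.2, clinical = 0.2),
                          treated_side_fraction = 16 / 35,
                          change_model = list(coupling = 0.5, drift_sd = 0.25),
                          clinical_baseline_mean = c(37.6, 18.8, 3.5, 10.0, 5.3),
                          clinical_baseline_sd = c(8.0, 3.7, 1.0, 2.7, 2.5),
                          clinical_change_mean = c(-40.0, -57.7, -58.0, -47.1, -74.0),
                          clinical_change_sd = c(18.0, 19.0, 30.7, 27.4, 30.5),
                          score_max = c(132, 66, 12, 36, 20),
                          min_baseline_score = 1,
                          discretize_clinical = TRUE,
                          seed = 1L) {
  cfg <- as.list(environment())
  if (n_subjects < 3) stop("n_subjects must be >= 3")
  if (any(region_counts < 0)) stop("region counts must be nonnegative")
  if (region_counts["cortical"] %% 2 || region_counts["subcortical"] %% 2)
    stop("cortical and subcortical region counts must be even (L/R pairs)")
  if (region_counts["cerebellar"] < 2 || (region_counts["cerebellar"] - 2) %% 2)
    stop("cerebellar count must be 2 midline regions plus L/R pairs")
  if (latent_rank < 0) stop("latent_rank must be >= 0")
  singular_strength <- rep_len(singular_strength, max(latent_rank, 1L))
  if (any(singular_strength < 0)) stop("singular_strength must be >= 0")
  cfg$singular_strength <- singular_strength
  if (noise_sd_imaging <= 0 || noise_sd_clinical <= 0)
    stop("noise SDs must be > 0")
  if (treated_side_fraction < 0 || treated_side_fraction > 1)
    stop("treated_side_fraction must be in [0, 1]")
  p <- sum(region_counts) * length(modalities)
  if (!is.null(imaging_saliences)) {
    imaging_saliences <- as.matrix(imaging_saliences)
    if (nrow(imaging_saliences) != p || ncol(imaging_saliences) < latent_rank)
      stop("imaging_saliences must be ", p, " x ", latent_rank)
    cfg$imaging_saliences <- unit_columns(imaging_saliences)
  }
  if (!is.null(clinical_saliences)) {
    clinical_saliences <- as.matrix(clinical_saliences)
    if (nrow(clinical_saliences) != 5 || ncol(clinical_saliences) < latent_rank)
      stop("clinical_saliences must be 5 x ", latent_rank)
    cfg$clinical_saliences <- unit_columns(clinical_saliences)
  }
  stopifnot(length(clinical_baseline_mean) == 5,
            length(clinical_baseline_sd) == 5,
            length(clinical_change_mean) == 5,
            length(clinical_change_sd) == 5,
            length(score_max) == 5)
  structure(cfg, class = "cohort_config")
}

unit_columns <- function(m) {
  nrm <- sqrt(colSums(m^2))
  if (any(nrm == 0)) stop("salience columns must be nonzero")
  sweep(m, 2, nrm, "/")
}

#' Region table for the default parcellation layout
#'
#' Builds the annotation table of 104 regions (under default counts):
#' lateralized cortical and subcortical pairs, cerebellar pairs and two
#' midline vermis-like regions.
#'
#' @param region_counts named counts as in [cohort_config()].
#' @return Data frame with `region`, `side`, `class`.
#' @export
region_table <- function(region_counts = c(cortical = 70, subcortical = 16,
                                           cerebellar = 18)) {
  pairs <- function(class, prefix, n_pairs) {
    if (n_pairs == 0) return(NULL)
    nm <- sprintf("%s_%02d", prefix, seq_len(n_pairs))
    data.frame(region = rep(nm, each = 2), side = rep(c("L", "R"), n_pairs),
               class = class, stringsAsFactors = FALSE)
  }
  cbl_pairs <- (region_counts["cerebellar"] - 2) / 2
  rbind(
    pairs("cortical", "ctx", region_counts["cortical"] / 2),
    pairs("subcortical", "sub", region_counts["subcortical"] / 2),
    pairs("cerebellar", "cbl", cbl_pairs),
    data.frame(region = c("cbl_vermis_1", "cbl_vermis_2"), side = "mid",
               class = "cerebellar", stringsAsFactors = FALSE))
}

# per-modality affine placement (offset, scale) of the standardized latent
# block onto raw feature values; offsets are ~10 SD from zero so the sign
# conventions (atrophy <= 0, others >= 0) survive clamping essentially
# unperturbed
modality_placement <- function(modality) {
  switch(modality,
         fALFF      = c(offset = 0.50, scale = 0.05),
         ReHo       = c(offset = 0.50, scale = 0.05),
         GM_atrophy = c(offset = -0.50, scale = 0.05),
         GM_density = c(offset = 0.60, scale = 0.06),
         c(offset = 0.5, scale = 0.05))
}

#' Generate a synthetic two-visit cohort with a planted latent association
#'
#' Draws per-subject latent scores `t_k ~ N(0,1)` and builds the imaging
#' block `X = sum_k s_k t_k u_k' + C B_x + E_x` and the continuous clinical
#' outcome block `Y = sum_k s_k t_k v_k' + C B_y + E_y` (standardized
#' covariates `C`, Gaussian noise `E`). `X` is mapped affinely onto raw
#' per-modality feature values respecting the sign conventions (atrophy
#' non-positive, functional/density non-negative); `Y` is mapped onto
#' percent changes which, combined with integer baseline scores, yield the
#' month-4 clinical table. Month-4 features drift from baseline by a
#' latent-linked component plus small noise. The planted truth (latent
#' scores, saliences, strengths) is returned for validation.
#'
#' @param config a [cohort_config()].
#' @return An object of class `synthetic_cohort`: list with
#'   `features_baseline`, `features_month4` ([feature_table]s, sides L/R/mid),
#'   `clinical_baseline`, `clinical_month4` ([clinical_table]s),
#'   `covariates` (data frame: age, gender, duration), `treated_side`,
#'   `truth` (planted structure) and `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 12, seed = 42))
#' coh$features_baseline
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  regions <- region_table(config$region_counts)
  ann <- do.call(rbind, lapply(config$modalities, function(m)
    cbind(modality = m, regions)))
  p <- nrow(ann)
  r <- config$latent_rank
  subjects <- sprintf("sub%03d", seq_len(n))

  # covariates (demographics of the emulated trial)
  age <- round(pmin(pmax(stats::rnorm(n, 56.6, 9.5), 40), 80))
  gender <- factor(ifelse(stats::rbinom(n, 1, 22 / 35) == 1, "male", "female"),
                   levels = c("female", "male"))
  duration <- round(pmax(stats::rnorm(n, 7.2, 2.8), 1), 1)
  covariates <- data.frame(age = age, gender = gender, duration = duration,
                           row.names = subjects)
  treated_side <- ifelse(stats::runif(n) < config$treated_side_fraction,
                         "right", "left")
  Cstd <- scale(cbind(age = age,
                      gender = as.numeric(gender == "male"),
                      duration = duration))
  Cstd[is.nan(Cstd)] <- 0  # degenerate covariate at tiny n

  # planted structure
  s <- config$singular_strength
  if (r > 0) {
    U <- config$imaging_saliences
    if (is.null(U)) U <- sparse_unit_matrix(p, r, config$salience_support)
    V <- config$clinical_saliences
    if (is.null(V)) V <- unit_columns(matrix(stats::rnorm(5 * r), 5, r))
    U <- U[, seq_len(r), drop = FALSE]
    V <- V[, seq_len(r), drop = FALSE]
    tscores <- matrix(stats::rnorm(n * r), n, r)
  } else {
    U <- matrix(0, p, 0); V <- matrix(0, 5, 0)
    tscores <- matrix(0, n, 0)
  }
  U_change <- if (r > 0) sparse_unit_matrix(p, r, config$salience_support)
              else matrix(0, p, 0)

  eff <- config$covariate_effect_sd
  Bx <- matrix(stats::rnorm(3 * p, 0, eff[["imaging"]]), 3, p)
  By <- matrix(stats::rnorm(3 * 5, 0, eff[["clinical"]]), 3, 5)

  signal <- function(load) if (r > 0)
    tscores %*% (t(load) * s[seq_len(r)]) else 0
  Xstd <- signal(U) + Cstd %*% Bx +
    matrix(stats::rnorm(n * p, 0, config$noise_sd_imaging), n, p)
  Ycont <- signal(V) + Cstd %*% By +
    matrix(stats::rnorm(n * 5, 0, config$noise_sd_clinical), n, 5)

  # month-4 drift: latent-linked component on its own saliences + small noise
  cm <- config$change_model
  drift <- (if (r > 0) tscores %*% (t(U_change) * (s[seq_len(r)] * cm$coupling))
            else 0) +
    matrix(stats::rnorm(n * p, 0, cm$drift_sd), n, p)

  place <- t(vapply(ann$modality, modality_placement, numeric(2)))
  to_features <- function(Z) {
    raw <- sweep(sweep(Z, 2, place[, "scale"], "*"), 2, place[, "offset"], "+")
    neg <- ann$modality == "GM_atrophy"
    raw[, neg] <- pmin(raw[, neg, drop = FALSE], 0)
    raw[, !neg] <- pmax(raw[, !neg, drop = FALSE], 0)
    rownames(raw) <- subjects
    feature_table(raw, ann)
  }
  features_baseline <- to_features(Xstd)
  features_month4 <- to_features(Xstd + drift)

  # clinical scores: integer baselines; month-4 via latent-linked % change
  sig_var <- if (r > 0) colSums((t(V) * s[seq_len(r)])^2) else rep(0, 5)
  theo_sd <- sqrt(sig_var + config$noise_sd_clinical^2 + colSums(By^2))
  pct <- sweep(sweep(Ycont, 2, theo_sd, "/"), 2, config$clinical_change_sd, "*")
  pct <- sweep(pct, 2, config$clinical_change_mean, "+")

  base_raw <- sweep(sweep(matrix(stats::rnorm(n * 5), n, 5), 2,
                          config$clinical_baseline_sd, "*"),
                    2, config$clinical_baseline_mean, "+")
  clip <- function(x) pmin(pmax(x, config$min_baseline_score),
                           rep(config$score_max, each = n))
  b <- clip(base_raw)
  m4 <- pmin(pmax(b * (1 + pct / 100), 0), rep(config$score_max, each = n))
  if (config$discretize_clinical) { b <- round(b); m4 <- round(m4) }
  rownames(b) <- rownames(m4) <- subjects
  colnames(b) <- colnames(m4) <- clinical_score_names()

  structure(list(
    features_baseline = features_baseline,
    features_month4 = features_month4,
    clinical_baseline = clinical_table(b, "baseline"),
    clinical_month4 = clinical_table(m4, "month4"),
    covariates = covariates,
    treated_side = treated_side,
    truth = list(latent_scores = tscores, imaging_saliences = U,
                 clinical_saliences = V, change_saliences = U_change,
                 singular_strengths = if (r > 0) s[seq_len(r)] else numeric(0),
                 percent_change_continuous = pct,
                 covariate_coef_imaging = Bx, covariate_coef_clinical = By),
    config = config), class = "synthetic_cohort")
}

sparse_unit_matrix <- function(p, r, support) {
  support <- min(support, p)
  m <- matrix(0, p, r)
  for (k in seq_len(r)) {
    idx <- sample.int(p, support)
    m[idx, k] <- stats::rnorm(support)
  }
  unit_columns(m)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort: ", nrow(x$features_baseline), " subjects, ",
      ncol(x$features_baseline), " imaging features, ",
      ncol(x$clinical_baseline), " clinical scores, planted rank ",
      x$config$latent_rank, "\n", sep = "")
  invisible(x)
}

#' Write a cohort to a directory of CSV tables
#'
#' Writes `features_baseline.csv`, `features_month4.csv`,
#' `clinical_baseline.csv`, `clinical_month4.csv`, `covariates.csv`,
#' `truth.json` and `manifest.json` (config + seed). Round-trips through
#' [read_cohort()] (the planted truth and config are restored from JSON).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(cohort$features_baseline,
                      file.path(dir, "features_baseline.csv"))
  write_feature_table(cohort$features_month4,
                      file.path(dir, "features_month4.csv"))
  write_clinical_table(cohort$clinical_baseline,
                       file.path(dir, "clinical_baseline.csv"))
  write_clinical_table(cohort$clinical_month4,
                       file.path(dir, "clinical_month4.csv"))
  cov <- data.frame(subject = rownames(cohort$covariates),
                    age = cohort$covariates$age,
                    gender = as.character(cohort$covariates$gender),
                    duration = cohort$covariates$duration,
                    treated_side = cohort$treated_side)
  utils::write.csv(cov, file.path(dir, "covariates.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       digits = NA)
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(list(config = cfg, package = "plsbrain",
                            version = as.character(utils::packageVersion("plsbrain"))),
                       file.path(dir, "manifest.json"), digits = NA,
                       auto_unbox = TRUE, force = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  fb <- read_feature_table(file.path(dir, "features_baseline.csv"))
  fm <- read_feature_table(file.path(dir, "features_month4.csv"))
  cb <- read_clinical_table(file.path(dir, "clinical_baseline.csv"), "baseline")
  cm <- read_clinical_table(file.path(dir, "clinical_month4.csv"), "month4")
  cov <- utils::read.csv(file.path(dir, "covariates.csv"))
  covariates <- data.frame(age = cov$age,
                           gender = factor(cov$gender,
                                           levels = c("female", "male")),
                           duration = cov$duration,
                           row.names = cov$subject)
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  config <- NULL
  mj <- file.path(dir, "manifest.json")
  if (file.exists(mj)) {
    manifest <- jsonlite::read_json(mj, simplifyVector = TRUE)
    config <- manifest$config
  }
  structure(list(features_baseline = fb, features_month4 = fm,
                 clinical_baseline = cb, clinical_month4 = cm,
                 covariates = covariates, treated_side = cov$treated_side,
                 truth = truth, config = config),
            class = "synthetic_cohort")
}
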