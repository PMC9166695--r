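#' Clinical motor-score table
#'
#' Holds the five motor scores recorded at one visit: MDS-UPDRS III total,
#' MDS-UPDRS III on the treated side, and the treated-side rigidity,
#' akinesia and tremor sub-scores.
#'
#' @param values numeric matrix, subjects x scores; column names default to
#'   [clinical_score_names()].
#' @param visit `"baseline"` or `"month4"`.
#' @return An object of class `clinical_table`.
#' @export
clinical_table <- function(values, visit = c("baseline", "month4")) {
  visit <- match.arg(visit)
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    if (ncol(values) != length(clinical_score_names()))
      stop("expected ", length(clinical_score_names()), " score columns")
    colnames(values) <- clinical_score_names()
  }
  if (any(values < 0, na.rm = TRUE)) stop("clinical scores must be >= 0")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("sub", seq_len(nrow(values)))
  structure(values, visit = visit, class = "clinical_table")
}

#' Canonical clinical score names
#' @return Character vector of the five motor-score columns.
#' @export
clinical_score_names <- function() {
  c("updrs3_total", "updrs3_treated_side", "rigidity", "akinesia", "tremor")
}

#' @export
print.clinical_table <- function(x, ...) {
  cat("clinical_table (", attr(x, "visit"), "): ", nrow(x), " subjects x ",
      ncol(x), " scores\n", sep = "")
  print(utils::head(unclass(x), 4))
  invisible(x)
}

check_aligned_visits <- function(baseline, month4) {
  if (!identical(rownames(baseline), rownames(month4)))
    stop("baseline and month-4 tables have different subject indices")
  if (!identical(colnames(baseline), colnames(month4)))
    stop("baseline and month-4 tables have different score columns")
}

#' Percent change in clinical scores between visits
#'
#' Per-subject, per-score percent change
#' `(score_month4 - score_baseline) / score_baseline * 100`; negative values
#' are improvements. Cells with a zero baseline score are undefined and are
#' returned as `NA` with a warning (the subject is retained).
#'
#' @param baseline,month4 aligned [clinical_table]s.
#' @return A subjects x scores matrix of class `outcome_table` (percent).
#' @examples
#' b <- clinical_table(cbind(10, 20, 4, 8, 5), "baseline")
#' m <- clinical_table(cbind(5, 10, 1, 8, 2), "month4")
#' percent_change(b, m)
#' @export
percent_change <- function(baseline, month4) {
  check_aligned_visits(baseline, month4)
  b <- unclass(baseline); m <- unclass(month4)
  out <- (m - b) / b * 100
  zero <- b == 0
  if (any(zero)) {
    out[zero] <- NA_real_
    warning(sum(zero), " cell(s) with zero baseline score set to NA ",
            "(percent change undefined)")
  }
  structure(out, class = "outcome_table")
}

#' @export
print.outcome_table <- function(x, ...) {
  cat("outcome_table: percent change, ", nrow(x), " subjects x ", ncol(x),
      " scores (negative = improvement)\n", sep = "")
  print(utils::head(unclass(x), 4))
  invisible(x)
}

#' Paired t-tests of clinical scores before vs after treatment
#'
#' Classical paired t-test per score column on month4 - baseline
#' differences, df = n - 1. Scores whose differences have zero variance are
#' flagged `degenerate` and get `NA` statistics.
#'
#' @param baseline,month4 aligned [clinical_table]s with `n >= 3` subjects.
#' @return Data frame with one row per score: `t`, `df`, `p`, `mean_diff`,
#'   `degenerate`.
#' @export
paired_tests <- function(baseline, month4) {
  check_aligned_visits(baseline, month4)
  if (nrow(baseline) < 3) stop("paired tests need at least 3 subjects")
  d <- unclass(month4) - unclass(baseline)
  res <- lapply(seq_len(ncol(d)), function(j) {
    dj <- d[, j]; dj <- dj[!is.na(dj)]
    if (stats::sd(dj) == 0)
      return(data.frame(t = NA_real_, df = length(dj) - 1L, p = NA_real_,
                        mean_diff = mean(dj), degenerate = TRUE))
    tt <- stats::t.test(dj)
    data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, mean_diff = mean(dj), degenerate = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- colnames(d)
  out
}

#' Cohort descriptive summary
#'
#' Mean +/- SD of every score at both visits, mean +/- SD of the per-subject
#' percent changes (the mean-of-ratios convention: percent changes are
#' computed per subject and then averaged, which is not the percent change
#' of the group means), plus demographic tallies — the layout of a clinical
#' trial descriptives table. Zero-baseline cells are excluded pairwise from
#' the change summaries; the `n` column reports how many subjects
#' contributed.
#'
#' @param baseline,month4 aligned [clinical_table]s.
#' @param covariates optional data frame with `age`, `gender`, `duration`.
#' @param treated_side optional character vector `"left"`/`"right"`.
#' @return A list of class `cohort_summary` with elements `scores` (data
#'   frame: per-score baseline/month4/change mean, SD, n) and
#'   `demographics`.
#' @export
cohort_summary <- function(baseline, month4, covariates = NULL,
                           treated_side = NULL) {
  check_aligned_visits(baseline, month4)
  chg <- suppressWarnings(percent_change(baseline, month4))
  msd <- function(x) {
    x <- x[!is.na(x)]
    c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else NA_real_,
      n = length(x))
  }
  b <- unclass(baseline); m <- unclass(month4); ch <- unclass(chg)
  scores <- data.frame(
    score = colnames(b),
    baseline_mean = apply(b, 2, function(x) msd(x)["mean"]),
    baseline_sd   = apply(b, 2, function(x) msd(x)["sd"]),
    month4_mean   = apply(m, 2, function(x) msd(x)["mean"]),
    month4_sd     = apply(m, 2, function(x) msd(x)["sd"]),
    change_mean   = apply(ch, 2, function(x) msd(x)["mean"]),
    change_sd     = apply(ch, 2, function(x) msd(x)["sd"]),
    n             = apply(ch, 2, function(x) msd(x)["n"]),
    row.names = NULL)
  demo <- list(n_subjects = nrow(b))
  if (!is.null(covariates)) {
    if (!is.null(covariates$age))
      demo$age <- msd(covariates$age)[c("mean", "sd")]
    if (!is.null(covariates$gender))
      demo$gender <- table(covariates$gender)
    if (!is.null(covariates$duration))
      demo$duration <- msd(covariates$duration)[c("mean", "sd")]
  }
  if (!is.null(treated_side)) demo$treated_side <- table(treated_side)
  structure(list(scores = scores, demographics = demo),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, digits = 1, ...) {
  d <- x$demographics
  cat("Cohort of", d$n_subjects, "subjects\n")
  if (!is.null(d$age))
    cat(sprintf("  age: %.1f +/- %.1f\n", d$age["mean"], d$age["sd"]))
  if (!is.null(d$gender))
    cat("  gender:", paste(names(d$gender), as.integer(d$gender),
                           collapse = ", "), "\n")
  if (!is.null(d$duration))
    cat(sprintf("  disease duration: %.1f +/- %.1f y\n",
                d$duration["mean"], d$duration["sd"]))
  if (!is.null(d$treated_side))
    cat("  treated side:", paste(names(d$treated_side),
                                 as.integer(d$treated_side),
                                 collapse = ", "), "\n")
  s <- x$scores
  fmt <- function(m, sd) sprintf("%6.1f +/- %4.1f", m, sd)
  cat("\n  score                 baseline         month4           change (%)   n\n")
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-20s %s %s %s %3d\n", s$score[i],
                fmt(s$baseline_mean[i], s$baseline_sd[i]),
                fmt(s$month4_mean[i], s$month4_sd[i]),
                fmt(s$change_mean[i], s$change_sd[i]), s$n[i]))
  invisible(x)
}

#' Write / read a clinical table CSV
#' @param table a [clinical_table].
#' @param path CSV path.
#' @param visit visit label used when reading.
#' @return The path (write) or a [clinical_table] (read).
#' @export
write_clinical_table <- function(table, path) {
  df <- data.frame(subject = rownames(table), unclass(table),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_clinical_table
#' @export
read_clinical_table <- function(path, visit = "baseline") {
  df <- utils::read.csv(path, check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  clinical_table(vals, visit)
}
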