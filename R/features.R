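#' Condition fMRI voxel time-series
#'
#' Applies the standard resting-state conditioning chain to every voxel:
#' drop the leading `drop_initial` volumes (unstable signal), remove the
#' per-voxel linear trend, regress out the confound series by least squares
#' and, only when `bandpass = TRUE`, apply an ideal frequency-domain
#' band-pass filter. The band-pass is opt-in because the fractional
#' amplitude metric ([falff()]) must see the full spectrum; connectivity
#' style metrics such as [reho()] are computed on the filtered series.
#'
#' @param block a [voxel_block].
#' @param band numeric length-2 frequency interval in Hz (default
#'   `c(0.01, 0.08)`); the upper edge must stay below Nyquist.
#' @param bandpass apply the band-pass filter (default `FALSE`).
#' @param detrend remove the linear trend (default `TRUE`; the intercept is
#'   always removed).
#' @return A [voxel_block] with conditioned data, `drop_initial = 0` and
#'   confounds trimmed to the retained volumes.
#' @export
condition_timeseries <- function(block, band = c(0.01, 0.08),
                                 bandpass = FALSE, detrend = TRUE) {
  stopifnot(inherits(block, "voxel_block"))
  tr <- block$repetition_time
  nyq <- 1 / (2 * tr)
  if (bandpass && band[2] >= nyq)
    stop("band upper edge ", band[2], " Hz is not below Nyquist ", nyq,
         " Hz at TR = ", tr, " s")
  keep <- seq.int(block$drop_initial + 1L, dim(block$data)[4])
  dat <- block$data[, , , keep, drop = FALSE]
  conf <- if (!is.null(block$confounds))
    block$confounds[keep, , drop = FALSE] else NULL

  d <- dim(dat)
  nt <- d[4]
  mat <- t(matrix(dat, prod(d[1:3]), nt))   # nt x nvox
  design <- cbind(intercept = rep(1, nt),
                  if (detrend) cbind(trend = seq_len(nt)),
                  conf)
  res <- stats::lm.fit(design, mat)$residuals
  if (bandpass) res <- apply(res, 2, bandpass_ideal, tr = tr, band = band)
  out <- array(t(res), d)
  voxel_block(out, tr, confounds = conf, drop_initial = 0L)
}

# ideal (boxcar) frequency-domain band-pass; bins with frequency inside
# [band[1], band[2]] (and their negative-frequency mirrors) are kept
bandpass_ideal <- function(x, tr, band) {
  n <- length(x)
  freq <- c(0, seq_len(n - 1)) / (n * tr)
  freq <- pmin(freq, 1 / tr - freq)   # fold to physical frequency
  keep <- freq >= band[1] & freq <= band[2]
  Re(stats::fft(stats::fft(x) * keep, inverse = TRUE)) / n
}

#' Fractional amplitude of low-frequency fluctuation (fALFF)
#'
#' Share of a series' spectral amplitude falling inside the low-frequency
#' band: the sum of square-rooted periodogram power over frequency bins in
#' `band`, divided by the sum over all positive-frequency bins. The series
#' must be conditioned (detrended, confound-regressed) but NOT band-pass
#' filtered — on band-limited data the ratio is identically 1.
#'
#' @param series numeric time-series (length >= 32).
#' @param repetition_time TR in seconds.
#' @param band frequency interval in Hz, default `c(0.01, 0.08)`.
#' @return Ratio in `[0, 1]`; 0 for an identically-zero series.
#' @examples
#' tt <- (0:439) * 2
#' falff(sin(2 * pi * 0.04 * tt), repetition_time = 2)   # in band -> 1
#' @export
falff <- function(series, repetition_time, band = c(0.01, 0.08)) {
  n <- length(series)
  if (n < 32) stop("series too short for a spectral estimate (need >= 32)")
  if (all(series == 0)) return(0)
  nf <- n %/% 2
  freq <- seq_len(nf) / (n * repetition_time)
  amp <- Mod(stats::fft(series))[1 + seq_len(nf)]
  inband <- freq >= band[1] & freq <= band[2]
  if (!any(inband))
    stop("no frequency bins inside [", band[1], ", ", band[2],
         "] Hz at n = ", n, ", TR = ", repetition_time)
  sum(amp[inband]) / sum(amp)
}

#' Regional homogeneity: Kendall's coefficient of concordance
#'
#' Kendall's W among `K` time-series: `W = 12 S / (K^2 (t^3 - t) - K T)`
#' where `S` is the sum over time points of squared deviations of the rank
#' sums from their mean and `T` the standard tie-correction term. 1 means
#' the series rise and fall in lockstep; under independence `E[W] = 1/K`
#' for long series.
#'
#' @param neighborhood K x t numeric matrix (rows = series); `K >= 2`,
#'   `t >= 3`.
#' @return Concordance in `[0, 1]`. If every series is constant the value
#'   is the degenerate sentinel 1 with a warning.
#' @examples
#' reho(rbind(1:5, 1:5, 1:5))   # perfect concordance -> 1
#' @export
reho <- function(neighborhood) {
  m <- as.matrix(neighborhood)
  k <- nrow(m); nt <- ncol(m)
  if (k < 2) stop("need at least 2 series")
  if (nt < 3) stop("need at least 3 time points")
  ranks <- t(apply(m, 1, rank))
  # tie correction per series: sum over tie groups of (m^3 - m)
  tiesum <- sum(apply(m, 1, function(x) {
    tl <- table(x)
    sum(tl^3 - tl)
  }))
  denom <- k^2 * (nt^3 - nt) - k * tiesum
  if (denom <= 0) {
    warning("all series constant; concordance degenerate, returning 1")
    return(1)
  }
  rs <- colSums(ranks)
  s <- sum((rs - mean(rs))^2)
  12 * s / denom
}

#' Voxel-wise ReHo map over cubic neighborhoods
#'
#' Computes Kendall's W for every voxel over its 3x3x3 neighborhood (27
#' voxels in the interior; clipped at the array boundary). Feed it
#' band-pass conditioned data ([condition_timeseries()] with
#' `bandpass = TRUE`).
#'
#' @param block a conditioned [voxel_block].
#' @return 3D array of concordance values.
#' @export
reho_map <- function(block) {
  stopifnot(inherits(block, "voxel_block"))
  d <- dim(block$data)
  out <- array(NA_real_, d[1:3])
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    xi <- max(1, i - 1):min(d[1], i + 1)
    yj <- max(1, j - 1):min(d[2], j + 1)
    zk <- max(1, k - 1):min(d[3], k + 1)
    nb <- block$data[xi, yj, zk, , drop = FALSE]
    nb <- matrix(nb, length(xi) * length(yj) * length(zk), d[4])
    out[i, j, k] <- suppressWarnings(reho(nb))
  }
  out
}

#' Voxel-wise fALFF map
#'
#' @param block a conditioned (unfiltered) [voxel_block].
#' @param band frequency interval in Hz.
#' @return 3D array of fALFF values.
#' @export
falff_map <- function(block, band = c(0.01, 0.08)) {
  stopifnot(inherits(block, "voxel_block"))
  d <- dim(block$data)
  mat <- matrix(block$data, prod(d[1:3]), d[4])
  vals <- apply(mat, 1, falff, repetition_time = block$repetition_time,
                band = band)
  array(vals, d[1:3])
}

#' Regional summary of a voxel map over a parcellation
#'
#' @param voxel_map 3D numeric array (e.g. a gray-matter density or
#'   Jacobian-determinant map, or a metric map from [falff_map()] /
#'   [reho_map()]).
#' @param labels 3D integer label array aligned with `voxel_map`; 0 =
#'   background.
#' @param region_table optional data frame mapping `label` to `region`
#'   metadata; when given, every nonzero label must appear in it.
#' @param statistic summary statistic (only `"mean"`).
#' @return Named numeric vector of per-region means (names = labels, or
#'   region names if `region_table` given). Regions listed in
#'   `region_table` but absent from `labels` are returned as `NA`.
#' @export
regional_summary <- function(voxel_map, labels, region_table = NULL,
                             statistic = "mean") {
  statistic <- match.arg(statistic, "mean")
  if (!identical(dim(voxel_map), dim(labels)))
    stop("voxel_map and labels have different shapes")
  lab <- as.vector(labels)
  nz <- lab != 0
  if (!any(nz)) stop("parcellation has no nonzero labels")
  means <- tapply(as.vector(voxel_map)[nz], lab[nz], mean)
  means <- stats::setNames(as.vector(means), dimnames(means)[[1]])
  if (is.null(region_table)) return(means)
  stray <- setdiff(names(means), as.character(region_table$label))
  if (length(stray))
    stop("labels missing from region_table: ", paste(stray, collapse = ", "))
  out <- means[as.character(region_table$label)]
  names(out) <- region_table$region
  if (anyNA(out))
    warning("region(s) with zero voxels: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  out
}

#' Read a 4D NIfTI file into a voxel block
#'
#' Thin wrapper over the RNifti package (suggested dependency); the TR is
#' taken from the header's 4th pixdim unless overridden.
#'
#' @param path NIfTI file.
#' @param repetition_time optional TR override in seconds.
#' @param confounds optional t x k confound matrix or TSV path.
#' @param drop_initial leading volumes to drop later (default 10).
#' @return A [voxel_block].
#' @export
read_voxel_nifti <- function(path, repetition_time = NULL, confounds = NULL,
                             drop_initial = 10L) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI requires the RNifti package")
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4) stop("expected a 4D NIfTI image")
  if (is.null(repetition_time)) {
    repetition_time <- RNifti::pixdim(img)[4]
    if (!is.finite(repetition_time) || repetition_time <= 0)
      stop("TR missing from NIfTI header; pass repetition_time (--tr)")
  }
  if (is.character(confounds))
    confounds <- as.matrix(utils::read.delim(confounds))
  voxel_block(unclass(img)[, , , , drop = FALSE], repetition_time,
              confounds = confounds, drop_initial = drop_initial)
}
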