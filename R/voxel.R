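#' Configuration for synthetic voxel time-series
#'
#' Describes a small 4D resting-state-like block used to validate the
#' spectral and concordance metrics: each voxel's series mixes a sinusoid
#' inside the 0.01-0.08 Hz band, a sinusoid outside it, a signal shared
#' within 3x3x3 neighborhoods, and white noise. Defaults match a typical
#' EPI protocol (450 volumes at TR = 2 s).
#'
#' @param grid_shape 3D extent (voxels per axis).
#' @param n_volumes number of time points (> 10, so dropping initial
#'   volumes leaves data).
#' @param repetition_time TR in seconds (> 0).
#' @param in_band_freq,out_band_freq frequencies (Hz) of the two planted
#'   sinusoids; both must be below Nyquist `1/(2 TR)`.
#' @param in_band_amplitude,out_band_amplitude sinusoid amplitudes.
#' @param noise_sd white-noise SD.
#' @param neighbor_coupling share in `[0, 1]` of a neighborhood-common
#'   signal: 1 makes all voxels of a 3x3x3 tile identical, 0 makes them
#'   independent.
#' @param seed integer RNG seed.
#' @return A list of class `timeseries_config`.
#' @export
timeseries_config <- function(grid_shape = c(6, 6, 6), n_volumes = 450,
                              repetition_time = 2.0,
                              in_band_freq = 0.04, out_band_freq = 0.15,
                              in_band_amplitude = 1, out_band_amplitude = 1,
                              noise_sd = 1, neighbor_coupling = 0.5,
                              seed = 1L) {
  if (n_volumes <= 10) stop("n_volumes must exceed 10")
  if (repetition_time <= 0) stop("repetition_time must be > 0")
  nyq <- 1 / (2 * repetition_time)
  if (in_band_freq >= nyq || out_band_freq >= nyq)
    stop("planted frequencies must be below Nyquist (", nyq, " Hz at TR = ",
         repetition_time, " s)")
  if (neighbor_coupling < 0 || neighbor_coupling > 1)
    stop("neighbor_coupling must be in [0, 1]")
  structure(as.list(environment())[c("grid_shape", "n_volumes",
                                     "repetition_time", "in_band_freq",
                                     "out_band_freq", "in_band_amplitude",
                                     "out_band_amplitude", "noise_sd",
                                     "neighbor_coupling", "seed")],
            class = "timeseries_config")
}

#' 4D voxel block container
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param repetition_time TR in seconds.
#' @param confounds optional t x k matrix of nuisance series (e.g. motion
#'   parameters), aligned with the full time axis.
#' @param drop_initial number of leading volumes to discard during
#'   conditioning (default 10).
#' @return An object of class `voxel_block`.
#' @export
voxel_block <- function(data, repetition_time, confounds = NULL,
                        drop_initial = 10L) {
  stopifnot(length(dim(data)) == 4, repetition_time > 0)
  nt <- dim(data)[4]
  if (nt <= drop_initial)
    stop("block has ", nt, " volumes; cannot drop ", drop_initial)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != nt)
      stop("confound rows (", nrow(confounds), ") must match volumes (", nt, ")")
  }
  structure(list(data = data, repetition_time = repetition_time,
                 confounds = confounds, drop_initial = as.integer(drop_initial)),
            class = "voxel_block")
}

#' @export
print.voxel_block <- function(x, ...) {
  d <- dim(x$data)
  cat("voxel_block: ", paste(d[1:3], collapse = " x "), " voxels x ", d[4],
      " volumes, TR = ", x$repetition_time, " s, ",
      if (is.null(x$confounds)) 0 else ncol(x$confounds), " confound(s)\n",
      sep = "")
  invisible(x)
}

#' Generate a synthetic voxel block
#'
#' @param config a [timeseries_config()].
#' @return A [voxel_block] with six synthetic motion-like confound series.
#' @examples
#' vb <- generate_voxel_block(timeseries_config(grid_shape = c(3, 3, 3),
#'                                              n_volumes = 60, seed = 3))
#' dim(vb$data)
#' @export
generate_voxel_block <- function(config = timeseries_config()) {
  stopifnot(inherits(config, "timeseries_config"))
  set.seed(config$seed)
  g <- config$grid_shape
  nt <- config$n_volumes
  tt <- (seq_len(nt) - 1) * config$repetition_time
  sin_in <- config$in_band_amplitude * sin(2 * pi * config$in_band_freq * tt)
  sin_out <- config$out_band_amplitude * sin(2 * pi * config$out_band_freq * tt)

  # neighborhood tiles: 3x3x3 blocks share one latent series
  tile <- function(idx) (idx - 1) %/% 3
  nx <- g[1]; ny <- g[2]; nz <- g[3]
  tiles <- array(0L, g)
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx))
    tiles[i, j, k] <- tile(i) + (max(tile(seq_len(nx))) + 1) *
      (tile(j) + (max(tile(seq_len(ny))) + 1) * tile(k))
  utiles <- sort(unique(as.vector(tiles)))
  shared <- matrix(stats::rnorm(length(utiles) * nt), length(utiles), nt)

  nvox <- prod(g)
  c0 <- config$neighbor_coupling
  dat <- array(0, c(g, nt))
  flat <- matrix(0, nvox, nt)
  tvec <- as.vector(tiles)
  own <- matrix(stats::rnorm(nvox * nt), nvox, nt)
  for (v in seq_len(nvox)) {
    sh <- shared[match(tvec[v], utiles), ]
    flat[v, ] <- sin_in + sin_out +
      config$noise_sd * (c0 * sh + (1 - c0) * own[v, ])
  }
  dat <- array(t(flat), c(nt, g))          # reorder: want (x,y,z,t)
  dat <- aperm(dat, c(2, 3, 4, 1))
  confounds <- apply(matrix(stats::rnorm(nt * 6, 0, 0.05), nt, 6), 2, cumsum)
  colnames(confounds) <- c(paste0("trans_", c("x", "y", "z")),
                           paste0("rot_", c("x", "y", "z")))
  voxel_block(dat, config$repetition_time, confounds)
}
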