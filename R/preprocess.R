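# Resting-state denoising chain: confound regression -> polynomial
# detrending -> zero-phase low-pass -> global signal regression -> spatial
# smoothing, plus the tSNR utility. Each step takes and returns a
# bold_series; the fixed ordering is enforced by preprocess_rest().

# series data as time x voxel matrix and back
series_matrix <- function(series) {
  d <- dim(series$data)
  t(matrix(series$data, nrow = prod(d[1:3]), ncol = d[4]))
}

matrix_series <- function(mat, template) {
  d <- dim(template$data)
  bold_series(array(t(mat), dim = d), template$affine, template$tr)
}

#' Remove nuisance time courses by multilinear regression
#'
#' Replaces every voxel time course by its least-squares residual against
#' an intercept plus the supplied confound columns (e.g. motion parameters).
#'
#' @param series a [bold_series()].
#' @param confounds numeric matrix, one row per volume, one column per
#'   nuisance regressor.
#' @return A [bold_series()] of residuals (orthogonal to every confound).
#' @export
regress_confounds <- function(series, confounds) {
  stopifnot(inherits(series, "bold_series"))
  confounds <- as.matrix(confounds)
  n_t <- dim(series$data)[4]
  if (nrow(confounds) != n_t)
    stop("confounds have ", nrow(confounds), " rows but series has ",
         n_t, " volumes")
  X <- cbind(1, confounds)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    warning("confound design is rank deficient; using pivoted least squares")
  resid <- qr.resid(qx, series_matrix(series))
  matrix_series(resid, series)
}

#' Remove a per-voxel polynomial baseline
#'
#' Fits and subtracts a least-squares polynomial of the given order from
#' every voxel time course. The fit uses an orthonormal polynomial basis
#' (numerically stable; the result is basis-invariant).
#'
#' @param series a [bold_series()].
#' @param order polynomial order >= 0 (0 removes the mean; default 3).
#' @return A detrended [bold_series()].
#' @export
detrend_polynomial <- function(series, order = 3L) {
  stopifnot(inherits(series, "bold_series"))
  if (order < 0) stop("polynomial order must be >= 0")
  n_t <- dim(series$data)[4]
  if (n_t <= order + 1L)
    stop("need more than order+1 volumes to detrend")
  X <- cbind(1, drift_basis(n_t, order))
  resid <- qr.resid(qr(X), series_matrix(series))
  matrix_series(resid, series)
}

#' Zero-phase low-pass filter
#'
#' Frequency-domain apodization: unit gain below the cutoff, raised-cosine
#' roll-off of width `transition_hz` centred on the cutoff, zero above. The
#' filter is applied symmetrically in the DFT domain, so it introduces no
#' phase shift.
#'
#' @param series a [bold_series()].
#' @param cutoff_hz cutoff frequency in Hz (default 0.1); must be below the
#'   Nyquist frequency 1/(2 tr).
#' @param transition_hz roll-off width in Hz.
#' @return A filtered [bold_series()].
#' @export
lowpass_filter <- function(series, cutoff_hz = 0.1, transition_hz = 0.02) {
  stopifnot(inherits(series, "bold_series"))
  nyq <- 1 / (2 * series$tr)
  if (cutoff_hz >= nyq)
    stop(sprintf("cutoff %.4g Hz is at/above Nyquist %.4g Hz",
                 cutoff_hz, nyq))
  n_t <- dim(series$data)[4]
  f <- fft_frequencies(n_t, series$tr)
  lo <- cutoff_hz - transition_hz / 2
  hi <- cutoff_hz + transition_hz / 2
  gain <- ifelse(f <= lo, 1,
                 ifelse(f >= hi, 0, 0.5 * (1 + cos(pi * (f - lo) / (hi - lo)))))
  mat <- series_matrix(series)
  out <- Re(stats::mvfft(stats::mvfft(mat) * gain, inverse = TRUE)) / n_t
  matrix_series(out, series)
}

#' Global signal regression
#'
#' Computes the mean time course over the brain mask and regresses it (plus
#' an intercept) out of every voxel.
#'
#' @param series a [bold_series()].
#' @param brain_mask a non-empty [roi_mask()] on the same grid.
#' @return A [bold_series()] whose voxel courses are orthogonal to the input
#'   global mean.
#' @export
global_signal_regress <- function(series, brain_mask) {
  stopifnot(inherits(series, "bold_series"), inherits(brain_mask, "roi_mask"))
  stop_if_grid_mismatch(series, brain_mask, "series and brain mask")
  if (!any(brain_mask$values)) stop("empty brain mask")
  mat <- series_matrix(series)
  g <- rowMeans(mat[, as.vector(brain_mask$values), drop = FALSE])
  resid <- qr.resid(qr(cbind(1, g)), mat)
  matrix_series(resid, series)
}

#' Isotropic Gaussian spatial smoothing
#'
#' Separable 3D Gaussian convolution with sigma = fwhm / (2 sqrt(2 ln 2))
#' per axis, in mm (converted to voxels through the affine). 4D input is
#' smoothed volume by volume. Edges are zero-padded; masks should be applied
#' after smoothing.
#'
#' @param x a [bold_series()], [stat_map()], or 3D/4D array (then
#'   `voxel_mm` must be given).
#' @param fwhm_mm full width at half maximum in mm (0 = identity).
#' @param voxel_mm voxel edge lengths, only for bare arrays.
#' @return Same type as the input.
#' @export
gaussian_smooth <- function(x, fwhm_mm, voxel_mm = NULL) {
  if (fwhm_mm < 0) stop("fwhm must be >= 0")
  if (inherits(x, "bold_series")) {
    vs <- voxel_sizes_mm(x$affine)
    d <- dim(x$data)
    out <- x$data
    for (tt in seq_len(d[4]))
      out[, , , tt] <- smooth3d(x$data[, , , tt], fwhm_mm, vs)
    return(bold_series(out, x$affine, x$tr))
  }
  if (inherits(x, "stat_map")) {
    vs <- voxel_sizes_mm(x$affine)
    return(stat_map(smooth3d(x$values, fwhm_mm, vs), x$affine, x$stat_kind,
                    x$dof, x$provenance))
  }
  if (is.array(x)) {
    if (is.null(voxel_mm)) stop("voxel_mm required for bare arrays")
    voxel_mm <- rep(voxel_mm, length.out = 3)
    if (length(dim(x)) == 3L) return(smooth3d(x, fwhm_mm, voxel_mm))
    if (length(dim(x)) == 4L) {
      out <- x
      for (tt in seq_len(dim(x)[4]))
        out[, , , tt] <- smooth3d(x[, , , tt], fwhm_mm, voxel_mm)
      return(out)
    }
  }
  stop("cannot smooth object of class ", class(x)[1])
}

# separable zero-padded Gaussian convolution of one volume
smooth3d <- function(vol, fwhm_mm, voxel_mm) {
  if (fwhm_mm == 0) return(vol)
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / voxel_mm
  d <- dim(vol)
  for (ax in 1:3) {
    K <- gauss_conv_matrix(d[ax], sigma_vox[ax])
    vol <- apply_along_axis(vol, ax, K)
  }
  vol
}

# n x n zero-padded convolution matrix for a unit-sum Gaussian kernel
gauss_conv_matrix <- function(n, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (off in (-r):r) {
    idx <- seq_len(n)
    jdx <- idx + off
    ok <- jdx >= 1 & jdx <= n
    K[cbind(idx[ok], jdx[ok])] <- K[cbind(idx[ok], jdx[ok])] + k[off + r + 1]
  }
  K
}

apply_along_axis <- function(vol, axis, K) {
  d <- dim(vol)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(vol, perm), nrow = d[axis])
  m <- K %*% m
  aperm(array(m, dim = d[perm]), order(perm))
}

#' Temporal signal-to-noise ratio over a mask
#'
#' Per-voxel temporal mean divided by temporal SD, averaged over the mask.
#' Zero-variance voxels are excluded with a warning.
#'
#' @param series a [bold_series()].
#' @param mask a non-empty [roi_mask()] (typically white matter).
#' @return Scalar tSNR.
#' @export
temporal_snr <- function(series, mask) {
  stopifnot(inherits(series, "bold_series"), inherits(mask, "roi_mask"))
  stop_if_grid_mismatch(series, mask, "series and mask")
  if (!any(mask$values)) stop("empty mask")
  mat <- series_matrix(series)[, as.vector(mask$values), drop = FALSE]
  mu <- colMeans(mat)
  sdv <- apply(mat, 2, stats::sd)
  bad <- sdv == 0
  if (any(bad)) {
    warning(sum(bad), " zero-variance voxel(s) excluded from tSNR")
    mu <- mu[!bad]; sdv <- sdv[!bad]
  }
  if (!length(mu)) stop("no voxels with temporal variance in mask")
  mean(mu / sdv)
}

#' Preprocessing configuration
#'
#' @param poly_order detrending polynomial order (default 3).
#' @param lowpass_hz low-pass cutoff in Hz (default 0.1).
#' @param fwhm_mm smoothing kernel FWHM in mm (default 8).
#' @param do_gsr apply global signal regression (default TRUE).
#' @param confounds optional time x k nuisance matrix.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(poly_order = 3L, lowpass_hz = 0.1,
                              fwhm_mm = 8, do_gsr = TRUE, confounds = NULL) {
  stopifnot(poly_order >= 0, lowpass_hz > 0, fwhm_mm >= 0)
  structure(list(poly_order = as.integer(poly_order),
                 lowpass_hz = lowpass_hz, fwhm_mm = fwhm_mm,
                 do_gsr = isTRUE(do_gsr), confounds = confounds),
            class = "preprocess_config")
}

#' Run the full resting-state denoising chain
#'
#' Fixed order: confound regression (if confounds given), polynomial
#' detrending, zero-phase low-pass filtering, global signal regression,
#' Gaussian smoothing. A step log is attached as attribute `"steps"`.
#'
#' @param series a [bold_series()].
#' @param brain_mask non-empty [roi_mask()] used for the global signal.
#' @param config a [preprocess_config()].
#' @return The preprocessed [bold_series()].
#' @export
preprocess_rest <- function(series, brain_mask,
                            config = preprocess_config()) {
  stopifnot(inherits(series, "bold_series"),
            inherits(config, "preprocess_config"))
  steps <- character(0)
  if (!is.null(config$confounds)) {
    series <- regress_confounds(series, config$confounds)
    steps <- c(steps, sprintf("regress_confounds(k=%d)",
                              ncol(as.matrix(config$confounds))))
  }
  series <- detrend_polynomial(series, config$poly_order)
  steps <- c(steps, sprintf("detrend_polynomial(order=%d)",
                            config$poly_order))
  series <- lowpass_filter(series, config$lowpass_hz)
  steps <- c(steps, sprintf("lowpass_filter(cutoff=%g Hz)",
                            config$lowpass_hz))
  if (config$do_gsr) {
    series <- global_signal_regress(series, brain_mask)
    steps <- c(steps, "global_signal_regress")
  }
  if (config$fwhm_mm > 0) {
    series <- gaussian_smooth(series, config$fwhm_mm)
    steps <- c(steps, sprintf("gaussian_smooth(fwhm=%g mm)", config$fwhm_mm))
  }
  attr(series, "steps") <- steps
  series
}
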