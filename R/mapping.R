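# Statistical mapping: task GLM t-maps, seed-based correlation t-maps, and
# spatial ICA with automated sensorimotor component selection.

#' Canonical double-gamma hemodynamic response function
#'
#' Response gamma peaking at 6 s minus an undershoot gamma peaking at 16 s
#' with ratio 1/6, normalized to unit peak.
#'
#' @param t time in seconds (vector).
#' @return HRF values at `t`.
#' @export
canonical_hrf <- function(t) {
  h <- stats::dgamma(t, shape = 7, rate = 1) -
    stats::dgamma(t, shape = 17, rate = 1) / 6
  h / max(stats::dgamma(0:32, shape = 7, rate = 1))
}

# convolve a per-volume boxcar with the HRF sampled at TR; truncate to the
# run length
convolve_hrf <- function(boxcar, tr, hrf_span_s = 32) {
  n_t <- length(boxcar)
  h <- canonical_hrf(seq(0, hrf_span_s, by = tr))
  y <- stats::convolve(boxcar, rev(h), type = "open")
  y[seq_len(n_t)]
}

#' Task regressor from a block design
#'
#' Boxcar of the chosen active blocks convolved with the canonical HRF,
#' truncated to the run length and mean-centred.
#'
#' @param design a [block_design()].
#' @param side "left", "right", or "both".
#' @return Numeric time course of length `design$n_volumes`.
#' @export
build_task_regressor <- function(design, side = c("left", "right", "both")) {
  side <- match.arg(side)
  stopifnot(inherits(design, "block_design"))
  box <- design_boxcar(design, side)
  if (all(box == 0)) stop("design yields an all-zero regressor")
  r <- convolve_hrf(box, design$tr)
  r - mean(r)
}

#' Per-voxel GLM t-map
#'
#' Ordinary least squares of every voxel time course on
#' `[intercept | regressor | confounds]`; the map holds the t statistic of
#' the regressor coefficient. No autocorrelation correction is applied
#' (single-run fixed-effects analysis). Voxels with zero residual variance
#' get a capped |t| of 1e8.
#'
#' @param series a [bold_series()].
#' @param regressor numeric time course, length = number of volumes.
#' @param confounds optional time x k nuisance matrix.
#' @param provenance method label stored on the map.
#' @return A [stat_map()] of kind "t" with `dof = t - p`.
#' @export
glm_tmap <- function(series, regressor, confounds = NULL,
                     provenance = "tb") {
  stopifnot(inherits(series, "bold_series"))
  n_t <- dim(series$data)[4]
  if (length(regressor) != n_t)
    stop("regressor length ", length(regressor), " != ", n_t, " volumes")
  X <- cbind(intercept = 1, reg = regressor)
  if (!is.null(confounds)) X <- cbind(X, as.matrix(confounds))
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("design matrix is rank deficient (collinear regressor/confounds)")
  Y <- series_matrix(series)
  coefs <- qr.coef(qx, Y)
  resid <- qr.resid(qx, Y)
  dof <- n_t - ncol(X)
  rss <- colSums(resid^2)
  XtX_inv <- chol2inv(qr.R(qx))
  se <- sqrt(pmax(rss / dof, 0) * XtX_inv[2, 2])
  tval <- ifelse(se > 0, coefs[2, ] / se,
                 sign(coefs[2, ]) * 1e8)
  tval[coefs[2, ] == 0 & se == 0] <- 0
  tval <- pmin(pmax(tval, -1e8), 1e8)
  stat_map(array(tval, dim = dim(series$data)[1:3]), series$affine,
           "t", dof = dof, provenance = provenance)
}

#' Mean seed time course
#'
#' Unweighted mean over the ROI voxels at each time point.
#'
#' @param series a [bold_series()].
#' @param roi a non-empty [roi_mask()] on the same grid.
#' @return Numeric time course.
#' @export
seed_timecourse <- function(series, roi) {
  stopifnot(inherits(series, "bold_series"), inherits(roi, "roi_mask"))
  stop_if_grid_mismatch(series, roi, "series and seed ROI")
  if (!any(roi$values)) stop("empty seed ROI")
  rowMeans(series_matrix(series)[, as.vector(roi$values), drop = FALSE])
}

#' Seed-based t-map
#'
#' Enters the seed time course as the regressor of a per-voxel
#' fixed-effects GLM.
#'
#' @param series a [bold_series()].
#' @param seed_tc seed time course (e.g. from [seed_timecourse()]).
#' @param confounds optional nuisance matrix.
#' @param provenance "aROI" or "fROI".
#' @return A [stat_map()] of kind "t".
#' @export
sba_tmap <- function(series, seed_tc, confounds = NULL,
                     provenance = "aROI") {
  if (stats::sd(seed_tc) == 0) stop("seed time course is constant")
  glm_tmap(series, seed_tc - mean(seed_tc), confounds,
           provenance = provenance)
}

# --- spatial ICA -----------------------------------------------------------

#' Spatial independent component analysis
#'
#' PCA whitening of the in-brain spatial data to `n_components`, followed by
#' fixed-point (FastICA-style) negentropy maximization with the logcosh
#' contrast and symmetric decorrelation. Each component's spatial map is
#' z-scored over the brain mask and its sign fixed so the spatial skewness
#' is non-negative. Deterministic under a fixed seed.
#'
#' @param series a [bold_series()] (typically preprocessed rest data).
#' @param brain_mask non-empty [roi_mask()]; ICA runs on these voxels.
#' @param n_components number of components (default 20); must be < number
#'   of volumes.
#' @param seed RNG seed for the unmixing initialisation.
#' @param max_iter,tol fixed-point iteration controls.
#' @return An `ica_decomposition`: list with `spatial_maps` (list of 3D
#'   z-scored arrays, 0 outside the brain mask), `time_courses`
#'   (volumes x components), `n_components`, `seed`, and convergence info.
#' @export
spatial_ica <- function(series, brain_mask, n_components = 20L, seed = 1L,
                        max_iter = 500L, tol = 1e-6) {
  stopifnot(inherits(series, "bold_series"), inherits(brain_mask, "roi_mask"))
  stop_if_grid_mismatch(series, brain_mask, "series and brain mask")
  n_t <- dim(series$data)[4]
  k <- as.integer(n_components)
  if (k >= n_t) stop("n_components must be below the number of volumes")
  inb <- as.vector(brain_mask$values)
  X <- series_matrix(series)[, inb, drop = FALSE]   # t x V
  X <- X - rowMeans(X)                              # centre each volume
  n_v <- ncol(X)

  # PCA whitening of the spatial data: rows of Z are uncorrelated, unit var
  sv <- svd(X, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  if (any(d < 1e-12)) stop("data rank below n_components")
  Z <- t(sv$v[, seq_len(k), drop = FALSE]) * sqrt(n_v)   # k x V, white

  set.seed(seed)
  W <- qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
  it <- 0L; delta <- Inf
  while (it < max_iter && delta > tol) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gp <- rowMeans(1 - G^2)
    W1 <- (G %*% t(Z)) / n_v - diag(gp, k) %*% W
    # symmetric decorrelation
    s <- svd(W1)
    W1 <- s$u %*% t(s$v)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    it <- it + 1L
  }
  S <- W %*% Z                                       # k x V spatial sources
  # sign: non-negative spatial skewness
  sk <- rowMeans(S^3)
  flip <- ifelse(sk < 0, -1, 1)
  S <- S * flip

  # time courses: X ~ A S  =>  A = X S' (S S')^{-1}
  A <- X %*% t(S) %*% solve(S %*% t(S))

  dims <- dim(series$data)[1:3]
  maps <- vector("list", k)
  for (i in seq_len(k)) {
    v <- S[i, ]
    v <- (v - mean(v)) / stats::sd(v)
    m <- array(0, dim = dims)
    m[inb] <- v
    maps[[i]] <- m
  }
  structure(list(n_components = k, spatial_maps = maps, time_courses = A,
                 seed = as.integer(seed), affine = series$affine,
                 brain_mask = brain_mask, iterations = it,
                 converged = delta <= tol),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> %d components, %s after %d iterations\n",
              x$n_components,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Select the sensorimotor ICA component
#'
#' Automated stand-in for expert selection: picks the component whose
#' supra-threshold voxels are most concentrated inside the sensorimotor
#' mask, scoring each component by
#' (supra-threshold voxels inside mask) / (supra-threshold voxels total).
#' Ties go to the higher inside count, then the lower component index.
#'
#' @param dec an `ica_decomposition` from [spatial_ica()].
#' @param sensorimotor_mask non-empty [roi_mask()] (pre/postcentral gyri).
#' @param z_thr z threshold used for the counts (default 2).
#' @return A [stat_map()] of kind "z" (provenance "ICA") with the selection
#'   report in attribute `"selection"`.
#' @export
select_sensorimotor_component <- function(dec, sensorimotor_mask,
                                          z_thr = 2) {
  stopifnot(inherits(dec, "ica_decomposition"),
            inherits(sensorimotor_mask, "roi_mask"))
  if (!any(sensorimotor_mask$values)) stop("empty sensorimotor mask")
  inside <- as.vector(sensorimotor_mask$values)
  k <- dec$n_components
  n_in <- n_tot <- numeric(k)
  for (i in seq_len(k)) {
    supra <- as.vector(dec$spatial_maps[[i]]) >= z_thr
    n_tot[i] <- sum(supra)
    n_in[i] <- sum(supra & inside)
  }
  if (all(n_in == 0))
    stop("no sensorimotor component: no component has supra-threshold ",
         "voxels inside the mask")
  score <- ifelse(n_tot > 0, n_in / n_tot, 0)
  best <- order(-score, -n_in, seq_len(k))[1]
  out <- stat_map(dec$spatial_maps[[best]], dec$affine, "z",
                  provenance = "ICA")
  attr(out, "selection") <- list(component = best, score = score[best],
                                 n_inside = n_in[best], n_total = n_tot[best],
                                 z_thr = z_thr, scores = score,
                                 note = paste("automated selection;",
                                              "stand-in for expert choice"))
  out
}
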