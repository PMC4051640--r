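#' 4D BOLD series container
#'
#' Wraps a 4D array (x, y, z, t) together with its voxel-to-world affine and
#' repetition time. All preprocessing and mapping operations take and return
#' this container.
#'
#' @param data 4D numeric array, dimensions (x, y, z, t) with t >= 2.
#' @param affine 4x4 voxel-to-world transform (mm); voxel indices are 1-based
#'   in R and mapped through the NIfTI 0-based convention internally.
#' @param tr repetition time in seconds.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, affine, tr) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  if (dim(data)[4] < 2L) stop("a BOLD series needs at least 2 volumes")
  affine <- check_affine(affine)
  if (!all(is.finite(data))) stop("non-finite values in BOLD series")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("tr must be a positive scalar (seconds)")
  structure(list(data = data, affine = affine, tr = as.numeric(tr)),
            class = "bold_series")
}

#' 3D statistical map (t or z per voxel)
#'
#' @param values 3D numeric array of statistic values.
#' @param affine 4x4 voxel-to-world transform.
#' @param stat_kind "t" or "z".
#' @param dof residual degrees of freedom (t maps only; NA for z).
#' @param provenance method label: one of "tb", "aROI", "fROI", "ICA".
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(values, affine, stat_kind = c("t", "z"), dof = NA_real_,
                     provenance = c("tb", "aROI", "fROI", "ICA")) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  stat_kind <- match.arg(stat_kind)
  provenance <- match.arg(provenance)
  affine <- check_affine(affine)
  if (!all(is.finite(values))) stop("non-finite values in statistical map")
  structure(list(values = values, affine = affine, stat_kind = stat_kind,
                 dof = as.numeric(dof), provenance = provenance),
            class = "stat_map")
}

#' Labelled binary 3D mask
#'
#' @param values 3D array coercible to logical (0/1).
#' @param affine 4x4 voxel-to-world transform.
#' @param label region label (e.g. "precentral_R", "lesion", "hand_aROI").
#' @param dilation_voxels provenance: number of 6-connected dilation
#'   iterations already applied (0 if undilated).
#' @param allow_empty permit an all-FALSE mask (e.g. a zero-radius lesion).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(values, affine, label = "mask", dilation_voxels = 0L,
                     allow_empty = FALSE) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (is.numeric(values)) {
    u <- unique(as.vector(values))
    if (!all(u %in% c(0, 1)))
      stop("mask values must be binary (0/1); got other values")
  }
  v <- array(as.logical(values), dim = dim(values))
  if (!allow_empty && !any(v)) stop("mask '", label, "' is empty")
  affine <- check_affine(affine)
  structure(list(values = v, affine = affine, label = as.character(label),
                 dilation_voxels = as.integer(dilation_voxels)),
            class = "roi_mask")
}

check_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  if (!all(is.finite(affine))) stop("affine has non-finite entries")
  d <- det(affine[1:3, 1:3])
  if (abs(d) < .Machine$double.eps) stop("affine is singular")
  affine
}

grid_dim <- function(x) {
  if (inherits(x, "bold_series")) dim(x$data)[1:3]
  else if (inherits(x, "stat_map")) dim(x$values)
  else if (inherits(x, "roi_mask")) dim(x$values)
  else if (is.array(x)) dim(x)[1:3]
  else stop("cannot determine grid for object of class ", class(x)[1])
}

#' @keywords internal
same_grid <- function(a, b, tol = 1e-6) {
  all(grid_dim(a) == grid_dim(b)) &&
    max(abs(get_affine(a) - get_affine(b))) < tol
}

get_affine <- function(x) {
  if (is.list(x) && !is.null(x$affine)) x$affine
  else stop("object has no affine")
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop("grid mismatch between ", what,
         ": dims/affines do not agree", call. = FALSE)
  invisible(TRUE)
}

# --- affine geometry -------------------------------------------------------

#' Map 1-based voxel indices to world mm
#'
#' @param affine 4x4 transform following the NIfTI convention (0-based voxel
#'   indices to mm).
#' @param ijk n x 3 matrix (or length-3 vector) of 1-based voxel indices.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(affine, ijk) {
  ijk <- matrix(ijk, ncol = 3L)
  xyz1 <- cbind(ijk - 1, 1) %*% t(affine)
  xyz1[, 1:3, drop = FALSE]
}

#' Map world mm to (fractional) 1-based voxel indices
#' @param affine 4x4 voxel-to-world transform.
#' @param xyz n x 3 matrix (or length-3 vector) of world coordinates in mm.
#' @return n x 3 matrix of fractional 1-based voxel indices.
#' @export
world_to_voxel <- function(affine, xyz) {
  xyz <- matrix(xyz, ncol = 3L)
  ijk0 <- cbind(xyz, 1) %*% t(solve(affine))
  ijk0[, 1:3, drop = FALSE] + 1
}

# voxel edge lengths in mm (column norms of the affine rotation block)
voxel_sizes_mm <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# world-mm coordinates of every voxel centre, as three arrays on the grid
grid_coordinates_mm <- function(dims, affine) {
  i <- array(rep(seq_len(dims[1]), times = prod(dims[2:3])), dim = dims)
  j <- array(rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]),
             dim = dims)
  k <- array(rep(seq_len(dims[3]), each = prod(dims[1:2])), dim = dims)
  xyz <- voxel_to_world(affine, cbind(as.vector(i), as.vector(j),
                                      as.vector(k)))
  list(x = array(xyz[, 1], dim = dims),
       y = array(xyz[, 2], dim = dims),
       z = array(xyz[, 3], dim = dims))
}

# mm coordinates of mask voxels (n x 3)
mask_coordinates_mm <- function(mask) {
  idx <- which(mask$values, arr.ind = TRUE)
  voxel_to_world(mask$affine, idx)
}

#' Dice coefficient of two binary masks
#'
#' @param a,b `roi_mask` objects (or logical arrays) on the same grid.
#' @return Scalar in `[0, 1]`; 2|A&B| / (|A| + |B|).
#' @export
dice_coefficient <- function(a, b) {
  va <- if (inherits(a, "roi_mask")) a$values else as.logical(a)
  vb <- if (inherits(b, "roi_mask")) b$values else as.logical(b)
  stopifnot(length(va) == length(vb))
  na <- sum(va); nb <- sum(vb)
  if (na + nb == 0) return(NA_real_)
  2 * sum(va & vb) / (na + nb)
}

# --- print methods ---------------------------------------------------------

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %d x %d x %d voxels, %d volumes, TR %.3g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  vs <- voxel_sizes_mm(x$affine)
  cat(sprintf("  voxel size %.3g x %.3g x %.3g mm\n", vs[1], vs[2], vs[3]))
  invisible(x)
}

#' @export
print.stat_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<stat_map> %s-map (%s), %d x %d x %d, range [%.3g, %.3g]",
              x$stat_kind, x$provenance, d[1], d[2], d[3],
              min(x$values), max(x$values)))
  if (is.finite(x$dof)) cat(sprintf(", dof %g", x$dof))
  cat("\n")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<roi_mask> '%s', %d x %d x %d, %d voxels set",
              x$label, d[1], d[2], d[3], sum(x$values)))
  if (x$dilation_voxels > 0)
    cat(sprintf(" (dilated %d voxels)", x$dilation_voxels))
  cat("\n")
  invisible(x)
}
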