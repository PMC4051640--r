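# Seed and evaluation ROI construction: hand-knob slab rule, paracentral
# foot ROI, ventral precentral mouth ROI, functional 6-mm-sphere ROI,
# morphological dilation and sagittal mirroring.

#' Hand-area anatomical ROI (knob slice rule)
#'
#' Intersects a gyrus mask with an axial slab of `n_slices *
#' slice_thickness_mm` mm centred on the hand knob's z coordinate
#' (half-open interval `[z - h, z + h)`, h = half the slab height). A
#' warning is emitted if the slab is clipped by the grid.
#'
#' @param gyrus_mask non-empty [roi_mask()] (pre- or postcentral gyrus).
#' @param knob_centre_mm world-mm coordinate of the hand knob.
#' @param n_slices number of slices (default 10).
#' @param slice_thickness_mm slice thickness (default 2 mm).
#' @return A [roi_mask()] labelled `"hand_aROI"`.
#' @export
build_hand_aroi <- function(gyrus_mask, knob_centre_mm, n_slices = 10L,
                            slice_thickness_mm = 2) {
  stopifnot(inherits(gyrus_mask, "roi_mask"), n_slices >= 1L,
            slice_thickness_mm > 0, length(knob_centre_mm) == 3L)
  if (!any(gyrus_mask$values)) stop("empty gyrus mask")
  dims <- dim(gyrus_mask$values)
  ijk <- world_to_voxel(gyrus_mask$affine, knob_centre_mm)
  if (any(ijk < 0.5) || any(ijk > dims + 0.5))
    stop("knob centre lies outside the grid")
  h <- n_slices * slice_thickness_mm / 2
  co <- grid_coordinates_mm(dims, gyrus_mask$affine)
  zmin <- knob_centre_mm[3] - h
  zmax <- knob_centre_mm[3] + h
  if (zmin < min(co$z) || zmax > max(co$z))
    warning("hand-area slab clipped by the grid boundary")
  v <- gyrus_mask$values & co$z >= zmin & co$z < zmax
  if (!any(v)) stop("hand aROI is empty (slab misses the gyrus mask)")
  roi_mask(v, gyrus_mask$affine, "hand_aROI")
}

#' Foot-area anatomical ROI
#'
#' The whole paracentral lobule, relabelled.
#'
#' @param paracentral_mask non-empty [roi_mask()].
#' @return A [roi_mask()] labelled `"foot_aROI"`.
#' @export
build_foot_aroi <- function(paracentral_mask) {
  stopifnot(inherits(paracentral_mask, "roi_mask"))
  if (!any(paracentral_mask$values)) stop("empty paracentral mask")
  roi_mask(paracentral_mask$values, paracentral_mask$affine, "foot_aROI")
}

#' Mouth-area anatomical ROI
#'
#' Ventral portion of the precentral gyrus: voxels with z in
#' `[sylvian_z_mm, knob_inferior_z_mm)`.
#'
#' @param precentral_mask non-empty [roi_mask()].
#' @param sylvian_z_mm inferior bound (Sylvian fissure level), mm.
#' @param knob_inferior_z_mm superior bound (inferior limit of the hand
#'   knob), mm; must exceed `sylvian_z_mm`.
#' @return A [roi_mask()] labelled `"mouth_aROI"`.
#' @export
build_mouth_aroi <- function(precentral_mask, sylvian_z_mm,
                             knob_inferior_z_mm) {
  stopifnot(inherits(precentral_mask, "roi_mask"))
  if (!any(precentral_mask$values)) stop("empty precentral mask")
  if (sylvian_z_mm >= knob_inferior_z_mm)
    stop("sylvian_z_mm must be below knob_inferior_z_mm")
  co <- grid_coordinates_mm(dim(precentral_mask$values),
                            precentral_mask$affine)
  v <- precentral_mask$values & co$z >= sylvian_z_mm &
    co$z < knob_inferior_z_mm
  if (!any(v)) stop("mouth aROI is empty")
  roi_mask(v, precentral_mask$affine, "mouth_aROI")
}

#' Functional ROI: sphere around the contralateral activation peak
#'
#' Finds the arg-max voxel of the map within the search mask (ties broken by
#' the lowest linear index, with a message) and returns the set of voxels
#' whose centres lie within `radius_mm` of that voxel's centre.
#'
#' @param contralateral_tmap a [stat_map()] from the non-diseased limb task.
#' @param search_mask non-empty [roi_mask()] restricting the peak search.
#' @param radius_mm sphere radius in mm (default 6).
#' @return A [roi_mask()] labelled `"fROI"`, with the peak coordinate in
#'   attribute `"centre_mm"`.
#' @export
build_froi <- function(contralateral_tmap, search_mask, radius_mm = 6) {
  stopifnot(inherits(contralateral_tmap, "stat_map"),
            inherits(search_mask, "roi_mask"), radius_mm > 0)
  stop_if_grid_mismatch(contralateral_tmap, search_mask, "map and mask")
  vals <- contralateral_tmap$values
  vals[!search_mask$values] <- -Inf
  if (!any(is.finite(vals))) stop("no finite map values inside search mask")
  mx <- max(vals)
  hits <- which(vals == mx)
  if (length(hits) > 1L)
    message("fROI peak tie between ", length(hits),
            " voxels; lowest linear index chosen")
  peak <- hits[1]
  dims <- dim(vals)
  peak_ijk <- arrayInd(peak, dims)
  centre <- voxel_to_world(contralateral_tmap$affine, peak_ijk)
  co <- grid_coordinates_mm(dims, contralateral_tmap$affine)
  v <- (co$x - centre[1])^2 + (co$y - centre[2])^2 +
    (co$z - centre[3])^2 <= radius_mm^2
  out <- roi_mask(v, contralateral_tmap$affine, "fROI")
  attr(out, "centre_mm") <- as.numeric(centre)
  out
}

#' Binary morphological dilation
#'
#' `n_iter` iterations of dilation with the 6-connected structuring element
#' (one pass adds every voxel sharing a face with the mask). Equivalent to
#' thresholding the city-block distance transform at `n_iter`. The
#' `dilation_voxels` provenance field is incremented accordingly.
#'
#' @param mask a [roi_mask()].
#' @param n_iter number of dilation iterations (>= 0).
#' @return The dilated [roi_mask()].
#' @export
dilate_mask <- function(mask, n_iter) {
  stopifnot(inherits(mask, "roi_mask"))
  if (n_iter < 0) stop("n_iter must be >= 0")
  v <- mask$values
  for (i in seq_len(n_iter)) {
    v <- v |
      shift_array(v, 1, 1) | shift_array(v, 1, -1) |
      shift_array(v, 2, 1) | shift_array(v, 2, -1) |
      shift_array(v, 3, 1) | shift_array(v, 3, -1)
  }
  roi_mask(v, mask$affine, mask$label,
           dilation_voxels = mask$dilation_voxels + as.integer(n_iter),
           allow_empty = !any(v))
}

#' Mirror a mask about a sagittal plane
#'
#' Reflects the mask about the plane `x = midline_x_mm` (nearest-voxel
#' resampling). Voxels whose reflection falls outside the grid are dropped
#' with a warning.
#'
#' @param mask a [roi_mask()].
#' @param midline_x_mm x coordinate of the mirror plane (default 0).
#' @return The mirrored [roi_mask()].
#' @export
mirror_mask <- function(mask, midline_x_mm = 0) {
  stopifnot(inherits(mask, "roi_mask"))
  dims <- dim(mask$values)
  idx <- which(mask$values, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(roi_mask(mask$values, mask$affine, mask$label,
                    mask$dilation_voxels, allow_empty = TRUE))
  xyz <- voxel_to_world(mask$affine, idx)
  xyz[, 1] <- 2 * midline_x_mm - xyz[, 1]
  ijk <- round(world_to_voxel(mask$affine, xyz))
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= dims[1] &
    ijk[, 2] >= 1 & ijk[, 2] <= dims[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= dims[3]
  if (!all(ok))
    warning(sum(!ok), " mirrored voxel(s) fell outside the grid; clipped")
  v <- array(FALSE, dim = dims)
  v[ijk[ok, , drop = FALSE]] <- TRUE
  roi_mask(v, mask$affine, paste0(mask$label, "_mirrored"),
           mask$dilation_voxels, allow_empty = !any(v))
}
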