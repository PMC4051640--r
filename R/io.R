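# NIfTI-1 and TSV input/output through RNifti.

#' Write a volume object as NIfTI-1
#'
#' Writes a [bold_series()], [stat_map()] or [roi_mask()] with its affine in
#' the sform/qform (code 2) and, for series, the TR in the 4th pixdim.
#'
#' @param obj the volume object.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(obj, path) {
  if (inherits(obj, "bold_series")) {
    data <- obj$data
    pd <- c(voxel_sizes_mm(obj$affine), obj$tr)
  } else if (inherits(obj, "stat_map")) {
    data <- obj$values
    pd <- voxel_sizes_mm(obj$affine)
  } else if (inherits(obj, "roi_mask")) {
    data <- array(as.integer(obj$values), dim = dim(obj$values))
    pd <- voxel_sizes_mm(obj$affine)
  } else stop("cannot write object of class ", class(obj)[1])
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- pd
  img <- RNifti::`sform<-`(img, structure(obj$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(obj$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' 4D images become [bold_series()] (TR from the 4th pixdim); 3D images
#' become a [stat_map()] or, for `type = "mask"`, a [roi_mask()] (values
#' must be binary).
#'
#' @param path NIfTI file path.
#' @param type "auto" (4D = series, 3D = map), "series", "map" or "mask".
#' @param label,stat_kind,provenance metadata for the created object.
#' @return A volume object.
#' @export
read_volume <- function(path, type = c("auto", "series", "map", "mask"),
                        label = NULL, stat_kind = "t", provenance = "tb") {
  type <- match.arg(type)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read '", path,
                                           "' as NIfTI: ", conditionMessage(e),
                                           call. = FALSE))
  aff <- unclass(RNifti::xform(img))
  attr(aff, "code") <- NULL
  attr(aff, "imagedim") <- NULL
  nd <- length(dim(img))
  if (type == "auto") type <- if (nd == 4L) "series" else "map"
  if (type == "series") {
    if (nd != 4L) stop("'", path, "' is not 4D")
    tr <- RNifti::pixdim(img)[4]
    if (!is.finite(tr) || tr <= 0) tr <- 1
    return(bold_series(array(as.numeric(img), dim = dim(img)), aff, tr))
  }
  if (nd == 4L && dim(img)[4] == 1L)
    img <- array(as.numeric(img), dim = dim(img)[1:3])
  if (length(dim(img)) != 3L) stop("'", path, "' is not 3D")
  vals <- array(as.numeric(img), dim = dim(img))
  if (type == "mask") {
    if (!all(vals %in% c(0, 1)))
      stop("mask file '", path, "' has non-binary values")
    return(roi_mask(vals, aff, label = if (is.null(label)) basename(path)
                    else label))
  }
  stat_map(vals, aff, stat_kind = stat_kind, provenance = provenance)
}

#' Write / read stimulation sites as TSV
#'
#' Columns: `site_id`, `x_mm`, `y_mm`, `z_mm`, `response_label` (plus any
#' projection/distance columns present).
#'
#' @param sites `ecs_sites` data.frame.
#' @param path TSV path.
#' @return `write_ecs_sites`: the path, invisibly. `read_ecs_sites`: the
#'   sites data.frame.
#' @export
write_ecs_sites <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ecs_sites
#' @export
read_ecs_sites <- function(path) {
  df <- utils::read.delim(path)
  need <- c("site_id", "x_mm", "y_mm", "z_mm", "response_label")
  if (!all(need %in% names(df)))
    stop("ECS site file must have columns ", paste(need, collapse = ", "))
  class(df) <- c("ecs_sites", "data.frame")
  df
}
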