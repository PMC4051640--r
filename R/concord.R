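# Concordance metrics: AMPLE thresholding, overlap sensitivity/specificity
# (alpha/beta), t-weighted centre-of-mass distances, and ECS site distance
# scoring.

#' AMPLE thresholding (percentage of local excitation)
#'
#' Finds the highest statistic within the motor cortex ipsilateral to the
#' lesion and thresholds the whole map at 50\% of that level. Supra-threshold
#' voxels use `>=`, so the peak is always included.
#'
#' @param map a [stat_map()].
#' @param ipsilateral_motor_mask non-empty [roi_mask()] in which the peak is
#'   sought (pre/postcentral gyri, or paracentral lobule for foot tasks).
#' @param fraction fraction of the in-mask peak (default 0.5).
#' @return An object of class `thresholded_map`: list with `source`,
#'   `threshold`, `supra` (logical 3D array over the whole grid) and
#'   `policy = "ample"`.
#' @export
ample_threshold <- function(map, ipsilateral_motor_mask, fraction = 0.5) {
  stopifnot(inherits(map, "stat_map"),
            inherits(ipsilateral_motor_mask, "roi_mask"))
  stop_if_grid_mismatch(map, ipsilateral_motor_mask, "map and motor mask")
  if (!any(ipsilateral_motor_mask$values)) stop("empty motor mask")
  mx <- max(map$values[ipsilateral_motor_mask$values])
  if (!is.finite(mx) || mx <= 0)
    stop("no excitable peak: in-mask maximum is not positive")
  thr <- fraction * mx
  structure(list(source = map, threshold = thr,
                 supra = map$values >= thr, policy = "ample"),
            class = "thresholded_map")
}

#' Fixed-value thresholding
#'
#' @param map a [stat_map()].
#' @param threshold statistic threshold; supra-threshold uses `>=`.
#' @return A `thresholded_map` with `policy = "fixed"`.
#' @export
fixed_threshold <- function(map, threshold) {
  stopifnot(inherits(map, "stat_map"), is.finite(threshold))
  structure(list(source = map, threshold = threshold,
                 supra = map$values >= threshold, policy = "fixed"),
            class = "thresholded_map")
}

#' @export
print.thresholded_map <- function(x, ...) {
  cat(sprintf("<thresholded_map> %s policy, threshold %.4g, %d supra voxels\n",
              x$policy, x$threshold, sum(x$supra)))
  invisible(x)
}

#' Overlap sensitivity and specificity (alpha / beta)
#'
#' Restricts both supra-threshold sets to the evaluation mask and computes
#' `alpha = V_overlap / V_tb` (sensitivity of the resting-state map with
#' respect to the task map) and `beta = V_overlap / V_rs` (specificity).
#'
#' @param tb `thresholded_map` of the task-based map.
#' @param rs `thresholded_map` of the resting-state map.
#' @param eval_mask non-empty [roi_mask()] (dilated motor cortex).
#' @return An `overlap_result`: list with `v_tb`, `v_rs`, `v_overlap`,
#'   `alpha`, `beta`, `mask_label`.
#' @export
overlap_alpha_beta <- function(tb, rs, eval_mask) {
  stopifnot(inherits(tb, "thresholded_map"), inherits(rs, "thresholded_map"),
            inherits(eval_mask, "roi_mask"))
  stop_if_grid_mismatch(tb$source, rs$source, "tb and rs maps")
  stop_if_grid_mismatch(tb$source, eval_mask, "maps and evaluation mask")
  if (!any(eval_mask$values)) stop("empty evaluation mask")
  m <- eval_mask$values
  v_tb <- sum(tb$supra & m)
  v_rs <- sum(rs$supra & m)
  if (v_tb == 0L || v_rs == 0L)
    stop("undefined overlap: no supra-threshold ",
         if (v_tb == 0L) "tb" else "rs",
         " voxels inside the evaluation mask")
  v_ov <- sum(tb$supra & rs$supra & m)
  structure(list(v_tb = v_tb, v_rs = v_rs, v_overlap = v_ov,
                 alpha = v_ov / v_tb, beta = v_ov / v_rs,
                 mask_label = eval_mask$label),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> V_tb=%d V_rs=%d V_overlap=%d alpha=%.2f beta=%.2f (%s)\n",
    x$v_tb, x$v_rs, x$v_overlap, x$alpha, x$beta, x$mask_label))
  invisible(x)
}

#' t-weighted centre of mass of a thresholded map
#'
#' Mean of the world-mm coordinates of the supra-threshold voxels inside the
#' anatomical mask, weighted by their statistic values. All supra-threshold
#' voxels are pooled; no cluster pre-selection.
#'
#' @param tmap a `thresholded_map`.
#' @param anatomical_mask non-empty [roi_mask()] (pre/postcentral gyri or
#'   paracentral lobule).
#' @return A `centre_of_mass`: list with `xyz_mm`, `weighted = TRUE`,
#'   `n_voxels`.
#' @export
weighted_com <- function(tmap, anatomical_mask) {
  stopifnot(inherits(tmap, "thresholded_map"),
            inherits(anatomical_mask, "roi_mask"))
  stop_if_grid_mismatch(tmap$source, anatomical_mask, "map and mask")
  sel <- tmap$supra & anatomical_mask$values
  if (!any(sel)) stop("no supra-threshold voxels inside the anatomical mask")
  idx <- which(sel, arr.ind = TRUE)
  xyz <- voxel_to_world(tmap$source$affine, idx)
  w <- tmap$source$values[sel]
  com <- colSums(xyz * w) / sum(w)
  structure(list(xyz_mm = as.numeric(com), weighted = TRUE,
                 n_voxels = nrow(idx)),
            class = "centre_of_mass")
}

#' Unweighted centroid of a lesion mask
#'
#' @param lesion_mask non-empty [roi_mask()].
#' @return A `centre_of_mass` with `weighted = FALSE`.
#' @export
lesion_com <- function(lesion_mask) {
  stopifnot(inherits(lesion_mask, "roi_mask"))
  if (!any(lesion_mask$values)) stop("empty lesion mask")
  xyz <- mask_coordinates_mm(lesion_mask)
  structure(list(xyz_mm = as.numeric(colMeans(xyz)), weighted = FALSE,
                 n_voxels = nrow(xyz)),
            class = "centre_of_mass")
}

#' @export
print.centre_of_mass <- function(x, ...) {
  cat(sprintf("<centre_of_mass> (%.1f, %.1f, %.1f) mm, %d voxels, %s\n",
              x$xyz_mm[1], x$xyz_mm[2], x$xyz_mm[3], x$n_voxels,
              if (x$weighted) "t-weighted" else "unweighted"))
  invisible(x)
}

#' Euclidean distance between two centres of mass
#'
#' @param a,b `centre_of_mass` objects (or length-3 mm coordinates).
#' @return Distance in mm.
#' @export
com_distance <- function(a, b) {
  pa <- if (inherits(a, "centre_of_mass")) a$xyz_mm else as.numeric(a)
  pb <- if (inherits(b, "centre_of_mass")) b$xyz_mm else as.numeric(b)
  stopifnot(length(pa) == 3L, length(pb) == 3L)
  sqrt(sum((pa - pb)^2))
}

# --- ECS distance scoring --------------------------------------------------

#' Project stimulation sites onto the cortical surface
#'
#' Sites whose containing voxel is inside the cortex mask are unchanged;
#' any other site is moved to the centre of the nearest cortex voxel
#' (Euclidean distance in world mm; ties broken by the lowest linear index,
#' with a message).
#'
#' @param sites `ecs_sites` data.frame (columns `x_mm`, `y_mm`, `z_mm`).
#' @param cortex_mask non-empty [roi_mask()].
#' @return The sites with columns `proj_x_mm`, `proj_y_mm`, `proj_z_mm` and
#'   `projected` (logical) added.
#' @export
project_site_to_cortex <- function(sites, cortex_mask) {
  stopifnot(is.data.frame(sites), inherits(cortex_mask, "roi_mask"))
  if (!any(cortex_mask$values)) stop("empty cortex mask")
  dims <- dim(cortex_mask$values)
  ctx_idx <- which(cortex_mask$values)
  ctx_xyz <- voxel_to_world(cortex_mask$affine,
                            which(cortex_mask$values, arr.ind = TRUE))
  out <- sites
  out$proj_x_mm <- out$x_mm; out$proj_y_mm <- out$y_mm
  out$proj_z_mm <- out$z_mm
  out$projected <- FALSE
  for (i in seq_len(nrow(sites))) {
    p <- c(sites$x_mm[i], sites$y_mm[i], sites$z_mm[i])
    ijk <- round(world_to_voxel(cortex_mask$affine, p))
    inside <- all(ijk >= 1) && all(ijk <= dims) &&
      cortex_mask$values[ijk[1], ijk[2], ijk[3]]
    if (inside) next
    d2 <- (ctx_xyz[, 1] - p[1])^2 + (ctx_xyz[, 2] - p[2])^2 +
      (ctx_xyz[, 3] - p[3])^2
    best <- which(d2 == min(d2))
    if (length(best) > 1L) {
      best <- best[order(ctx_idx[best])][1]
      message("site ", i, ": projection tie; lowest linear index chosen")
    }
    out$proj_x_mm[i] <- ctx_xyz[best, 1]
    out$proj_y_mm[i] <- ctx_xyz[best, 2]
    out$proj_z_mm[i] <- ctx_xyz[best, 3]
    out$projected[i] <- TRUE
  }
  out
}

#' Distance from a stimulation site to the activation border
#'
#' Zero if the (projected) site lies inside a supra-threshold voxel;
#' otherwise the Euclidean world-mm distance to the nearest supra-threshold
#' voxel centre.
#'
#' @param site_xyz_mm length-3 world coordinate (use the projected
#'   coordinate if the site was on the dura).
#' @param activation a `thresholded_map` (or a [roi_mask()], e.g. a
#'   ground-truth activation) with a non-empty supra set.
#' @return Distance in mm.
#' @export
ecs_distance <- function(site_xyz_mm, activation) {
  if (inherits(activation, "roi_mask")) {
    supra <- activation$values
    affine <- activation$affine
  } else if (inherits(activation, "thresholded_map")) {
    supra <- activation$supra
    affine <- activation$source$affine
  } else stop("activation must be a thresholded_map or roi_mask")
  if (!any(supra)) stop("empty activation: no supra voxels")
  p <- as.numeric(site_xyz_mm)
  stopifnot(length(p) == 3L)
  dims <- dim(supra)
  ijk <- round(world_to_voxel(affine, p))
  if (all(ijk >= 1) && all(ijk <= dims) && supra[ijk[1], ijk[2], ijk[3]])
    return(0)
  xyz <- voxel_to_world(affine, which(supra, arr.ind = TRUE))
  sqrt(min((xyz[, 1] - p[1])^2 + (xyz[, 2] - p[2])^2 + (xyz[, 3] - p[3])^2))
}

#' Proportion of sites within a distance cutoff
#'
#' @param distances_mm numeric vector of site-to-activation distances.
#' @param cutoff_mm cutoff in mm; matching uses strict `<`.
#' @return Percentage (0-100) of distances strictly below the cutoff.
#' @export
match_rate <- function(distances_mm, cutoff_mm) {
  d <- distances_mm[!is.na(distances_mm)]
  if (!length(d)) stop("no distances supplied")
  100 * mean(d < cutoff_mm)
}

# --- summary aggregation ---------------------------------------------------

#' Group means and SDs with a grand summary row
#'
#' Aggregates per-case values the way the study's summary tables do:
#' a mean and SD per group (e.g. task) plus a grand mean/SD over all
#' available cells. Missing cells (NA) are excluded; the SD is the sample SD
#' (n-1), reported as 0 for single-value groups (flagged). All-missing
#' groups are omitted with a warning.
#'
#' @param values numeric vector of per-case values (NA = missing).
#' @param groups grouping factor/character of the same length (optional).
#' @return A data.frame with columns `group` (including `"all"`), `n`,
#'   `mean`, `sd`, `single` (TRUE where SD was forced to 0).
#' @export
aggregate_summary <- function(values, groups = NULL) {
  stopifnot(is.numeric(values))
  if (is.null(groups)) groups <- rep("all", length(values))
  stopifnot(length(groups) == length(values))
  one <- function(v) {
    v <- v[!is.na(v)]
    n <- length(v)
    if (n == 0L) return(NULL)
    list(n = n, mean = mean(v),
         sd = if (n >= 2L) stats::sd(v) else 0,
         single = n == 1L)
  }
  rows <- list()
  for (g in unique(as.character(groups))) {
    s <- one(values[groups == g])
    if (is.null(s)) {
      warning("group '", g, "' has no available values; omitted")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(group = g, n = s$n,
                                            mean = s$mean, sd = s$sd,
                                            single = s$single)
  }
  s <- one(values)
  multi <- !identical(unique(as.character(groups)), "all")
  if (!is.null(s) && multi)
    rows[[length(rows) + 1L]] <- data.frame(group = "all", n = s$n,
                                            mean = s$mean, sd = s$sd,
                                            single = s$single)
  do.call(rbind, rows)
}
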