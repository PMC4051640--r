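# Synthetic BOLD phantom: parametric anatomy, lesion, ECS sites and
# task/rest time series with known ground truth. Regions are boxes, slabs
# and ellipsoids (no atlas needed); the hand knob is a posterior spherical
# bump on the precentral slab so the slice-based hand ROI rule has something
# to bite on.

#' Phantom specification
#'
#' Describes the synthetic subject: grid geometry, acquisition parameters,
#' region definitions and signal/noise amplitudes. Amplitudes are percent of
#' a baseline of 100 (so a 2\% effect is 2 signal units); `noise_sd` is in
#' signal units, giving a white-matter tSNR of `100 / noise_sd` when drift
#' and global signal are disabled.
#'
#' @param grid_shape integer length-3: voxels per axis.
#' @param voxel_size isotropic voxel edge in mm.
#' @param n_volumes number of volumes of a resting-state run.
#' @param tr repetition time in seconds.
#' @param network_amplitude shared low-frequency network fluctuation, % signal.
#' @param task_effect task activation amplitude, % signal.
#' @param noise_sd i.i.d. Gaussian noise SD, signal units.
#' @param drift_coeffs SDs of random per-voxel coefficients on an orthonormal
#'   polynomial drift basis, orders 1..length (order <= 3).
#' @param global_amp amplitude of the shared global fluctuation, % signal.
#' @param regions optional named list overriding the default region geometry
#'   (see [phantom_regions()]).
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(36L, 36L, 30L), voxel_size = 2.5,
                         n_volumes = 200L, tr = 2.8,
                         network_amplitude = 2, task_effect = 2,
                         noise_sd = 0.5, drift_coeffs = c(0.3, 0.2, 0.1),
                         global_amp = 0.3, regions = NULL, seed = 42L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0),
            voxel_size > 0, n_volumes >= 2L, tr > 0,
            network_amplitude >= 0, task_effect >= 0, noise_sd >= 0,
            global_amp >= 0, length(drift_coeffs) <= 3L)
  spec <- list(grid_shape = grid_shape, voxel_size = voxel_size,
               n_volumes = as.integer(n_volumes), tr = tr,
               baseline = 100,
               network_amplitude = network_amplitude,
               task_effect = task_effect, noise_sd = noise_sd,
               drift_coeffs = drift_coeffs, global_amp = global_amp,
               regions = if (is.null(regions)) phantom_regions() else regions,
               seed = as.integer(seed))
  spec$affine <- phantom_affine(grid_shape, voxel_size)
  check_regions_in_grid(spec)
  class(spec) <- "phantom_spec"
  spec
}

# RAS+ affine with the world origin at the grid centre
phantom_affine <- function(grid_shape, voxel_size) {
  aff <- diag(c(rep(voxel_size, 3), 1))
  aff[1:3, 4] <- -voxel_size * (grid_shape - 1) / 2
  aff
}

#' Default phantom region geometry
#'
#' All coordinates in world mm (origin at grid centre, x left(-)/right(+),
#' y posterior(-)/anterior(+), z inferior(-)/superior(+)). The precentral
#' "gyrus" is a parasagittal slab with a spherical hand-knob bump on its
#' posterior face; the postcentral slab sits behind it; the paracentral
#' lobule is a medial superior box; the mouth strip is the ventral part of
#' the precentral slab; the lesion is an ellipsoid near the right central
#' region.
#'
#' @return Named list of region parameter lists.
#' @export
phantom_regions <- function() {
  list(
    brain = list(type = "ellipsoid", centre = c(0, 0, 0),
                 semi_axes = c(42, 42, 35)),
    white_matter = list(type = "ellipsoid", centre = c(0, 10, -2),
                        semi_axes = c(16, 12, 10)),
    precentral_R = list(type = "box", x = c(12, 40), y = c(-18, -6),
                        z = c(-26, 30)),
    precentral_L = list(type = "box", x = c(-40, -12), y = c(-18, -6),
                        z = c(-26, 30)),
    postcentral_R = list(type = "box", x = c(12, 40), y = c(-36, -24),
                         z = c(-26, 30)),
    postcentral_L = list(type = "box", x = c(-40, -12), y = c(-36, -24),
                         z = c(-26, 30)),
    paracentral_R = list(type = "box", x = c(1, 11), y = c(-30, -6),
                         z = c(18, 32)),
    paracentral_L = list(type = "box", x = c(-11, -1), y = c(-30, -6),
                         z = c(18, 32)),
    # posterior bump on the precentral slab, protruding into the central
    # sulcus gap between the pre- and postcentral boxes
    hand_knob_R = list(type = "sphere", centre = c(26, -21, 18), radius = 6),
    hand_knob_L = list(type = "sphere", centre = c(-26, -21, 18), radius = 6),
    hand_activation_radius = 10,     # ball around the knob centre (mm)
    network_z = c(6, 30),            # dorsal strip carrying the RSN source
    mouth_strip_z = c(-26, -6),      # ventral precentral z-window (mm)
    lesion = list(type = "ellipsoid", centre = c(24, -28, 4),
                  semi_axes = c(9, 8, 9))
  )
}

region_bounds <- function(r) {
  switch(r$type,
    box = rbind(r$x, r$y, r$z),
    sphere = rbind(r$centre[1] + c(-1, 1) * r$radius,
                   r$centre[2] + c(-1, 1) * r$radius,
                   r$centre[3] + c(-1, 1) * r$radius),
    ellipsoid = rbind(r$centre[1] + c(-1, 1) * r$semi_axes[1],
                      r$centre[2] + c(-1, 1) * r$semi_axes[2],
                      r$centre[3] + c(-1, 1) * r$semi_axes[3]),
    stop("unknown region type ", r$type))
}

check_regions_in_grid <- function(spec) {
  lims <- voxel_to_world(spec$affine,
                         rbind(c(1, 1, 1), spec$grid_shape))
  lo <- pmin(lims[1, ], lims[2, ]) - spec$voxel_size / 2
  hi <- pmax(lims[1, ], lims[2, ]) + spec$voxel_size / 2
  for (nm in names(spec$regions)) {
    r <- spec$regions[[nm]]
    if (!is.list(r) || is.null(r$type)) next
    b <- region_bounds(r)
    if (any(b[, 1] < lo) || any(b[, 2] > hi))
      stop("region '", nm, "' extends outside the phantom grid")
  }
  invisible(TRUE)
}

# evaluate a region predicate on voxel-centre coordinate arrays
region_mask_values <- function(r, co) {
  switch(r$type,
    box = co$x >= r$x[1] & co$x <= r$x[2] &
          co$y >= r$y[1] & co$y <= r$y[2] &
          co$z >= r$z[1] & co$z <= r$z[2],
    sphere = (co$x - r$centre[1])^2 + (co$y - r$centre[2])^2 +
             (co$z - r$centre[3])^2 <= r$radius^2,
    ellipsoid = {
      a <- r$semi_axes
      if (any(a <= 0)) array(FALSE, dim = dim(co$x))
      else ((co$x - r$centre[1]) / a[1])^2 + ((co$y - r$centre[2]) / a[2])^2 +
           ((co$z - r$centre[3]) / a[3])^2 <= 1
    },
    stop("unknown region type ", r$type))
}

#' Build the phantom ground truth
#'
#' Evaluates every region of the specification on the voxel grid and returns
#' the full set of masks: brain, white matter, lesion, the four gyrus slabs
#' (the precentral slabs include the hand-knob bumps), the paracentral
#' lobules, per-task activation masks and the sensorimotor network mask
#' (union of the pre/postcentral gyri).
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `ground_truth`: a list of `roi_mask` objects
#'   (`brain`, `white_matter`, `lesion`, `precentral_L/R`, `postcentral_L/R`,
#'   `paracentral_L/R`, `network`) plus `activation`, a named list of
#'   per-task masks (`hand_L`, `hand_R`, `foot_L`, `foot_R`, `mouth_L`,
#'   `mouth_R`; suffix = hemisphere of the mask), and the knob centres.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  co <- grid_coordinates_mm(spec$grid_shape, spec$affine)
  rg <- spec$regions
  aff <- spec$affine
  mk <- function(v, label, allow_empty = FALSE)
    roi_mask(array(v, dim = spec$grid_shape), aff, label,
             allow_empty = allow_empty)

  knob_R <- region_mask_values(rg$hand_knob_R, co)
  knob_L <- region_mask_values(rg$hand_knob_L, co)
  pre_R <- region_mask_values(rg$precentral_R, co) | knob_R
  pre_L <- region_mask_values(rg$precentral_L, co) | knob_L
  post_R <- region_mask_values(rg$postcentral_R, co)
  post_L <- region_mask_values(rg$postcentral_L, co)
  para_R <- region_mask_values(rg$paracentral_R, co)
  para_L <- region_mask_values(rg$paracentral_L, co)
  wm <- region_mask_values(rg$white_matter, co)
  lesion <- region_mask_values(rg$lesion, co)
  # resting network: dorsal sensorimotor strip (pre/postcentral within the
  # hand-area z window) -- a compact subset of the gyri, so its z-scored
  # ICA map stands well clear of the component-selection threshold
  nz <- rg$network_z
  network <- (pre_R | pre_L | post_R | post_L) & co$z >= nz[1] &
    co$z <= nz[2]

  # hand activation: ball around the knob centre, spanning the central
  # sulcus (motor + sensory hand area)
  ar <- rg$hand_activation_radius
  hand_R <- (co$x - rg$hand_knob_R$centre[1])^2 +
    (co$y - rg$hand_knob_R$centre[2])^2 +
    (co$z - rg$hand_knob_R$centre[3])^2 <= ar^2
  hand_L <- (co$x - rg$hand_knob_L$centre[1])^2 +
    (co$y - rg$hand_knob_L$centre[2])^2 +
    (co$z - rg$hand_knob_L$centre[3])^2 <= ar^2
  mz <- rg$mouth_strip_z
  mouth_R <- pre_R & co$z >= mz[1] & co$z <= mz[2]
  mouth_L <- pre_L & co$z >= mz[1] & co$z <= mz[2]

  # brain mask: central ellipsoid plus every defined structure, so all
  # signal-carrying voxels are inside the brain
  brain <- region_mask_values(rg$brain, co) |
    pre_R | pre_L | post_R | post_L | para_R | para_L |
    hand_R | hand_L | lesion | wm

  truth <- list(
    spec = spec,
    brain = mk(brain, "brain"),
    white_matter = mk(wm, "white_matter"),
    lesion = mk(lesion, "lesion", allow_empty = TRUE),
    precentral_R = mk(pre_R, "precentral_R"),
    precentral_L = mk(pre_L, "precentral_L"),
    postcentral_R = mk(post_R, "postcentral_R"),
    postcentral_L = mk(post_L, "postcentral_L"),
    paracentral_R = mk(para_R, "paracentral_R"),
    paracentral_L = mk(para_L, "paracentral_L"),
    network = mk(network, "sensorimotor_network"),
    activation = list(
      hand_R = mk(hand_R, "hand_R"), hand_L = mk(hand_L, "hand_L"),
      foot_R = mk(para_R, "foot_R"), foot_L = mk(para_L, "foot_L"),
      mouth_R = mk(mouth_R, "mouth_R"), mouth_L = mk(mouth_L, "mouth_L")),
    knob_centre = list(R = rg$hand_knob_R$centre, L = rg$hand_knob_L$centre)
  )
  class(truth) <- "ground_truth"
  truth
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> grid %s, voxel %.3g mm\n",
              paste(x$spec$grid_shape, collapse = "x"), x$spec$voxel_size))
  cat(sprintf("  brain %d vox, network %d vox, lesion %d vox\n",
              sum(x$brain$values), sum(x$network$values),
              sum(x$lesion$values)))
  invisible(x)
}

# --- block design ----------------------------------------------------------

#' Block design for the motor task
#'
#' The default design follows the study layout of 12 active blocks (6 per
#' side) and 6 rest blocks, tiling the run exactly: six repetitions of
#' rest / active_left / active_right, each block `block_len` volumes.
#'
#' @param n_volumes total volumes (must equal 18 * block_len for the default
#'   layout).
#' @param tr repetition time, seconds.
#' @param block_len block length in volumes.
#' @param task which motor task the run probes ("hand", "foot" or "mouth").
#' @return Object of class `block_design` with a `blocks` data.frame
#'   (condition, onset volume 1-based, duration volumes).
#' @export
block_design <- function(n_volumes = 144L, tr = 3.0, block_len = 8L,
                         task = c("hand", "foot", "mouth")) {
  task <- match.arg(task)
  n_volumes <- as.integer(n_volumes)
  block_len <- as.integer(block_len)
  conds <- rep(c("rest", "active_left", "active_right"), times = 6L)
  if (n_volumes != length(conds) * block_len)
    stop("default layout needs n_volumes == 18 * block_len (",
         length(conds) * block_len, "), got ", n_volumes)
  blocks <- data.frame(condition = conds,
                       onset = seq(1L, by = block_len,
                                   length.out = length(conds)),
                       duration = block_len)
  structure(list(n_volumes = n_volumes, tr = tr, task = task,
                 blocks = blocks),
            class = "block_design")
}

#' @export
print.block_design <- function(x, ...) {
  cat(sprintf("<block_design> %s task, %d volumes, TR %.3g s, %d blocks\n",
              x$task, x$n_volumes, x$tr, nrow(x$blocks)))
  invisible(x)
}

# boxcar (0/1 per volume) for one side of a design
design_boxcar <- function(design, side = c("left", "right", "both")) {
  side <- match.arg(side)
  want <- switch(side,
                 left = "active_left", right = "active_right",
                 both = c("active_left", "active_right"))
  box <- numeric(design$n_volumes)
  bl <- design$blocks[design$blocks$condition %in% want, , drop = FALSE]
  if (nrow(bl) == 0L) stop("design has no '", side, "' active blocks")
  for (r in seq_len(nrow(bl)))
    box[bl$onset[r]:(bl$onset[r] + bl$duration[r] - 1L)] <- 1
  box
}

# --- nuisance components ---------------------------------------------------

# orthonormal polynomial drift basis (orders 1..k), columns unit-norm
drift_basis <- function(n, k) {
  if (k == 0L) return(matrix(0, n, 0))
  b <- stats::poly(seq_len(n), degree = k)          # orthonormal, mean-zero
  matrix(b, nrow = n)
}

# shared nuisance built from one RNG stream: per-voxel drift + global course
nuisance_terms <- function(spec, n_vox, n_t) {
  k <- length(spec$drift_coeffs)
  drift <- matrix(0, n_t, n_vox)
  if (k > 0L && any(spec$drift_coeffs != 0)) {
    basis <- drift_basis(n_t, k) * sqrt(n_t)        # O(1) amplitude columns
    coefs <- matrix(stats::rnorm(n_vox * k), k, n_vox) * spec$drift_coeffs
    drift <- basis %*% coefs
  }
  global <- numeric(n_t)
  if (spec$global_amp > 0) {
    g <- stats::rnorm(n_t)
    global <- spec$global_amp * (g - mean(g)) / stats::sd(g)
  }
  list(drift = drift, global = global)
}

#' Band-limited network source
#'
#' Gaussian white noise brick-wall low-pass filtered below `cutoff_hz` in the
#' frequency domain, then z-scored. This is the shared fluctuation planted in
#' the phantom's sensorimotor network.
#'
#' @param n_t number of time points.
#' @param tr repetition time, seconds.
#' @param cutoff_hz upper frequency bound (default 0.1 Hz).
#' @return Numeric vector, mean 0, SD 1.
#' @export
bandlimited_source <- function(n_t, tr, cutoff_hz = 0.1) {
  x <- stats::rnorm(n_t)
  f <- fft_frequencies(n_t, tr)
  gain <- as.numeric(f <= cutoff_hz)
  y <- Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n_t
  (y - mean(y)) / stats::sd(y)
}

# frequency (Hz) of each DFT bin, folded to [0, Nyquist]
fft_frequencies <- function(n_t, tr) {
  k <- 0:(n_t - 1)
  k <- pmin(k, n_t - k)
  k / (n_t * tr)
}

# --- simulators ------------------------------------------------------------

#' Simulate a block-design task run
#'
#' Voxels inside the task's activation masks carry a boxcar-convolved-HRF
#' response scaled to `task_effect` percent of baseline (left-side blocks
#' drive the right-hemisphere mask and vice versa); every brain voxel
#' additionally carries polynomial drift, a shared global fluctuation and
#' i.i.d. Gaussian noise on a baseline of 100.
#'
#' @param spec a [phantom_spec()] (its `n_volumes`/`tr` are overridden by the
#'   design for the task run).
#' @param design a [block_design()].
#' @param truth ground truth from [make_phantom()].
#' @return A [bold_series()].
#' @export
simulate_task_bold <- function(spec, design, truth) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(design, "block_design"),
            inherits(truth, "ground_truth"))
  stop_if_grid_mismatch(truth$brain, roi_mask(
    array(TRUE, spec$grid_shape), spec$affine, "grid"), "spec and truth")
  n_t <- design$n_volumes
  n_vox <- prod(spec$grid_shape)
  set.seed(spec$seed + 1L)

  reg_L <- convolve_hrf(design_boxcar(design, "left"), design$tr)
  reg_R <- convolve_hrf(design_boxcar(design, "right"), design$tr)

  mat <- matrix(spec$baseline, n_t, n_vox)
  amp <- spec$baseline * spec$task_effect / 100
  act_R <- truth$activation[[paste0(design$task, "_R")]]$values
  act_L <- truth$activation[[paste0(design$task, "_L")]]$values
  mat[, as.vector(act_R)] <- mat[, as.vector(act_R)] + amp * reg_L
  mat[, as.vector(act_L)] <- mat[, as.vector(act_L)] + amp * reg_R

  brain <- as.vector(truth$brain$values)
  nt <- nuisance_terms(spec, sum(brain), n_t)
  mat[, brain] <- mat[, brain] + nt$drift + nt$global
  if (spec$noise_sd > 0)
    mat <- mat + stats::rnorm(length(mat), sd = spec$noise_sd)

  bold_series(array(t(mat), dim = c(spec$grid_shape, n_t)), spec$affine,
              design$tr)
}

#' Simulate a resting-state run
#'
#' All voxels of the sensorimotor network share one band-limited (< 0.1 Hz)
#' source scaled to `network_amplitude` percent of baseline; every brain
#' voxel carries drift, a shared global fluctuation, and i.i.d. Gaussian
#' noise on a baseline of 100.
#'
#' @inheritParams simulate_task_bold
#' @return A [bold_series()].
#' @export
simulate_rest_bold <- function(spec, truth) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(truth, "ground_truth"))
  n_t <- spec$n_volumes
  n_vox <- prod(spec$grid_shape)
  set.seed(spec$seed + 2L)

  source_tc <- bandlimited_source(n_t, spec$tr, 0.1)
  amp <- spec$baseline * spec$network_amplitude / 100

  mat <- matrix(spec$baseline, n_t, n_vox)
  net <- as.vector(truth$network$values)
  mat[, net] <- mat[, net] + amp * source_tc

  brain <- as.vector(truth$brain$values)
  nt <- nuisance_terms(spec, sum(brain), n_t)
  mat[, brain] <- mat[, brain] + nt$drift + nt$global
  if (spec$noise_sd > 0)
    mat <- mat + stats::rnorm(length(mat), sd = spec$noise_sd)

  out <- bold_series(array(t(mat), dim = c(spec$grid_shape, n_t)),
                     spec$affine, spec$tr)
  attr(out, "network_source") <- source_tc
  out
}

# --- ECS site placement ----------------------------------------------------

#' Place synthetic stimulation sites near an activation surface
#'
#' Samples `n` voxels on the outer surface of the activation mask and pushes
#' each outward (along the direction away from the mask centroid) by
#' `offset_mm`, emulating stimulation points on or above the cortical
#' surface.
#'
#' @param truth ground truth from [make_phantom()].
#' @param n number of sites (>= 1).
#' @param offset_mm outward offset from the activation surface in mm.
#' @param seed RNG seed for the site sample.
#' @param activation which activation mask to target (default "hand_R").
#' @return A data.frame of class `ecs_sites` with columns `site_id`, `x_mm`,
#'   `y_mm`, `z_mm`, `response_label`.
#' @export
place_ecs_sites <- function(truth, n, offset_mm = 0, seed = 1L,
                            activation = "hand_R") {
  stopifnot(inherits(truth, "ground_truth"))
  if (n < 1L) stop("n must be >= 1")
  mask <- truth$activation[[activation]]
  if (is.null(mask) || !any(mask$values)) stop("empty activation mask")
  surf <- mask_surface(mask$values)
  idx <- which(surf, arr.ind = TRUE)
  set.seed(seed)
  pick <- idx[sample.int(nrow(idx), n, replace = n > nrow(idx)), ,
              drop = FALSE]
  xyz <- voxel_to_world(mask$affine, pick)
  centroid <- colMeans(mask_coordinates_mm(mask))
  dirs <- sweep(xyz, 2, centroid)
  nrm <- sqrt(rowSums(dirs^2))
  nrm[nrm == 0] <- 1
  dirs <- dirs / nrm
  xyz <- xyz + offset_mm * dirs
  resp <- sub("_[LR]$", "", activation)
  out <- data.frame(site_id = seq_len(n), x_mm = xyz[, 1], y_mm = xyz[, 2],
                    z_mm = xyz[, 3], response_label = resp)
  class(out) <- c("ecs_sites", "data.frame")
  out
}

# outer surface: mask voxels with at least one 6-neighbour outside the mask
mask_surface <- function(v) {
  er <- v
  er[] <- v &
    shift_array(v, 1, 1) & shift_array(v, 1, -1) &
    shift_array(v, 2, 1) & shift_array(v, 2, -1) &
    shift_array(v, 3, 1) & shift_array(v, 3, -1)
  v & !er
}

# shift a 3D logical/numeric array by one voxel along an axis, padding
# with `fill`
shift_array <- function(v, axis, by, fill = FALSE) {
  d <- dim(v)
  out <- array(fill, dim = d)
  src <- dst <- lapply(d, seq_len)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  if (by > 0) { dst[[axis]] <- (by + 1):n; src[[axis]] <- 1:(n - by) }
  else if (by < 0) { dst[[axis]] <- 1:(n + by); src[[axis]] <- (1 - by):n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- v[src[[1]], src[[2]], src[[3]]]
  out
}
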