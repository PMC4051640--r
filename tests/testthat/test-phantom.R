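test_that("phantom generation is deterministic and masks are consistent", {
  spec <- phantom_spec()
  t1 <- make_phantom(spec)
  t2 <- make_phantom(spec)
  expect_identical(t1$network$values, t2$network$values)
  expect_identical(t1$lesion$values, t2$lesion$values)
  # all structures live inside the brain mask
  for (nm in c("white_matter", "lesion", "precentral_R", "postcentral_L",
               "paracentral_R", "network"))
    expect_true(all(t1$brain$values[t1[[nm]]$values]))
  for (nm in names(t1$activation))
    expect_gt(sum(t1$activation[[nm]]$values), 0)
  # the knob bump makes the precentral gyrus protrude beyond its slab
  box_only <- phantom_regions()$precentral_R
  co <- motormap:::grid_coordinates_mm(spec$grid_shape, spec$affine)
  in_box <- co$y >= box_only$y[1] & co$y <= box_only$y[2]
  expect_gt(sum(t1$precentral_R$values & !in_box), 0)
})

test_that("zero-radius lesion gives an empty lesion mask only", {
  rg <- phantom_regions()
  rg$lesion$semi_axes <- c(0, 0, 0)
  truth <- make_phantom(phantom_spec(regions = rg))
  expect_equal(sum(truth$lesion$values), 0)
  expect_gt(sum(truth$brain$values), 0)
  expect_gt(sum(truth$network$values), 0)
})

test_that("a region outside the grid is rejected", {
  rg <- phantom_regions()
  rg$lesion$centre <- c(200, 0, 0)
  expect_error(phantom_spec(regions = rg), "outside")
})

test_that("ellipsoid lesion volume matches the lattice enumeration oracle", {
  spec <- phantom_spec()
  truth <- make_phantom(spec)
  ax <- spec$regions$lesion$semi_axes
  ctr <- spec$regions$lesion$centre
  # oracle: enumerate voxel centres directly
  co <- expand.grid(i = seq_len(spec$grid_shape[1]),
                    j = seq_len(spec$grid_shape[2]),
                    k = seq_len(spec$grid_shape[3]))
  xyz <- voxel_to_world(spec$affine, as.matrix(co))
  n_oracle <- sum(((xyz[, 1] - ctr[1]) / ax[1])^2 +
                  ((xyz[, 2] - ctr[2]) / ax[2])^2 +
                  ((xyz[, 3] - ctr[3]) / ax[3])^2 <= 1)
  expect_equal(sum(truth$lesion$values), n_oracle)
  continuum <- 4 / 3 * pi * prod(ax) / spec$voxel_size^3
  expect_lt(abs(n_oracle - continuum) / continuum, 0.10)
})

test_that("noise-free task voxel equals task_effect times the regressor", {
  spec <- clean_spec()
  truth <- make_phantom(spec)
  design <- block_design(task = "hand", tr = 3.0)
  bold <- simulate_task_bold(spec, design, truth)
  vox <- which(truth$activation$hand_R$values, arr.ind = TRUE)[1, ]
  tc <- bold$data[vox[1], vox[2], vox[3], ] - spec$baseline
  # oracle: boxcar convolved with an independently coded HRF
  box <- rep(0, design$n_volumes)
  bl <- design$blocks[design$blocks$condition == "active_left", ]
  for (r in seq_len(nrow(bl)))
    box[bl$onset[r]:(bl$onset[r] + bl$duration[r] - 1)] <- 1
  h <- oracle_hrf(seq(0, 32, by = design$tr))
  expected <- spec$task_effect *
    convolve(box, rev(h), type = "open")[seq_len(design$n_volumes)]
  expect_lt(max(abs(tc - expected)), 1e-10)
  # non-activated brain voxel carries no signal at all
  bg <- which(truth$brain$values & !truth$activation$hand_R$values &
              !truth$activation$hand_L$values, arr.ind = TRUE)[1, ]
  expect_lt(max(abs(bold$data[bg[1], bg[2], bg[3], ] - spec$baseline)),
            1e-12)
})

test_that("zero task effect leaves activated voxels indistinguishable", {
  spec <- phantom_spec(task_effect = 0)
  truth <- make_phantom(spec)
  design <- block_design(task = "hand", tr = 3.0)
  bold <- simulate_task_bold(spec, design, truth)
  mat <- apply(bold$data, 4, as.vector)
  act <- as.vector(truth$activation$hand_R$values)
  bg <- as.vector(truth$brain$values) & !act &
    !as.vector(truth$activation$hand_L$values)
  v_act <- apply(mat[act, ], 1, var)
  set.seed(7)
  v_bg <- apply(mat[sample(which(bg), 500), ], 1, var)
  expect_gt(wilcox.test(v_act, v_bg)$p.value, 0.01)
})

test_that("rest simulation plants a shared sub-0.1 Hz network source", {
  spec <- phantom_spec()
  truth <- make_phantom(spec)
  r1 <- simulate_rest_bold(spec, truth)
  r2 <- simulate_rest_bold(spec, truth)
  expect_identical(r1$data, r2$data)          # fixed seed, bit-identical

  src <- attr(r1, "network_source")
  spec_dens <- Mod(fft(src))^2
  f <- motormap:::fft_frequencies(length(src), spec$tr)
  expect_lt(sum(spec_dens[f > 0.1]) / sum(spec_dens), 0.01)

  mat <- apply(r1$data, 4, as.vector)
  net <- which(as.vector(truth$network$values))
  bg <- which(as.vector(truth$brain$values) &
              !as.vector(truth$network$values))
  set.seed(11)
  cor_net <- cor(t(mat[sample(net, 60), ]))
  cor_bg <- cor(t(mat[sample(bg, 60), ]))
  mean_off <- function(m) mean(m[upper.tri(m)])
  expect_gt(mean_off(cor_net) - mean_off(cor_bg), 0.3)
})

test_that("network correlations collapse without the shared source", {
  spec <- phantom_spec(network_amplitude = 0, n_volumes = 120L)
  truth <- make_phantom(spec)
  r <- simulate_rest_bold(spec, truth)
  mat <- apply(r$data, 4, as.vector)
  net <- which(as.vector(truth$network$values))
  bg <- which(as.vector(truth$brain$values) &
              !as.vector(truth$network$values))
  set.seed(3)
  mean_off <- function(m) mean(m[upper.tri(m)])
  d <- mean_off(cor(t(mat[sample(net, 60), ]))) -
    mean_off(cor(t(mat[sample(bg, 60), ])))
  expect_lt(abs(d), 0.05)
})

test_that("noise-free network voxels are perfectly correlated", {
  spec <- clean_spec(n_volumes = 80L)
  truth <- make_phantom(spec)
  r <- simulate_rest_bold(spec, truth)
  mat <- apply(r$data, 4, as.vector)
  net <- which(as.vector(truth$network$values))[1:10]
  cc <- cor(t(mat[net, ]))
  expect_lt(max(abs(cc - 1)), 1e-10)
})

test_that("ECS sites are placed at the requested offset", {
  truth <- default_truth()
  expect_error(place_ecs_sites(truth, 0), ">= 1")

  s0 <- place_ecs_sites(truth, 6, offset_mm = 0, seed = 5)
  d0 <- vapply(seq_len(nrow(s0)), function(i)
    ecs_distance(c(s0$x_mm[i], s0$y_mm[i], s0$z_mm[i]),
                 truth$activation$hand_R), numeric(1))
  expect_true(all(d0 == 0))

  s5 <- place_ecs_sites(truth, 6, offset_mm = 5, seed = 5)
  vs <- truth$spec$voxel_size
  d5 <- vapply(seq_len(nrow(s5)), function(i)
    ecs_distance(c(s5$x_mm[i], s5$y_mm[i], s5$z_mm[i]),
                 truth$activation$hand_R), numeric(1))
  expect_true(all(d5 >= 5 - vs & d5 <= 5 + vs))

  expect_identical(place_ecs_sites(truth, 6, 5, seed = 9),
                   place_ecs_sites(truth, 6, 5, seed = 9))
})
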