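mk_map <- function(vals, aff = diag(c(2, 2, 2, 1)), prov = "tb")
  stat_map(vals, aff, "t", provenance = prov)

test_that("AMPLE sets the threshold to half the in-mask peak", {
  dims <- c(6, 6, 6)
  vals <- array(1, dims)
  vals[2, 2, 2] <- 10
  vals[5, 5, 5] <- 20                       # global max outside the mask
  mask_v <- array(FALSE, dims); mask_v[1:3, 1:3, 1:3] <- TRUE
  mask <- roi_mask(mask_v, diag(c(2, 2, 2, 1)), "motor_R")
  thr <- ample_threshold(mk_map(vals), mask)
  expect_equal(thr$threshold, 5)
  expect_true(thr$supra[2, 2, 2])
  expect_true(thr$supra[5, 5, 5])           # supra computed over whole map
  # oracle: brute masked max
  expect_equal(thr$threshold, 0.5 * max(vals[mask_v]))

  cst <- mk_map(array(4, dims))
  thr2 <- ample_threshold(cst, mask)
  expect_equal(thr2$threshold, 2)
  expect_true(all(thr2$supra[mask_v]))

  neg <- mk_map(array(-1, dims))
  expect_error(ample_threshold(neg, mask), "no excitable peak")
})

test_that("alpha and beta follow the overlap formula", {
  dims <- c(10, 10, 5)
  aff <- diag(c(2, 2, 2, 1))
  mask <- roi_mask(array(TRUE, dims), aff, "eval")
  mk_thr <- function(idx) {
    v <- array(0, dims); v[idx] <- 1
    fixed_threshold(mk_map(v, aff), 1)
  }
  a <- mk_thr(1:50)
  b <- mk_thr(26:125)
  ov <- overlap_alpha_beta(a, b, mask)
  expect_equal(c(ov$v_tb, ov$v_rs, ov$v_overlap), c(50, 100, 25))
  expect_equal(ov$alpha, 0.5)
  expect_equal(ov$beta, 0.25)

  same <- overlap_alpha_beta(a, a, mask)
  expect_equal(c(same$alpha, same$beta), c(1, 1))

  disj <- overlap_alpha_beta(a, mk_thr(200:240), mask)
  expect_equal(c(disj$alpha, disj$beta), c(0, 0))

  # swapping tb and rs swaps alpha and beta
  sw <- overlap_alpha_beta(b, a, mask)
  expect_equal(sw$alpha, ov$beta)
  expect_equal(sw$beta, ov$alpha)

  expect_error(overlap_alpha_beta(mk_thr(1), mk_thr(1),
                                  roi_mask(array(c(FALSE, rep(TRUE,
                                    prod(dims) - 1)), dims), aff, "m")),
               "undefined overlap")
})

test_that("raising a threshold never increases the overlap", {
  set.seed(40)
  dims <- c(10, 10, 5)
  aff <- diag(c(2, 2, 2, 1))
  mask <- roi_mask(array(TRUE, dims), aff, "eval")
  m1 <- mk_map(array(rnorm(prod(dims)), dims), aff)
  m2 <- mk_map(array(rnorm(prod(dims)), dims), aff)
  thrs <- c(-1, -0.5, 0, 0.5)
  prev <- Inf
  for (th in thrs) {
    ov <- overlap_alpha_beta(fixed_threshold(m1, th),
                             fixed_threshold(m2, -1), mask)
    expect_lte(ov$v_overlap, prev)
    expect_lte(ov$v_overlap, min(ov$v_tb, ov$v_rs))
    expect_true(ov$alpha >= 0 && ov$alpha <= 1 &&
                ov$beta >= 0 && ov$beta <= 1)
    prev <- ov$v_overlap
  }
})

test_that("weighted centre of mass matches the exhaustive-sum oracle", {
  aff <- diag(c(2, 2, 2, 1))
  dims <- c(10, 10, 10)
  # two voxels: t=1 at x index 1, t=3 at x index 6 (0 and 10 mm)
  v <- array(0, dims); v[1, 1, 1] <- 1; v[6, 1, 1] <- 3
  thr <- fixed_threshold(mk_map(v, aff), 1)
  mask <- roi_mask(array(TRUE, dims), aff, "anat")
  com <- weighted_com(thr, mask)
  expect_equal(com$xyz_mm[1], 7.5)

  v1 <- array(0, dims); v1[3, 4, 5] <- 2
  com1 <- weighted_com(fixed_threshold(mk_map(v1, aff), 1), mask)
  expect_equal(com1$xyz_mm, as.numeric(voxel_to_world(aff, c(3, 4, 5))))

  set.seed(41)
  vr <- array(runif(1000), dims)
  thr_r <- fixed_threshold(mk_map(vr, aff), 0.5)
  com_r <- weighted_com(thr_r, mask)
  # oracle: explicit loop
  num <- c(0, 0, 0); den <- 0
  for (i in 1:10) for (j in 1:10) for (k in 1:10)
    if (vr[i, j, k] >= 0.5) {
      w <- vr[i, j, k]
      num <- num + w * as.numeric(voxel_to_world(aff, c(i, j, k)))
      den <- den + w
    }
  expect_lt(max(abs(com_r$xyz_mm - num / den)), 1e-10)

  empty_sel <- fixed_threshold(mk_map(array(0, dims), aff), 1)
  expect_error(weighted_com(empty_sel, mask), "no supra")
})

test_that("lesion centroid and CoM distances are Euclidean in mm", {
  aff <- diag(c(2, 2, 2, 1))
  dims <- c(10, 10, 10)
  v <- array(FALSE, dims); v[4, 5, 6] <- TRUE
  expect_equal(lesion_com(roi_mask(v, aff, "l"))$xyz_mm,
               as.numeric(voxel_to_world(aff, c(4, 5, 6))))

  set.seed(42)
  v2 <- array(runif(1000) > 0.8, dims)
  com <- lesion_com(roi_mask(v2, aff, "l2"))
  idx <- which(v2, arr.ind = TRUE)
  expect_lt(max(abs(com$xyz_mm - colMeans(voxel_to_world(aff, idx)))), 1e-10)

  a <- structure(list(xyz_mm = c(0, 0, 0)), class = "centre_of_mass")
  b <- structure(list(xyz_mm = c(3, 4, 0)), class = "centre_of_mass")
  expect_equal(com_distance(a, b), 5)
  expect_equal(com_distance(b, a), 5)
  expect_equal(com_distance(a, a), 0)
})

test_that("cortical projection moves only extra-cortical sites", {
  aff <- diag(c(2, 2, 2, 1))
  dims <- c(10, 10, 10)
  v <- array(FALSE, dims); v[, , 1:3] <- TRUE      # slab z in [0, 4] mm
  cortex <- roi_mask(v, aff, "cortex")
  sites <- data.frame(site_id = 1:2,
                      x_mm = c(8, 8), y_mm = c(8, 8), z_mm = c(2, 9),
                      response_label = "hand")
  out <- project_site_to_cortex(sites, cortex)
  expect_false(out$projected[1])
  expect_equal(out$proj_z_mm[1], 2)
  expect_true(out$projected[2])
  expect_equal(out$proj_z_mm[2], 4)                # top slab surface
  expect_equal(out$proj_x_mm[2], 8)
  expect_equal(abs(out$z_mm[2] - out$proj_z_mm[2]), 5)
})

test_that("site-to-activation distance is zero inside, metric outside", {
  aff <- diag(c(2, 2, 2, 1))
  dims <- c(10, 10, 10)
  v <- array(0, dims); v[3:5, 3:5, 3:5] <- 1
  thr <- fixed_threshold(mk_map(v, aff), 1)
  inside <- voxel_to_world(aff, c(4, 4, 4))
  expect_equal(ecs_distance(inside, thr), 0)
  p <- as.numeric(voxel_to_world(aff, c(5, 4, 4))) + c(5, 0, 0)
  expect_equal(ecs_distance(p, thr), 5)
  # oracle: brute-force scan over supra voxel centres
  far <- c(0.3, -1.2, 17.4)
  xyz <- voxel_to_world(aff, which(v == 1, arr.ind = TRUE))
  d_oracle <- sqrt(min(colSums((t(xyz) - far)^2)))
  expect_lt(abs(ecs_distance(far, thr) - d_oracle), 1e-8)
  empty <- fixed_threshold(mk_map(array(0, dims), aff), 1)
  expect_error(ecs_distance(far, empty), "empty activation")
})

test_that("match rate counts distances strictly below the cutoff", {
  expect_equal(match_rate(c(0, 0, 0), 10), 100)
  expect_equal(match_rate(c(12, 15), 10), 0)
  expect_equal(match_rate(c(5, 10, 15), 10), 100 / 3)   # 10 not counted
  expect_error(match_rate(numeric(0), 10), "no distances")
})

test_that("aggregation follows the summary-table conventions", {
  vals <- c(1, 2, 3, NA, 10)
  grp <- c("a", "a", "a", "b", "b")
  s <- aggregate_summary(vals, grp)
  expect_equal(s$mean[s$group == "a"], 2)
  expect_equal(s$sd[s$group == "a"], 1)
  expect_equal(s$n[s$group == "b"], 1)
  expect_equal(s$sd[s$group == "b"], 0)            # single value: SD 0
  expect_true(s$single[s$group == "b"])
  expect_equal(s$mean[s$group == "all"], 4)        # NA excluded
  expect_warning(aggregate_summary(c(1, NA), c("x", "y")), "omitted")
})
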