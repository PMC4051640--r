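test_that("task regressor peaks about one HRF delay after block onset", {
  design <- block_design(task = "hand", tr = 3.0)
  # isolate a single left block
  keep <- which(design$blocks$condition == "active_left")[1]
  design$blocks$condition[setdiff(which(
    design$blocks$condition != "rest"), keep)] <- "rest"
  r <- build_task_regressor(design, "left")
  onset_s <- (design$blocks$onset[keep] - 1) * design$tr
  peak_s <- (which.max(r) - 1) * design$tr
  # block is 24 s long; the response should crest near block end + HRF lag,
  # certainly lagging onset by more than the 6 s HRF peak delay
  expect_gt(peak_s - onset_s, 6 - design$tr)
  expect_lt(peak_s - onset_s, 24 + 6 + design$tr)

  expect_error(build_task_regressor(design, "right"), "no 'right'")
})

test_that("both-sides regressor is the sum of the sides before centring", {
  design <- block_design(task = "hand", tr = 3.0)
  r_l <- build_task_regressor(design, "left")
  r_r <- build_task_regressor(design, "right")
  r_b <- build_task_regressor(design, "both")
  d <- (r_l + r_r) - r_b
  expect_lt(max(abs(d - mean(d))), 1e-12)
})

test_that("GLM t-map matches a per-voxel lm oracle", {
  s <- toy_series(dims = c(5, 5, 5), n_t = 50, seed = 10)
  set.seed(11)
  reg <- rnorm(50)
  conf <- matrix(rnorm(50 * 2), 50, 2)
  map <- glm_tmap(s, reg, conf)
  expect_equal(map$dof, 50 - 4)
  mat <- t(apply(s$data, 4, as.vector))
  t_oracle <- apply(mat, 2, function(y) {
    fit <- summary(lm(y ~ reg + conf))
    fit$coefficients["reg", "t value"]
  })
  expect_lt(max(abs(as.vector(map$values) - t_oracle)), 1e-8)
})

test_that("GLM t is scale-free and caps perfect fits", {
  s <- toy_series(dims = c(4, 4, 3), n_t = 60, seed = 12)
  set.seed(13)
  reg <- rnorm(60)
  m1 <- glm_tmap(s, reg)
  s3 <- s; s3$data <- 3 * s$data
  m3 <- glm_tmap(s3, reg)
  expect_lt(max(abs(m1$values - m3$values)), 1e-8)

  # noiseless voxel identical to the regressor
  sp <- s
  sp$data[1, 1, 1, ] <- 5 + reg
  mp <- glm_tmap(sp, reg)
  expect_gt(abs(mp$values[1, 1, 1]), 1e6)

  # pure-noise voxels stay below |t| = 5
  expect_lt(max(abs(m1$values)), 5)

  expect_error(glm_tmap(s, reg, cbind(reg)), "rank deficient")
  expect_error(glm_tmap(s, reg[-1]), "volumes")
})

test_that("seed time course is the unweighted ROI mean", {
  s <- toy_series(dims = c(3, 3, 3), n_t = 40, seed = 14)
  m <- array(FALSE, dim = c(3, 3, 3)); m[1, 1, 1] <- TRUE
  roi1 <- roi_mask(m, s$affine, "one")
  expect_equal(seed_timecourse(s, roi1), s$data[1, 1, 1, ])

  s2 <- s
  s2$data[2, 1, 1, ] <- 1 + sin(seq_len(40))
  s2$data[3, 1, 1, ] <- 1 - sin(seq_len(40))
  m2 <- array(FALSE, dim = c(3, 3, 3)); m2[2:3, 1, 1] <- TRUE
  expect_lt(max(abs(seed_timecourse(s2, roi_mask(m2, s$affine, "pm")) - 1)),
            1e-12)
})

test_that("seed-based t-map behaves at the extremes", {
  s <- toy_series(dims = c(4, 4, 3), n_t = 60, seed = 15)
  seed_tc <- rnorm(60)
  s$data[1, 1, 1, ] <- seed_tc
  v <- rnorm(60)
  v <- qr.resid(qr(cbind(1, seed_tc)), v)   # exactly orthogonal voxel
  s$data[2, 1, 1, ] <- v
  map <- sba_tmap(s, seed_tc)
  expect_equal(which.max(map$values), 1L)
  expect_gt(abs(map$values[1, 1, 1]), 1e6)
  expect_lt(abs(map$values[2, 1, 1]), 0.1)
  expect_error(sba_tmap(s, rep(1, 60)), "constant")
})

test_that("spatial ICA recovers planted orthogonal sources", {
  dims <- c(10, 10, 4)
  n_t <- 60
  aff <- toy_affine(dims = dims)
  src1 <- array(0, dims); src1[2:4, 2:4, 1:2] <- 1
  src2 <- array(0, dims); src2[7:9, 6:9, 3:4] <- 1
  set.seed(20)
  tc1 <- rnorm(n_t); tc2 <- rnorm(n_t)
  data <- array(rnorm(prod(dims) * n_t, sd = 0.05), dim = c(dims, n_t))
  for (tt in seq_len(n_t))
    data[, , , tt] <- data[, , , tt] + tc1[tt] * src1 + tc2[tt] * src2
  s <- bold_series(data, aff, 2)
  brain <- roi_mask(array(TRUE, dims), aff, "brain")
  dec <- spatial_ica(s, brain, n_components = 2, seed = 42)
  cors <- sapply(dec$spatial_maps, function(m)
    c(abs(cor(as.vector(m), as.vector(src1))),
      abs(cor(as.vector(m), as.vector(src2)))))
  # each truth source is matched by some component
  expect_gt(max(cors[1, ]), 0.9)
  expect_gt(max(cors[2, ]), 0.9)

  # determinism and the z-scoring contract
  dec2 <- spatial_ica(s, brain, n_components = 2, seed = 42)
  expect_identical(dec$spatial_maps, dec2$spatial_maps)
  for (m in dec$spatial_maps) {
    expect_lt(abs(mean(m[brain$values])), 1e-6)
    expect_lt(abs(sd(m[brain$values]) - 1), 1e-6)
  }
  expect_error(spatial_ica(s, brain, n_components = 60), "below")
})

test_that("sensorimotor component selection scores inside-concentration", {
  dims <- c(8, 8, 4)
  aff <- toy_affine(dims = dims)
  mask_v <- array(FALSE, dims); mask_v[2:4, 2:4, 2] <- TRUE
  mask <- roi_mask(mask_v, aff, "motor")
  mk_map <- function(v) { a <- array(0, dims); a[v] <- 5; a }
  dec <- structure(list(
    n_components = 2L,
    spatial_maps = list(mk_map(which(!mask_v)[1:20]), mk_map(which(mask_v))),
    time_courses = matrix(0, 10, 2), seed = 1L, affine = aff,
    brain_mask = NULL, iterations = 1L, converged = TRUE),
    class = "ica_decomposition")
  sel <- select_sensorimotor_component(dec, mask, z_thr = 2)
  rep <- attr(sel, "selection")
  expect_equal(rep$component, 2L)
  expect_equal(rep$score, 1)

  dec$spatial_maps[[2]] <- mk_map(which(!mask_v)[21:30])
  expect_error(select_sensorimotor_component(dec, mask, z_thr = 2),
               "no sensorimotor component")
})
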