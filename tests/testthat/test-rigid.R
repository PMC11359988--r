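# Rigid parameterization, matrices, deformation fields and warping.

test_that("params_to_matrix matches the explicit five-matrix product", {
  expect_equal(params_to_matrix(rigid_params()), diag(4))

  # right-handed z rotation by 90 degrees maps (1,0,0) to (0,1,0)
  A <- params_to_matrix(rigid_params(r = c(0, 0, 90)))
  expect_equal(as.numeric(A %*% c(1, 0, 0, 1))[1:3], c(0, 1, 0))

  set.seed(3)
  for (i in 1:20) {
    p <- rigid_params(runif(3, -20, 20), runif(3, -40, 40))
    ctr <- runif(3, -50, 50)
    rad <- p$r * pi / 180
    Rx <- rbind(c(1, 0, 0), c(0, cos(rad[1]), -sin(rad[1])), c(0, sin(rad[1]), cos(rad[1])))
    Ry <- rbind(c(cos(rad[2]), 0, sin(rad[2])), c(0, 1, 0), c(-sin(rad[2]), 0, cos(rad[2])))
    Rz <- rbind(c(cos(rad[3]), -sin(rad[3]), 0), c(sin(rad[3]), cos(rad[3]), 0), c(0, 0, 1))
    h <- function(R, t = c(0, 0, 0)) { m <- diag(4); m[1:3, 1:3] <- R; m[1:3, 4] <- t; m }
    oracle <- h(diag(3), p$t) %*% h(diag(3), ctr) %*% h(Rz) %*% h(Ry) %*% h(Rx) %*%
      h(diag(3), -ctr)
    expect_lt(max(abs(params_to_matrix(p, ctr) - oracle)), 1e-12)
  }
})

test_that("rigid matrices are orthonormal, invert exactly and preserve distances", {
  set.seed(4)
  for (i in 1:10) {
    p <- rigid_params(runif(3, -10, 10), runif(3, -30, 30))
    A <- params_to_matrix(p, runif(3, -20, 20))
    R <- A[1:3, 1:3]
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_lt(abs(det(R) - 1), 1e-9)
    Ai <- invert_matrix(A)
    expect_lt(max(abs(A %*% Ai - diag(4))), 1e-10)
    # transpose construction agrees with generic solve()
    expect_lt(max(abs(Ai - solve(A))), 1e-10)
    # pairwise distances preserved
    x <- c(runif(3, -30, 30), 1); y <- c(runif(3, -30, 30), 1)
    expect_lt(abs(sqrt(sum(((A %*% x) - (A %*% y))[1:3]^2)) - sqrt(sum((x - y)[1:3]^2))), 1e-9)
  }
  expect_equal(invert_matrix(diag(4)), diag(4))
  Tm <- diag(4); Tm[1:3, 4] <- c(3, -2, 1)
  expect_equal(invert_matrix(Tm)[1:3, 4], c(-3, 2, -1))
  bad <- diag(4); bad[1, 1] <- 2
  expect_error(invert_matrix(bad), "rigid")
})

test_that("stepwise matrix composition matches the combined transform", {
  ctr <- c(5, 5, 5)
  t1 <- params_to_matrix(rigid_params(t = c(2, 0, -1)), ctr)
  t2 <- params_to_matrix(rigid_params(t = c(-1, 3, 4)), ctr)
  expect_lt(max(abs(t1 %*% t2 -
                      params_to_matrix(rigid_params(t = c(1, 3, 3)), ctr))), 1e-10)
  # successive z rotations compose additively about the same centre
  r1 <- params_to_matrix(rigid_params(r = c(0, 0, 10)), ctr)
  r2 <- params_to_matrix(rigid_params(r = c(0, 0, 25)), ctr)
  expect_lt(max(abs(r1 %*% r2 - params_to_matrix(rigid_params(r = c(0, 0, 35)), ctr))), 1e-10)
})

test_that("matrix_to_field equals per-voxel matrix products", {
  sh <- c(5, 4, 3); sp <- c(2, 2, 4); org <- c(1, -2, 0)
  idf <- matrix_to_field(diag(4), sh, sp, org)
  expect_equal(idf$coords_mm, grid_phys_coords(sh, sp, org))

  Tm <- diag(4); Tm[1:3, 4] <- c(1, 0, 0)
  tf <- matrix_to_field(Tm, sh, sp, org)
  expect_equal(tf$coords_mm - idf$coords_mm,
               matrix(rep(c(1, 0, 0), each = prod(sh)), ncol = 3))

  set.seed(5)
  A <- params_to_matrix(rigid_params(runif(3, -5, 5), runif(3, -20, 20)), c(4, 4, 6))
  fld <- matrix_to_field(A, sh, sp, org)
  k <- 0
  for (z in 0:(sh[3] - 1)) for (y in 0:(sh[2] - 1)) for (x in 0:(sh[1] - 1)) {
    k <- k + 1
    phys <- org + c(x, y, z) * sp
    expect_equal(fld$coords_mm[k, ], as.numeric(A %*% c(phys, 1))[1:3],
                 tolerance = 1e-12)
  }
})

test_that("warping: identity exact, integer shifts exact, inverse-consistent", {
  set.seed(6)
  v <- volume(array(rnorm(12 * 12 * 8), c(12, 12, 8)), spacing = c(2, 2, 4))
  idf <- matrix_to_field(diag(4), dim(v$voxels), v$spacing, v$origin)
  expect_identical(warp_volume(v, idf)$voxels, v$voxels)

  # +1 voxel shift along x in mm; pull-back moves content by -1 voxel
  Tm <- diag(4); Tm[1, 4] <- v$spacing[1]
  w <- warp_volume(v, matrix_to_field(Tm, dim(v$voxels), v$spacing, v$origin), fill = -5)
  shifted <- array(-5, dim(v$voxels))
  shifted[1:11, , ] <- v$voxels[2:12, , ]
  expect_equal(w$voxels, shifted)

  # warp by A then A^-1 restores a smooth Gaussian blob (unit amplitude)
  # within 1e-3 RMS away from a 2-voxel border
  sh <- c(64, 64, 64)
  ctr <- (sh - 1) / 2
  px <- swinreg:::grid_phys_coords(sh, c(1, 1, 1), c(0, 0, 0))
  g <- array(exp(-rowSums(sweep(px, 2, ctr, "-")^2) / (2 * 10^2)), sh)
  gv <- volume(g, spacing = c(1, 1, 1))
  A <- params_to_matrix(rigid_params(c(2, -1.5, 1), c(4, -3, 5)), volume_center(gv))
  f1 <- matrix_to_field(A, sh, gv$spacing, gv$origin)
  f2 <- matrix_to_field(invert_matrix(A), sh, gv$spacing, gv$origin)
  back <- warp_volume(warp_volume(gv, f1, fill = 0), f2, fill = 0)
  core <- back$voxels[3:62, 3:62, 3:62] - g[3:62, 3:62, 3:62]
  expect_lt(sqrt(mean(core^2)), 1e-3)
})

test_that("segmentation warping is nearest-neighbour with a closed label set", {
  set.seed(7)
  s <- segmentation(array(sample(0:3, 10 * 10 * 6, TRUE), c(10, 10, 6)),
                    c("a", "b", "c"), spacing = c(2, 2, 4))
  idf <- matrix_to_field(diag(4), dim(s$labels), s$spacing, s$origin)
  expect_identical(warp_segmentation(s, idf)$labels, s$labels)

  Tm <- diag(4); Tm[2, 4] <- 2 * s$spacing[2]
  w <- warp_segmentation(s, matrix_to_field(Tm, dim(s$labels), s$spacing, s$origin))
  shifted <- array(0, dim(s$labels))
  shifted[, 1:8, ] <- s$labels[, 3:10, ]
  expect_equal(w$labels, shifted)

  A <- params_to_matrix(rigid_params(c(3, 1, -2), c(10, -5, 15)), c(10, 10, 12))
  wr <- warp_segmentation(s, matrix_to_field(A, dim(s$labels), s$spacing, s$origin))
  expect_true(all(unique(as.vector(wr$labels)) %in% 0:3))
})

test_that("landmarks track warped image content (pull-back consistency)", {
  lms <- landmarks(c("p1", "p2"), c("head", "neck"), rbind(c(10, 8, 6), c(4, 4, 20)))
  expect_equal(lm_xyz(transform_landmarks(lms, diag(4))), lm_xyz(lms),
               ignore_attr = TRUE)

  # image warped with +3 mm translation field: content and landmarks move -3 mm
  Tm <- diag(4); Tm[1, 4] <- 3
  moved <- transform_landmarks(lms, Tm)
  expect_equal(lm_xyz(moved)[, 1], lm_xyz(lms)[, 1] - 3)
  expect_equal(moved$region, lms$region)

  # single bright voxel tracks its landmark within one voxel under random rigid
  set.seed(9)
  for (i in 1:5) {
    sh <- c(20, 20, 12); sp <- c(2, 2, 4)
    v <- array(0, sh); v[11, 9, 7] <- 1
    pos <- (c(11, 9, 7) - 1) * sp
    vol <- volume(v, sp)
    A <- params_to_matrix(rigid_params(runif(3, -4, 4), runif(3, -8, 8)),
                          volume_center(vol))
    w <- warp_volume(vol, matrix_to_field(A, sh, sp, vol$origin), fill = 0)
    peak <- (which(w$voxels == max(w$voxels), arr.ind = TRUE)[1, ] - 1) * sp
    lm <- transform_landmarks(landmarks("pk", "head", rbind(pos)), A)
    expect_lt(sqrt(sum((lm_xyz(lm) - peak)^2)), sqrt(sum(sp^2)))
  }
})

test_that("rigid parameter JSON round trip", {
  p <- rigid_params(c(1.25, -2.5, 3), c(-1, 0.5, 2))
  f <- tempfile(fileext = ".json")
  write_rigid_params(p, f, center = c(10, 20, 30))
  r <- read_rigid_params(f)
  expect_equal(r$params$t, p$t)
  expect_equal(r$params$r, p$r)
  expect_equal(r$center, c(10, 20, 30))
})
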