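# Synthetic phantom generator, CBCT simulation, misalignments, deformation,
# dataset assembly.

test_that("phantoms are seed-deterministic with five structures and tagged landmarks", {
  spec <- phantom_spec(shape = c(32, 32, 16), spacing = c(4, 4, 8), seed = 7)
  p1 <- make_phantom(spec)
  p2 <- make_phantom(spec)
  expect_identical(p1$ct$voxels, p2$ct$voxels)
  expect_identical(p1$seg$labels, p2$seg$labels)
  expect_identical(as.data.frame(unclass(p1$lms)), as.data.frame(unclass(p2$lms)))

  expect_setequal(setdiff(unique(as.vector(p1$seg$labels)), 0L), 1:5)
  expect_equal(p1$seg$structure_names,
               c("eyes", "optic_nerve", "brainstem", "spinal_cord", "larynx"))
  expect_equal(sum(p1$lms$region == "head"), 10L)
  expect_equal(sum(p1$lms$region == "neck"), 10L)

  # head landmarks above the boundary plane, neck landmarks below
  ext_z <- dim(p1$ct$voxels)[3] * p1$ct$spacing[3]
  zb <- spec$boundary_fraction * ext_z
  expect_true(all(p1$lms$z_mm[p1$lms$region == "head"] > zb))
  expect_true(all(p1$lms$z_mm[p1$lms$region == "neck"] <= zb))
  expect_error(phantom_spec(shape = c(16, 16, 8)), "at least")
})

test_that("CBCT simulation applies the configured offset exactly when noiseless", {
  spec <- phantom_spec(shape = c(32, 32, 16), spacing = c(4, 4, 8), seed = 8,
                       intensity_offset = 0.1, streak_amplitude = 0,
                       noise_sigma = 0, shading_amplitude = 0)
  ph <- make_phantom(spec)
  cb <- simulate_cbct(ph$ct, spec)
  expect_lt(abs(mean(cb$voxels - ph$ct$voxels) - 0.1), 1e-6)
  # zero-artifact configuration is an exact copy
  spec0 <- spec; spec0$intensity_offset <- 0
  expect_equal(simulate_cbct(ph$ct, spec0)$voxels, ph$ct$voxels)
  # reproducible under the phantom_spec() seed
  specn <- spec; specn$noise_sigma <- 10; specn$streak_amplitude <- 20
  expect_identical(simulate_cbct(ph$ct, specn)$voxels,
                   simulate_cbct(ph$ct, specn)$voxels)
})

test_that("misalignment sampling is uniform within bounds", {
  set.seed(9)
  draws <- replicate(1e4, {
    p <- sample_misalignment(3, 3, spacing = c(2, 2, 4))
    c(p$t / c(2, 2, 4), p$r)
  })
  expect_true(all(abs(draws) <= 3))
  se <- (2 * 3) / sqrt(12) / sqrt(1e4)        # sd of U(-3,3) / sqrt(n)
  expect_true(all(abs(rowMeans(draws)) < 3 * se))
  z <- sample_misalignment(0, 0, c(1, 1, 1))
  expect_equal(c(z$t, z$r), rep(0, 6))
  expect_error(sample_misalignment(-1, 0), "non-negative")
})

test_that("neck deformation vanishes in the head and bounds landmark motion", {
  spec <- phantom_spec(shape = c(32, 32, 16), spacing = c(4, 4, 8), seed = 10,
                       deform_magnitude_mm = 3)
  ph <- make_phantom(spec)
  d <- apply_neck_deformation(ph$ct, ph$seg, ph$lms, spec)

  # magnitude zero is the identity on all three outputs
  spec0 <- spec; spec0$deform_magnitude_mm <- 0
  d0 <- apply_neck_deformation(ph$ct, ph$seg, ph$lms, spec0)
  expect_identical(d0$vol$voxels, ph$ct$voxels)
  expect_identical(d0$seg$labels, ph$seg$labels)
  expect_identical(lm_xyz(d0$lms), lm_xyz(ph$lms))

  # voxels above the boundary plane are untouched
  ext_z <- dim(ph$ct$voxels)[3] * ph$ct$spacing[3]
  zb_vox <- floor(spec$boundary_fraction * ext_z / ph$ct$spacing[3]) + 2
  expect_equal(d$vol$voxels[, , zb_vox:16], ph$ct$voxels[, , zb_vox:16])
  expect_equal(d$seg$labels[, , zb_vox:16], ph$seg$labels[, , zb_vox:16])

  # landmark displacement bounded by the configured magnitude
  disp <- sqrt(rowSums((lm_xyz(d$lms) - lm_xyz(ph$lms))^2))
  expect_true(all(disp <= 3 + 1e-9))
  expect_true(any(disp > 0))
  # head landmarks do not move
  expect_true(all(disp[ph$lms$region == "head"] < 1e-12))
})

test_that("no single rigid transform aligns both regions of a deformed phantom", {
  spec <- phantom_spec(shape = c(32, 32, 16), spacing = c(4, 4, 8), seed = 11,
                       deform_magnitude_mm = 6)
  ph <- make_phantom(spec)
  d <- apply_neck_deformation(ph$ct, ph$seg, ph$lms, spec)
  # grid search over rigid motions: no candidate gets both regional TREs small
  best <- Inf
  for (tx in seq(-4, 4, by = 2)) for (ty in seq(-4, 4, by = 2)) for (rz in seq(-2, 2, by = 1)) {
    A <- params_to_matrix(rigid_params(c(tx, ty, 0), c(0, 0, rz)), volume_center(ph$ct))
    t <- tre(ph$lms, transform_landmarks(d$lms, invert_matrix(A)))
    best <- min(best, max(t))
  }
  half_voxel <- 0.5 * max(spec$spacing)
  expect_gt(best, half_voxel * 0.25)
})

test_that("dataset assembly splits, serializes and closes under the true transform", {
  man <- tiny_dataset()
  spl <- vapply(man$cases, `[[`, "", "split")
  expect_equal(c(sum(spl == "train"), sum(spl == "val"), sum(spl == "test")),
               c(3L, 1L, 1L))
  # split counting at n = 10 with (0.7, 0.1, 0.2)
  sp <- rep(c("train", "val", "test"), c(max(1, round(10 * .7)), max(1, round(10 * .1)), 2))
  expect_equal(sum(sp == "train"), 7L)

  # same master seed reproduces the manifest exactly (fresh directory)
  man2 <- make_dataset(5, phantom_spec(shape = c(32L, 32L, 16L), spacing = c(2, 2, 4),
                                       seed = 42L, deform_magnitude_mm = 0),
                       file.path(tempdir(), "swr_ds_tiny2"), split = c(3, 1, 1) / 5,
                       deform = FALSE)
  expect_equal(lapply(man$cases, `[[`, "true_params"),
               lapply(man2$cases, `[[`, "true_params"))
  d1 <- swinreg:::load_case(man, man$cases[[1]])
  d2 <- swinreg:::load_case(man2, man2$cases[[1]])
  expect_identical(d1$fixed$voxels, d2$fixed$voxels)
  expect_identical(d1$moving$voxels, d2$moving$voxels)

  # registering with the recorded true parameters restores alignment
  ev <- evaluate_model(man, use_true_params = TRUE, split = "test", initial = TRUE)
  expect_lt(ev$per_case$TRE_H[1], max(man$spacing))
  expect_lt(ev$per_case$TRE_N[1], max(man$spacing))
  expect_gt(ev$per_case$DSC[1], 0.95)
  expect_error(make_dataset(2, phantom_spec()), "at least 3")
  expect_error(make_dataset(5, phantom_spec(), split = c(0.5, 0.2)), "split")
})
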