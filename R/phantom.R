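# Synthetic head-neck phantom generator.
#
# Procedural CT-like volumes (ellipsoidal skull over a cylindrical neck, HU-like
# units with air at -1000) carrying five labelled structures -- eyes, optic
# nerve and brainstem in the head; spinal cord and larynx in the neck -- plus
# ten landmarks per region, CBCT-style degradation (intensity offset, smooth
# shading, radial streaks, noise), uniformly sampled rigid misalignments, and a
# smooth neck-only deformation that vanishes above the head/neck boundary
# plane. Everything is a pure function of the phantom_spec() seed.

#' Phantom specification
#'
#' @param shape Voxel grid (minimum 32 x 32 x 16).
#' @param spacing Voxel spacing in mm.
#' @param seed Master seed; every derived quantity is a pure function of it.
#' @param intensity_offset CBCT global additive intensity shift (HU-like).
#' @param streak_amplitude Amplitude of the radial streak artifact pattern.
#' @param noise_sigma Additive Gaussian noise sd for the CBCT simulation.
#' @param shading_amplitude Relative amplitude of the smooth multiplicative
#'   shading field.
#' @param deform_magnitude_mm Peak neck deformation displacement.
#' @param boundary_fraction Axial fraction (of physical extent, from the
#'   inferior end) where the neck ends and the head begins.
#' @param rot_range_deg,trans_range_vox Misalignment sampling ranges.
#' @return A `swr_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 32L), spacing = c(2, 2, 4), seed = 1L,
                         intensity_offset = 40, streak_amplitude = 30,
                         noise_sigma = 20, shading_amplitude = 0.08,
                         deform_magnitude_mm = 3, boundary_fraction = 0.5,
                         rot_range_deg = 3, trans_range_vox = 3) {
  shape <- as.integer(shape)
  if (any(shape < c(32L, 32L, 16L))) stop("phantom shape must be at least 32 x 32 x 16")
  if (boundary_fraction <= 0 || boundary_fraction >= 1) stop("boundary_fraction in (0,1)")
  structure(list(shape = shape, spacing = as.numeric(spacing), seed = as.integer(seed),
                 intensity_offset = intensity_offset, streak_amplitude = streak_amplitude,
                 noise_sigma = noise_sigma, shading_amplitude = shading_amplitude,
                 deform_magnitude_mm = deform_magnitude_mm,
                 boundary_fraction = boundary_fraction,
                 rot_range_deg = rot_range_deg, trans_range_vox = trans_range_vox),
            class = "swr_phantom_spec")
}

phantom_structures <- c("eyes", "optic_nerve", "brainstem", "spinal_cord", "larynx")

smooth_noise <- function(shape, sigma_vox, sd = 1) {
  x <- array(stats::rnorm(prod(shape)), shape)
  x <- cpp_gaussian_blur3d(x, as.integer(shape), sigma_vox)
  x / stats::sd(x) * sd
}

#' Generate a head-neck phantom
#'
#' @param spec A [phantom_spec()].
#' @return List: `ct` (`swr_volume`, HU-like), `seg` (`swr_segmentation`, five
#'   structures), `lms` (`swr_landmarks`, 10 head + 10 neck points).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  set.seed(spec$seed)
  sh <- spec$shape; sp <- spec$spacing
  ext <- sh * sp
  n <- prod(sh)
  # physical coordinate grids
  px <- (rep(seq_len(sh[1]), times = sh[2] * sh[3]) - 1) * sp[1]
  py <- (rep(rep(seq_len(sh[2]), each = sh[1]), times = sh[3]) - 1) * sp[2]
  pz <- (rep(seq_len(sh[3]), each = sh[1] * sh[2]) - 1) * sp[3]
  cx <- ext[1] / 2; cy <- ext[2] / 2
  zb <- spec$boundary_fraction * ext[3]            # head/neck boundary plane
  # per-phantom anatomical jitter (makes cases distinct)
  jit <- stats::rnorm(6, sd = 0.02)
  ct <- rep(-1000, n)
  # --- head: ellipsoidal skull with brain interior --------------------------
  hz <- (zb + ext[3]) / 2
  ax <- (0.33 + jit[1]) * ext[1]; ay <- (0.37 + jit[2]) * ext[2]
  az <- 0.58 * (ext[3] - zb)
  rell <- sqrt(((px - cx) / ax)^2 + ((py - cy) / ay)^2 + ((pz - hz) / az)^2)
  brain <- rell < 0.88
  skull <- rell >= 0.88 & rell <= 1
  ct[skull] <- 700
  ct[brain] <- 35
  # --- neck: soft-tissue cylinder with a vertebral column -------------------
  nrad <- (0.22 + jit[3]) * ext[1]
  neck <- sqrt((px - cx)^2 + (py - cy)^2) < nrad & pz <= zb + 0.05 * ext[3] & pz > 0.03 * ext[3]
  neck <- neck & !brain & !skull
  ct[neck] <- 40
  vert <- sqrt((px - cx)^2 + (py - (cy + 0.10 * ext[2]))^2) < 0.07 * ext[1] &
    pz <= zb & pz > 0.03 * ext[3]
  ct[vert] <- 600
  # --- five structures ------------------------------------------------------
  lab <- integer(n)
  eye_z <- hz + 0.05 * ext[3]
  eye_r <- 0.070 * ext[1]
  eye_y <- cy - (0.22 + jit[4]) * ext[2]
  eyeL <- sqrt((px - (cx - 0.14 * ext[1]))^2 + (py - eye_y)^2 + (pz - eye_z)^2) < eye_r
  eyeR <- sqrt((px - (cx + 0.14 * ext[1]))^2 + (py - eye_y)^2 + (pz - eye_z)^2) < eye_r
  nerve <- abs(pz - eye_z) < 0.035 * ext[3] & abs(px - cx) < 0.14 * ext[1] &
    abs(py - (eye_y + 0.12 * ext[2])) < 0.035 * ext[2]
  bs_r <- 0.065 * ext[1]
  brainstem <- sqrt((px - cx)^2 + (py - cy)^2) < bs_r & pz > zb & pz < hz
  cord <- sqrt((px - cx)^2 + (py - (cy + 0.10 * ext[2]))^2) < 0.045 * ext[1] &
    pz <= zb & pz > 0.04 * ext[3]
  lar <- sqrt((px - cx)^2 + (py - (cy - 0.15 * ext[2]))^2) < 0.06 * ext[1] &
    pz <= zb - 0.05 * ext[3] & pz > zb - 0.30 * ext[3]
  lab[eyeL | eyeR] <- 1L
  lab[nerve & lab == 0L] <- 2L
  lab[brainstem & lab == 0L] <- 3L
  lab[cord & lab == 0L] <- 4L
  lab[lar & lab == 0L] <- 5L
  if (length(unique(lab)) != 6L) stop("structures do not fit the requested shape")
  # structures visible in CT
  ct[lab == 1L] <- 10; ct[lab == 2L] <- 60; ct[lab == 3L] <- 55
  ct[lab == 4L] <- 50; ct[lab == 5L] <- -300
  # soft-tissue texture
  tex <- smooth_noise(sh, c(1.5, 1.5, 1), sd = 18)
  body <- ct > -900
  ct[body] <- ct[body] + tex[body]
  ctv <- array(ct, sh)
  seg <- segmentation(array(lab, sh), phantom_structures, sp, c(0, 0, 0))
  # --- landmarks ------------------------------------------------------------
  hpts <- rbind(
    eye_center_L = c(cx - 0.14 * ext[1], eye_y, eye_z),
    eye_center_R = c(cx + 0.14 * ext[1], eye_y, eye_z),
    eye_ant_L = c(cx - 0.14 * ext[1], eye_y - eye_r, eye_z),
    eye_ant_R = c(cx + 0.14 * ext[1], eye_y - eye_r, eye_z),
    nerve_mid = c(cx, eye_y + 0.12 * ext[2], eye_z),
    brainstem_top = c(cx, cy, hz - 0.02 * ext[3]),
    brainstem_mid = c(cx, cy, (zb + hz) / 2),
    skull_ant = c(cx, cy - ay, hz),
    skull_post = c(cx, cy + ay, hz),
    skull_top = c(cx, cy, hz + az)
  )
  zm <- zb * 0.55
  npts <- rbind(
    cord_c1 = c(cx, cy + 0.10 * ext[2], zb - 0.05 * ext[3]),
    cord_c3 = c(cx, cy + 0.10 * ext[2], zb - 0.20 * ext[3]),
    cord_c5 = c(cx, cy + 0.10 * ext[2], zb - 0.35 * ext[3]),
    cord_c7 = c(cx, cy + 0.10 * ext[2], max(zb - 0.45 * ext[3], 0.06 * ext[3])),
    larynx_top = c(cx, cy - 0.15 * ext[2], zb - 0.06 * ext[3]),
    larynx_mid = c(cx, cy - 0.15 * ext[2], zb - 0.17 * ext[3]),
    larynx_low = c(cx, cy - 0.15 * ext[2], zb - 0.28 * ext[3]),
    neck_ant = c(cx, cy - nrad, zm),
    neck_left = c(cx - nrad, cy, zm),
    neck_right = c(cx + nrad, cy, zm)
  )
  lms <- landmarks(c(rownames(hpts), rownames(npts)),
                   c(rep("head", nrow(hpts)), rep("neck", nrow(npts))),
                   rbind(hpts, npts))
  list(ct = volume(ctv, sp, c(0, 0, 0)), seg = seg, lms = lms)
}

#' Simulate a CBCT acquisition from a phantom CT
#'
#' Global intensity offset, smooth multiplicative shading of the attenuation
#' (relative to air), a radial streak pattern about the axial axis, and
#' additive Gaussian noise. Deterministic for a given spec seed.
#'
#' @param ct A `swr_volume` from [make_phantom()].
#' @param spec The [phantom_spec()].
#' @return Degraded `swr_volume`.
#' @export
simulate_cbct <- function(ct, spec) {
  set.seed(spec$seed + 7919L)
  sh <- dim(ct$voxels); sp <- ct$spacing
  ext <- sh * sp
  x <- ct$voxels
  shading <- smooth_noise(sh, c(6, 6, 3), sd = spec$shading_amplitude)
  y <- (x + 1000) * (1 + shading) - 1000 + spec$intensity_offset
  if (spec$streak_amplitude != 0) {
    px <- (rep(seq_len(sh[1]), times = sh[2] * sh[3]) - 1) * sp[1] - ext[1] / 2
    py <- (rep(rep(seq_len(sh[2]), each = sh[1]), times = sh[3]) - 1) * sp[2] - ext[2] / 2
    theta <- atan2(py, px)
    r <- sqrt(px^2 + py^2) / (ext[1] / 2)
    streak <- spec$streak_amplitude * sin(12 * theta) * exp(-2 * r) * (r > 0.05)
    y <- y + array(streak, sh)
  }
  if (spec$noise_sigma > 0)
    y <- y + array(stats::rnorm(prod(sh), sd = spec$noise_sigma), sh)
  volume(y, ct$spacing, ct$origin)
}

#' Sample a rigid misalignment
#'
#' Each rotation component is uniform in [-rot, +rot] degrees and each
#' translation uniform in [-trans, +trans] voxels, converted to mm via the
#' spacing.
#'
#' @param rot_range_deg,trans_range_vox Non-negative ranges.
#' @param spacing Voxel spacing (mm) used to convert translations.
#' @return A `swr_rigid_params`.
#' @export
sample_misalignment <- function(rot_range_deg = 3, trans_range_vox = 3,
                                spacing = c(1, 1, 1)) {
  if (rot_range_deg < 0 || trans_range_vox < 0) stop("ranges must be non-negative")
  t_vox <- stats::runif(3, -trans_range_vox, trans_range_vox)
  r <- stats::runif(3, -rot_range_deg, rot_range_deg)
  rigid_params(t_vox * spacing, r)
}

# Smooth ramp: 0 above the boundary, 1 well below it.
neck_weight <- function(pz, zb, taper) {
  s <- pmin(pmax((zb - pz) / taper, 0), 1)
  s * s * (3 - 2 * s)
}

#' Apply a smooth neck-only deformation
#'
#' A random smooth displacement field, exactly zero above the head/neck
#' boundary plane and bounded by `deform_magnitude_mm` below it, applied
#' consistently to the volume (trilinear), segmentation (nearest) and
#' landmarks (field lookup). This emulates the posture change between planning
#' CT and treatment-day CBCT that makes a single rigid transform unable to fit
#' head and neck simultaneously.
#'
#' @param vol,seg,lms Phantom components.
#' @param spec The [phantom_spec()] (fields `deform_magnitude_mm`,
#'   `boundary_fraction`, `seed`).
#' @return List with deformed `vol`, `seg`, `lms`.
#' @export
apply_neck_deformation <- function(vol, seg, lms, spec) {
  mag <- spec$deform_magnitude_mm
  if (mag == 0) return(list(vol = vol, seg = seg, lms = lms))
  set.seed(spec$seed + 104729L)
  sh <- dim(vol$voxels); sp <- vol$spacing
  ext <- sh * sp
  zb <- spec$boundary_fraction * ext[3]
  taper <- 0.18 * ext[3]
  pz <- array((rep(seq_len(sh[3]), each = sh[1] * sh[2]) - 1) * sp[3], sh)
  w <- neck_weight(pz, zb, taper)
  # structured component: a neck bend — rotation about the x axis through a
  # pivot on the boundary plane, with angle growing toward the inferior end.
  # The depth-dependent angle makes the field non-rigid by construction, so no
  # single rigid transform can undo it.
  py <- array((rep(rep(seq_len(sh[2]), each = sh[1]), times = sh[3]) - 1) * sp[2], sh)
  pivot_y <- ext[2] / 2
  alpha0 <- stats::runif(1, 0.03, 0.06) * sample(c(-1, 1), 1)
  ang <- alpha0 * w
  dy_b <- cos(ang) * (py - pivot_y) - sin(ang) * (pz - zb) - (py - pivot_y)
  dz_b <- sin(ang) * (py - pivot_y) + cos(ang) * (pz - zb) - (pz - zb)
  # random smooth component with shorter correlation length
  r <- lapply(1:3, function(i) smooth_noise(sh, c(4, 4, 2), sd = 1) * w)
  bmax <- max(sqrt(dy_b^2 + dz_b^2))
  rmax <- max(sqrt(r[[1]]^2 + r[[2]]^2 + r[[3]]^2))
  d <- list(r[[1]] * (0.35 * bmax / rmax),
            dy_b + r[[2]] * (0.35 * bmax / rmax),
            dz_b + r[[3]] * (0.35 * bmax / rmax))
  nrm <- sqrt(d[[1]]^2 + d[[2]]^2 + d[[3]]^2)
  scale <- mag / max(nrm)
  d <- lapply(d, function(f) f * scale)
  # pull-back sampling at x + d(x)
  phys <- grid_phys_coords(sh, sp, vol$origin)
  disp <- cbind(as.numeric(d[[1]]), as.numeric(d[[2]]), as.numeric(d[[3]]))
  coords <- sweep(sweep(phys + disp, 2L, vol$origin, "-"), 2L, sp, "/")
  x4 <- vol$voxels; dim(x4) <- c(sh, 1L)
  vv <- cpp_sample_trilinear(x4, as.integer(c(sh, 1L)), coords, min(vol$voxels))
  sv <- cpp_sample_nearest(seg$labels, as.integer(c(sh, 1L)), coords, 0)
  # landmarks track content: y + d(y) = x  =>  y ~ x - d(x) for smooth small d
  xyz <- lm_xyz(lms)
  vox <- sweep(sweep(xyz, 2L, vol$origin, "-"), 2L, sp, "/")
  dl <- vapply(1:3, function(i) {
    di <- d[[i]]; dim(di) <- c(sh, 1L)
    cpp_sample_trilinear(di, as.integer(c(sh, 1L)), vox, 0)[, 1]
  }, numeric(nrow(xyz)))
  list(vol = volume(array(vv, sh), sp, vol$origin),
       seg = segmentation(array(as.integer(round(sv)), sh), seg$structure_names, sp, seg$origin),
       lms = landmarks(lms$name, lms$region, xyz - dl))
}

#' Generate a registration dataset of phantom pairs
#'
#' For each case: phantom -> CBCT simulation -> optional neck deformation ->
#' rigid misalignment of the moving side, with the true parameters recorded.
#' Files are written as NIfTI + landmark CSVs under `dir/case_XXX/`, with a
#' JSON manifest. The pre-misalignment moving image (`moving_base`) is stored
#' so training can compose augmentation with the stored misalignment instead
#' of resampling twice.
#'
#' @param n_pairs Number of cases (>= 3).
#' @param spec Base [phantom_spec()]; case i uses seed `spec$seed + i`.
#' @param dir Output directory.
#' @param split Train/validation/test fractions.
#' @param deform Apply the neck deformation to the moving side.
#' @return The manifest (also written to `dir/manifest.json`).
#' @export
make_dataset <- function(n_pairs, spec = phantom_spec(), dir = tempfile("phantoms"),
                         split = c(0.7, 0.1, 0.2), deform = TRUE) {
  if (n_pairs < 3) stop("need at least 3 pairs")
  if (length(split) != 3L || any(split < 0) || abs(sum(split) - 1) > 1e-6)
    stop("split must be 3 non-negative fractions summing to 1")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_train <- max(1L, round(n_pairs * split[1]))
  n_val <- max(if (split[2] > 0) 1L else 0L, round(n_pairs * split[2]))
  n_test <- n_pairs - n_train - n_val
  if (n_test < 1L && split[3] > 0) { n_test <- 1L; n_train <- n_train - 1L }
  splits <- rep(c("train", "val", "test"), times = c(n_train, n_val, n_test))
  cases <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    cspec <- spec
    cspec$seed <- spec$seed + i
    ph <- make_phantom(cspec)
    cb <- simulate_cbct(ph$ct, cspec)
    moving <- list(vol = cb, seg = ph$seg, lms = ph$lms)
    deformed <- deform && cspec$deform_magnitude_mm > 0
    if (deformed) moving <- apply_neck_deformation(cb, ph$seg, ph$lms, cspec)
    set.seed(cspec$seed + 65537L)
    mis <- sample_misalignment(cspec$rot_range_deg, cspec$trans_range_vox, cspec$spacing)
    center <- volume_center(ph$ct)
    A <- params_to_matrix(mis, center)
    fld <- matrix_to_field(A, dim(ph$ct$voxels), cspec$spacing, ph$ct$origin)
    mov_vol <- warp_volume(moving$vol, fld)
    mov_seg <- warp_segmentation(moving$seg, fld)
    mov_lms <- transform_landmarks(moving$lms, A)
    cdir <- file.path(dir, sprintf("case_%03d", i))
    dir.create(cdir, showWarnings = FALSE)
    write_volume(ph$ct, file.path(cdir, "fixed.nii.gz"))
    write_volume(ph$seg, file.path(cdir, "fixed_seg.nii.gz"))
    write_landmarks(ph$lms, file.path(cdir, "fixed_lms.csv"))
    write_volume(mov_vol, file.path(cdir, "moving.nii.gz"))
    write_volume(mov_seg, file.path(cdir, "moving_seg.nii.gz"))
    write_landmarks(mov_lms, file.path(cdir, "moving_lms.csv"))
    write_volume(moving$vol, file.path(cdir, "moving_base.nii.gz"))
    write_volume(moving$seg, file.path(cdir, "moving_base_seg.nii.gz"))
    write_landmarks(moving$lms, file.path(cdir, "moving_base_lms.csv"))
    cases[[i]] <- list(case_id = sprintf("case_%03d", i), split = splits[i],
                       dir = sprintf("case_%03d", i),
                       true_params = list(t = mis$t, r = mis$r),
                       center = center, deformed = deformed)
  }
  manifest <- list(n_pairs = n_pairs, shape = spec$shape, spacing = spec$spacing,
                   seed = spec$seed, boundary_fraction = spec$boundary_fraction,
                   deform_magnitude_mm = if (deform) spec$deform_magnitude_mm else 0,
                   structures = phantom_structures, cases = cases)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$dir <- dir
  invisible(manifest)
}

#' Read a dataset manifest
#' @param dir Dataset directory containing `manifest.json`.
#' @return Manifest list with `$dir` set.
#' @export
read_manifest <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  m$dir <- dir
  m
}

load_case <- function(manifest, case, base = FALSE) {
  cdir <- file.path(manifest$dir, case$dir)
  pre <- if (base) "moving_base" else "moving"
  list(fixed = read_volume(file.path(cdir, "fixed.nii.gz")),
       fixed_seg = read_segmentation(file.path(cdir, "fixed_seg.nii.gz"),
                                     manifest$structures),
       fixed_lms = read_landmarks(file.path(cdir, "fixed_lms.csv")),
       moving = read_volume(file.path(cdir, paste0(pre, ".nii.gz"))),
       moving_seg = read_segmentation(file.path(cdir, paste0(pre, "_seg.nii.gz")),
                                      manifest$structures),
       moving_lms = read_landmarks(file.path(cdir, paste0(pre, "_lms.csv"))))
}
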