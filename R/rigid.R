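# Rigid parameterization, 4x4 matrices, deformation fields and resampling.
#
# Conventions (fixed and documented; the warp/landmark math depends on them):
#  * rotations are intrinsic x, then y, then z (rotation part = Rz %*% Ry %*% Rx),
#    right-handed, in degrees at the interface, about `center` (default: the
#    volume's physical centre);
#  * all transforms act in physical mm space, so anisotropic spacing is safe;
#  * resampling is pull-back: output voxel at physical x samples the moving
#    image at A %*% x, so content moves by A^-1 and landmarks are mapped by
#    A^-1 to track the warped anatomy.

#' Rigid parameters
#'
#' Six-parameter rigid motion: translation in mm and rotation in degrees about
#' the x, y, z axes.
#'
#' @param t Length-3 translation (mm).
#' @param r Length-3 rotation (degrees).
#' @return An object of class `swr_rigid_params`.
#' @export
rigid_params <- function(t = c(0, 0, 0), r = c(0, 0, 0)) {
  t <- as.numeric(t); r <- as.numeric(r)
  if (length(t) != 3L || length(r) != 3L || any(!is.finite(c(t, r))))
    stop("rigid parameters must be two finite length-3 vectors")
  structure(list(t = t, r = r), class = "swr_rigid_params")
}

#' @export
print.swr_rigid_params <- function(x, ...) {
  cat("<swr_rigid_params> t = (", paste(format(x$t, digits = 4), collapse = ", "),
      ") mm, r = (", paste(format(x$r, digits = 4), collapse = ", "), ") deg\n", sep = "")
  invisible(x)
}

rot_x <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
rot_y <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
rot_z <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))

hom <- function(R3, t3 = c(0, 0, 0)) {
  m <- diag(4)
  m[1:3, 1:3] <- R3
  m[1:3, 4] <- t3
  m
}

#' Build the 4x4 rigid matrix A = T . C . Rz . Ry . Rx . C^-1
#'
#' @param p A `swr_rigid_params`.
#' @param center Physical rotation centre (mm).
#' @return 4x4 numeric matrix (homogeneous, physical mm space).
#' @export
params_to_matrix <- function(p, center = c(0, 0, 0)) {
  rad <- p$r * pi / 180
  R <- rot_z(rad[3]) %*% rot_y(rad[2]) %*% rot_x(rad[1])
  Tm <- hom(diag(3), p$t)
  Cm <- hom(diag(3), center)
  Ci <- hom(diag(3), -center)
  Tm %*% Cm %*% hom(R) %*% Ci
}

# d A / d p_i for p = (tx,ty,tz,rx,ry,rz); rotations in degrees.
rigid_matrix_jacobian <- function(p, center = c(0, 0, 0)) {
  rad <- p$r * pi / 180
  k <- pi / 180
  dx <- rbind(c(0, 0, 0), c(0, -sin(rad[1]), -cos(rad[1])), c(0, cos(rad[1]), -sin(rad[1])))
  dy <- rbind(c(-sin(rad[2]), 0, cos(rad[2])), c(0, 0, 0), c(-cos(rad[2]), 0, -sin(rad[2])))
  dz <- rbind(c(-sin(rad[3]), -cos(rad[3]), 0), c(cos(rad[3]), -sin(rad[3]), 0), c(0, 0, 0))
  Rx <- rot_x(rad[1]); Ry <- rot_y(rad[2]); Rz <- rot_z(rad[3])
  Tm <- hom(diag(3), p$t); Cm <- hom(diag(3), center); Ci <- hom(diag(3), -center)
  jac <- vector("list", 6L)
  for (i in 1:3) {
    d <- matrix(0, 4, 4)
    d[i, 4] <- 1
    jac[[i]] <- d
  }
  # derivative blocks enter with a zero (not 1) homogeneous corner
  hom0 <- function(R3) { m <- matrix(0, 4, 4); m[1:3, 1:3] <- R3; m }
  jac[[4]] <- Tm %*% Cm %*% hom0(Rz %*% Ry %*% dx) %*% Ci * k
  jac[[5]] <- Tm %*% Cm %*% hom0(Rz %*% dy %*% Rx) %*% Ci * k
  jac[[6]] <- Tm %*% Cm %*% hom0(dz %*% Ry %*% Rx) %*% Ci * k
  jac
}

is_rigid_matrix <- function(A, tol = 1e-9) {
  R <- A[1:3, 1:3]
  all(abs(A[4, ] - c(0, 0, 0, 1)) < tol) &&
    max(abs(crossprod(R) - diag(3))) < tol &&
    abs(det(R) - 1) < tol
}

#' Invert a rigid matrix
#'
#' Uses the transpose of the rotation block; rejects non-rigid inputs.
#' @param A 4x4 rigid matrix.
#' @return 4x4 rigid matrix with `A %*% invert_matrix(A) = I` to 1e-10.
#' @export
invert_matrix <- function(A, tol = 1e-6) {
  if (!is_rigid_matrix(A, tol)) stop("matrix is not rigid (orthonormal rotation, det +1)")
  R <- A[1:3, 1:3]
  hom(t(R), -t(R) %*% A[1:3, 4])
}

#' Deformation field realizing a rigid matrix
#'
#' For each voxel of the target geometry with physical coordinate x, the field
#' holds the physical coordinate A x at which the moving image is sampled.
#'
#' @param A 4x4 matrix.
#' @param shape,spacing,origin Target grid geometry.
#' @return List with `coords_mm` (n x 3), plus the geometry; class
#'   `swr_field`.
#' @export
matrix_to_field <- function(A, shape, spacing, origin) {
  phys <- grid_phys_coords(shape, spacing, origin)
  mm <- tcrossprod(phys, A[1:3, 1:3])
  mm <- sweep(mm, 2L, A[1:3, 4], "+")
  structure(list(coords_mm = mm, shape = as.integer(shape),
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "swr_field")
}

field_identity <- function(shape, spacing, origin)
  matrix_to_field(diag(4), shape, spacing, origin)

#' Warp a volume through a deformation field
#'
#' Trilinear interpolation at the field's sample coordinates; positions outside
#' the moving image return `fill` (default: its minimum intensity).
#'
#' @param vol Moving `swr_volume`.
#' @param field A `swr_field` on the output geometry.
#' @param fill Background fill value.
#' @return Warped `swr_volume` on the field's geometry.
#' @export
warp_volume <- function(vol, field, fill = NULL) {
  if (is.null(fill)) fill <- min(vol$voxels)
  sh <- dim(vol$voxels)
  vox <- sweep(sweep(field$coords_mm, 2L, vol$origin, "-"), 2L, vol$spacing, "/")
  x4 <- vol$voxels; dim(x4) <- c(sh, 1L)
  vals <- cpp_sample_trilinear(x4, as.integer(c(sh, 1L)), vox, fill)
  volume(array(vals, dim = field$shape), field$spacing, field$origin)
}

#' @rdname warp_volume
#' @param seg Moving `swr_segmentation` (nearest-neighbour sampling).
#' @export
warp_segmentation <- function(seg, field) {
  sh <- dim(seg$labels)
  vox <- sweep(sweep(field$coords_mm, 2L, seg$origin, "-"), 2L, seg$spacing, "/")
  vals <- cpp_sample_nearest(seg$labels, as.integer(c(sh, 1L)), vox, 0)
  segmentation(array(as.integer(round(vals)), dim = field$shape),
               seg$structure_names, field$spacing, field$origin)
}

#' Transform landmarks consistently with a warped image
#'
#' Pull-back resampling with matrix A moves image content by A^-1, so landmark
#' coordinates are mapped by A^-1 to keep tracking the anatomy of the warped
#' moving image. Region tags are preserved.
#'
#' @param lms A `swr_landmarks`.
#' @param A The 4x4 rigid matrix used to warp the image.
#' @return Transformed `swr_landmarks`.
#' @export
transform_landmarks <- function(lms, A) {
  Ai <- invert_matrix(A)
  xyz <- lm_xyz(lms)
  new <- sweep(tcrossprod(xyz, Ai[1:3, 1:3]), 2L, Ai[1:3, 4], "+")
  landmarks(lms$name, lms$region, new)
}

#' Physical centre of a volume (default rotation centre)
#' @param vol A `swr_volume` or `swr_segmentation`.
#' @return Length-3 mm coordinate.
#' @export
volume_center <- function(vol) {
  sh <- if (!is.null(vol$voxels)) dim(vol$voxels) else dim(vol$labels)
  vol$origin + (sh - 1) / 2 * vol$spacing
}

# ---- JSON (de)serialization ------------------------------------------------

#' Serialize rigid parameters to/from JSON
#' @param p A `swr_rigid_params`.
#' @param center Rotation centre recorded alongside.
#' @param path File path.
#' @export
write_rigid_params <- function(p, path, center = c(0, 0, 0)) {
  jsonlite::write_json(list(tx = p$t[1], ty = p$t[2], tz = p$t[3],
                            rx = p$r[1], ry = p$r[2], rz = p$r[3],
                            center = center),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rigid_params
#' @export
read_rigid_params <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(params = rigid_params(c(j$tx, j$ty, j$tz), c(j$rx, j$ry, j$rz)),
       center = as.numeric(j$center))
}

# ---- differentiable rigid warp (autodiff op) -------------------------------

# Warp a constant multi-channel moving array through the rigid matrix built
# from a 6-vector parameter tensor (tx,ty,tz in mm, rx,ry,rz in deg). The
# backward pass chains the trilinear coordinate gradient through dA/dp.
# moving: (nx,ny,nz,c) array; geometry shared by input and output.
tg_rigid_warp <- function(params6, moving, spacing, origin, center, fill = 0) {
  pv <- as.numeric(tg_v(params6))
  p <- rigid_params(pv[1:3], pv[4:6])
  A <- params_to_matrix(p, center)
  sh <- dim(moving)[1:3]
  phys <- grid_phys_coords(sh, spacing, origin)
  mm <- sweep(tcrossprod(phys, A[1:3, 1:3]), 2L, A[1:3, 4], "+")
  vox <- sweep(sweep(mm, 2L, origin, "-"), 2L, spacing, "/")
  xd <- as.integer(dim(moving))
  y <- cpp_sample_trilinear(moving, xd, vox, fill)
  yarr <- array(y, dim = dim(moving))
  tg_op(yarr, list(params6), function(g) {
    gm <- g
    dim(gm) <- c(prod(sh), xd[4])
    gcoord_vox <- cpp_sample_trilinear_grad(moving, xd, vox, gm)   # d/d voxel coord
    gcoord_mm <- sweep(gcoord_vox, 2L, spacing, "/")               # d/d mm coord
    jac <- rigid_matrix_jacobian(p, center)
    homg <- cbind(phys, 1)
    gp <- vapply(jac, function(dA) {
      sum(gcoord_mm * tcrossprod(homg, dA[1:3, ]))
    }, numeric(1))
    tg_acc(params6, gp)
  })
}
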