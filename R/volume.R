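# Volume / segmentation / landmark data model, NIfTI and CSV I/O, and
# preprocessing (resampling, crop-or-pad, intensity normalization).
#
# Geometry convention: voxel indices are 0-based and axis-aligned;
# physical coordinate (mm) = origin + index * spacing. No direction matrix.

#' Construct a 3D volume
#'
#' A volume is a 3D scalar grid (CT or CBCT intensities, arbitrary units) with
#' per-axis voxel spacing in mm and a physical-space origin in mm. Physical
#' coordinates follow \code{origin + 0-based index * spacing}.
#'
#' @param voxels 3D numeric array.
#' @param spacing Positive length-3 numeric, mm per voxel.
#' @param origin Length-3 numeric, mm position of voxel (0,0,0).
#' @return An object of class `swr_volume`.
#' @export
volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L) stop("expected 3 spatial axes, got ", length(dim(voxels)))
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values")
  if (any(!is.finite(voxels))) stop("volume contains non-finite voxel values")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "swr_volume")
}

#' @export
print.swr_volume <- function(x, ...) {
  cat("<swr_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels @ (", paste(format(x$spacing), collapse = ", "), ") mm",
      ", origin (", paste(format(x$origin), collapse = ", "), ") mm\n", sep = "")
  cat("  intensity range [", format(min(x$voxels)), ", ", format(max(x$voxels)), "]\n", sep = "")
  invisible(x)
}

#' Construct a segmentation map
#'
#' Integer label grid on the same geometry as a companion volume. Label 0 is
#' background; labels 1..K index `structure_names`.
#'
#' @param labels 3D integer-valued array.
#' @param structure_names Character vector of K structure names.
#' @inheritParams volume
#' @return An object of class `swr_segmentation`.
#' @export
segmentation <- function(labels, structure_names, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(labels)) != 3L) stop("expected 3 spatial axes, got ", length(dim(labels)))
  K <- length(structure_names)
  if (K < 1L) stop("need at least one structure name")
  u <- unique(as.vector(labels))
  if (any(u != round(u)) || any(u < 0) || any(u > K))
    stop("labels must be integers in 0..", K)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  structure(list(labels = labels, structure_names = as.character(structure_names),
                 spacing = spacing, origin = origin),
            class = "swr_segmentation")
}

#' @export
print.swr_segmentation <- function(x, ...) {
  cat("<swr_segmentation> ", paste(dim(x$labels), collapse = " x "),
      " voxels, ", length(x$structure_names), " structures: ",
      paste(x$structure_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Construct a landmark set
#'
#' Named physical-space points, each tagged as belonging to the head or neck
#' region, used for region-stratified target registration error.
#'
#' @param name Character vector.
#' @param region Character vector, each "head" or "neck".
#' @param xyz_mm Numeric matrix (n x 3) of physical coordinates in mm.
#' @return An object of class `swr_landmarks` (a data.frame).
#' @export
landmarks <- function(name, region, xyz_mm) {
  xyz_mm <- matrix(as.numeric(xyz_mm), ncol = 3L)
  if (!all(region %in% c("head", "neck"))) stop("region must be 'head' or 'neck'")
  if (any(!is.finite(xyz_mm))) stop("landmark coordinates must be finite")
  df <- data.frame(name = as.character(name), region = as.character(region),
                   x_mm = xyz_mm[, 1], y_mm = xyz_mm[, 2], z_mm = xyz_mm[, 3],
                   stringsAsFactors = FALSE)
  class(df) <- c("swr_landmarks", "data.frame")
  df
}

lm_xyz <- function(lms) as.matrix(lms[, c("x_mm", "y_mm", "z_mm")])

same_geometry <- function(a, b, tol = 1e-6) {
  ga <- if (!is.null(a$voxels)) dim(a$voxels) else dim(a$labels)
  gb <- if (!is.null(b$voxels)) dim(b$voxels) else dim(b$labels)
  all(ga == gb) && all(abs(a$spacing - b$spacing) < tol) && all(abs(a$origin - b$origin) < tol)
}

# Physical coordinates (mm) of every voxel, n x 3, column-major voxel order.
grid_phys_coords <- function(shape, spacing, origin) {
  ix <- (seq_len(shape[1]) - 1) * spacing[1] + origin[1]
  iy <- (seq_len(shape[2]) - 1) * spacing[2] + origin[2]
  iz <- (seq_len(shape[3]) - 1) * spacing[3] + origin[3]
  cbind(rep(ix, times = shape[2] * shape[3]),
        rep(rep(iy, each = shape[1]), times = shape[3]),
        rep(iz, each = shape[1] * shape[2]))
}

# ---- NIfTI I/O -------------------------------------------------------------

make_xform <- function(spacing, origin) {
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  structure(m, code = 2L)
}

#' Write a volume or segmentation to NIfTI
#'
#' Voxels are stored as float64 so that write/read round-trips are bit-exact.
#'
#' @param vol A `swr_volume` or `swr_segmentation`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  arr <- if (inherits(vol, "swr_segmentation")) vol$labels else vol$voxels
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, vol$spacing)
  img <- RNifti::`qform<-`(img, make_xform(vol$spacing, vol$origin))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a 3D NIfTI volume
#'
#' @param path NIfTI file path.
#' @param with_segmentation If `TRUE`, also read the companion segmentation
#'   stored next to the image with a `_seg` suffix.
#' @param structure_names Structure names for the companion segmentation.
#' @return A `swr_volume`, or `list(volume=, segmentation=)` when
#'   `with_segmentation` is `TRUE`.
#' @export
read_volume <- function(path, with_segmentation = FALSE, structure_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected 3 spatial axes, got ", length(dim(arr)))
  arr <- array(as.numeric(arr), dim = dim(arr))   # plain array, no header attrs
  if (any(!is.finite(arr))) stop("volume contains non-finite voxel values")
  xf <- RNifti::xform(img)
  spacing <- abs(c(xf[1, 1], xf[2, 2], xf[3, 3]))
  origin <- xf[1:3, 4]
  vol <- volume(arr, spacing = spacing, origin = origin)
  if (!with_segmentation) return(vol)
  seg_path <- sub("\\.nii(\\.gz)?$", "_seg.nii\\1", path)
  list(volume = vol, segmentation = read_segmentation(seg_path, structure_names))
}

#' @rdname read_volume
#' @export
read_segmentation <- function(path, structure_names) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected 3 spatial axes, got ", length(dim(arr)))
  arr <- array(as.integer(round(arr)), dim = dim(arr))
  xf <- RNifti::xform(img)
  if (is.null(structure_names))
    structure_names <- paste0("structure_", seq_len(max(1, max(arr))))
  segmentation(arr, structure_names,
               spacing = abs(c(xf[1, 1], xf[2, 2], xf[3, 3])), origin = xf[1:3, 4])
}

#' Read and write landmark CSV files
#'
#' CSV columns: `name,region,x_mm,y_mm,z_mm` with region in head/neck.
#' @param path CSV path.
#' @return A `swr_landmarks`.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "region", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df))) stop("landmark CSV must have columns ", paste(need, collapse = ","))
  landmarks(df$name, df$region, as.matrix(df[, c("x_mm", "y_mm", "z_mm")]))
}

#' @rdname read_landmarks
#' @param lms A `swr_landmarks`.
#' @export
write_landmarks <- function(lms, path) {
  utils::write.csv(as.data.frame(unclass(lms)), path, row.names = FALSE)
  invisible(path)
}

# ---- preprocessing ---------------------------------------------------------

#' Resample a volume to a new voxel spacing
#'
#' Trilinear interpolation on the physical grid; the physical extent is
#' preserved to within one voxel per axis and the origin is unchanged.
#' Segmentations are resampled nearest-neighbour so the label set is preserved.
#'
#' @param vol A `swr_volume`.
#' @param target_spacing Positive length-3 numeric (mm).
#' @return Resampled `swr_volume`.
#' @export
resample_volume <- function(vol, target_spacing) {
  target_spacing <- as.numeric(rep(target_spacing, length.out = 3))
  if (any(target_spacing <= 0)) stop("target spacing must be positive")
  sh <- dim(vol$voxels)
  if (all(abs(target_spacing - vol$spacing) < 1e-12)) return(vol)
  new_sh <- pmax(1L, as.integer(floor((sh - 1) * vol$spacing / target_spacing + 1e-9)) + 1L)
  phys <- grid_phys_coords(new_sh, target_spacing, vol$origin)
  vox <- sweep(sweep(phys, 2L, vol$origin, "-"), 2L, vol$spacing, "/")
  x4 <- vol$voxels; dim(x4) <- c(sh, 1L)
  vals <- cpp_sample_trilinear(x4, as.integer(c(sh, 1L)), vox, min(vol$voxels))
  volume(array(vals, dim = new_sh), spacing = target_spacing, origin = vol$origin)
}

#' @rdname resample_volume
#' @param seg A `swr_segmentation`.
#' @export
resample_segmentation <- function(seg, target_spacing) {
  target_spacing <- as.numeric(rep(target_spacing, length.out = 3))
  if (any(target_spacing <= 0)) stop("target spacing must be positive")
  sh <- dim(seg$labels)
  if (all(abs(target_spacing - seg$spacing) < 1e-12)) return(seg)
  new_sh <- pmax(1L, as.integer(floor((sh - 1) * seg$spacing / target_spacing + 1e-9)) + 1L)
  phys <- grid_phys_coords(new_sh, target_spacing, seg$origin)
  vox <- sweep(sweep(phys, 2L, seg$origin, "-"), 2L, seg$spacing, "/")
  vals <- cpp_sample_nearest(seg$labels, as.integer(c(sh, 1L)), vox, 0)
  segmentation(array(as.integer(round(vals)), dim = new_sh), seg$structure_names,
               spacing = target_spacing, origin = seg$origin)
}

#' Crop or pad a volume to a target voxel shape
#'
#' Regions outside the input are filled with `fill` (default: the minimum
#' observed intensity, i.e. air for CT-like volumes). The origin is updated so
#' retained voxels keep their physical coordinates.
#'
#' @param vol A `swr_volume` or `swr_segmentation`.
#' @param target_shape Positive integer length-3.
#' @param center Voxel-index triple (0-based) around which to crop, or
#'   `"auto"` for the volume centre.
#' @param fill Background fill value; segmentations always fill with 0.
#' @return Cropped/padded object of the same class.
#' @export
crop_or_pad <- function(vol, target_shape, center = "auto", fill = NULL) {
  target_shape <- as.integer(rep(target_shape, length.out = 3))
  if (any(target_shape < 1L)) stop("target shape must be positive")
  is_seg <- inherits(vol, "swr_segmentation")
  arr <- if (is_seg) vol$labels else vol$voxels
  sh <- dim(arr)
  if (identical(center, "auto")) center <- (sh - 1) / 2
  center <- as.numeric(center)
  if (is.null(fill)) fill <- if (is_seg) 0 else min(arr)
  start <- as.integer(round(center - (target_shape - 1) / 2))   # 0-based src start
  out <- array(fill, dim = target_shape)
  src_lo <- pmax(start, 0L)
  src_hi <- pmin(start + target_shape - 1L, sh - 1L)
  if (all(src_lo <= src_hi)) {
    dst_lo <- src_lo - start
    out[(dst_lo[1] + 1):(dst_lo[1] + 1 + src_hi[1] - src_lo[1]),
        (dst_lo[2] + 1):(dst_lo[2] + 1 + src_hi[2] - src_lo[2]),
        (dst_lo[3] + 1):(dst_lo[3] + 1 + src_hi[3] - src_lo[3])] <-
      arr[(src_lo[1] + 1):(src_hi[1] + 1),
          (src_lo[2] + 1):(src_hi[2] + 1),
          (src_lo[3] + 1):(src_hi[3] + 1)]
  }
  new_origin <- vol$origin + start * vol$spacing
  if (is_seg) segmentation(out, vol$structure_names, vol$spacing, new_origin)
  else volume(out, vol$spacing, new_origin)
}

#' Normalize volume intensities to [0, 1]
#'
#' @param vol A `swr_volume`.
#' @param method `"minmax"` maps the observed range to \\[0,1\\]; `"window"`
#'   clips to `window` then rescales.
#' @param window Length-2 numeric `(lo, hi)` for the window method.
#' @return Normalized `swr_volume`.
#' @export
normalize_intensity <- function(vol, method = c("minmax", "window"), window = c(-1000, 1000)) {
  method <- match.arg(method)
  x <- vol$voxels
  if (method == "minmax") {
    rng <- range(x)
    if (diff(rng) == 0) {
      warning("constant volume under minmax normalization; returning zeros")
      return(volume(array(0, dim(x)), vol$spacing, vol$origin))
    }
    y <- (x - rng[1]) / diff(rng)
  } else {
    if (length(window) != 2L || window[2] <= window[1]) stop("window must be (lo, hi) with hi > lo")
    y <- pmin(pmax(x, window[1]), window[2])
    y <- (y - window[1]) / diff(window)
  }
  volume(y, vol$spacing, vol$origin)
}
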