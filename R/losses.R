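# Training objective: perceptual similarity loss on DAE encoder pyramids,
# soft Dice on warped one-hot segmentations, squared latent distance under the
# anatomical constraint encoder, and their weighted sum
#   L = L_perceptual + lambda_ae * L_ae + lambda_dice * L_dice
# with defaults lambda_dice = 1, lambda_ae = 0.1 and pyramid weights
# (1, 0.5, 0.5). SSIM / NCC / MI dissimilarities are drop-in alternatives to
# the perceptual term for ablations.

#' Loss weights
#'
#' @param omega Per-level weights of the perceptual pyramid.
#' @param lambda_dice Weight of the Dice constraint term.
#' @param lambda_ae Weight of the encoded-segmentation constraint term.
#' @return A `swr_loss_weights` list.
#' @export
loss_weights <- function(omega = c(1, 0.5, 0.5), lambda_dice = 1, lambda_ae = 0.1) {
  if (any(c(omega, lambda_dice, lambda_ae) < 0)) stop("loss weights must be non-negative")
  structure(list(omega = as.numeric(omega), lambda_dice = lambda_dice,
                 lambda_ae = lambda_ae), class = "swr_loss_weights")
}

#' Perceptual similarity loss
#'
#' Weighted sum over pyramid levels of the mean absolute difference between
#' the frozen DAE-encoder features of the fixed and the warped moving image.
#' The L1 norm is reduced as a mean over voxels and channels per level, which
#' keeps the weights independent of volume size.
#'
#' @param metric_dae Image-trained `swr_dae`.
#' @param fixed 3D array (normalized intensities).
#' @param moved 3D array or tensor (warped moving image).
#' @param w A [loss_weights()].
#' @return Scalar tensor (or numeric if inputs are plain arrays).
#' @export
perceptual_loss <- function(metric_dae, fixed, moved, w = loss_weights(),
                            fixed_pyramid = NULL) {
  n <- length(w$omega)
  pf <- if (is.null(fixed_pyramid)) multiscale_features(metric_dae, fixed, n_levels = n)
        else fixed_pyramid
  pm <- multiscale_features(metric_dae, moved, n_levels = n)
  total <- NULL
  for (i in seq_len(n)) {
    li <- tg_mean(tg_abs(tg_sub(pm[[i]], tg_v(pf[[i]]))))
    li <- tg_scale(li, w$omega[i])
    total <- if (is.null(total)) li else tg_add(total, li)
  }
  total
}

#' Soft Dice loss over selected structures
#'
#' (1/K) sum_k (1 - 2|A_k ^ B_k| / (|A_k| + |B_k|)) with an epsilon guard for
#' empty structures. Operates on one-hot (possibly soft, trilinear-warped)
#' channel arrays so it stays differentiable.
#'
#' @param fixed_onehot (nx,ny,nz,K) array.
#' @param moved_onehot (nx,ny,nz,K) array or tensor.
#' @param structures Integer indices of the structures entering the mean
#'   (default: all channels).
#' @param eps Smoothing constant.
#' @return Scalar tensor/numeric in [0, 1].
#' @export
dice_loss <- function(fixed_onehot, moved_onehot, structures = NULL, eps = 1e-5) {
  fv <- tg_v(fixed_onehot)
  K <- dim(fv)[4]
  if (is.null(structures)) structures <- seq_len(K)
  if (length(structures) == 0L) stop("empty structure selection")
  nvox <- prod(dim(fv)[1:3])
  fmat <- fv; dim(fmat) <- c(nvox, K)
  mmat <- if (is_tensor(moved_onehot)) tg_reshape(moved_onehot, c(nvox, K)) else {
    m <- moved_onehot; dim(m) <- c(nvox, K); m
  }
  total <- NULL
  for (k in structures) {
    mk <- tg_cols(mmat, k)
    fk <- fmat[, k, drop = FALSE]
    inter <- tg_sum(tg_mul(mk, fk))
    denom <- tg_add(tg_sum(mk), sum(fk))
    dk <- tg_sub(1, tg_div(tg_add(tg_scale(inter, 2), eps), tg_add(denom, eps)))
    total <- if (is.null(total)) dk else tg_add(total, dk)
  }
  out <- tg_scale(total, 1 / length(structures))
  if (is_tensor(moved_onehot)) out else tg_v(out)
}

#' Encoded-segmentation (global anatomy) loss
#'
#' Squared Euclidean distance between the anatomical-constraint-encoder latent
#' codes of the fixed and warped moving segmentations.
#'
#' @param ace_dae Segmentation-trained `swr_dae`.
#' @param fixed_onehot,moved_onehot (nx,ny,nz,K) arrays (moved may be a tensor).
#' @return Scalar tensor/numeric, >= 0, symmetric in its arguments.
#' @export
ae_loss <- function(ace_dae, fixed_onehot, moved_onehot, fixed_code = NULL) {
  cf <- if (is.null(fixed_code)) ace_encode(ace_dae, tg_v(fixed_onehot)) else fixed_code
  cm <- ace_encode(ace_dae, if (is_tensor(moved_onehot)) moved_onehot else tg_v(moved_onehot))
  if (is_tensor(cm)) {
    d <- tg_sub(cm, cf)
    tg_sum(tg_mul(d, d))
  } else sum((cm - cf)^2)
}

#' Combined registration loss
#'
#' `L = similarity + lambda_ae * L_ae + lambda_dice * L_dice`. Segmentation
#' terms are skipped when the one-hot masks are `NULL` (training without
#' segmentations) or when their weight is zero.
#'
#' @param metric_dae,ace_dae Pretrained DAEs (ace may be `NULL` if unused).
#' @param fixed,moved Image arrays (moved may be a tensor).
#' @param fixed_onehot,moved_onehot Optional one-hot masks.
#' @param w A [loss_weights()].
#' @param structures Structure indices for the Dice term.
#' @param similarity One of "perceptual", "ssim", "ncc", "mi".
#' @return List: `total` (scalar tensor), `components` (named numeric:
#'   similarity, dice, ae).
#' @export
total_loss <- function(metric_dae, ace_dae, fixed, moved,
                       fixed_onehot = NULL, moved_onehot = NULL,
                       w = loss_weights(), structures = NULL,
                       similarity = c("perceptual", "ssim", "ncc", "mi"),
                       cache = NULL) {
  similarity <- match.arg(similarity)
  sim <- if (similarity == "perceptual")
    perceptual_loss(metric_dae, fixed, moved, w, fixed_pyramid = cache$fixed_pyramid)
  else alt_similarity(fixed, moved, kind = similarity)
  total <- sim
  comp <- c(similarity = as.numeric(tg_v(sim)), dice = 0, ae = 0)
  has_seg <- !is.null(fixed_onehot) && !is.null(moved_onehot)
  if (has_seg && w$lambda_dice > 0) {
    ld <- dice_loss(fixed_onehot, moved_onehot, structures)
    comp["dice"] <- as.numeric(tg_v(ld))
    total <- tg_add(total, tg_scale(ld, w$lambda_dice))
  }
  if (has_seg && w$lambda_ae > 0 && !is.null(ace_dae)) {
    la <- ae_loss(ace_dae, fixed_onehot, moved_onehot, fixed_code = cache$fixed_code)
    comp["ae"] <- as.numeric(tg_v(la))
    total <- tg_add(total, tg_scale(la, w$lambda_ae))
  }
  list(total = total, components = comp)
}

# ---- alternative similarity losses (ablation) ------------------------------

gauss_kernel3d <- function(sigma = 1.5, radius = 3L, channels = 1L) {
  ax <- (-radius):radius
  k1 <- exp(-ax^2 / (2 * sigma^2))
  k3 <- outer(outer(k1, k1), k1)
  k3 <- k3 / sum(k3)
  W <- array(0, c(dim(k3), channels, channels))
  for (c in seq_len(channels)) W[, , , c, c] <- k3
  W
}

#' Alternative differentiable dissimilarities: SSIM, NCC, MI
#'
#' Drop-in replacements for the perceptual term: `1 - SSIM` (Gaussian-window
#' structural similarity), `1 - NCC^2` (squared Pearson correlation), and
#' negative mutual information with soft (triangular) histogram binning.
#'
#' @param fixed 3D array.
#' @param moved 3D array or tensor.
#' @param kind One of "ssim", "ncc", "mi".
#' @param bins Soft-histogram bin count for MI.
#' @return Scalar tensor/numeric (lower = more similar).
#' @export
alt_similarity <- function(fixed, moved, kind = c("ssim", "ncc", "mi"), bins = 32L) {
  kind <- match.arg(kind)
  fv <- tg_v(fixed)
  was_tensor <- is_tensor(moved)
  out <- switch(kind,
    ssim = {
      sh <- dim(fv)
      W <- gauss_kernel3d(1.5, 3L)
      b0 <- numeric(1)
      f4 <- fv; dim(f4) <- c(sh, 1L)
      m4 <- if (was_tensor) tg_reshape(moved, c(sh, 1L)) else { m <- tg_v(moved); dim(m) <- c(sh, 1L); m }
      C1 <- 0.01^2; C2 <- 0.03^2
      mu_f <- tg_conv3d(f4, W, b0, 1L, 3L)
      mu_m <- tg_conv3d(m4, W, b0, 1L, 3L)
      f2 <- tg_conv3d(tg_mul(f4, f4), W, b0, 1L, 3L)
      m2 <- tg_conv3d(tg_mul(m4, m4), W, b0, 1L, 3L)
      fm <- tg_conv3d(tg_mul(f4, m4), W, b0, 1L, 3L)
      var_f <- tg_sub(f2, tg_mul(mu_f, mu_f))
      var_m <- tg_sub(m2, tg_mul(mu_m, mu_m))
      cov <- tg_sub(fm, tg_mul(mu_f, mu_m))
      num <- tg_mul(tg_add(tg_scale(tg_mul(mu_f, mu_m), 2), C1),
                    tg_add(tg_scale(cov, 2), C2))
      den <- tg_mul(tg_add(tg_add(tg_mul(mu_f, mu_f), tg_mul(mu_m, mu_m)), C1),
                    tg_add(tg_add(var_f, var_m), C2))
      tg_sub(1, tg_mean(tg_div(num, den)))
    },
    ncc = {
      n <- length(fv)
      fc <- fv - mean(fv)
      mc <- tg_sub(moved, tg_mean(moved))
      num <- tg_sum(tg_mul(mc, fc))
      den <- tg_sqrt(tg_scale(tg_sum(tg_mul(mc, mc)), sum(fc^2) + 1e-12))
      r <- tg_div(num, tg_add(den, 1e-12))
      tg_sub(1, tg_mul(r, r))
    },
    mi = {
      # triangular soft assignment to `bins` bin centres on [0,1]; the kernels
      # form a partition of unity, so the joint histogram sums to 1 exactly
      n <- length(fv)
      h <- 1 / (bins - 1)
      centers <- seq(0, 1, length.out = bins)
      rng <- range(fv); fn <- if (diff(rng) > 0) (fv - rng[1]) / diff(rng) else fv * 0
      A <- pmax(1 - abs(outer(as.numeric(fn), centers, "-")) / h, 0)
      mv <- tg_v(moved)
      rngm <- range(mv)
      mnorm <- if (diff(rngm) > 0) tg_scale(tg_sub(moved, rngm[1]), 1 / diff(rngm)) else tg_scale(moved, 0)
      mflat <- tg_reshape(mnorm, c(n, 1L))
      Bcols <- vector("list", bins)
      for (j in seq_len(bins)) {
        d <- tg_abs(tg_sub(mflat, centers[j]))
        Bcols[[j]] <- tg_relu(tg_sub(1, tg_scale(d, 1 / h)))
      }
      B <- tg_cbind(Bcols)
      joint <- tg_matmul(B, A / n, ta = TRUE)   # p(moved bin, fixed bin)
      tg_scale(tg_mi_from_joint(joint), -1 / log(2))  # negative MI, in bits
    })
  if (was_tensor) out else as.numeric(tg_v(out))
}
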