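# 3D denoising autoencoder (DAE).
#
# Pretrained twice: on images it yields the perceptual similarity metric
# network (its first encoder layers supply multi-scale features for the
# perceptual loss), and on one-hot segmentation masks it yields the anatomical
# constraint encoder ACE(.), whose latent code distance forms the global
# segmentation loss. The encoder is a chain of stride-2 convolutions down to a
# flat latent vector; the decoder mirrors it with 2x upsampling convolutions
# and additive skip connections, reconstructing the clean input from a
# corrupted one under an MSE objective.

#' DAE configuration
#'
#' @param in_channels 1 for images, K (number of structures) for one-hot
#'   segmentation masks.
#' @param base_channels Channels of the first encoder level; doubled per level.
#' @param depth Number of stride-2 encoder convolutions. 5 at full clinical
#'   scale (240 x 240 x 64 with a 512 latent); 3 at phantom scale.
#' @param latent Length of the latent code (512 at full scale).
#' @param noise_kind `"gaussian"` (additive, images) or `"flip"` (binary
#'   channel flips, segmentations).
#' @param noise_magnitude Noise standard deviation as a fraction of the
#'   intensity range, or flip probability.
#' @return A `swr_dae_config`.
#' @export
dae_config <- function(in_channels = 1L, base_channels = 8L, depth = 3L,
                       latent = 128L, noise_kind = c("gaussian", "flip"),
                       noise_magnitude = 0.1) {
  noise_kind <- match.arg(noise_kind)
  structure(list(in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth), latent = as.integer(latent),
                 noise_kind = noise_kind, noise_magnitude = noise_magnitude),
            class = "swr_dae_config")
}

dae_grids <- function(input_shape, depth) {
  gs <- vector("list", depth)
  g <- as.integer(input_shape)
  for (l in seq_len(depth)) {
    g <- as.integer(ceiling(g / 2))
    gs[[l]] <- g
  }
  gs
}

#' Initialize a DAE
#'
#' @param cfg A [dae_config()].
#' @param input_shape Spatial shape the network is built for (the latent
#'   projection is shape-specific).
#' @return A `swr_dae` with parameter tensors.
#' @export
dae_net <- function(cfg, input_shape) {
  input_shape <- as.integer(input_shape)
  d <- cfg$depth
  ch <- cfg$base_channels * 2L^(seq_len(d) - 1L)
  gs <- dae_grids(input_shape, d)
  p <- list()
  cin <- cfg$in_channels
  for (l in seq_len(d)) {
    p[[paste0("enc", l, "_W")]] <- init_w(3, 3, 3, cin, ch[l])
    p[[paste0("enc", l, "_b")]] <- init_b(ch[l])
    cin <- ch[l]
  }
  nflat <- prod(gs[[d]]) * ch[d]
  p$lat_W <- init_w(nflat, cfg$latent)
  p$lat_b <- init_b(cfg$latent)
  p$unlat_W <- init_w(cfg$latent, nflat)
  p$unlat_b <- init_b(nflat)
  for (l in seq(d, 1L)) {
    cout <- if (l > 1L) ch[l - 1L] else ch[1L]
    p[[paste0("dec", l, "_W")]] <- init_w(3, 3, 3, ch[l], cout)
    p[[paste0("dec", l, "_b")]] <- init_b(cout)
  }
  p$out_W <- init_w(3, 3, 3, ch[1L], cfg$in_channels)
  p$out_b <- init_b(cfg$in_channels)
  structure(list(cfg = cfg, input_shape = input_shape, params = p,
                 channels = ch, grids = gs),
            class = "swr_dae")
}

#' @export
print.swr_dae <- function(x, ...) {
  n <- sum(vapply(x$params, function(p) length(p$value), numeric(1)))
  cat("<swr_dae> depth", x$cfg$depth, ", latent", x$cfg$latent,
      ", in_channels", x$cfg$in_channels, ",", format(n, big.mark = ","),
      "parameters, input", paste(x$input_shape, collapse = "x"), "\n")
  invisible(x)
}

# Parameter views: tensors (trainable) or raw arrays (frozen — gradients still
# flow to the *input*, never to the weights).
dae_p <- function(dae, frozen) {
  if (!frozen) return(dae$params)
  lapply(dae$params, function(t) t$value)
}

#' Corrupt a volume for denoising pretraining
#'
#' @param x 3D or 4D array (spatial axes, optional channel axis).
#' @param kind `"gaussian"`: additive Gaussian noise with standard deviation
#'   `magnitude` times the intensity range; `"flip"`: each voxel-channel is
#'   flipped (x -> 1 - x) with probability `magnitude` (binary inputs).
#' @param magnitude Noise level; 0 returns the input unchanged.
#' @param seed Optional integer for a local, restorable RNG state.
#' @return Corrupted array of the same shape.
#' @export
corrupt <- function(x, kind = c("gaussian", "flip"), magnitude = 0.1, seed = NULL) {
  kind <- match.arg(kind)
  if (magnitude == 0) return(x)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (kind == "gaussian") {
    rng <- diff(range(x))
    if (rng == 0) rng <- 1
    x + array(stats::rnorm(length(x), sd = magnitude * rng), dim = dim(x))
  } else {
    flip <- array(stats::runif(length(x)) < magnitude, dim = dim(x))
    x * (1 - flip) + (1 - x) * flip
  }
}

# Encoder pass. x: tensor/array (nx,ny,nz,cin). Returns list(levels=list of
# post-ReLU feature tensors, latent=latent tensor).
dae_encode <- function(dae, x, frozen = TRUE, n_levels = dae$cfg$depth) {
  p <- dae_p(dae, frozen)
  levels <- vector("list", n_levels)
  h <- x
  for (l in seq_len(dae$cfg$depth)) {
    h <- tg_relu(tg_conv3d(h, p[[paste0("enc", l, "_W")]], p[[paste0("enc", l, "_b")]],
                           stride = 2L, pad = 1L))
    if (l <= n_levels) levels[[l]] <- h
  }
  hv <- tg_v(h)
  flat <- tg_reshape(h, c(1L, length(hv)))
  latent <- tg_linear(flat, p$lat_W, p$lat_b)
  list(levels = levels, latent = tg_reshape(latent, dae$cfg$latent))
}

dae_decode <- function(dae, enc, frozen = TRUE) {
  p <- dae_p(dae, frozen)
  d <- dae$cfg$depth
  gs <- dae$grids
  nflat <- prod(gs[[d]]) * dae$channels[d]
  h <- tg_relu(tg_linear(tg_reshape(enc$latent, c(1L, dae$cfg$latent)), p$unlat_W, p$unlat_b))
  h <- tg_reshape(h, c(gs[[d]], dae$channels[d]))
  for (l in seq(d, 1L)) {
    target <- if (l > 1L) gs[[l - 1L]] else dae$input_shape
    h <- tg_upsample2(h)
    h <- tg_crop_spatial(h, target)
    h <- tg_conv3d(h, p[[paste0("dec", l, "_W")]], p[[paste0("dec", l, "_b")]],
                   stride = 1L, pad = 1L)
    if (l > 1L) h <- tg_add(h, enc$levels[[l - 1L]])   # additive skip fusion
    h <- tg_relu(h)
  }
  tg_conv3d(h, p$out_W, p$out_b, stride = 1L, pad = 1L)
}

#' DAE forward pass
#'
#' @param dae A `swr_dae`.
#' @param x Input array (spatial shape matching the network; 3D arrays are
#'   treated as single-channel).
#' @return List with `reconstruction` (array, input shape) and `latent`
#'   (numeric vector of length `cfg$latent`).
#' @export
dae_forward <- function(dae, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (!all(dim(x)[1:3] == dae$input_shape))
    stop("input shape ", paste(dim(x)[1:3], collapse = "x"),
         " does not match network shape ", paste(dae$input_shape, collapse = "x"))
  enc <- dae_encode(dae, x, frozen = TRUE)
  rec <- dae_decode(dae, enc, frozen = TRUE)
  list(reconstruction = tg_v(rec), latent = as.numeric(tg_v(enc$latent)))
}

#' Pretrain a DAE on clean items
#'
#' Minimizes the mean squared error between the reconstruction of a corrupted
#' item and the clean item, with Adam. Deterministic for a fixed RNG state.
#'
#' @param dae A `swr_dae`.
#' @param items List of arrays (shape matching the network).
#' @param epochs,lr Training schedule.
#' @param verbose Print per-epoch losses.
#' @return The trained `swr_dae`, with a `$log` data.frame of epoch losses.
#' @export
train_dae <- function(dae, items, epochs = 30L, lr = 1e-3, verbose = FALSE) {
  if (length(items) < 2L) stop("need at least 2 training items")
  items <- lapply(items, function(x) { if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L); x })
  opt <- adam_init(dae$params, lr = lr)
  nk <- dae$cfg$noise_kind
  nm <- dae$cfg$noise_magnitude
  log <- data.frame(epoch = integer(0), loss = numeric(0))
  for (ep in seq_len(epochs)) {
    tot <- 0
    for (it in sample(length(items))) {
      clean <- items[[it]]
      noisy <- corrupt(clean, nk, nm)
      tg_tape_start()
      enc <- dae_encode(dae, tg_tensor(noisy), frozen = FALSE)
      rec <- dae_decode(dae, enc, frozen = FALSE)
      dlt <- tg_sub(rec, clean)
      loss <- tg_mean(tg_mul(dlt, dlt))
      tg_backward(loss)
      tg_tape_stop()
      adam_step(dae$params, opt)
      tot <- tot + tg_v(loss)
    }
    log <- rbind(log, data.frame(epoch = ep, loss = tot / length(items)))
    if (verbose) message(sprintf("dae epoch %d  mse %.6f", ep, tot / length(items)))
  }
  dae$log <- log
  dae
}

#' Multi-scale encoder features (perceptual metric network)
#'
#' Activations of the first `n_levels` encoder layers with frozen weights;
#' each level halves the spatial resolution.
#'
#' @param dae A trained `swr_dae`.
#' @param x Input array or tensor; gradients flow to the input only.
#' @param n_levels Number of pyramid levels (default 3).
#' @return List of feature tensors (use `tg_v()` for plain arrays).
#' @export
multiscale_features <- function(dae, x, n_levels = 3L) {
  if (n_levels > dae$cfg$depth) stop("n_levels exceeds encoder depth ", dae$cfg$depth)
  xv <- tg_v(x)
  if (length(dim(xv)) == 3L) {
    if (is_tensor(x)) x <- tg_reshape(x, c(dim(xv), 1L)) else dim(x) <- c(dim(xv), 1L)
  }
  p <- dae_p(dae, frozen = TRUE)
  levels <- vector("list", n_levels)
  h <- x
  for (l in seq_len(n_levels)) {
    h <- tg_relu(tg_conv3d(h, p[[paste0("enc", l, "_W")]], p[[paste0("enc", l, "_b")]],
                           stride = 2L, pad = 1L))
    levels[[l]] <- h
  }
  levels
}

#' Encode a segmentation with the anatomical constraint encoder
#'
#' @param dae A `swr_dae` trained on one-hot segmentation masks.
#' @param seg_onehot (nx,ny,nz,K) one-hot array or tensor, or a
#'   `swr_segmentation` (converted internally).
#' @return Latent code: numeric vector, or tensor when the input is a tensor.
#' @export
ace_encode <- function(dae, seg_onehot) {
  if (inherits(seg_onehot, "swr_segmentation"))
    seg_onehot <- seg_onehot_array(seg_onehot)
  xv <- tg_v(seg_onehot)
  if (dim(xv)[4] != dae$cfg$in_channels)
    stop("segmentation has ", dim(xv)[4], " channels; encoder expects ", dae$cfg$in_channels)
  enc <- dae_encode(dae, seg_onehot, frozen = TRUE, n_levels = 0L)
  if (is_tensor(seg_onehot)) enc$latent else as.numeric(tg_v(enc$latent))
}

#' One-hot channel expansion of a segmentation
#'
#' @param seg A `swr_segmentation`.
#' @return (nx,ny,nz,K) numeric 0/1 array.
#' @export
seg_onehot_array <- function(seg) {
  K <- length(seg$structure_names)
  sh <- dim(seg$labels)
  out <- array(0, c(sh, K))
  for (k in seq_len(K)) out[, , , k] <- (seg$labels == k) * 1
  out
}
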