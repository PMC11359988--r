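# Swin-Transformer rigid registration network G(F, M) = [t, r].
#
# Architecture: a 2-channel 3D patch embedding (kernel 7, stride 4), four
# stages (convolution + one Swin block each; stages 2-4 downsample by 2 and
# double the channels, stage 1 keeps resolution), then a final LayerNorm and
# two fully connected layers regressing the six rigid parameters from the
# flattened final-stage features.
# Each Swin block is the canonical pair of sub-blocks
#   z' = W-MSA(LN(z)) + z ;  z = MLP(LN(z')) + z'
# followed by the same with shifted-window attention (SW-MSA). Attention is
# softmax(Q K^T / sqrt(d)) V per head, windowed.

#' Swin network configuration
#'
#' @param embed_dim Base channel count C after patch embedding.
#' @param window Attention window (voxels per axis of the token grid); shrunk
#'   per stage to the grid size when the grid is smaller.
#' @param heads Attention heads per stage (must divide the stage channels).
#' @param mlp_ratio Hidden width of the MLP relative to the channels.
#' @param ln_eps LayerNorm epsilon.
#' @param head_hidden Width of the first fully connected regression layer.
#' @param input_shape Volume shape the network is built for; the regression
#'   head flattens the final-stage feature grid (keeping the spatial
#'   arrangement that encodes rotation), so its weight shape depends on it.
#' @param scale_t,scale_r Output scaling: raw head outputs are multiplied by
#'   these to give mm and degrees. `scale_t` may be per-axis (length 3);
#'   matching it to the expected motion range per axis (anisotropic spacing
#'   makes z translations span more mm) keeps the raw outputs of order one.
#' @return A `swr_swin_config` list.
#' @export
swin_config <- function(embed_dim = 48L, window = c(5L, 5L, 4L),
                        heads = c(3L, 6L, 12L, 24L), mlp_ratio = 4,
                        ln_eps = 1e-5, head_hidden = 64L,
                        input_shape = c(64L, 64L, 32L),
                        scale_t = 10, scale_r = 10) {
  ch <- embed_dim * c(1L, 2L, 4L, 8L)
  if (any(ch %% heads != 0L)) stop("heads must divide the per-stage channel counts ",
                                   paste(ch, collapse = ","))
  structure(list(embed_dim = as.integer(embed_dim), window = as.integer(window),
                 heads = as.integer(heads), mlp_ratio = mlp_ratio, ln_eps = ln_eps,
                 head_hidden = as.integer(head_hidden),
                 input_shape = as.integer(input_shape),
                 scale_t = rep(as.numeric(scale_t), length.out = 3L),
                 scale_r = rep(as.numeric(scale_r), length.out = 3L)),
            class = "swr_swin_config")
}

# final-stage token grid for a given input shape: /4 embedding, then three
# stride-2 stages (ceiling division throughout)
stage4_grid <- function(input_shape) {
  g <- as.integer(ceiling(input_shape / 4))
  for (i in 1:3) g <- as.integer(ceiling(g / 2))
  g
}

init_w <- function(..., sd = 0.02) tg_param(array(stats::rnorm(prod(...), sd = sd), dim = c(...)))
init_b <- function(n) tg_param(numeric(n))

#' Initialize a Swin registration network
#'
#' Uses the current RNG state; the final regression layer uses a small
#' initialization so an untrained network starts near (not exactly at) the
#' identity transform while keeping a live gradient path into the backbone.
#'
#' @param cfg A [swin_config()].
#' @return A `swr_swin_net`: list of config and named parameter tensors.
#' @export
swin_net <- function(cfg = swin_config()) {
  C <- cfg$embed_dim
  p <- list(embed_W = init_w(7, 7, 7, 2, C), embed_b = init_b(C))
  ch_in <- c(C, C, 2L * C, 4L * C)
  ch_out <- c(C, 2L * C, 4L * C, 8L * C)
  for (s in 1:4) {
    cs <- ch_out[s]
    p[[paste0("s", s, "_conv_W")]] <- init_w(3, 3, 3, ch_in[s], cs)
    p[[paste0("s", s, "_conv_b")]] <- init_b(cs)
    for (h in 1:2) {
      pre <- paste0("s", s, "_h", h, "_")
      p[[paste0(pre, "ln1g")]] <- tg_param(rep(1, cs))
      p[[paste0(pre, "ln1b")]] <- init_b(cs)
      p[[paste0(pre, "qkvW")]] <- init_w(cs, 3L * cs)
      p[[paste0(pre, "qkvb")]] <- init_b(3L * cs)
      p[[paste0(pre, "projW")]] <- init_w(cs, cs)
      p[[paste0(pre, "projb")]] <- init_b(cs)
      p[[paste0(pre, "ln2g")]] <- tg_param(rep(1, cs))
      p[[paste0(pre, "ln2b")]] <- init_b(cs)
      hid <- as.integer(round(cfg$mlp_ratio * cs))
      p[[paste0(pre, "mlp1W")]] <- init_w(cs, hid)
      p[[paste0(pre, "mlp1b")]] <- init_b(hid)
      p[[paste0(pre, "mlp2W")]] <- init_w(hid, cs)
      p[[paste0(pre, "mlp2b")]] <- init_b(cs)
    }
  }
  p$head_lng <- tg_param(rep(1, 8L * C))
  p$head_lnb <- init_b(8L * C)
  head_in <- prod(stage4_grid(cfg$input_shape)) * 8L * C
  p$fc1W <- init_w(head_in, cfg$head_hidden)
  p$fc1b <- init_b(cfg$head_hidden)
  # small (not zero) final-layer init: a zero matrix would cut the only
  # gradient path into the backbone, freezing it whenever per-sample head
  # gradients average out; sd 0.002 still starts within ~0.1 mm of identity
  p$fc2W <- init_w(cfg$head_hidden, 6L, sd = 0.002)
  p$fc2b <- tg_param(numeric(6L))
  structure(list(cfg = cfg, params = p), class = "swr_swin_net")
}

#' @export
print.swr_swin_net <- function(x, ...) {
  n <- sum(vapply(x$params, function(p) length(p$value), numeric(1)))
  cat("<swr_swin_net> C =", x$cfg$embed_dim, ", window", paste(x$cfg$window, collapse = "x"),
      ",", format(n, big.mark = ","), "parameters\n")
  invisible(x)
}

# ---- window partition plans ------------------------------------------------

.win_cache <- new.env(parent = emptyenv())

# Plan mapping token-grid order -> padded window order and back, with region
# ids for the shifted-window attention mask. Padding tokens (grid right-padded
# to a window multiple) carry id -1 and are masked out for real queries.
win_plan <- function(grid, window, shifted) {
  key <- paste(c(grid, window, shifted), collapse = "_")
  if (!is.null(.win_cache[[key]])) return(.win_cache[[key]])
  w <- pmin(window, grid)
  pgrid <- as.integer(ceiling(grid / w) * w)
  sh <- ifelse(shifted & w < pgrid, w %/% 2L, 0L)
  np <- prod(pgrid)
  cx <- rep(0:(pgrid[1] - 1L), times = pgrid[2] * pgrid[3])
  cy <- rep(rep(0:(pgrid[2] - 1L), each = pgrid[1]), times = pgrid[3])
  cz <- rep(0:(pgrid[3] - 1L), each = pgrid[1] * pgrid[2])
  # source position before the cyclic shift
  sx <- (cx + sh[1]) %% pgrid[1]
  sy <- (cy + sh[2]) %% pgrid[2]
  sz <- (cz + sh[3]) %% pgrid[3]
  real <- sx < grid[1] & sy < grid[2] & sz < grid[3]
  rowsrc <- ifelse(real, sx + grid[1] * (sy + grid[2] * sz) + 1L, 0L)
  # Region ids on the post-shift layout: only the last window along a shifted
  # axis mixes wrapped-around (spatially non-contiguous) tokens, which must
  # not attend each other. Ids follow the canonical slicing
  # [0, p-w), [p-w, p-s), [p-s, p). Padding tokens get -1 (always masked).
  rid_ax <- function(c0, p, wl, s) ifelse(c0 < p - wl, 0L, ifelse(c0 < p - s, 1L, 2L))
  id <- ifelse(real,
               rid_ax(cx, pgrid[1], w[1], sh[1]) +
                 3L * rid_ax(cy, pgrid[2], w[2], sh[2]) +
                 9L * rid_ax(cz, pgrid[3], w[3], sh[3]),
               -1L)
  wflat <- (cx %/% w[1]) + (pgrid[1] %/% w[1]) * ((cy %/% w[2]) + (pgrid[2] %/% w[2]) * (cz %/% w[3]))
  pflat <- (cx %% w[1]) + w[1] * ((cy %% w[2]) + w[2] * (cz %% w[3]))
  ord <- order(wflat, pflat)
  rowidx <- rowsrc[ord]
  ids <- id[ord]
  wlen <- prod(w)
  nw <- np %/% wlen
  masks <- vector("list", nw)
  for (k in seq_len(nw)) {
    seg <- ids[((k - 1L) * wlen + 1L):(k * wlen)]
    if (length(unique(seg)) > 1L) {
      m <- outer(seg, seg, "!=") * -1e9
      masks[[k]] <- m
    }
  }
  inv <- integer(sum(grid > 0) * 0 + prod(grid))
  realpos <- which(rowidx > 0L)
  inv[rowidx[realpos]] <- realpos
  plan <- list(pgrid = pgrid, w = w, shift = sh, nw = nw, wlen = wlen,
               rowidx = rowidx, invidx = inv, masks = masks)
  .win_cache[[key]] <- plan
  plan
}

#' Partition a feature grid into attention windows (and back)
#'
#' Utility used by the attention layers and exposed for inspection: partitions
#' an (x, y, z, channels) array into non-overlapping windows (grid dims must be
#' divisible by the window), returning a list of (window-voxels x channels)
#' matrices. `window_reverse` is its exact inverse.
#'
#' @param x 4D array (3 spatial axes, then channels).
#' @param window Integer length-3 window size.
#' @return List of matrices, one per window, ordered by window position.
#' @export
window_partition <- function(x, window) {
  grid <- dim(x)[1:3]
  window <- as.integer(rep(window, length.out = 3))
  if (any(grid %% window != 0L)) stop("grid dims must be divisible by the window")
  C <- dim(x)[4]
  plan <- win_plan(grid, window, shifted = FALSE)
  toks <- x
  dim(toks) <- c(prod(grid), C)
  out <- lapply(seq_len(plan$nw), function(k) {
    rows <- plan$rowidx[((k - 1L) * plan$wlen + 1L):(k * plan$wlen)]
    toks[rows, , drop = FALSE]
  })
  attr(out, "grid") <- grid
  attr(out, "window") <- window
  out
}

#' @rdname window_partition
#' @param wins List from [window_partition()].
#' @param grid,window2 Grid and window used to partition (defaults to the
#'   attributes stored on `wins`).
#' @export
window_reverse <- function(wins, grid = attr(wins, "grid"), window2 = attr(wins, "window")) {
  plan <- win_plan(grid, window2, shifted = FALSE)
  C <- ncol(wins[[1]])
  all <- do.call(rbind, wins)
  toks <- all[plan$invidx, , drop = FALSE]
  array(toks, dim = c(grid, C))
}

# ---- multi-head attention composite op -------------------------------------

# qkv: (n x 3C) tensor for one window; mask: NULL or additive (n x n) matrix.
tg_mha <- function(qkv, nheads, mask = NULL) {
  qv <- tg_v(qkv)
  n <- nrow(qv)
  C <- ncol(qv) %/% 3L
  dh <- C %/% nheads
  sc <- 1 / sqrt(dh)
  Ps <- Qs <- Ks <- Vs <- vector("list", nheads)
  out <- matrix(0, n, C)
  for (h in seq_len(nheads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    Q <- qv[, cols, drop = FALSE]
    K <- qv[, C + cols, drop = FALSE]
    V <- qv[, 2L * C + cols, drop = FALSE]
    S <- tcrossprod(Q, K) * sc
    if (!is.null(mask)) S <- S + mask
    S <- S - S[cbind(seq_len(n), max.col(S, "first"))]
    E <- exp(S)
    P <- E / rowSums(E)
    out[, cols] <- P %*% V
    Ps[[h]] <- P; Qs[[h]] <- Q; Ks[[h]] <- K; Vs[[h]] <- V
  }
  tg_op(out, list(qkv), function(g) {
    gq <- matrix(0, n, 3L * C)
    for (h in seq_len(nheads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      gO <- g[, cols, drop = FALSE]
      P <- Ps[[h]]
      gP <- tcrossprod(gO, Vs[[h]])
      gV <- crossprod(P, gO)
      dS <- P * (gP - rowSums(gP * P))
      gq[, cols] <- (dS %*% Ks[[h]]) * sc
      gq[, C + cols] <- crossprod(dS, Qs[[h]]) * sc
      gq[, 2L * C + cols] <- gV
    }
    tg_acc(qkv, gq)
  })
}

# All windows of one attention layer in a single composite op: the input is
# the window-ordered qkv matrix (N_pad x 3C); window k occupies the contiguous
# row block [(k-1)*wlen+1, k*wlen]. One tape node instead of ~4 per window.
tg_mha_batched <- function(ordered, wlen, nheads, masks) {
  ov <- tg_v(ordered)
  N <- nrow(ov)
  C <- ncol(ov) %/% 3L
  dh <- C %/% nheads
  sc <- 1 / sqrt(dh)
  nw <- N %/% wlen
  out <- matrix(0, N, C)
  cache <- vector("list", nw)
  for (k in seq_len(nw)) {
    rows <- ((k - 1L) * wlen + 1L):(k * wlen)
    qkv <- ov[rows, , drop = FALSE]
    hc <- vector("list", nheads)
    for (h in seq_len(nheads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Q <- qkv[, cols, drop = FALSE]
      K <- qkv[, C + cols, drop = FALSE]
      V <- qkv[, 2L * C + cols, drop = FALSE]
      S <- tcrossprod(Q, K) * sc
      if (!is.null(masks[[k]])) S <- S + masks[[k]]
      S <- S - S[cbind(seq_len(wlen), max.col(S, "first"))]
      E <- exp(S)
      P <- E / rowSums(E)
      out[rows, cols] <- P %*% V
      hc[[h]] <- list(P = P, Q = Q, K = K, V = V)
    }
    cache[[k]] <- hc
  }
  tg_op(out, list(ordered), function(g) {
    gq <- matrix(0, N, 3L * C)
    for (k in seq_len(nw)) {
      rows <- ((k - 1L) * wlen + 1L):(k * wlen)
      for (h in seq_len(nheads)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        hc <- cache[[k]][[h]]
        gO <- g[rows, cols, drop = FALSE]
        gP <- tcrossprod(gO, hc$V)
        dS <- hc$P * (gP - rowSums(gP * hc$P))
        gq[rows, cols] <- (dS %*% hc$K) * sc
        gq[rows, C + cols] <- crossprod(dS, hc$Q) * sc
        gq[rows, 2L * C + cols] <- crossprod(hc$P, gO)
      }
    }
    tg_acc(ordered, gq)
  })
}

# Windowed multi-head self-attention over a token matrix (ntok x C) laid out
# in column-major grid order. Returns (ntok x C).
window_attention_tokens <- function(tokens, grid, qkvW, qkvb, projW, projb,
                                    window, nheads, shifted) {
  plan <- win_plan(grid, window, shifted)
  qkv <- tg_linear(tokens, qkvW, qkvb)
  ordered <- tg_rows(qkv, plan$rowidx)
  all <- tg_mha_batched(ordered, plan$wlen, nheads, plan$masks)
  real <- tg_rows(all, plan$invidx)
  tg_linear(real, projW, projb)
}

#' Windowed multi-head self-attention on a feature grid
#'
#' @param x 4D array or tensor (x, y, z, channels).
#' @param net A `swr_swin_net` (for its parameters); `stage` selects the
#'   parameter set, `half` 1 = W-MSA, 2 = SW-MSA.
#' @param stage,half Integers.
#' @param shifted Use the shifted-window variant (cyclic half-window shift with
#'   attention masking).
#' @return Tensor with the input shape.
#' @export
window_attention <- function(x, net, stage, half = 1L, shifted = FALSE) {
  xv <- tg_v(x)
  grid <- dim(xv)[1:3]
  C <- dim(xv)[4]
  toks <- tg_reshape(x, c(prod(grid), C))
  pre <- paste0("s", stage, "_h", half, "_")
  p <- net$params
  o <- window_attention_tokens(toks, grid, p[[paste0(pre, "qkvW")]], p[[paste0(pre, "qkvb")]],
                               p[[paste0(pre, "projW")]], p[[paste0(pre, "projb")]],
                               net$cfg$window, net$cfg$heads[stage], shifted)
  tg_reshape(o, c(grid, C))
}

# ---- blocks and stages -----------------------------------------------------

swin_block_tokens <- function(tokens, grid, net, stage) {
  cfg <- net$cfg
  p <- net$params
  for (half in 1:2) {
    pre <- paste0("s", stage, "_h", half, "_")
    a <- tg_layernorm(tokens, p[[paste0(pre, "ln1g")]], p[[paste0(pre, "ln1b")]], cfg$ln_eps)
    a <- window_attention_tokens(a, grid, p[[paste0(pre, "qkvW")]], p[[paste0(pre, "qkvb")]],
                                 p[[paste0(pre, "projW")]], p[[paste0(pre, "projb")]],
                                 cfg$window, cfg$heads[stage], shifted = (half == 2L))
    tokens <- tg_add(tokens, a)
    m <- tg_layernorm(tokens, p[[paste0(pre, "ln2g")]], p[[paste0(pre, "ln2b")]], cfg$ln_eps)
    m <- tg_linear(m, p[[paste0(pre, "mlp1W")]], p[[paste0(pre, "mlp1b")]])
    m <- tg_gelu(m)
    m <- tg_linear(m, p[[paste0(pre, "mlp2W")]], p[[paste0(pre, "mlp2b")]])
    tokens <- tg_add(tokens, m)
  }
  tokens
}

#' One Swin block (W-MSA and SW-MSA sub-blocks with MLPs)
#'
#' @param x 4D feature array or tensor.
#' @param net A `swr_swin_net`.
#' @param stage Stage index (parameter set).
#' @return Tensor with the input shape.
#' @export
swin_block <- function(x, net, stage) {
  xv <- tg_v(x)
  grid <- dim(xv)[1:3]
  C <- dim(xv)[4]
  toks <- tg_reshape(x, c(prod(grid), C))
  toks <- swin_block_tokens(toks, grid, net, stage)
  tg_reshape(toks, c(grid, C))
}

#' Patch embedding: kernel-7 stride-4 convolution of the 2-channel pair
#'
#' @param net A `swr_swin_net`.
#' @param pair 4D array (x, y, z, 2): fixed and moving volumes stacked on the
#'   channel axis.
#' @return Tensor of shape (x/4, y/4, z/4, C).
#' @export
patch_embed <- function(net, pair) {
  if (dim(tg_v(pair))[4] != 2L) stop("patch embedding expects 2 input channels")
  tg_conv3d(pair, net$params$embed_W, net$params$embed_b, stride = 4L, pad = 3L)
}

#' Stage forward: convolution (downsampling for stages 2-4) + Swin block
#'
#' @param x 4D feature tensor.
#' @param net A `swr_swin_net`.
#' @param stage Stage index in 1..4.
#' @return Tensor; stages 2-4 halve the resolution and double the channels.
#' @export
stage_forward <- function(x, net, stage) {
  stopifnot(stage %in% 1:4)
  stride <- if (stage == 1L) 1L else 2L
  p <- net$params
  y <- tg_conv3d(x, p[[paste0("s", stage, "_conv_W")]], p[[paste0("s", stage, "_conv_b")]],
                 stride = stride, pad = 1L)
  grid <- dim(tg_v(y))[1:3]
  if (any(grid < 1L)) stop("feature grid underflow at stage ", stage,
                           "; use a smaller window/larger input")
  swin_block(y, net, stage)
}

#' Regression head: flattened final-stage features + two fully connected layers
#'
#' A final (token-wise) LayerNorm is applied, then the feature grid is
#' flattened and reduced by two fully connected layers to the six rigid
#' parameters. Flattening (rather than pooling) preserves the spatial
#' arrangement of the tokens, which is what encodes rotations.
#'
#' @param net A `swr_swin_net`.
#' @param x Final-stage feature tensor (4D).
#' @return Length-6 parameter tensor (t mm, r deg) after output scaling.
#' @export
regression_head <- function(net, x) {
  xv <- tg_v(x)
  C <- dim(xv)[4]
  toks <- tg_reshape(x, c(prod(dim(xv)[1:3]), C))
  # final LayerNorm (standard Swin) keeps the features well-scaled
  toks <- tg_layernorm(toks, net$params$head_lng, net$params$head_lnb, net$cfg$ln_eps)
  nfeat <- length(xv)
  if (nfeat != nrow(net$params$fc1W$value))
    stop("final-stage feature size ", nfeat, " does not match the network's ",
         "configured input shape (fc1 expects ", nrow(net$params$fc1W$value), ")")
  flat <- tg_reshape(toks, c(1L, nfeat))
  h <- tg_relu(tg_linear(flat, net$params$fc1W, net$params$fc1b))
  o <- tg_linear(h, net$params$fc2W, net$params$fc2b)
  o <- tg_reshape(o, 6L)
  tg_mul(o, c(rep(net$cfg$scale_t, length.out = 3), rep(net$cfg$scale_r, length.out = 3)))
}

#' Full network forward pass
#'
#' @param net A `swr_swin_net`.
#' @param fixed,moving 3D arrays (normalized intensities) sharing a geometry.
#' @return List with `params6` (length-6 tensor, differentiable), `params`
#'   (`swr_rigid_params`), and `matrix` (4x4, built about `center`).
#' @param center Physical rotation centre (mm).
#' @export
swin_forward <- function(net, fixed, moving, center = c(0, 0, 0)) {
  if (!all(dim(fixed) == dim(moving))) stop("fixed and moving volumes must share geometry")
  pair <- array(c(fixed, moving), dim = c(dim(fixed), 2L))
  x <- patch_embed(net, tg_tensor(pair))
  for (s in 1:4) x <- stage_forward(x, net, s)
  p6 <- regression_head(net, x)
  pv <- as.numeric(tg_v(p6))
  rp <- rigid_params(pv[1:3], pv[4:6])
  list(params6 = p6, params = rp, matrix = params_to_matrix(rp, center))
}
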