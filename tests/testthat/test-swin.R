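# Swin registration network: embedding, windows, attention, blocks, head.

test_that("window partition/reverse is an exact inverse and counts windows", {
  set.seed(21)
  x <- array(rnorm(8 * 8 * 4 * 3), c(8, 8, 4, 3))
  wp <- window_partition(x, c(4, 4, 4))
  expect_length(wp, 4L)            # 2 * 2 * 1 windows
  expect_identical(window_reverse(wp), x)

  cg <- array(5, c(8, 4, 4, 2))
  expect_true(all(vapply(window_partition(cg, c(4, 4, 4)),
                         function(w) all(w == 5), logical(1))))
})

test_that("full-grid window attention equals a dense multi-head oracle", {
  set.seed(22)
  net <- swin_net(tiny_swin_cfg())   # window (4,4,4) replaced below by full grid
  cfg <- swin_config(embed_dim = 8L, window = c(6L, 6L, 4L), heads = c(2L, 2L, 2L, 2L),
                     head_hidden = 16L)
  set.seed(22)
  net <- swin_net(cfg)
  fg <- array(rnorm(6 * 6 * 4 * 8), c(6, 6, 4, 8))
  out <- tg_v(window_attention(fg, net, stage = 1, half = 1, shifted = FALSE))

  toks <- matrix(fg, 6 * 6 * 4, 8)
  qkv <- sweep(toks %*% net$params$s1_h1_qkvW$value, 2, net$params$s1_h1_qkvb$value, "+")
  C <- 8L; dh <- 4L
  dense <- matrix(0, nrow(toks), C)
  for (h in 1:2) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    Q <- qkv[, cols]; K <- qkv[, C + cols]; V <- qkv[, 2 * C + cols]
    S <- Q %*% t(K) / sqrt(dh)
    P <- exp(S - apply(S, 1, max)); P <- P / rowSums(P)
    dense[, cols] <- P %*% V
  }
  dense <- sweep(dense %*% net$params$s1_h1_projW$value, 2,
                 net$params$s1_h1_projb$value, "+")
  expect_lt(max(abs(out - array(dense, dim(fg)))), 1e-5)
})

test_that("single-voxel windows reduce attention to a per-token projection", {
  set.seed(23)
  cfg <- swin_config(embed_dim = 4L, window = c(1L, 1L, 1L), heads = c(2L, 2L, 2L, 2L),
                     head_hidden = 8L)
  net <- swin_net(cfg)
  fg <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
  out <- tg_v(window_attention(fg, net, 1, 1, shifted = FALSE))
  # softmax over a single element is 1: output = proj(V(x)) per token
  toks <- matrix(fg, 18, 4)
  qkv <- sweep(toks %*% net$params$s1_h1_qkvW$value, 2, net$params$s1_h1_qkvb$value, "+")
  V <- qkv[, 9:12]
  expected <- sweep(V %*% net$params$s1_h1_projW$value, 2, net$params$s1_h1_projb$value, "+")
  expect_equal(out, array(expected, dim(fg)), tolerance = 1e-12)
})

test_that("shifted-window masking blocks information flow across wrapped windows", {
  # op-level check: perturbing a masked counterpart leaves the output unchanged
  plan <- swinreg:::win_plan(c(8L, 8L, 4L), c(4L, 4L, 4L), shifted = TRUE)
  expect_gt(sum(!vapply(plan$masks, is.null, logical(1))), 0L)
  k <- which(!vapply(plan$masks, is.null, logical(1)))[1]
  mask <- plan$masks[[k]]
  pair <- which(mask < 0, arr.ind = TRUE)[1, ]   # (query i, masked key j)
  set.seed(24)
  qkv <- matrix(rnorm(64 * 12), 64, 12)          # C = 4, 2 heads
  base <- tg_v(swinreg:::tg_mha_batched(tg_tensor(qkv), 64L, 2L, list(mask)))
  qkv2 <- qkv
  qkv2[pair[2], ] <- qkv2[pair[2], ] + 100       # perturb masked token's Q/K/V
  pert <- tg_v(swinreg:::tg_mha_batched(tg_tensor(qkv2), 64L, 2L, list(mask)))
  expect_lt(max(abs(pert[pair[1], ] - base[pair[1], ])), 1e-6)
  # and the same perturbation does change some unmasked query's output
  free <- which(mask[, pair[2]] == 0)
  free <- setdiff(free, pair[2])
  expect_gt(max(abs(pert[free, ] - base[free, ])), 1e-8)
})

test_that("a Swin block with zeroed projection/MLP output weights is the identity", {
  set.seed(25)
  net <- swin_net(tiny_swin_cfg())
  for (nm in names(net$params)) {
    if (grepl("projW|projb|mlp2W|mlp2b", nm)) net$params[[nm]]$value[] <- 0
  }
  fg <- array(rnorm(8 * 8 * 4 * 8), c(8, 8, 4, 8))
  expect_equal(tg_v(swin_block(fg, net, stage = 1)), fg, tolerance = 1e-12)
})

test_that("swin block output matches an independent step-by-step composition", {
  set.seed(26)
  net <- swin_net(tiny_swin_cfg())
  fg <- array(rnorm(4 * 4 * 4 * 8), c(4, 4, 4, 8))
  got <- tg_v(swin_block(fg, net, stage = 1))

  ln <- function(x, g, b, eps = 1e-5) {
    mu <- rowMeans(x); xc <- x - mu
    s <- sqrt(rowMeans(xc^2) + eps)
    sweep(sweep(xc / s, 2, g, "*"), 2, b, "+")
  }
  toks <- matrix(fg, 64, 8)
  p <- lapply(net$params, function(t) t$value)
  for (h in 1:2) {
    pre <- paste0("s1_h", h, "_")
    a <- ln(toks, p[[paste0(pre, "ln1g")]], p[[paste0(pre, "ln1b")]])
    a <- tg_v(swinreg:::window_attention_tokens(
      tg_tensor(a), c(4L, 4L, 4L),
      p[[paste0(pre, "qkvW")]], p[[paste0(pre, "qkvb")]],
      p[[paste0(pre, "projW")]], p[[paste0(pre, "projb")]],
      c(4L, 4L, 4L), 2L, shifted = (h == 2)))
    toks <- toks + a
    m <- ln(toks, p[[paste0(pre, "ln2g")]], p[[paste0(pre, "ln2b")]])
    m <- sweep(m %*% p[[paste0(pre, "mlp1W")]], 2, p[[paste0(pre, "mlp1b")]], "+")
    m <- m * pnorm(m)
    m <- sweep(m %*% p[[paste0(pre, "mlp2W")]], 2, p[[paste0(pre, "mlp2b")]], "+")
    toks <- toks + m
  }
  expect_equal(got, array(toks, dim(fg)), tolerance = 1e-10)
})

test_that("patch embedding and stages obey the feature-shape law", {
  set.seed(27)
  cfg <- study_swin_cfg()
  net <- swin_net(cfg)
  pair <- array(rnorm(64 * 64 * 32 * 2), c(64, 64, 32, 2))
  x <- patch_embed(net, pair)
  expect_equal(dim(tg_v(x)), c(16, 16, 8, 16))       # input/4, C channels
  expect_equal(length(net$params$embed_W$value) + length(net$params$embed_b$value),
               7^3 * 2 * 16 + 16)                    # analytic parameter count
  # zero input with zero bias gives zero output (linearity)
  net$params$embed_b$value[] <- 0
  z <- patch_embed(net, array(0, c(32, 32, 16, 2)))
  expect_true(all(tg_v(z) == 0))

  shapes <- list(c(16, 16, 8, 16), c(8, 8, 4, 32), c(4, 4, 2, 64), c(2, 2, 1, 128))
  for (s in 1:4) {
    x <- stage_forward(x, net, s)
    expect_equal(dim(tg_v(x)), shapes[[s]])          # H/2^(i+1), 2^(i-1) C
  }
})

test_that("regression head maps hand-set weights to scaled parameters", {
  set.seed(28)
  cfg <- swin_config(embed_dim = 4L, window = c(2L, 2L, 2L), heads = c(2L, 2L, 2L, 2L),
                     head_hidden = 6L, scale_t = 1, scale_r = 1)
  net <- swin_net(cfg)
  # choose fc weights so the raw output is exactly (1,2,3,4,5,6)
  C8 <- 32L
  net$params$fc1W$value[] <- 0
  net$params$fc1b$value[] <- 1
  net$params$fc2W$value[] <- 0
  net$params$fc2b$value[] <- 1:6
  fg <- array(rnorm(2 * 2 * 1 * C8), c(2, 2, 1, C8))
  p6 <- as.numeric(tg_v(regression_head(net, fg)))
  expect_equal(p6, as.numeric(1:6), tolerance = 1e-12)
  expect_length(p6, 6L)
  # output scaling multiplies translations and rotations
  net$cfg$scale_t <- 10; net$cfg$scale_r <- 2
  expect_equal(as.numeric(tg_v(regression_head(net, fg))), c(10, 20, 30, 8, 10, 12),
               tolerance = 1e-12)
})

test_that("forward pass: zero head gives identity; outputs are always rigid", {
  set.seed(29)
  net <- swin_net(tiny_swin_cfg())
  Fv <- smooth_volume(c(32, 32, 16), seed = 1)
  Mv <- smooth_volume(c(32, 32, 16), seed = 2)
  net$params$fc2W$value[] <- 0                       # zeroed head -> identity
  fw <- swin_forward(net, Fv, Mv, center = c(31, 31, 30))
  expect_equal(fw$matrix, diag(4))
  # non-zero head: rigid invariants hold by construction
  set.seed(30)
  net$params$fc2W$value[] <- rnorm(length(net$params$fc2W$value), sd = 0.05)
  fw2 <- swin_forward(net, Fv, Mv, center = c(31, 31, 30))
  R <- fw2$matrix[1:3, 1:3]
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
  expect_lt(abs(det(R) - 1), 1e-9)
  expect_error(swin_forward(net, Fv, smooth_volume(c(16, 16, 8))), "geometry")
  # swapping the input channels changes the prediction (learnable asymmetry)
  fw3 <- swin_forward(net, Mv, Fv, center = c(31, 31, 30))
  expect_gt(max(abs(c(fw3$params$t, fw3$params$r) - c(fw2$params$t, fw2$params$r))), 1e-8)
})

test_that("autodiff gradient through the network matches finite differences", {
  set.seed(31)
  net <- swin_net(tiny_swin_cfg())
  net$params$fc2W$value[] <- rnorm(length(net$params$fc2W$value), sd = 0.01)
  Fv <- smooth_volume(c(32, 32, 16), seed = 3)
  Mv <- smooth_volume(c(32, 32, 16), seed = 4)
  tg_tape_start()
  fw <- swin_forward(net, Fv, Mv, center = c(31, 31, 30))
  loss <- tg_sum(tg_mul(fw$params6, fw$params6))
  tg_backward(loss)
  tg_tape_stop()
  g_ad <- net$params$fc1W$grad[5, 3]
  w0 <- net$params$fc1W$value[5, 3]
  f_at <- function(w) {
    net$params$fc1W$value[5, 3] <- w
    fw <- swin_forward(net, Fv, Mv, center = c(31, 31, 30))
    sum(tg_v(fw$params6)^2)
  }
  fd <- (f_at(w0 + 1e-4) - f_at(w0 - 1e-4)) / 2e-4
  net$params$fc1W$value[5, 3] <- w0
  expect_lt(abs(fd - g_ad) / max(abs(fd), 1e-12), 0.05)
})
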