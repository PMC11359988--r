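# Training losses: perceptual, Dice, encoded-anatomy, combination, alternatives.

test_that("loss weight defaults follow the reference protocol", {
  w <- loss_weights()
  expect_equal(w$omega, c(1, 0.5, 0.5))
  expect_equal(w$lambda_dice, 1)
  expect_equal(w$lambda_ae, 0.1)
  expect_error(loss_weights(lambda_dice = -1), "non-negative")
  cfg <- default_config()
  expect_equal(cfg$loss$lambda_dice, 1)
  expect_equal(cfg$loss$lambda_ae, 0.1)
  expect_equal(cfg$loss$omega, c(1, 0.5, 0.5))
  expect_equal(cfg$train$lr, 1e-4)
  expect_equal(cfg$train$batch_size, 1L)
})

test_that("perceptual loss is zero on identical inputs and reduces as mean L1", {
  set.seed(61)
  dae <- dae_net(dae_config(1L, 4L, 3L, 16L), c(16, 16, 8))
  a <- smooth_volume(c(16, 16, 8), seed = 62)
  b <- smooth_volume(c(16, 16, 8), seed = 63)
  expect_equal(tg_v(perceptual_loss(dae, a, a)), 0)
  # hand-computed weighted mean-L1 over the same pyramids
  pa <- lapply(multiscale_features(dae, a), tg_v)
  pb <- lapply(multiscale_features(dae, b), tg_v)
  w <- loss_weights()
  oracle <- sum(vapply(1:3, function(i) w$omega[i] * mean(abs(pa[[i]] - pb[[i]])),
                       numeric(1)))
  expect_equal(tg_v(perceptual_loss(dae, a, b, w)), oracle, tolerance = 1e-12)
  expect_gt(oracle, 0)
})

test_that("dice loss matches voxel-counting oracles", {
  oh <- function(...) { a <- array(0, c(8, 8, 4, 1)); a[...] <- 1; a }
  same <- oh(1:4, 1:4, 1:2, 1)
  expect_equal(dice_loss(same, same), 0, tolerance = 1e-4)
  disj <- oh(5:8, 5:8, 3:4, 1)
  expect_equal(dice_loss(same, disj), 1, tolerance = 1e-4)
  # equal-size masks overlapping on exactly half their voxels
  a <- array(0, c(8, 8, 4, 1)); a[1:4, 1, 1, 1] <- 1
  b <- array(0, c(8, 8, 4, 1)); b[3:6, 1, 1, 1] <- 1
  expect_equal(dice_loss(a, b), 0.5, tolerance = 1e-4)
  expect_error(dice_loss(a, b, structures = integer(0)), "empty")
})

test_that("dice restricted to head structures ignores neck-structure edits", {
  set.seed(64)
  K <- 5
  a <- array(0, c(12, 12, 6, K))
  a[3:5, 3:5, 4:5, 1] <- 1; a[7:9, 3:5, 4:5, 3] <- 1
  a[3:5, 7:9, 1:2, 4] <- 1; a[7:9, 7:9, 1:2, 5] <- 1
  b <- a
  b[, , , 4] <- 0; b[1:2, 1:2, 1, 4] <- 1          # move a neck structure
  expect_equal(dice_loss(a, a, structures = 1:3), dice_loss(a, b, structures = 1:3),
               tolerance = 1e-12)
  expect_gt(dice_loss(a, b, structures = 4:5), 0)
})

test_that("encoded-anatomy loss is zero on identical inputs and symmetric", {
  set.seed(65)
  dae <- dae_net(dae_config(2L, 4L, 2L, 12L, "flip", 0.05), c(8, 8, 4))
  a <- array(0, c(8, 8, 4, 2)); a[2:4, 2:4, 2:3, 1] <- 1; a[6:7, 6:7, 1:2, 2] <- 1
  b <- a; b[, , , 1] <- 0; b[3:5, 3:5, 2:3, 1] <- 1
  expect_equal(ae_loss(dae, a, a), 0)
  expect_equal(ae_loss(dae, a, b), ae_loss(dae, b, a))
  # equals the squared distance of the two latent codes
  oracle <- sum((ace_encode(dae, a) - ace_encode(dae, b))^2)
  expect_equal(ae_loss(dae, a, b), oracle, tolerance = 1e-12)
})

test_that("total loss combines components linearly in the lambdas", {
  set.seed(66)
  dae <- dae_net(dae_config(1L, 4L, 3L, 16L), c(16, 16, 8))
  sdae <- dae_net(dae_config(2L, 4L, 2L, 12L, "flip", 0.05), c(16, 16, 8))
  f <- smooth_volume(c(16, 16, 8), seed = 67)
  m <- smooth_volume(c(16, 16, 8), seed = 68)
  foh <- array(0, c(16, 16, 8, 2)); foh[3:6, 3:6, 3:5, 1] <- 1; foh[10:12, 10:12, 2:4, 2] <- 1
  moh <- foh; moh[, , , 1] <- 0; moh[5:8, 3:6, 3:5, 1] <- 1
  w <- loss_weights()
  tl <- total_loss(dae, sdae, f, m, foh, moh, w = w, structures = 1:2)
  expect_equal(tg_v(tl$total),
               tl$components[["similarity"]] + 1 * tl$components[["dice"]] +
                 0.1 * tl$components[["ae"]], tolerance = 1e-10)
  # doubled lambdas double the constraint contributions
  w2 <- loss_weights(lambda_dice = 2, lambda_ae = 0.2)
  tl2 <- total_loss(dae, sdae, f, m, foh, moh, w = w2, structures = 1:2)
  expect_equal(tg_v(tl2$total) - tl2$components[["similarity"]],
               2 * (tg_v(tl$total) - tl$components[["similarity"]]), tolerance = 1e-10)
  # zero lambdas reduce exactly to the similarity term
  w0 <- loss_weights(lambda_dice = 0, lambda_ae = 0)
  tl0 <- total_loss(dae, sdae, f, m, foh, moh, w = w0, structures = 1:2)
  expect_equal(tg_v(tl0$total), tg_v(perceptual_loss(dae, f, m, w0)))
  # hand arithmetic on the combination rule
  expect_equal(2.0 + 1 * 0.4 + 0.1 * 0.3, 2.43)
})

test_that("alternative similarities vanish on identical inputs; MI separates noise", {
  a <- smooth_volume(c(16, 16, 8), seed = 69)
  expect_equal(alt_similarity(a, a, "ssim"), 0, tolerance = 1e-9)
  expect_equal(alt_similarity(a, a, "ncc"), 0, tolerance = 1e-9)
  set.seed(70)
  n1 <- array(runif(64^3), c(64, 64, 64))
  n2 <- array(runif(64^3), c(64, 64, 64))
  expect_lt(-alt_similarity(n1, n2, "mi"), 0.05)    # independent: ~0 bits
  expect_gt(-alt_similarity(n1, n1, "mi"), 1)       # self: strongly dependent
  expect_error(alt_similarity(a, a, "zncc"), "arg")
})

test_that("alternative similarities carry gradients through warping", {
  mov <- array(smooth_volume(c(12, 12, 8), seed = 71), c(12, 12, 8, 1))
  fixed <- smooth_volume(c(12, 12, 8), seed = 72)
  for (kind in c("ssim", "ncc", "mi")) {
    pt <- tg_param(c(1, -1, 1, 2, -2, 1))
    tg_tape_start()
    w <- tg_rigid_warp(pt, mov, c(2, 2, 4), c(0, 0, 0), c(11, 11, 14), fill = 0)
    L <- alt_similarity(fixed, tg_reshape(w, c(12, 12, 8)), kind)
    tg_backward(L)
    tg_tape_stop()
    expect_true(all(is.finite(pt$grad)))
    expect_gt(max(abs(pt$grad)), 0)
  }
})
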