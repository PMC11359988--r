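# Training loop, inference, evaluation and ablations.
#
# Weakly supervised training: per iteration a fresh augmentation misalignment
# is composed with the case's stored misalignment (single resampling, no
# double interpolation blur), the network predicts the six rigid parameters,
# the moving image and its one-hot segmentation are warped differentiably
# through the predicted matrix, and the combined loss (perceptual +
# lambda_dice Dice + lambda_ae encoded-anatomy) is backpropagated into the
# registration network only; the metric and constraint encoders stay frozen.

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 1e-4,
#' batch size 1, 500 epochs, augmentation of +/-3 degrees and +/-3 voxels.
#' Reduced problem sizes typically use fewer epochs and a larger learning
#' rate (see the vignette).
#'
#' @param lr Backbone learning rate; 0 freezes the backbone at its random
#'   initialization (head-only training, the desk-scale default regime).
#' @param batch_size Pairs per gradient step (the protocol trains with 1).
#' @param epochs Training epochs.
#' @param seed RNG seed for the whole run.
#' @param aug_rot_deg,aug_trans_vox Augmentation misalignment ranges.
#' @param similarity Image dissimilarity: "perceptual", "ssim", "ncc" or "mi".
#' @param weights A [loss_weights()].
#' @param structures Which structures feed the constraint losses: "head"
#'   (eyes, optic nerve, brainstem -- the default, biasing accuracy toward the
#'   head), "all", or "none" (no segmentations used, as at inference).
#' @param swin A [swin_config()].
#' @param head_lr Learning rate for the regression head (final LayerNorm and
#'   the two fully connected layers); defaults to `lr`. In the small-data
#'   regime a faster head over a slowly-moving backbone stabilizes learning.
#' @param grad_clip Global gradient-norm clip applied before each Adam step
#'   (0 disables). Guards against the out-of-bounds death spiral: once a
#'   predicted transform pushes the moving volume fully outside the fixed
#'   grid, the warp gradient vanishes and training cannot recover.
#' @param lr_decay Multiplier applied to both learning rates after two thirds
#'   of the epochs (1 = constant). A late step-down shrinks the oscillation
#'   of small-batch SGD around its optimum.
#' @param weight_decay Decoupled weight decay applied to the regression head
#'   (the backbone, when trained, is not decayed). With few training pairs
#'   the head otherwise overfits; this is the stochastic analogue of the
#'   ridge penalty that makes linear readouts of the features generalize.
#' @param val_every Validate (TRE on the val split) every this many epochs.
#' @param avg_tail Fraction of final epochs over which trained parameters are
#'   Polyak-averaged; the average competes with the best-validation
#'   checkpoint (both are scored on the validation split, the better one is
#'   kept). 0 disables. Averaging cancels the late-phase oscillation of
#'   small-batch SGD around its optimum.
#' @return A `swr_train_config`.
#' @export
train_config <- function(lr = 1e-4, batch_size = 1L, epochs = 500L, seed = 0L,
                         aug_rot_deg = 3, aug_trans_vox = 3,
                         similarity = "perceptual",
                         weights = loss_weights(),
                         structures = c("head", "all", "none"),
                         swin = swin_config(), head_lr = NULL, grad_clip = 1,
                         lr_decay = 1, weight_decay = 0, val_every = 10L,
                         avg_tail = 0) {
  structures <- match.arg(structures)
  if (lr < 0) stop("learning rate must be non-negative")
  if (lr == 0 && is.null(head_lr)) stop("head_lr must be set when the backbone is frozen")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 aug_rot_deg = aug_rot_deg, aug_trans_vox = aug_trans_vox,
                 similarity = similarity, weights = weights,
                 structures = structures, swin = swin,
                 head_lr = if (is.null(head_lr)) lr else head_lr,
                 grad_clip = grad_clip, lr_decay = lr_decay,
                 weight_decay = weight_decay,
                 val_every = as.integer(val_every), avg_tail = avg_tail),
            class = "swr_train_config")
}

structure_indices <- function(structures, structure_names) {
  head_set <- c("eyes", "optic_nerve", "brainstem")
  switch(structures,
         head = which(structure_names %in% head_set),
         all = seq_along(structure_names),
         none = integer(0))
}

norm01 <- function(x) { r <- range(x); if (diff(r) == 0) x * 0 else (x - r[1]) / diff(r) }

#' Pretrain the two DAE metric networks for a dataset
#'
#' Trains the image DAE (perceptual metric network) on the fixed CTs and
#' simulated CBCTs of the training split, and the segmentation DAE
#' (anatomical constraint encoder) on the one-hot masks of the structures
#' that will feed the constraint losses ("head": eyes, optic nerve,
#' brainstem; "all": all five).
#'
#' @param manifest Dataset manifest from [make_dataset()]/[read_manifest()].
#' @param structures Structure set the constraint encoder is trained on.
#' @param epochs,lr Schedule for both pretrainings.
#' @param latent_img,latent_seg Latent sizes (512 at full clinical scale).
#' @param base_channels,depth Encoder layout.
#' @param seed RNG seed.
#' @return List with `metric_dae` and `ace_dae` (trained `swr_dae`).
#' @export
pretrain_daes <- function(manifest, structures = c("head", "all"),
                          epochs = 25L, lr = 2e-3,
                          latent_img = 128L, latent_seg = 64L,
                          base_channels = 8L, depth = 3L, seed = 0L) {
  structures <- match.arg(structures)
  set.seed(seed)
  train_cases <- Filter(function(cs) cs$split == "train", manifest$cases)
  if (length(train_cases) == 0L) stop("manifest has no training cases")
  sh <- as.integer(manifest$shape)
  sidx <- structure_indices(structures, manifest$structures)
  imgs <- list(); segs <- list()
  for (cs in train_cases) {
    d <- load_case(manifest, cs, base = TRUE)
    imgs[[length(imgs) + 1L]] <- norm01(d$fixed$voxels)
    imgs[[length(imgs) + 1L]] <- norm01(d$moving$voxels)
    segs[[length(segs) + 1L]] <- seg_onehot_array(d$fixed_seg)[, , , sidx, drop = FALSE]
    segs[[length(segs) + 1L]] <- seg_onehot_array(d$moving_seg)[, , , sidx, drop = FALSE]
  }
  metric_dae <- dae_net(dae_config(1L, base_channels, depth, latent_img,
                                   "gaussian", 0.1), sh)
  metric_dae <- train_dae(metric_dae, imgs, epochs = epochs, lr = lr)
  ace_dae <- dae_net(dae_config(length(sidx), base_channels, depth, latent_seg,
                                "flip", 0.05), sh)
  ace_dae <- train_dae(ace_dae, segs, epochs = epochs, lr = lr)
  list(metric_dae = metric_dae, ace_dae = ace_dae, structures = structures)
}

# ACE-only pretraining (used by ablation() when the provided encoder does not
# match a variant's structure set).
pretrain_ace <- function(manifest, structures, epochs = 25L, lr = 2e-3,
                         latent_seg = 64L, base_channels = 8L, depth = 3L,
                         seed = 0L) {
  set.seed(seed)
  train_cases <- Filter(function(cs) cs$split == "train", manifest$cases)
  sh <- as.integer(manifest$shape)
  sidx <- structure_indices(structures, manifest$structures)
  segs <- list()
  for (cs in train_cases) {
    d <- load_case(manifest, cs, base = TRUE)
    segs[[length(segs) + 1L]] <- seg_onehot_array(d$fixed_seg)[, , , sidx, drop = FALSE]
    segs[[length(segs) + 1L]] <- seg_onehot_array(d$moving_seg)[, , , sidx, drop = FALSE]
  }
  ace <- dae_net(dae_config(length(sidx), base_channels, depth, latent_seg,
                            "flip", 0.05), sh)
  train_dae(ace, segs, epochs = epochs, lr = lr)
}

#' Train the registration network
#'
#' @param manifest Dataset manifest.
#' @param cfg A [train_config()].
#' @param metric_dae Pretrained image DAE (required for the perceptual loss).
#' @param ace_dae Pretrained segmentation DAE (required when `lambda_ae > 0`
#'   and structures are used).
#' @param verbose Print epoch summaries.
#' @return A `swr_reg_model`: the network, config, DAEs, and training log.
#' @export
train_registration <- function(manifest, cfg = train_config(),
                               metric_dae = NULL, ace_dae = NULL,
                               verbose = FALSE) {
  if (cfg$similarity == "perceptual" && is.null(metric_dae))
    stop("perceptual similarity requires a pretrained metric DAE")
  set.seed(cfg$seed)
  sh <- as.integer(manifest$shape)
  sp <- as.numeric(manifest$spacing)
  sidx <- structure_indices(cfg$structures, manifest$structures)
  use_seg <- length(sidx) > 0L &&
    (cfg$weights$lambda_dice > 0 || cfg$weights$lambda_ae > 0)
  if (use_seg && cfg$weights$lambda_ae > 0 && is.null(ace_dae))
    stop("lambda_ae > 0 requires a pretrained anatomical constraint encoder")
  train_cases <- Filter(function(cs) cs$split == "train", manifest$cases)
  val_cases <- Filter(function(cs) cs$split == "val", manifest$cases)
  data <- lapply(train_cases, function(cs) {
    d <- load_case(manifest, cs, base = TRUE)
    base4 <- d$moving$voxels; dim(base4) <- c(sh, 1L)
    list(fixedN = norm01(d$fixed$voxels),
         fixed_oh = seg_onehot_array(d$fixed_seg)[, , , sidx, drop = FALSE],
         base_vol = d$moving, base4 = base4,
         base_oh = seg_onehot_array(d$moving_seg)[, , , sidx, drop = FALSE],
         mis = rigid_params(cs$true_params$t, cs$true_params$r),
         center = as.numeric(cs$center))
  })
  if (use_seg && cfg$weights$lambda_ae > 0 &&
      ace_dae$cfg$in_channels != length(sidx))
    stop("anatomical constraint encoder was trained on ", ace_dae$cfg$in_channels,
         " structures but the loss uses ", length(sidx))
  for (i in seq_along(data)) {
    data[[i]]$cache <- list(
      fixed_pyramid = if (cfg$similarity == "perceptual")
        lapply(multiscale_features(metric_dae, data[[i]]$fixedN), tg_v),
      fixed_code = if (use_seg && cfg$weights$lambda_ae > 0 && !is.null(ace_dae))
        ace_encode(ace_dae, data[[i]]$fixed_oh))
  }
  net <- swin_net(cfg$swin)
  head_names <- c("head_lng", "head_lnb", "fc1W", "fc1b", "fc2W", "fc2b")
  body_params <- net$params[setdiff(names(net$params), head_names)]
  head_params <- net$params[head_names]
  freeze_body <- cfg$lr == 0
  if (freeze_body) {
    # untracked backbone: backward stops at the head, which also skips the
    # backbone's reverse pass entirely
    for (p in body_params) p$track <- FALSE
  }
  opt_body <- if (!freeze_body) adam_init(body_params, lr = cfg$lr)
  opt_head <- adam_init(head_params, lr = cfg$head_lr %||% cfg$lr,
                        weight_decay = cfg$weight_decay %||% 0)
  bsz <- max(1L, cfg$batch_size)
  bcount <- 0L
  ace_hash_before <- if (!is.null(ace_dae)) sum(params_flatten(ace_dae$params)) else NA_real_
  log <- data.frame()
  best <- list(tre = Inf, flat = NULL, epoch = NA_integer_)
  tail_start <- if (cfg$avg_tail > 0) max(1L, ceiling((1 - cfg$avg_tail) * cfg$epochs)) else NA_integer_
  tail_sum <- NULL; tail_n <- 0L
  val_tre_of <- function() {
    if (length(val_cases) == 0L) return(NA_real_)
    mean(vapply(val_cases, function(cs) {
      d <- load_case(manifest, cs)
      r <- register_pair(net, d$fixed, d$moving)
      unname(tre(d$fixed_lms, transform_landmarks(d$moving_lms, r$matrix))["tre_head_mm"])
    }, numeric(1)))
  }
  decay_at <- if ((cfg$lr_decay %||% 1) != 1) ceiling(2 / 3 * cfg$epochs) else NA_integer_
  for (ep in seq_len(cfg$epochs)) {
    if (!is.na(decay_at) && ep == decay_at) {
      opt_head$lr <- opt_head$lr * cfg$lr_decay
      if (!freeze_body) opt_body$lr <- opt_body$lr * cfg$lr_decay
    }
    comp_sum <- c(similarity = 0, dice = 0, ae = 0); tot_sum <- 0
    for (ci in sample(length(data))) {
      d <- data[[ci]]
      aug <- sample_misalignment(cfg$aug_rot_deg, cfg$aug_trans_vox, sp)
      A_mis <- params_to_matrix(d$mis, d$center)
      A_tot <- A_mis %*% params_to_matrix(aug, d$center)
      fld <- matrix_to_field(A_tot, sh, sp, d$base_vol$origin)
      mov <- warp_volume(d$base_vol, fld)
      movN <- norm01(mov$voxels)
      tg_tape_start()
      fw <- swin_forward(net, d$fixedN, movN, center = d$center)
      wimg <- tg_rigid_warp(fw$params6, array(movN, c(sh, 1L)), sp,
                            d$base_vol$origin, d$center, fill = 0)
      wimg3 <- tg_reshape(wimg, sh)
      woh <- NULL
      if (use_seg) {
        mov_oh <- array(cpp_sample_trilinear(d$base_oh, as.integer(dim(d$base_oh)),
                                             sweep(sweep(fld$coords_mm, 2L, d$base_vol$origin, "-"),
                                                   2L, sp, "/"), 0),
                        dim = dim(d$base_oh))
        woh <- tg_rigid_warp(fw$params6, mov_oh, sp, d$base_vol$origin, d$center, fill = 0)
      }
      tl <- total_loss(metric_dae, ace_dae, d$fixedN, wimg3,
                       fixed_onehot = if (use_seg) d$fixed_oh else NULL,
                       moved_onehot = woh, w = cfg$weights,
                       structures = seq_along(sidx), similarity = cfg$similarity,
                       cache = d$cache)
      tg_backward(tl$total)
      tg_tape_stop()
      bcount <- bcount + 1L
      if (bcount %% bsz == 0L) {
        if (bsz > 1L) {
          for (p in net$params) if (!is.null(p$grad)) p$grad <- p$grad / bsz
        }
        if (cfg$grad_clip > 0) {
          if (!freeze_body) clip_global_norm(body_params, cfg$grad_clip)
          clip_global_norm(head_params, cfg$grad_clip)
        }
        if (!freeze_body) adam_step(body_params, opt_body)
        adam_step(head_params, opt_head)
      }
      tot_sum <- tot_sum + as.numeric(tg_v(tl$total))
      comp_sum <- comp_sum + tl$components
    }
    n <- length(data)
    row <- data.frame(epoch = ep, total = tot_sum / n,
                      similarity = comp_sum[["similarity"]] / n,
                      dice = comp_sum[["dice"]] / n, ae = comp_sum[["ae"]] / n,
                      val_tre_h = NA_real_)
    if (!is.na(tail_start) && ep >= tail_start) {
      cur <- params_flatten(net$params)
      tail_sum <- if (is.null(tail_sum)) cur else tail_sum + cur
      tail_n <- tail_n + 1L
    }
    if (length(val_cases) > 0L && (ep %% cfg$val_every == 0L || ep == cfg$epochs)) {
      vt <- val_tre_of()
      row$val_tre_h <- vt
      if (vt < best$tre) best <- list(tre = vt, flat = params_flatten(net$params), epoch = ep)
    }
    log <- rbind(log, row)
    if (verbose) message(sprintf(
      "epoch %3d  total %.5f  sim %.5f  dice %.4f  ae %.4f  valTRE_H %s",
      ep, row$total, row$similarity, row$dice, row$ae,
      ifelse(is.na(row$val_tre_h), "-", sprintf("%.2f", row$val_tre_h))))
  }
  # candidate selection on the validation split: tail average vs best epoch
  if (!is.null(tail_sum) && tail_n > 0L) {
    params_restore(net$params, tail_sum / tail_n)
    avg_tre <- val_tre_of()
    if (!is.null(best$flat) && is.finite(best$tre) && !is.na(avg_tre) &&
        best$tre < avg_tre) {
      params_restore(net$params, best$flat)
    } else if (!is.na(avg_tre)) {
      best <- list(tre = avg_tre, flat = NULL, epoch = NA_integer_)
    }
  } else if (!is.null(best$flat)) params_restore(net$params, best$flat)
  if (!is.null(ace_dae)) {
    stopifnot(identical(ace_hash_before, sum(params_flatten(ace_dae$params))))
  }
  structure(list(net = net, cfg = cfg, metric_dae = metric_dae,
                 ace_dae = ace_dae, log = log, best_epoch = best$epoch),
            class = "swr_reg_model")
}

#' @export
print.swr_reg_model <- function(x, ...) {
  cat("<swr_reg_model> trained", max(x$log$epoch), "epochs; final total loss",
      format(x$log$total[nrow(x$log)], digits = 4))
  if (!is.na(x$best_epoch)) cat("; best validation epoch", x$best_epoch)
  cat("\n")
  invisible(x)
}

#' Register a moving volume to a fixed volume
#'
#' A single forward pass of the trained network; no segmentations are needed
#' at inference time.
#'
#' @param net A `swr_swin_net` or `swr_reg_model`.
#' @param fixed,moving `swr_volume` pair on the same geometry.
#' @return List: `params` (`swr_rigid_params`), `matrix` (4x4), `warped`
#'   (moving resampled by the predicted transform), `center`.
#' @export
register_pair <- function(net, fixed, moving) {
  if (inherits(net, "swr_reg_model")) net <- net$net
  if (!same_geometry(fixed, moving)) stop("fixed and moving must share geometry")
  ctr <- volume_center(fixed)
  fw <- swin_forward(net, norm01(fixed$voxels), norm01(moving$voxels), center = ctr)
  fld <- matrix_to_field(fw$matrix, dim(fixed$voxels), fixed$spacing, fixed$origin)
  list(params = fw$params, matrix = fw$matrix,
       warped = warp_volume(moving, fld), center = ctr)
}

#' Evaluate a model (or the recorded ground truth) on a dataset split
#'
#' Per case: register, warp the moving segmentation and landmarks by the
#' predicted matrix, and compute DSC / SSIM / TRE_H / TRE_N against the fixed
#' side. The "initial" row uses the identity transform (no registration);
#' `use_true_params` substitutes the recorded misalignment's inverse for the
#' network (ground-truth closure).
#'
#' @param manifest Dataset manifest.
#' @param model A `swr_reg_model` (ignored when `use_true_params`).
#' @param split Which split to evaluate.
#' @param use_true_params Evaluate the recorded true transform instead.
#' @param initial Also return the unregistered (identity) metrics.
#' @return List: `per_case`, `summary`, and when `initial`, `initial_per_case`,
#'   `initial_summary`.
#' @export
evaluate_model <- function(manifest, model = NULL, split = "test",
                           use_true_params = FALSE, initial = TRUE) {
  cases <- Filter(function(cs) cs$split == split, manifest$cases)
  if (length(cases) == 0L) stop("no cases in split ", split)
  rows <- data.frame(); irows <- data.frame()
  for (cs in cases) {
    d <- load_case(manifest, cs)
    sh <- dim(d$fixed$voxels)
    if (use_true_params) {
      A <- invert_matrix(params_to_matrix(rigid_params(cs$true_params$t, cs$true_params$r),
                                          as.numeric(cs$center)))
      t0 <- Sys.time()
      fld <- matrix_to_field(A, sh, d$fixed$spacing, d$fixed$origin)
      warped <- warp_volume(d$moving, fld)
      dt <- as.numeric(Sys.time() - t0, units = "secs")
    } else {
      t0 <- Sys.time()
      r <- register_pair(model, d$fixed, d$moving)
      dt <- as.numeric(Sys.time() - t0, units = "secs")
      A <- r$matrix
      fld <- matrix_to_field(A, sh, d$fixed$spacing, d$fixed$origin)
      warped <- r$warped
    }
    wseg <- warp_segmentation(d$moving_seg, fld)
    wlms <- transform_landmarks(d$moving_lms, A)
    rows <- rbind(rows, cbind(case = cs$case_id,
                              metrics_report(d$fixed, warped, d$fixed_seg, wseg,
                                             d$fixed_lms, wlms, time_s = dt)))
    if (initial) {
      irows <- rbind(irows, cbind(case = cs$case_id,
                                  metrics_report(d$fixed, d$moving, d$fixed_seg,
                                                 d$moving_seg, d$fixed_lms,
                                                 d$moving_lms, time_s = 0)))
    }
  }
  out <- list(per_case = rows, summary = aggregate_metrics(rows))
  if (initial) {
    out$initial_per_case <- irows
    out$initial_summary <- aggregate_metrics(irows)
  }
  out
}

#' Train and compare constraint-ablation variants
#'
#' Variants: `full` (head-structure constraints; the default method),
#' `noseg` (no segmentations), `allseg` (all five structures), `dice_only`
#' (lambda_ae = 0) and `ae_only` (lambda_dice = 0). All variants share the
#' dataset and the training seed.
#'
#' @param manifest Dataset manifest.
#' @param variants Character vector of variant names.
#' @param cfg Base [train_config()].
#' @param metric_dae,ace_dae Pretrained DAEs; a variant whose structure set
#'   does not match `ace_dae` gets a freshly pretrained matching encoder.
#' @param verbose Passed through to training.
#' @return List: `models` (per variant), `table` (one metrics row per variant).
#' @export
ablation <- function(manifest, variants = c("full", "noseg", "allseg",
                                            "dice_only", "ae_only"),
                     cfg = train_config(), metric_dae = NULL, ace_dae = NULL,
                     verbose = FALSE) {
  known <- c("full", "noseg", "allseg", "dice_only", "ae_only")
  bad <- setdiff(variants, known)
  if (length(bad)) stop("unknown variant(s): ", paste(bad, collapse = ", "))
  models <- list(); tab <- data.frame()
  for (v in variants) {
    vcfg <- cfg
    if (v == "noseg") {
      vcfg$structures <- "none"
      vcfg$weights$lambda_dice <- 0; vcfg$weights$lambda_ae <- 0
    } else if (v == "allseg") vcfg$structures <- "all"
    else if (v == "dice_only") vcfg$weights$lambda_ae <- 0
    else if (v == "ae_only") vcfg$weights$lambda_dice <- 0
    v_ace <- ace_dae
    sidx_v <- structure_indices(vcfg$structures, manifest$structures)
    if (length(sidx_v) > 0L && vcfg$weights$lambda_ae > 0 &&
        (is.null(v_ace) || v_ace$cfg$in_channels != length(sidx_v))) {
      v_ace <- pretrain_ace(manifest, structures = vcfg$structures, seed = cfg$seed)
    }
    m <- train_registration(manifest, vcfg, metric_dae, v_ace, verbose = verbose)
    ev <- evaluate_model(manifest, m, initial = FALSE)
    mu <- ev$summary[ev$summary$stat == "mean", ]
    tab <- rbind(tab, cbind(variant = v, mu[, c("DSC", "SSIM", "TRE_H", "TRE_N", "time")]))
    models[[v]] <- m
  }
  list(models = models, table = tab)
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load model checkpoints
#'
#' Single-file checkpoints holding the configuration and all parameter values;
#' `load_checkpoint` rebuilds the object and restores weights exactly.
#'
#' @param obj A `swr_swin_net`, `swr_dae` or `swr_reg_model`.
#' @param path Destination file.
#' @export
save_checkpoint <- function(obj, path) {
  pack_net <- function(o) list(kind = class(o)[1], cfg = o$cfg,
                               input_shape = o$input_shape,
                               values = lapply(o$params, function(p) p$value))
  payload <- if (inherits(obj, "swr_reg_model")) {
    list(kind = "swr_reg_model", cfg = obj$cfg, net = pack_net(obj$net),
         metric_dae = if (!is.null(obj$metric_dae)) pack_net(obj$metric_dae),
         ace_dae = if (!is.null(obj$ace_dae)) pack_net(obj$ace_dae),
         log = obj$log, best_epoch = obj$best_epoch)
  } else pack_net(obj)
  saveRDS(payload, path)
  invisible(path)
}

unpack_net <- function(pl) {
  obj <- if (pl$kind == "swr_swin_net") swin_net(pl$cfg)
  else dae_net(pl$cfg, pl$input_shape)
  for (nm in names(pl$values)) obj$params[[nm]]$value <- pl$values[[nm]]
  obj
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  pl <- readRDS(path)
  if (pl$kind == "swr_reg_model") {
    structure(list(net = unpack_net(pl$net), cfg = pl$cfg,
                   metric_dae = if (!is.null(pl$metric_dae)) unpack_net(pl$metric_dae),
                   ace_dae = if (!is.null(pl$ace_dae)) unpack_net(pl$ace_dae),
                   log = pl$log, best_epoch = pl$best_epoch),
              class = "swr_reg_model")
  } else unpack_net(pl)
}
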