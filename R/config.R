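# YAML configuration: one nested document drives data generation, DAE
# pretraining, model layout, loss selection and the training loop.

#' Default pipeline configuration
#'
#' The `train` and `loss` sections carry the reference protocol defaults
#' (Adam, learning rate 1e-4, batch size 1, 500 epochs; lambda_dice = 1,
#' lambda_ae = 0.1, pyramid weights 1, 0.5, 0.5); the `data` and `model`
#' sections default to the desk-scale phantom setting (64 x 64 x 32 at
#' 2 x 2 x 4 mm, embedding width 16).
#'
#' @return Nested list of sections: data, dae, model, loss, train.
#' @export
default_config <- function() {
  list(
    data = list(dir = "phantom_data", n_pairs = 24L, shape = c(64L, 64L, 32L),
                spacing = c(2, 2, 4), seed = 1L, split = c(0.7, 0.1, 0.2),
                deform_magnitude_mm = 3, boundary_fraction = 0.5,
                intensity_offset = 40, streak_amplitude = 30, noise_sigma = 20,
                rot_range_deg = 3, trans_range_vox = 3),
    dae = list(epochs = 25L, lr = 2e-3, latent_img = 128L, latent_seg = 64L,
               base_channels = 8L, depth = 3L, seed = 0L),
    model = list(embed_dim = 16L, window = c(4L, 4L, 4L),
                 heads = c(2L, 4L, 8L, 16L), mlp_ratio = 4, head_hidden = 64L,
                 scale_t = c(12, 12, 24), scale_r = 12),
    loss = list(similarity = "perceptual", lambda_dice = 1, lambda_ae = 0.1,
                omega = c(1, 0.5, 0.5), structures = "head"),
    train = list(lr = 1e-4, batch_size = 1L, epochs = 500L, seed = 0L,
                 aug_rot_deg = 3, aug_trans_vox = 3, val_every = 10L)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]]))
      merge_config(base[[nm]], override[[nm]]) else override[[nm]]
  }
  base
}

#' Load a YAML configuration, filling unset keys with defaults
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

#' Build typed objects from a configuration
#'
#' @param cfg Nested list from [load_config()].
#' @return List: `phantom_spec`, `swin_config`, `train_config`.
#' @export
config_objects <- function(cfg) {
  ps <- phantom_spec(shape = cfg$data$shape, spacing = cfg$data$spacing,
                     seed = cfg$data$seed,
                     intensity_offset = cfg$data$intensity_offset,
                     streak_amplitude = cfg$data$streak_amplitude,
                     noise_sigma = cfg$data$noise_sigma,
                     deform_magnitude_mm = cfg$data$deform_magnitude_mm,
                     boundary_fraction = cfg$data$boundary_fraction,
                     rot_range_deg = cfg$data$rot_range_deg,
                     trans_range_vox = cfg$data$trans_range_vox)
  sc <- swin_config(embed_dim = cfg$model$embed_dim, window = cfg$model$window,
                    heads = cfg$model$heads, mlp_ratio = cfg$model$mlp_ratio,
                    head_hidden = cfg$model$head_hidden,
                    input_shape = cfg$data$shape,
                    scale_t = cfg$model$scale_t, scale_r = cfg$model$scale_r)
  tc <- train_config(lr = cfg$train$lr, batch_size = cfg$train$batch_size,
                     epochs = cfg$train$epochs, seed = cfg$train$seed,
                     aug_rot_deg = cfg$train$aug_rot_deg,
                     aug_trans_vox = cfg$train$aug_trans_vox,
                     similarity = cfg$loss$similarity,
                     weights = loss_weights(cfg$loss$omega, cfg$loss$lambda_dice,
                                            cfg$loss$lambda_ae),
                     structures = cfg$loss$structures,
                     swin = sc, val_every = cfg$train$val_every)
  list(phantom_spec = ps, swin_config = sc, train_config = tc)
}
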