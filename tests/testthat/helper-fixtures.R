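# Shared fixtures, built lazily once per test run and memoized.
# Heavy artifacts (datasets, pretrained DAEs, the trained study model) are
# reused across test files so the suite stays within a desk-scale budget.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# A smooth random test volume in [0, 1].
smooth_volume <- function(shape = c(16L, 16L, 8L), seed = 1L, sigma = c(2, 2, 1.5)) {
  set.seed(seed)
  x <- array(rnorm(prod(shape)), shape)
  x <- swinreg:::cpp_gaussian_blur3d(x, as.integer(shape), sigma)
  (x - min(x)) / diff(range(x))
}

# Tiny reduced Swin configuration used across network tests (32 x 32 x 16).
tiny_swin_cfg <- function() swin_config(embed_dim = 8L, window = c(4L, 4L, 4L),
                                        heads = c(2L, 2L, 2L, 2L), head_hidden = 16L,
                                        input_shape = c(32L, 32L, 16L))

# ---- parameter-recovery study (64 x 64 x 32 phantoms) ----------------------
# Network and optimizer settings of the desk-scale study: embedding width 16,
# flattened regression head of width 256, output scales matched to the
# augmented +/-3 voxel / +/-3 degree misalignment range, frozen backbone,
# batch accumulation 8, head learning rate 3e-3 stepped down to 1e-3 after
# two thirds of the epochs, gradient clip 5.

study_swin_cfg <- function(input_shape = c(64L, 64L, 32L), spacing = c(2, 2, 4))
  swin_config(embed_dim = 16L, window = c(4L, 4L, 4L),
              heads = c(2L, 4L, 8L, 16L), head_hidden = 256L,
              input_shape = input_shape,
              scale_t = 2 * 3 * spacing, scale_r = 2 * 3 * 2)

study_train_cfg <- function(epochs, structures = "head", seed = 0L,
                            input_shape = c(64L, 64L, 32L), spacing = c(2, 2, 4)) {
  w <- loss_weights()
  if (structures == "none") { w$lambda_dice <- 0; w$lambda_ae <- 0 }
  train_config(lr = 0, head_lr = 3e-3, batch_size = 8L, epochs = epochs,
               seed = seed, structures = structures, weights = w,
               swin = study_swin_cfg(input_shape, spacing),
               grad_clip = 5, lr_decay = 1 / 3, val_every = 10L)
}

study_spec <- function(seed = 500L, deform = 0)
  phantom_spec(shape = c(64L, 64L, 32L), spacing = c(2, 2, 4), seed = seed,
               deform_magnitude_mm = deform)

# 24 undeformed phantom pairs: 16 train / 2 val / 6 test.
dataset_undeformed <- function() fixture("ds_undeformed", function() {
  make_dataset(24, study_spec(seed = 500L, deform = 0),
               file.path(tempdir(), "swr_ds_undeformed"),
               split = c(16, 2, 6) / 24, deform = FALSE)
})

# DAEs pretrained on the undeformed training split.
study_daes <- function() fixture("daes", function() {
  pretrain_daes(dataset_undeformed(), structures = "head", epochs = 8L,
                lr = 2e-3, seed = 0L)
})

# The reduced registration model trained on the undeformed dataset.
study_model <- function() fixture("model", function() {
  daes <- study_daes()
  train_registration(dataset_undeformed(), study_train_cfg(epochs = 120L),
                     daes$metric_dae, daes$ace_dae)
})

# ---- head-focus study (neck-deformed phantoms, 48 x 48 x 24) ---------------

focus_spec <- function(seed = 900L)
  phantom_spec(shape = c(48L, 48L, 24L), spacing = c(2, 2, 4), seed = seed,
               deform_magnitude_mm = 3)

# 14 neck-deformed phantom pairs: 10 train / 1 val / 3 test.
dataset_deformed <- function() fixture("ds_deformed", function() {
  make_dataset(14, focus_spec(seed = 900L),
               file.path(tempdir(), "swr_ds_deformed"),
               split = c(10, 1, 3) / 14, deform = TRUE)
})

deformed_daes <- function() fixture("daes_deformed", function() {
  pretrain_daes(dataset_deformed(), structures = "head", epochs = 6L,
                lr = 2e-3, seed = 0L)
})

focus_cfg <- function(structures)
  study_train_cfg(epochs = 50L, structures = structures, seed = 0L,
                  input_shape = c(48L, 48L, 24L), spacing = c(2, 2, 4))

# ---- tiny fixtures for fast pipeline mechanics tests -----------------------

tiny_dataset <- function() fixture("ds_tiny", function() {
  make_dataset(5, phantom_spec(shape = c(32L, 32L, 16L), spacing = c(2, 2, 4),
                               seed = 42L, deform_magnitude_mm = 0),
               file.path(tempdir(), "swr_ds_tiny"), split = c(3, 1, 1) / 5,
               deform = FALSE)
})

tiny_daes <- function() fixture("daes_tiny", function() {
  pretrain_daes(tiny_dataset(), epochs = 3L, lr = 2e-3, base_channels = 4L,
                latent_img = 32L, latent_seg = 16L, seed = 0L)
})
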