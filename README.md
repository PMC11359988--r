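# swinreg

Weakly supervised 3D **rigid registration of head-neck CBCT to planning CT**
for image-guided radiotherapy, with accuracy deliberately biased toward the
head region.

In head-neck radiotherapy the daily cone-beam CT (CBCT) must be aligned to
the planning CT by a rigid transform (couch corrections allow rotation and
translation only). Two things make this hard: CBCT intensities are shifted,
shaded and noisy relative to CT, and the flexible neck changes posture
between scans, so no single rigid transform fits head and neck at once —
while the anatomy that matters most (eyes, optic nerves, brainstem) sits in
the head. `swinreg` implements a registration network that addresses both.

## Method

A Swin-Transformer regression network predicts the six rigid parameters
directly from the image pair:

```
G(F, M) = [t, r],   t, r ∈ R^3        (translation mm, rotation deg)
A = T · R,          M(φ(A)) = warped moving image
```

The network is a 2-channel patch embedding (kernel 7, stride 4) followed by
four stages of convolution + Swin block (windowed multi-head self-attention
`softmax(QK^T/√d)V` with alternating half-window shifts), a final LayerNorm,
and two fully connected layers over the flattened final-stage features
(flattening, not pooling, preserves the spatial arrangement that encodes
rotation). Training minimizes

```
L = L_perceptual + λ_ae · L_ae + λ_dice · L_dice     (λ_dice = 1, λ_ae = 0.1)
```

* `L_perceptual = Σ_i ω_i ‖R_i(F) − R_i(M(φ))‖_1`, ω = (1, 0.5, 0.5), where
  `R_i` are the first three encoder layers of a 3D denoising autoencoder
  pretrained on the images — a modality-robust alternative to voxel-wise
  similarity;
* `L_dice` is a smoothed soft Dice over the warped one-hot segmentations of
  selected structures;
* `L_ae = ‖ACE(SF) − ACE(SM(φ))‖²_2` compares latent codes of a second,
  segmentation-trained autoencoder (the anatomical constraint encoder).

By default the two constraint terms use only the head structures, which is
what biases accuracy toward the head. Segmentations are needed **only during
training** — inference takes just the two volumes.

Because no deep-learning runtime is available in this environment, the
package ships its own reverse-mode autodifferentiation tape with compiled
C++ kernels (direct 3D convolution, trilinear warping with analytic
gradients in the six rigid parameters); every gradient path is
finite-difference-tested.

A seeded phantom generator produces head-neck-like CT volumes with five
labelled structures (eyes, optic nerve, brainstem, spinal cord, larynx), ten
landmarks per region, CBCT-style degradation, and a smooth neck-only
deformation (a bend plus random field that vanishes above the head/neck
boundary) — reproducing the study conditions at desk scale. Evaluation
reports Dice overlap (DSC), 3D SSIM and head/neck landmark target
registration error (TRE_H / TRE_N, mm).

## Worked example

```r
library(swinreg)

## 16 phantom pairs (48 x 48 x 24 @ 2 x 2 x 4 mm; 10 train / 3 val / 3 test),
## misaligned by up to +/-3 degrees and +/-3 voxels, with neck deformation
## on the moving side
man <- make_dataset(16, phantom_spec(shape = c(48L, 48L, 24L), seed = 1),
                    "phantoms", split = c(10, 3, 3) / 16)

## pretrain the perceptual metric network and the anatomical constraint
## encoder, then train the registration network (desk-scale protocol:
## frozen backbone, batch accumulation 8, head learning rate 3e-3 with a
## step decay, outputs scaled to the misalignment range)
daes <- pretrain_daes(man, epochs = 6)
cfg <- train_config(lr = 0, head_lr = 3e-3, batch_size = 8L, epochs = 120,
                    seed = 0, grad_clip = 5, lr_decay = 1/3,
                    swin = swin_config(embed_dim = 16L, window = c(4L, 4L, 4L),
                                       heads = c(2L, 4L, 8L, 16L),
                                       head_hidden = 256L,
                                       input_shape = c(48L, 48L, 24L),
                                       scale_t = c(12, 12, 24), scale_r = 12))
model <- train_registration(man, cfg, daes$metric_dae, daes$ace_dae)

## register a test pair (no segmentations needed at inference)
d <- read_volume("phantoms/case_016/fixed.nii.gz")
m <- read_volume("phantoms/case_016/moving.nii.gz")
r <- register_pair(model, d, m)
r$params
#> <swr_rigid_params> t = (-0.1114,  3.1115,  6.2906) mm, r = (-1.6585, -1.4270, -0.8446) deg

## evaluate against the identity ("initial") baseline on the test split
ev <- evaluate_model(man, model)
ev$initial_summary
#>   stat        DSC       SSIM    TRE_H     TRE_N time n
#> 1 mean 0.22715043 0.19525306 7.905624 7.7723478    0 3
#> 2   sd 0.04074366 0.01600623 1.282341 0.6594813    0 3
ev$summary
#>   stat       DSC       SSIM    TRE_H    TRE_N  time n
#> 1 mean 0.5698676 0.26181912 3.735922 3.430988 0.145 3
#> 2   sd 0.2084171 0.03587105 1.817296 1.257286 0.055 3
```

`r$params` is the predicted rigid correction (translation in mm, rotation in
degrees about the volume centre). The summary rows report mean ± sd of Dice
overlap, 3D SSIM, and head/neck landmark error in mm over the held-out test
pairs: here registration cuts TRE_H from 7.9 to 3.7 mm and TRE_N from 7.8 to
3.4 mm (both by more than half) and more than doubles the Dice overlap,
from a standing start of ±3-degree / ±3-voxel misalignments on degraded,
neck-deformed phantoms. The `ablation()` helper retrains the loss variants
(no segmentations / all structures / single constraint terms) on identical
seeds and data for comparison, and `exec/swinreg` exposes the same pipeline
as a command line (`make-data`, `pretrain-dae`, `train`, `register`,
`evaluate`, `ablation`).

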