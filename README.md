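# axialseg

Medical image segmentation with little labeled data, in two coupled parts:

1. **Deformable-model augmentation.** A statistical shape model (point
   distribution model) is fitted to annotated object contours after
   generalized Procrustes alignment: `s = s̄₀ + E b`, with mode matrix `E`
   and eigenvalues `λ`. New plausible contours are sampled inside the
   hyperrectangle `|b_j| ≤ 1.5 √λ_j` and filled with realistic texture
   pulled from real images through a 2D thin-plate spline
   `f(x,y) = a₁ + a₂x + a₃y + Σ wᵢ U(‖pᵢ−(x,y)‖)`, `U(r) = r² log r²`.
   The training set grows by a configured fraction (default 30%).
2. **A dual-branch gated axial-attention network.** Axial self-attention
   factors 2D attention into height and width passes; learnable scalar
   gates `G_Q, G_K, G_V1, G_V2` down-weight relative-position terms that
   small datasets cannot estimate reliably. A shallow global branch sees
   the whole image; a deeper local branch processes a 4×4 grid of 16
   patches with one shared sub-network; features are fused and projected
   to a per-pixel probability map, trained with binary cross-entropy
   (Adam, defaults lr 1e-4, 25 epochs, batch 4) and evaluated with
   DSC = 2|X∩Y|/(|X|+|Y|), IoU and Recall.

Everything runs on CPU: all layers carry hand-derived backward passes
(the attention core in RcppArmadillo), and a seeded synthetic fixture
generator makes the whole pipeline testable without external data. The
package is aimed at method developers who want a transparent, fully
inspectable reference implementation rather than a GPU training harness.

## Worked example

```r
library(axialseg)

# 1. synthetic labeled data: 20 organ-like blobs with corresponding landmarks
real <- make_blob_dataset(n = 20, image_size = 48, n_landmarks = 20, seed = 17)

# 2. statistical shape model from the annotated contours
model <- fit_ssm_from_samples(real)
model
#> <shape_model> 20 landmarks, 8 modes, leading mode explains 32.7% of retained variance

# 3. grow the training set by 30% with simulated, textured samples
aug <- augment_dataset(real, model, augment_config(fraction = 0.30, seed = 2))
length(aug)                       # 20 real + round(0.3 * 20) simulated
#> [1] 26
aug[[26]]
#> <seg_sample> 48x48 gray, mask area 356 px, contour with 20 landmarks
round(aug[[26]]$meta$b, 4)        # mode coefficients, all inside 1.5*sqrt(lambda)
#> [1]  0.0123  0.0088 -0.0117  0.0077  0.0047 -0.0114 -0.0031  0.0068

# 4. train the dual-branch gated axial-attention network at toy scale
cfg <- network_config(in_channels = 1, base_channels = 4, global_depth = 1,
                      local_depth = 1, n_heads = 2, input_size = c(48, 48))
fit <- train(aug, net_config = cfg,
             train_cfg = train_config(learning_rate = 0.01, epochs = 60,
                                      batch_size = 4, seed = 1))
fit
#> <seg_fit> 60 epochs, final loss 0.08059

# 5. evaluate on the real samples
evaluate(fit, real)
#> <eval_report> n = 20  DSC 0.9702  IoU 0.9424  Recall 0.9473
```

The shape model keeps the modes explaining 98% of contour variance; the
simulated sample's `b` vector is its position in shape space; the final
report gives mean overlap between thresholded predictions (sigmoid ≥ 0.5)
and the reference masks — here the small network segments the held
training distribution almost perfectly after 60 epochs.

A thin command-line front end over the same functions lives at
`inst/cli/axialseg.R` (subcommands `fixtures`, `augment`, `train`, `eval`,
`demo`).

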