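# lungfat

Two-stage analysis of axial chest-CT slice sequences in plain R:

1. **Lung slice localization.** A convolutional bidirectional GRU
   (ConvBiGRU) classifies the center slice of each sliding window of
   L ∈ {3, 5, 7} consecutive slices as *first lung slice* (0), *other* (1)
   or *last lung slice* (2), bracketing the lung region of a chest series.
   Localization error is reported as the mean physical distance
   MD = Σ |No_pred − No_true| · sp_t / N in millimetres, where sp_t is the
   inter-slice spacing.
2. **Adipose tissue segmentation.** A UNet segments subcutaneous (SAT) or
   visceral (VAT) adipose tissue on the selected slice range. Three
   optional skip-pathway blocks — multi-resolution fusion (MR),
   competitive Maxout (CP) and an additive attention gate (ATTN) — can be
   enabled in any of the 2³ combinations, giving a built-in ablation
   harness. Training minimizes the smoothed Dice loss
   DCL = 1 − (κ + 2Σ y_t y_p)/(κ + Σ y_t² + Σ y_p²) with κ = 1, optionally
   plus an additive class-weight penalty W = 1/log(α + w), α = 1.1, by
   stochastic gradient descent with momentum β = 0.9.

The package is aimed at medical-image-analysis researchers who want a
fully inspectable, dependency-light reference implementation of this
two-stage design: every forward pass and every gradient is written in R
(im2col convolutions on BLAS), so each formula can be read, tested and
modified directly. A seeded phantom generator produces 16-bit slice
sequences with known SAT/VAT masks and localization labels, so the whole
pipeline — file formats included — is exercisable and testable without any
clinical data.

## Worked example

```r
library(lungfat)

# a phantom volume with known anatomy: lungs span slices 3..8
vol <- generate_volume(phantom_spec(n_slices = 12, image_size = 64,
                                    lung_first = 3, lung_last = 8,
                                    spacing_mm = 2.5, seed = 42))
table(vol$loc_labels)
#>  0  1  2
#>  1 10  1

# class-weight penalties for this volume's window labels (natural log,
# alpha = 1.1): the rare boundary classes get the large weights
wins <- make_windows(vol$slices, vol$loc_labels, L = 5)
counts <- tabulate(vapply(wins, function(w) w$label, integer(1)) + 1L, 3L)
round(compute_class_weights(counts, alpha = 1.1)$W, 4)
#> [1] 4.9275 1.6255 4.9275

# localization error in physical units: predictions (3, 7) against truths
# (1, 7) at spacings 2 mm and 5 mm -> (|3-1|*2 + 0)/2 = 2 mm
mean_distance(c(3, 7), c(1, 7), spacing_mm = c(2, 5))
#> [1] 2

# train a small MR+ATTN UNet on this volume's six SAT slices
samples <- make_seg_samples(vol, "SAT")
cfg <- unet_config(use_mr = TRUE, use_attn = TRUE,
                   depth = 3, base_channels = 8)
m <- train_segmenter(samples, cfg, epochs = 80, lr = 0.3,
                     dice_target = 0.9, seed = 7)
tail(m$history, 1)
#>    epoch     loss      dice
#> 45    45 6.072668 0.9031395
evaluate_segmenter(m, samples)
#> <metrics: dice 0.914, f1 0.914, precision 0.899, recall 0.930 (n = 6)>
```

Training stops at epoch 45, when the epoch's mean training Dice
(binarized at 0.5) first reaches the 0.9 target; the reported loss is the
Dice loss plus the additive foreground class-weight penalty, which shifts
its level but not its gradients. The metrics line gives per-image
averaged Dice, F1, precision and recall of the binarized predictions on
the six training slices.

The end-to-end pipeline (phantom generation → localizer training →
lung-range selection → SAT/VAT segmentation → manifest) runs via

```r
run_pipeline(pipeline_config(out_dir = "runs/demo", seed = 1))
```

and a thin command-line wrapper lives at `inst/cli/lungfat.R`
(`phantom`, `run`, `ablate` subcommands).

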