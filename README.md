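# cxrseg

Semantic segmentation of chest radiograph-like grayscale images — lungs,
heart, and clavicles plus background — with gradient-based edge enhancement
feeding a U-Net, for researchers studying how classical contour operators
interact with deep segmentation models, and as a fully self-contained,
CPU-scale testbed for that pipeline.

## What it implements

* **Edge operators** (`convolve3x3`, `edge_map`): the gradient correlation
  sums g\_x(i,j) = Σ\_u Σ\_v I(i+u, j+v)·k\_x(u+1, v+1) with the standard
  Sobel (±1/±2) and Scharr (±3/±10) kernel pairs, combined into the total
  gradient g = √(g\_x² + g\_y²); three border modes; plus CLAHE and adaptive
  mean thresholding for artifact suppression, and `enhance_image()` which
  blends the normalized edge magnitude into the network input.
* **A from-scratch U-Net** (`build_unet`, `train_model`): encoder/decoder
  with skip connections and per-channel **sigmoid** output (multi-label —
  classes may overlap), trained with the class-weighted focal loss
  FL = −α\_t (1−p\_t)^γ log p\_t, inverse-frequency class weights
  (mean-normalized), Adam, and a polynomial learning-rate decay
  lr(s) = (lr₀ − lr\_end)(1 − s/S)^p + lr\_end. Convolutions run as
  im2col + BLAS products; backward passes are exact analytic gradients
  checked against finite differences.
* **Evaluation** (`dice`, `jaccard`, `evaluate_model`, `cross_validate`,
  `paired_t_test`): per-class accuracy / Dice / Jaccard, the combined
  objective (mean Dice + mean Jaccard over structure classes, in [0,2]),
  80:20 hold-out and stratified k-fold protocols, and an exact paired
  t-test for method comparison.
* **Data pipeline** (`combine_masks`, `augment_dataset`, `split_dataset`):
  left/right mask merging with an appended background channel, ±5° rotation
  augmentation (exactly one copy per image, zero excluded), resizing and
  normalization, and leakage-guarded, optionally stratified splits.
* **Synthetic phantoms** (`generate_phantom`, `generate_dataset`): seeded,
  bit-reproducible chest-like images with exact ground truth and the
  characteristic imbalance lungs ≫ heart ≫ clavicles, so everything above
  is testable without external data.

## Worked example

```r
library(cxrseg)

train <- generate_dataset(16, phantom_spec(height = 64, width = 64, seed = 1))
test  <- generate_dataset(4,  phantom_spec(height = 64, width = 64, seed = 999))

cfg <- train_config(epochs = 60, batch_size = 2, seed = 7,
                    enhance = enhance_options(method = "sobel"))
fit <- train_model(train, unet_spec(depth = 2, base_filters = 8), cfg)

tail(fit$history[c("epoch", "train_loss", "train_acc", "lr")], 3)
#>    epoch  train_loss train_acc       lr
#> 58    58 0.006088327 0.9700661 5.95e-05
#> 59    59 0.006067699 0.9701576 4.30e-05
#> 60    60 0.006052242 0.9701767 2.65e-05

report <- evaluate_model(fit$model, test, cfg)
report
#> <metrics_report> n = 4, combined objective 1.7335
#>        class accuracy   dice jaccard
#> 1      lungs   0.9424 0.9037  0.8245
#> 2      heart   0.9928 0.9458  0.8974
#> 3  clavicles   0.9944 0.8652  0.7639
#> 4 background   0.9500 0.9630  0.9286
```

Reading the output: the history confirms the focal loss descending under
the decaying learning rate; the report gives per-class means over the four
held-out phantoms. Dice/Jaccard measure mask overlap (1 = pixel-perfect),
and the combined objective sums mean Dice and mean Jaccard over the three
structure classes, so 2 is perfect. Clavicles score lowest — they are the
thinnest, lowest-contrast class, which is exactly the imbalance the class
weights and focal loss are there to fight.

The same pipeline is scriptable from a shell via the bundled launcher
(`inst/cli/cxrseg`): `synth`, `enhance`, `train`, `eval`, and `cv`
subcommands, every run writing its fully resolved seeded configuration next
to its artifacts.

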