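# mismatch

Semi-supervised binary segmentation of medical images via consistency
between two decoders that learn *opposite morphological feature
perturbations*.

## The problem and the idea

Pixel-wise labels for medical images (CT vessel masks, MRI tumour masks)
are scarce and expensive, so semi-supervised methods try to exploit the
many unlabelled scans that accompany the few labelled ones. The dominant
recipe — make predictions invariant to input-level augmentations — works
poorly for segmentation, because pixels are densely distributed and the
low-density regions that consistency training seeks do not align with
object boundaries in image space.

MisMatch instead perturbs *features*, and learns the perturbations. One
shared encoder `f_e` feeds two decoders:

* decoder `f_d1` is built from **Positive Attention Shifting Blocks
  (PASB)**: each block gates its plain two-convolution main branch with
  `sigmoid` of a *dilated* side convolution. The gate's effective
  receptive field (ERF) exceeds the main branch's, which dilates
  high-confidence foreground;
* decoder `f_d2` uses **Negative Attention Shifting Blocks (NASB)**: the
  side branch has the same two convolution stages but wrapped in identity
  skip connections. A residual stack is an ensemble of short paths with
  binomial weights, so the gate's ERF is smaller than the main branch's,
  eroding high-confidence foreground.

The kernel-size conditions behind the two designs, for a feature map at
depth `n` with main kernel `K` and side kernel `K'`:

    ERF ratio (PASB):  (K'/K) * sqrt(1 / (1 + 1/(n+1)))  > 1
                       requires K' > sqrt(2) K; doubled by design,
                       so K' = 9 for K = 3 (dilation rate 5)

    ERF ratio (NASB):  p^2 sqrt(1/(1+2/n)) + 2p(1-p) sqrt(1/(1+1/(n+1))) + (1-p)^2
                       < 1 for every finite n (p = 0.5)

Training minimises a soft Dice loss on labelled items and an
`alpha`-weighted mean-squared error between the batch-normalised paired
predictions on unlabelled items (streaming or combined schedule). The
final prediction is the average of the two decoder outputs, and the final
model averages the checkpoints of the last 10 epochs.

The package also ships pixel-wise calibration analysis (per-bin accuracy
and confidence, expected calibration error, reliability diagrams),
IoU/Dice/Hausdorff/ASD segmentation metrics, an empirical gradient-probe
ERF measurement, and a synthetic phantom generator (tubular vessels,
ellipsoidal tumours, 2D and 3D) that builds fully reproducible
labelled/unlabelled benchmarks — so everything is testable without any
clinical data. The small convolutional networks themselves (2D/3D
convolutions, instance norm, pooling, Adam, backpropagation) are
implemented inside the package as a compact layer library.

## Worked example

```r
library(mismatch)

# a reproducible benchmark: 5 labelled + 100 unlabelled 64x64 phantoms
bench <- make_benchmark(
  split_spec(n_labelled = 5, n_unlabelled = 100, n_val = 0, n_test = 10),
  phantom_spec(seed = 1))

# the full dual-decoder network and the supervised single-decoder baseline
mm  <- build_network(network_spec(dims = 2, base_width = 4, depth = 3,
                                  decoder_variant = "MM", seed = 11))
sup <- build_network(network_spec(dims = 2, base_width = 4, depth = 3,
                                  decoder_variant = "unet", seed = 11))

cfg <- train_config(lr = 1e-2, epochs = 10, avg_last_k = 10, seed = 11)
fit_mm  <- train(mm,  bench, cfg, loss_config(alpha = 0.002))
fit_sup <- train(sup, bench, cfg, loss_config())

mean(evaluate_network(fit_mm$network,  bench$test)$iou)
#> [1] 0.9220353
mean(evaluate_network(fit_sup$network, bench$test)$iou)
#> [1] 0.7051243
```

With one labelled case's worth of data, the semi-supervised dual-decoder
model reaches a mean test IoU of 0.92 against 0.70 for supervised
training on the same five labelled images.

The analytic ERF design rules are one call away:

```r
minimal_side_kernel(3)        # 9  (doubled sqrt(2)*K condition, odd)
erf_ratio_pasb(3, 9, n = 1)   # 2.449...  (> 1: the gate sees further)
erf_ratio_nasb(1)             # 0.8026... (< 1: the gate sees less far)
```

and the empirical gradient probe confirms them on real weights:

```r
measure_empirical_erf(block_stack("pasb"), c(41, 41))
#> ERF gradient probe: support_area = 389 pixels above 0.01 of peak; centre at ( 21, 21 )
```

A thin command-line layer wraps the same functions
(`generate`, `train`, `evaluate`, `calibrate`, `erf-report`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mismatch.R", package="mismatch"))')" \
    erf-report --K 3 --K-side 9 --n-max 5
```

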