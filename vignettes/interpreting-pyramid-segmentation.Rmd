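---
title: "Interpreting pyramid-pooling segmentation with gradient-based class activation maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting pyramid-pooling segmentation with gradient-based class activation maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyrexcam)
```

## The problem

Convolutional segmentation networks for brain-tumor MRI are accurate but
opaque: a pyramid scene parsing (PSP) module demonstrably improves dice
scores, yet nothing in the score says *why*, or whether each pooling scale
contributes anything at all.  `pyrexcam` implements a compact pyramid
segmentation network together with gradient-weighted class activation
mapping (Grad-CAM) taken at three kinds of tap points — the backbone
features, each pyramid stage in isolation, and the concatenated multiscale
context features — so that the contribution of every scale can be seen,
binarized, and scored quantitatively against the model output and the
ground truth.

Everything runs on synthetic phantom slices by default, so the full
pipeline (data, training, attribution, evaluation, ablation) is exercised
end to end without any external download.  Real BraTS-layout NIfTI cases
are supported through the same `mri_io` interface.

## The segmentation model

The backbone is a small residual network.  Each block computes

$$y = F(x, \{W_i\}) + W_s x,$$

where $F$ is the learned two-convolution residual mapping and $W_s$ is a
learned 1×1 projection exactly when the channel count or resolution
changes (identity otherwise).  A stem convolution and three stride-2
blocks give ×8 downsampling: a 64×64 slice yields an 8×8 feature map
with 64 channels.

The pyramid module pools those features onto each of the configured output
grids (defaults 1×1, 2×2, 3×3, 6×6) by **adaptive average pooling** —
the scale values are output grid sizes, which is the only reading that
works for arbitrary input sizes.  Each pooled map passes through a 1×1
reduction convolution (default 16 channels), is bilinearly upsampled back
to 8×8, multiplied by its **stage weight** (default 1; the weighted
variant studied by the harnesses uses 1:2:2:1), and concatenated with the
original features: 64 + 4·16 = 128 channels.  Dropout (default 0.01)
follows the concatenation — the "drop rate" hyperparameter is read as a
dropout probability; it is isolated in `train_config()`/`build_pspnet()`
so the alternative weight-decay reading can be swapped in.  A decoder of
three learned ×2 deconvolutions (64, 32, 32 channels) and a final 1×1
convolution produces one score per pixel at input resolution; the sigmoid
of the score is the foreground probability.

Training minimizes the soft dice loss
$1 - (2\sum p g + 1)/(\sum p + \sum g + 1)$ with Adam.  Defaults: batch
size 8, 10 epochs, learning rate $10^{-4}$, fully seeded (shuffling,
dropout, and initialization all derive from explicit seeds, so runs are
bit-reproducible single-threaded).

### Architecture choices that were genuinely open

The backbone depth/width, decoder widths, initialization, and
normalization are not pinned down by the problem statement, and two
findings from building the package are worth recording:

* **Instance normalization is available but off by default.**  With the
  dice loss and the short default regime, per-channel mean removal blocks
  the one direction the optimizer needs first — a global shift of the
  score map that turns the initial all-foreground prediction off — and
  routes it through slowly moving bias terms.  In side-by-side runs at
  identical seeds the normalized model was still predicting everything
  foreground after 10 epochs while the unnormalized one had converged.
  `norm = TRUE` remains available on both builders.
* **The scoring head is He-initialized, not zero-initialized.**  A
  zero-initialized head wastes the first epochs (no gradient reaches the
  backbone until the head moves), which matters at a fixed small epoch
  budget.

## Grad-CAM for dense prediction

At a tap point with activations $A^k$ (channel $k$, spatial size
$Z = h \cdot w$), the attribution weight of each channel is the global
average pool of the backpropagated gradient of a scalar class score
$y^c$:

$$\alpha_k^c = \frac{1}{Z} \sum_i \sum_j
  \frac{\partial y^c}{\partial A^k_{ij}},$$

and the localization map is the rectified weighted sum

$$L^c = \mathrm{ReLU}\Big(\sum_k \alpha_k^c A^k\Big),$$

bilinearly upsampled to input resolution and min–max normalized to
$[0, 1]$ (an identically zero raw map is passed through with
`raw_max = 0` recorded).  Attribution needs no model modification or
retraining; the test suite asserts via parameter checksums that a frozen
checkpoint is bit-identical before and after computing every map.

**The class score for a dense head.**  Grad-CAM is defined for a scalar
$y^c$; a segmentation head produces a map.  `target_score()` sums the
class scores spatially, and `grad_cam()` by default restricts that sum to
the *predicted foreground* pixels.  The unrestricted full-image sum is
available (`restrict_to_prediction = FALSE`) but makes a poor default:
once the model is confident, its normalized map collapses onto a few
feature cells (in a converged run the 99th percentile of map values was
about 0.5 and the median 0), so binarizing at moderate thresholds selects
almost nothing.  Restricting the score to the predicted region — the
standard segmentation extension of Grad-CAM — produces maps that cover
the segmented structure and make the threshold analyses meaningful.  If
the prediction is empty the full sum is used as a fallback.

**Per-stage maps.**  A single pyramid stage, visualized alone, is nearly
meaningless (a 1×1-pooled stage is spatially constant).  `stage_cam()`
therefore fuses the backbone channels with *only* the chosen stage's
upsampled, weighted channels and attributes that fused map; the union of
the per-stage channel sets plus the backbone reproduces exactly the
concatenated feature set attributed by `psp_cam()`.

## Quantitative heat-map evaluation

`dice_coefficient()` implements the smoothed overlap
$(2|X \cap Y| + 1)/(|X| + |Y| + 1)$; the +1 keeps the value in $(0, 1]$
and defines two empty masks as perfect agreement.

`psnr_binary()` compares binary images with peak value 1, so the mean
squared error is the mismatch fraction and
$\mathrm{PSNR} = -10 \log_{10}(\text{mismatch fraction})$ dB.  Identical
images return `Inf`, which `psnr_curve()` excludes from its means with a
logged count.  `psnr_curve()` binarizes each normalized CAM at the
threshold grid 0.05–0.45 (step 0.05), compares against the predicted mask
(probability cut 0.5, configurable) and the ground truth, and averages
each series over images.  The binarization comparator is `>=`
(threshold-inclusive); this affects only exact ties.

## The phantom generator

`phantom_spec()` emulates what the pipeline needs from a Flair slice with
a whole-tumor lesion, nothing more:

| parameter | default | meaning |
|---|---|---|
| `image_size` | 64 px | square slice side |
| `n_lesions` | 1 | bright disks per slice |
| `lesion_radius_range` | 5–12 px | uniform radius draw |
| `lesion_intensity` | 0.85 | lesion level relative to image max |
| `halo_width` | 3 px | linear intensity decay around the rim |
| `noise_sigma` | 0.05 | additive Gaussian noise SD |
| `background_level` | 0.15 | parenchyma base intensity |

A slice is built as an elliptical "brain" of smoothly varying intensity
(base 0.15 plus a 0.30-amplitude coarse Gaussian field) on a dark
background, with lesion disks drawn uniformly inside the ellipse eroded
by the radius (so disks never touch the boundary), a halo decaying
linearly over `halo_width`, then noise, then clipping to $[0, 1]$.  The
contrast regime — lesion at 0.85 against parenchyma at 0.15–0.45 with
noise 0.05 — mirrors the strong hyperintensity of whole-tumor lesions on
Flair.  The mask is the union of the disks only (halos are image-only
texture).  Draw order is fixed (ellipse, then per lesion radius → centre,
then noise) so a manifest's per-sample seed regenerates any slice bit for
bit, and enlarging the radius range while holding the seed can only grow
the mask (the centre moves by at most the radius increment).

What the phantoms deliberately do **not** model: anatomy, multimodal
intensity physics, 3D lesion continuity across slices, partial-volume
boundaries.  Passing tests on phantoms demonstrates that the machinery —
optimization, attribution, evaluation — is correct and reproducible; it
does not certify segmentation quality on clinical data.

## Problem sizes and numerical choices

The end-to-end checks train the default network on 200 phantom slices
(64×64, one or two lesions) for the standard 10-epoch regime and evaluate
on 50 held-out slices; harness unit tests use 4–8 slices and 1–3 epochs.
These sizes are the package's chosen desk-scale study conditions: large
enough for the default regime to converge (held-out dice well above 0.7),
small enough to run anywhere.

Other conventions, fixed and documented rather than tuned: adaptive
pooling uses floor/ceil bin edges so bins tile the input exactly;
bilinear interpolation uses half-pixel centres (`align_corners = false`)
everywhere (stage upsampling, CAM upsampling, phantom fields);
per-slice min–max normalization for real volumes with the constant slice
mapping to zero; BraTS label sets WT = {1,2,4}, TC = {1,4}, ET = {4} with
Flair driving WT/TC and T1ce driving ET; slices with empty masks are kept
unless `drop_empty = TRUE`; the six-scale pyramid variant (scales up to
12) requires a 12×12 feature map, so the ablation harness widens its
input to 96×96 and records the widening.

## Limitations

* Training is CPU-bound, hand-rolled backpropagation; it is meant for
  desk-scale slices (≤ 128×128), not full 240×240 BraTS volumes.
* The default head is binary (whole tumor).  TC/ET plumbing exists via
  `target_spec()` but the experiments focus on WT.
* A training penalty that discourages redundant stage features (suggested
  by the scale-ablation observation that six scales tend to collapse onto
  the same regions) has no defined functional form and is not
  implemented.
* Attribution variants beyond Grad-CAM (Grad-CAM++, Score-CAM, guided
  backpropagation) are out of scope.

## A minimal session

```{r example, eval = FALSE}
data <- generate_dataset(32, phantom_spec(), seed = 1)
model <- build_pspnet(input_size = 64L, seed = 1)
tr <- train_model(model, data$samples,
                  train_config(epochs = 3, learning_rate = 1e-3, seed = 1))
s <- generate_phantom(phantom_spec(seed = 99))
predict(tr$model, s$image)$mask |> table()
cam <- psp_cam(tr$model, s$image)
write_overlay_png(cam_overlay(s$image, cam), "psp_cam.png")
```
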