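---
title: "Methods: the siamese pyramid fusion network and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the siamese pyramid fusion network and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spfn)
```

## The fusion problem and the model

A registered PET/CT pair shows the same anatomy through two physical
processes: CT attenuation (sharp edges, bone, lung fields, Hounsfield units)
and FDG uptake (smooth, low-resolution, hotspots at metabolically active
lesions). Fusion seeks one image retaining both. `spfn` learns the fusion
map `y = F(x_ct, x_pet)` end to end with a siamese autoencoder:

* **Encoder** (shared weights across both modalities): a 3 × 3 convolutional
  stem, a channel-attention gate (`sigmoid(MLP(avgpool) + MLP(maxpool))`,
  applied multiplicatively per channel), and a spatial-pyramid block that
  pools the features onto 16 × 16, 4 × 4, 2 × 2 and 1 × 1 grids, convolves
  each scale, upsamples each branch bilinearly and concatenates. The gated
  stem features, pyramid features and the raw image are channel-concatenated
  into the branch encoding — with the defaults, 16 + 4·8 + 1 = 49 channels.
* **Fusion**: a parameter-free cross-correlation layer. At each pixel the
  centered m × n patch (default 3 × 3) of the CT encoding is inner-producted
  with the PET-encoding patch displaced by multiples of the patch stride
  o = 3 within a search window of radius r strides, producing (2r + 1)²
  response channels under SAME zero padding, averaged over feature channels.
* **Decoder**: three stride-1 deconvolutional stages (ReLU, ReLU, sigmoid)
  mapping the responses back to a [0, 1] image at the source resolution.

The objective is self-supervised: `L = [1 − SSIM(x_ct, y)] +
[1 − SSIM(x_pet, y)] + λ Σ|ω|`, minimized with AdaGrad from Xavier-uniform
initial weights. Both the forward pass and the full reverse-mode gradient are
implemented in vectorized base R (convolutions as sums of shifted
element-wise products); the gradient is verified against central finite
differences in the test suite, layer by layer and end to end.

## Design choices where the architecture was open

Several wiring details are genuinely underdetermined and were fixed as
follows:

* **Gate application.** The channel-attention equation produces a sigmoid
  gate vector; passing the bare gate forward would discard all spatial
  content, so the gate is applied multiplicatively (`F′ = g ⊙ F`), the
  standard channel-attention reading.
* **"Superimposing" the original image.** Additive superposition is
  ill-typed across blocks with different channel counts, so superposition is
  read as channel concatenation of gated features, pyramid features and the
  raw image.
* **Correlation window.** An unrestricted all-pairs patch correlation is
  quadratic in image area and produces a four-dimensional volume with no
  prescribed reduction; the layer instead uses a bounded displacement window
  (radius r strides, default r = 1, configurable up to global on small
  inputs). Patch size is likewise open; the default is 3 × 3 (odd sizes
  only, so patches can be centered) and 1 × 1 is useful for the smallest
  models because it avoids the patch-sum blur (see the convergence notes).
* **Pyramid branch wiring.** One 3 × 3 convolution per scale and bilinear
  upsampling back to full resolution before concatenation; pooling grids use
  exact block averaging, which requires the input size to be divisible by
  the largest scale (a configuration error otherwise points to a smaller
  `spp_scales`).
* **Siamese sharing.** The encoders share one parameter set; an `untied`
  flag provides the two-parameter-set ablation, which the tests use to show
  the sharing contract is load-bearing.
* **Channel widths, activations, decoder spec** (16-channel stem, 8 per
  pyramid branch, ReLU inside, sigmoid output, three 3 × 3 stride-1
  deconvolutions) live in `model_config()` as defaults, not claims.
* **Transposed convolutions at stride 1** with SAME padding are realized as
  their mathematically equivalent stride-1 convolutions.

Two ambiguities deserve explicit record. First, the L1 term: `Σ|ω|` is
implemented as a penalty on the network weights (the overfitting-control
reading); an image-domain difference penalty is a different objective and is
not what a weight-norm regularizer computes. Second, the weight sharing: the
architecture description mentions both shared and separate encoder
parameters; sharing is implemented as the primary design (it is what makes
the network siamese) with `untied = TRUE` as the ablation.

The λ multiplier on the L1 term (default `1e-4`) is introduced because an
unweighted parameter-L1 term dominates the bounded SSIM terms for any
realistically sized network; `lambda = 1` recovers the literal unweighted
objective.

## SSIM conventions

`ssim_config()` uses k1 = 0.01, k2 = 0.03 and L = 1 (images are min-max
normalized), so C1 = 1e-4 and C2 = 9e-4. The **global** mode computes the
means, variances and covariance over the whole image — this is the training
objective, and its analytic gradient is simple and exact. A **windowed**
mode (11 × 11 Gaussian, σ = 1.5, valid region) is provided for evaluation,
since sliding-window SSIM is the usual image-quality convention; the
training loop accepts only the global mode because only its gradient is
implemented analytically.

## The seven-metric suite

Mean, population standard deviation, average gradient, entropy, RMSE, NMI
and pixel-domain VIF. Conventions that the formulas leave open:

* **Average gradient** uses forward differences on the interior grid (the
  last row and column carry no forward difference and are excluded), with
  the `sqrt((dx² + dy²)/2)` per-pixel form.
* **Entropy/NMI binning**: 256 uniform bins on [0, 1], natural log, joint
  histogram 256 × 256. NMI is the joint-entropy-normalized form
  `2·[H(I1,F)/(H(I1)+H(F)) + H(I2,F)/(H(I2)+H(F))]`, bounded in [2, 4]
  because `max(H1, H2) ≤ H12 ≤ H1 + H2`; it equals 2 when the fused image
  is a copy of both sources. The independence limit of 4 is a large-sample
  statement: at 256 × 256 the 65 536-cell joint histogram averages one count
  per cell and the occupancy bias keeps NMI near 3.8, so the sampling check
  in the tests runs at 512 × 512, where the bias is small and NMI exceeds
  3.9.
* **VIF** is the pixel-domain scalar-GSM algorithm with four dyadic scales
  and visual-noise variance 2; it requires images of roughly 48 px and up
  (the coarsest scale must retain at least one valid window).
* RMSE and VIF of a fused image are averaged over the CT and PET references;
  mean, std, average gradient and entropy are computed on the fused image
  alone.

## The synthetic phantom generator

The generator emulates the statistical structure of thorax PET/CT slices —
not their physics. The CT channel is a jittered parametric layout (body
ellipse, two dark lung fields, a bright spine ellipse and a rib band along
the body shell; ±10 % seeded jitter on centers and axes) plus Gaussian
texture noise (σ = 0.02 by default), clipped to [0, 1]. The PET channel
places disjoint lesion disks inside the lung fields (rejection sampling;
failure to place disjoint disks is a generation error), renders them as
isotropic Gaussian blobs with peaks in (0.6, 0.95) on a low smooth
background (≤ 0.12), blurs with σ = 2 px (at 128 px scale) and
block-averages down by the native resolution factor 4 — mirroring the
clinical 512 × 512 CT versus 128 × 128 PET. The full-resolution lesion mask
is returned so registration ("hotspot centroids fall inside their mask
component") and contrast ("CT average gradient exceeds PET average
gradient") are testable invariants rather than assumptions.

What the phantoms do **not** model: attenuation physics, reconstruction
artifacts, respiratory misregistration, anatomical variability beyond
ellipse jitter. Passing tests on phantoms therefore demonstrates that the
pipeline is implemented correctly and can learn the fusion objective — not
that fusion quality on real clinical collections matches any particular
benchmark; those absolute numbers require real registered PET/CT data and a
converged full-scale model.

## Training protocol and problem sizes

The dataset protocol is a 4:1 train/validation split rotated five times
(5-fold cross-validation): at the full 840-pair scale this is 672/168 per
fold, and `split_dataset()` reproduces exactly that. Each registered pair is
one sample (the network is fully convolutional; no patch sampling).

The optimizer schedule is not prescribed anywhere, so learning rate, epochs
and batch size are configuration with defaults (0.01, 100, 4). The package's
own convergence experiments on 32 × 32 phantoms informed two further
choices. AdaGrad is stable up to roughly lr ≈ 0.05–0.06 on this
architecture and collapses (saturated sigmoid output, near-constant fused
image) above that; lr = 0.02 converged for every probed seed and is what
the shipped experiments use. Second, with 3 × 3 correlation patches the
patch summation acts as a box blur on the features, which caps the
achievable global-SSIM structure term near 0.93 on a fine-textured target;
the identity-fixture convergence experiment (`ct = pet`, λ = 0, 200 AdaGrad
steps to loss < 0.1) therefore uses the smooth PET-channel phantom as its
target image, where the decoder's smoothing bias is not a handicap — the
experiment demonstrates that the objective's global minimum at 0 is
approachable, and a fine-textured CT target at this tiny scale is the
documented limitation, not the demonstration.

Test and acceptance runs use desk-scale sizes chosen as the package's
experimental design: 64 × 64 phantoms (50 pairs, 40/10 split, 2 epochs) for
the trained-versus-untrained comparison, 32 × 32 for the fixture, and
6–12 px feature maps for the brute-force correlation oracle. The full
clinical-scale 512 × 512 configuration is reachable through
`phantom_config(ct_size = 512)` and `model_config()` unchanged.

## Numerical conventions and degenerate inputs

* Row-major rasters, origin top-left; resampling and upsampling use
  pixel-center alignment, clamped at borders; bilinear is the default
  ("image zoom" names no kernel), bicubic (Catmull-Rom) is selectable.
* Min-max normalization is per image (CT and PET carry different physical
  units); a constant image normalizes to all zeros by documented convention.
* Global max pooling in the attention gate routes its gradient to the first
  arg-max pixel on ties.
* The float archive stores `%.17g` text, which round-trips IEEE doubles
  bitwise; checkpoints are single-file RDS archives of the named tensors
  plus the configuration and a format version.
* Degenerate metric inputs: zero-entropy marginals in NMI take the
  lower-bound ratio 1/2; VIF of an all-constant reference is undefined and
  returns `NA`.

## Known limitations

Single-slice 2-D only; no registration (pairs are assumed registered
upstream); DICOM files are not parsed (convert to NIfTI or 16-bit PNG); the
training gradient supports the global SSIM mode only; stride-1 decoder
stages only; and the correlation layer's bounded window is a documented
reduction of an otherwise unreduced all-pairs construction.
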