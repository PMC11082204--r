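---
title: "Dual-branch selective-attention capsule networks for hyperspectral soft-rot detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-branch selective-attention capsule networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Postharvest soft rot of kiwifruit is a fungal disease whose early stages are
nearly invisible to the eye: lesions begin as subtle watery, ringed spots on
the peel, and by the time they are visually obvious the fruit is lost.
Hyperspectral imaging — here 150 narrow bands spanning 470–900 nm — captures
per-pixel reflectance spectra that respond to the chemical changes of
infection well before the spatial appearance does. The classification task
this package implements is patch-based: a fruit image is normalized to
256×256 pixels, tiled into 64×64 blocks at stride 32 (49 blocks per image),
and every block is assigned one of three classes — `background`, `healthy`,
or `soft_rot`.

The package provides four things:

1. the **DBSACaps network** and its ablation variants, implemented from
   scratch (forward pass, hand-derived backpropagation, Adam) in
   single-precision C++ on top of BLAS;
2. the **dataset-construction pipeline** (normalization, blocking, fraction
   rules, image-level splits, augmentation);
3. a **synthetic hyperspectral scene generator** with ground-truth masks, so
   the whole method is buildable and testable without the (private) original
   fruit dataset;
4. training, evaluation, ablation and configuration/CLI tooling around them.

## The network

### Dual-branch feature extraction

An input patch is a cube $x \in [0,1]^{150 \times 64 \times 64}$. Two
branches process it in parallel:

* **Spectral branch** — three 3-D convolutions with kernels $d \times 1
  \times 1$ and *valid* padding: $(7,\text{stride }2)$, $(7,\text{stride
  }2)$, $(33,\text{stride }1)$ with 64, 64 and 128 channels. Valid
  convolution shrinks the band axis by $\lfloor (D-d)/s \rfloor + 1$ per
  layer, tracing $150 \to 72 \to 33 \to 1$, after which the singleton depth
  is dropped: a $128 \times 64 \times 64$ map. Because every kernel is
  $1\times1$ spatially, the branch has *zero spatial receptive field*: each
  output pixel is a nonlinear function of that pixel's spectrum alone (the
  tests verify this perturbation property exactly).
* **Spatial branch** — one full-depth $150 \times 1 \times 1$ convolution
  collapses the spectrum to a 64-channel 2-D image (a learned linear
  projection per pixel), followed by two padded $3\times3$ convolutions
  (64, then 128 channels). This branch mixes space but touches the spectrum
  only through that single linear map.

All activations are rectifiers. Keeping the branches separate prevents the
two feature families from interfering during extraction; their parameter
cost is 299,712 (spectral) + 120,448 (spatial) = 420,160.

### Selective-attention fusion

Mild lesions differ from healthy peel mainly spectrally; severe ones also
spatially. A fixed 50/50 concatenation of the branches would weight both
feature families equally for every sample. Instead, each branch map $U_s$
($s \in \{\mathrm{spe}, \mathrm{spa}\}$) is summarized by a
squeeze-and-excitation descriptor $Z_s = \mathrm{SEWeight}(U_s)$: global
average pooling over space, a bottleneck affine map $128 \to 8$, a
rectifier, an expanding affine map $8 \to 128$, and a sigmoid. The two
descriptors then compete through a per-channel two-way softmax,

$$att_{\mathrm{spe}} = \frac{e^{Z_{\mathrm{spe}}}}{e^{Z_{\mathrm{spe}}} +
e^{Z_{\mathrm{spa}}}}, \qquad att_{\mathrm{spa}} = 1 - att_{\mathrm{spe}},$$

and the fused map is $V = \mathrm{concat}(att_{\mathrm{spe}} \otimes
U_{\mathrm{spe}},\; att_{\mathrm{spa}} \otimes U_{\mathrm{spa}}) \in
\mathbb{R}^{256 \times 64 \times 64}$, where $\otimes$ broadcasts the
per-channel weight over space. The complementarity
$att_{\mathrm{spe}} + att_{\mathrm{spa}} = 1$ holds per channel by
construction and is asserted to $10^{-6}$ in the tests. The two SE blocks
have separate weights (2 × 2,184 = 4,368 parameters); sharing them would
change the parameter total (see *Reverse-engineered choices* below).

### Capsule classification

The fused map feeds a capsule head instead of a pooled CNN classifier:

* **Primary capsules** — a $256 \to 512$ convolution (kernel 6, stride 7,
  valid, with bias) followed by batch normalization with learnable scale
  and shift gives a $512 \times 9 \times 9$ tensor, regrouped as 64 capsule
  types × 81 grid positions × 8 dimensions = 5,184 capsules, each squashed
  by $\mathrm{squash}(s) = \frac{\lVert s\rVert^2}{1+\lVert s\rVert^2}
  \frac{s}{\lVert s \rVert}$ so its norm lies in $[0,1)$.
* **Digit capsules** — every (primary capsule, class) pair owns an
  independent $8 \times 16$ prediction matrix (5,184 × 3 × 128 = 1,990,656
  weights, no routing bias). **Dynamic routing** runs for 3 iterations:
  logits $b$ start at zero; each iteration softmax-normalizes $b$ over the
  3 output capsules per input capsule into couplings $c$, forms $v_j =
  \mathrm{squash}(\sum_i c_{ij}\hat u_{j|i})$, and adds the agreement
  $\hat u_{j|i} \cdot v_j$ to $b_{ij}$ (skipped after the last iteration).
  A class's score is the length of its digit capsule; argmax predicts, with
  ties broken toward the lowest class index.
* **Margin loss** — the only training objective of the final model:
  $\sum_k T_k \max(0, m^+ - \lVert v_k \rVert)^2 + \lambda (1-T_k)
  \max(0, \lVert v_k \rVert - m^-)^2$ with $m^+ = 0.9$, $m^- = 0.1$,
  $\lambda = 0.5$, batch-averaged. No reconstruction decoder is attached to
  DBSACaps itself.

The assembled model has exactly **7,135,312** trainable parameters
(420,160 + 4,368 + 4,720,128 + 1,990,656), which
`scripts/acceptance.R` recomputes by building the model and counting.

### Reverse-engineered choices

The primary-capsule convolution geometry (kernel 6, stride 7, bias, batch
normalization with affine terms), the SE reduction ratio 16 with
*unshared* per-branch weights, and the per-pair digit transforms are not
fully specified by the published description. They are fixed here as the
unique configuration among standard capsule-network choices whose exact
parameter count matches the published total; the decomposition above is
asserted in the test suite. The margin-loss constants come from the
original capsule-network formulation, which the published model cites for
its loss.

### Variants

`dbsa_model()` builds ten variants: `DBSACaps` (full model), `DBCaps`
(attention removed — plain concatenation), `DBSA`/`DBNet` (capsule head
replaced by a convolution + fully-connected classifier under
cross-entropy, with/without attention), `SpectralCaps`/`SpatialCaps`
(single branch + capsules), `HybridCaps` (the spectral stack followed by a
3×3 2-D convolution, then capsules — a single-branch hybrid), and
`DBSACapsWithRec1/2/3` (DBSACaps plus reconstruction decoders fed by the
true-class-masked 48-dimensional digit output: Rec1 is the classic
three-affine-layer decoder; Rec2 reconstructs a 64×64 plane by an affine
map and expands to 150 bands with one 3×3 convolution; Rec3 reconstructs
32×32, upsamples by a stride-2 transposed convolution, then expands
spectrally). Where their internals are under-documented (head widths of
`DBNet`, the hybrid's 2-D depth, decoder widths), the package fixes
configurable defaults and documents them; the published parameter totals of
the Rec decoders are not reproduced and are not used as checks.

## Dataset construction

* **Normalization** — every band is resized bilinearly to 256×256 and the
  cube min–max scaled to $[0,1]$ globally (a constant cube maps to zero).
  Radiometric reference calibration is not part of the pipeline.
* **Blocking** — half-open 64×64 windows at stride 32, 0-based offsets,
  row-major; windows that would overrun are dropped (none at
  256/64/32). A 256×256 scene yields exactly 49 windows.
* **Labeling** — strictly more than 10% soft-rot pixels ⇒ `soft_rot`; else
  strictly more than 50% background pixels ⇒ `background`; else `healthy`.
  When both thresholds fire, soft rot wins — rot detection is the purpose,
  and the rules are applied in their published order.
* **Splitting** — whole images are shuffled by seed and apportioned
  2:1:1 by largest-remainder rounding *before* blocking, so all patches of
  an image share a split and leakage is structurally impossible.
* **Augmentation** — healthy and soft-rot patches are expanded ×4:
  original, horizontal mirror, random crop of side fraction 0.85 resized
  back, and multiplication by a smooth shadow gain field (a 4×4 uniform
  grid in $[0.7, 1]$, bilinearly upsampled). Background patches are left
  alone. Every spatial transform is identical across bands, preserving
  per-pixel spectra up to a common factor. The crop fraction and shadow
  parameters are declared package defaults: the augmentation reference the
  published pipeline cites gives no formulas.
* **Evaluation-set augmentation** — the published count table quadruples
  the healthy/soft-rot counts of *all three* splits, so `build_dataset()`
  augments validation and test patches by default, reproducing that table
  exactly; `augment_eval = FALSE` restores the more conventional
  train-only augmentation.

## The synthetic scene generator

The original kiwifruit dataset is private, so the package ships a seeded
generator whose scenes have the statistical structure the classifier
exploits, without claiming radiometric realism:

* **Signatures** are smooth parametric curves over wavelength — sums of
  logistic ramps and Gaussian bumps. Healthy peel follows a vegetation-like
  curve (green bump at 550 nm, chlorophyll dip at 670 nm, red edge at ~715
  nm, NIR plateau ≈ 0.74). Soft rot is a *continuous deformation* of the
  healthy curve controlled by severity ∈ [0,1]: the NIR plateau drops (to
  ≈ 45% at severity 1), the red edge shifts ~25 nm redward, and the green
  bump flattens; at severity 0 it equals the healthy curve exactly.
  Background is low and flat. Mild lesions therefore differ from healthy
  peel almost purely spectrally, severe ones strongly; the band-wise mean
  absolute healthy-vs-severe-rot separation is ≈ 0.20, far above the 0.05
  floor the generator guarantees.
* **Geometry** — a fruit ellipse on dark background; lesions are discs
  with a surrounding "watery ring" annulus (default width 3 px) at half
  the core severity, mirroring the ringed watery spots of the disease.
* **Noise** — i.i.d. Gaussian per band and pixel, truncated to $[0,1]$.
  No spatial texture model: this is the simplest noise that exercises the
  pipeline, and it means passing tests say nothing about sensor artifacts,
  illumination fields or biological texture in real data.
* **Determinism** — one integer seed fans out through fixed sub-streams
  (placement, rendering noise, augmentation, shuffling), so every artifact
  is bit-reproducible; this is asserted in the tests.
* **Presets** — `easy` (severity 1, noise sd 0.01) and `hard` (severities
  0.2–0.6, noise sd 0.05). These presets define the package's study
  conditions for the training benchmarks and were fixed once, up front.

`synthetic_patch_set()` additionally builds class-balanced single-window
sets, with a `spatially_flat` mode in which each window is uniformly one
class at one severity — all class information is then carried by per-pixel
spectra. The acceptance suite uses this mode (mild severities 0.10–0.25,
noise sd 0.10, 16-pixel windows — a difficulty calibrated so neither model
sits at ceiling) to probe the direction "deep nonlinear spectral
processing beats a single linear spectral projection when only spectra
carry the signal", comparing `SpectralCaps` against `SpatialCaps` over
three seeds. An important caveat emerged from the package's own
measurements: when every pixel of a window is statistically exchangeable,
the window-mean spectrum is a sufficient statistic, and the spatial
branch — whose linear collapse commutes with spatial averaging — has
structurally optimal access to it while also denoising before its
nonlinearities. On such data the spatial branch is at least as strong as
the spectral stack, so this directional check is expected to fail by
design of the data, not by defect of the implementation; the corresponding
acceptance expectation documents that tension rather than hiding it (see
*Known limitations*).

## Training and evaluation

Training uses Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) with the published
recipe as defaults: learning rate 5e-6, weight decay 1e-6 (L2 added to
gradients), batch size 16, 100 epochs, routing 3. Each epoch shuffles under
a derived seed; validation OA/AA are computed per epoch and the
best-validation-OA weights are restored afterwards (the published work
states no selection rule; best-validation OA is the package's choice). An
optional `stop_at_val_oa` stops once a target validation OA is reached.
`lr_sweep()` covers the standard grid {1e-3, 1e-4, 1e-5, 5e-6}.

Numerical notes, all deliberate:

* The core runs in single precision (the standard precision for this model
  family) with hand-derived gradients, including the fully unrolled
  backward pass through the three routing iterations; the test suite
  validates every variant's gradient against central finite differences.
* Gradients are accumulated over micro-batches (default 2 samples) inside
  each batch of 16 to bound activation memory (~300 MB instead of ~2.5 GB);
  batch normalization therefore normalizes per micro-batch ("ghost" batch
  norm). Evaluation always uses running statistics, so predictions are
  deterministic and independent of batch composition.
* `squash` backward uses a guarded norm ($\sqrt{n^2 + 10^{-12}}$) so the
  zero capsule has zero gradient; margin-loss gradients through a length
  use $v/\max(\lVert v\rVert, 10^{-9})$.
* Argmax ties (exactly equal lengths) go to the lowest class index; class
  order is fixed as (background, healthy, soft_rot).

**Metrics.** OA is trace/total of the 3×3 confusion matrix; AA is the
unweighted mean of per-class recalls — the reading under which published
per-class "accuracy" tables average to the printed AA. Precision, recall
and F1 are per class with macro averages; division by zero yields 0 and
sets a flag rather than NaN.

## Problem sizes used by the shipped checks

The packaged tests and acceptance script run at deliberately small scale,
chosen as the smallest sizes that still demonstrate each property: exact
arithmetic checks (parameter count, count tables, depth trace) are
instantaneous; property suites use reduced spatial sizes (13–16 px) where
the architecture allows; the learning benchmark trains DBSACaps on 40
easy-preset patches per class for at most 30 epochs at learning rate 1e-4
(stopping once validation OA reaches 0.95), and the spectral-vs-spatial
comparison trains each single-branch variant for 15 epochs on 20
spatially-flat 16-pixel patches per class across three seeds. These sizes
are the package's own benchmark definitions, not statements about the
original study's scale.

## Known limitations

* The generator's spectra are parametric stand-ins, not measured kiwifruit
  reflectance; no claim of radiometric or biological realism is made, and
  accuracy on synthetic scenes does not predict accuracy on real fruit.
* Only the 150-band configuration satisfies the spectral stack's fixed
  valid-convolution chain (the third kernel must meet depth 33); other band
  counts are rejected with an error naming the offending layer.
* The reconstruction decoders reproduce the *structure* of the published
  ablation, not its printed parameter totals, which cannot be reconciled
  with any standard decoder widths; they are excluded from exact checks.
* On spatially exchangeable synthetic patches the spatial branch's
  collapse-and-average route is provably at least as informative as any
  per-pixel nonlinear pipeline, so the synthetic generator cannot
  demonstrate a spectral-branch advantage of the kind reported on real
  fruit, where within-patch spatial heterogeneity breaks that sufficiency
  argument. The acceptance suite keeps the directional expectation and
  lets it fail visibly.
* Single-device, single-thread training only; no GPU path.
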