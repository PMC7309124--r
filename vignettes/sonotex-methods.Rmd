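---
title: "Methods: texture and multi-resolution CNN classification of HCC in B-mode ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: texture and multi-resolution CNN classification of HCC in B-mode ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hepatocellular carcinoma (HCC) typically develops on a cirrhotic liver, and
in B-mode ultrasound the tumor and the surrounding cirrhotic parenchyma
(PAR) can look deceptively alike: both are granular speckle textures whose
differences lie in coarseness, heterogeneity, echogenicity and structural
complexity rather than in crisp boundaries. `sonotex` implements a complete
comparison framework for the binary HCC-vs-PAR patch recognition task:

* polygon-annotation driven patch generation from clinician markings
  (VGG Image Annotator files),
* a conventional pipeline — 47 textural features, four relevance-based
  feature selectors, four classical classifiers,
* a multi-resolution convolutional network with atrous spatial pyramid
  pooling (ASPP), implemented natively in compiled code,
* a shared evaluation layer (confusion-matrix metrics, ROC/AUC,
  sliding-window confidence maps), and
* a seeded speckle-phantom generator that emulates the two-class contrast
  so the whole framework is testable without clinical images.

Clinical ultrasound datasets of this kind are not publicly distributable;
everything quantitative in the test suite therefore runs on the synthetic
phantoms, and the structural facts of the published protocol (patch sizes,
augmentation counts, architecture volumes, feature inventory) are asserted
exactly.

## Patch generation

The tumor is annotated as a polygon (even-odd interior rule, 0-based
`(x, y)` pixel coordinates). A 56×56 window slides over the image with
stride 1 in raster order and is accepted greedily:

* **HCC**: the window lies entirely inside the polygon and its
  intersection-over-union with every previously accepted patch is below
  0.1%.
* **PAR**: the window lies entirely outside the polygon, at least one of
  its four corners falls on the polygon boundary, and its intersection
  with every accepted patch is below 0.1% *of its own area*.

The two overlap rules are deliberately asymmetric (union-relative for HCC,
own-area-relative for PAR), following the source protocol literally. The
traversal order is not specified there; we fix row-major, stride-1 greedy
acceptance so the output is deterministic, and verify the implementation
against a literal brute-force enumeration of all windows. "Corner on the
boundary" is evaluated against the rasterized polygon outline with a
1-pixel tolerance: with fractional vertex coordinates, exact incidence is a
measure-zero event.

**Augmentation.** Training patches are augmented ×10: the original plus 9
draws without replacement from the pool of rotations every 5° in
[−45°, 45°], zoom factors 0.8/1.0/1.2, and horizontal reflection. The
full transform grid has 19 × 3 × 2 = 114 combinations while the published
bookkeeping implies a ×10 multiplier (5324 → 53,240 training patches); we
resolve this by seeded sampling of 9 distinct non-identity transforms per
patch. Resampling is bilinear about the patch center with reflected
borders, which avoids both aliasing and out-of-support artifacts at this
patch size.

**Splitting** is by seeded shuffling, patient-grouped by default so that no
patient contributes to two partitions. The published experiments do not
state whether their splits were patient-disjoint; a flag provides both
modes, and all phantom experiments here use grouped splits, which is the
conservative choice against within-image leakage.

## The 47 textural features

Features are computed on 56×56 patches after a 3×3 median prefilter
(speckle attenuation). The inventory — the source names the families but
not the per-family counts — is pinned as:

| family | count |
|---|---|
| Haralick statistics of order-2 co-occurrence matrices | 6 |
| Haralick statistics of order-3 co-occurrence tensors | 6 |
| autocorrelation index (diagonal unit lag) | 1 |
| Hurst fractal index | 1 |
| edge frequency / contrast / mean orientation | 3 |
| Laws energy maps (L5/E5/S5/W5/R5 × density, frequency) | 10 |
| Haar wavelet entropies (4 level-1 + 16 level-2 subbands) | 20 |

Order-2 co-occurrence uses the 8 unit displacement vectors at multiples of
45°; order-3 uses the 4 collinear and 8 right-angle direction pairs with
displacement components of magnitude 2, the current pixel central. One
tensor is kept per displacement configuration and each Haralick statistic
is the arithmetic mean over configurations. Gray-level quantization is not
stated in the source; we use 32 levels for order 2 and 16 for order 3 (a
16³ tensor remains well populated by the ~3000 valid triples of a 56×56
patch), both configurable. For order-3 tensors the pairwise statistics
(contrast, homogeneity, correlation) average over the three tuple pairs
and variance averages the per-position variances; a zero-variance marginal
defines correlation 0 rather than an error.

The wavelet entropy is stated in the source as a raw sum
`-Σ |I| log2 |I|` over subband coefficients. Applied literally this is
neither scale-invariant nor a Shannon entropy, so by default each
subband's coefficient magnitudes are L1-normalized first (making the
quantity a proper entropy); `normalize = FALSE` gives the literal reading.
Entropies are evaluated at both the first and second Haar level on all
four components — 20 values, which is also what makes the inventory reach
47.

The Hurst index uses the increment-scaling estimator: the slope of
`log E|I(p) − I(q)|` against `log d` over horizontal/vertical lags 1–8,
clipped to [0, 1]; a constant patch is defined as maximally smooth (1).
The estimator is validated by simulate-and-recover on spectral-synthesis
fractional Brownian surfaces (H ∈ {0.3, 0.5, 0.7}, tolerance ±0.15 on the
10-seed mean).

Edge statistics threshold the Sobel gradient magnitude at its Otsu value;
the threshold is computed directly from the 256-bin histogram (the
standard between-class-variance maximizer; agreement with `EBImage::otsu`
is asserted in the tests) because wrapping every gradient map in an image
object dominated batch extraction time. Degenerate inputs never throw: a
constant patch yields `(0, 0, 0)`.

Local binary patterns (for the published LBP+GLCM comparison variant) use
N = 8 neighbors on a radius-1 circle, bilinear interpolation off-grid,
strict inequality in the sign function, and concatenated 256-bin
histograms over non-overlapping cells (14 px on a 56-px patch); border
pixels without a complete neighborhood are skipped.

## Feature selection

Four selectors, combined by union:

* **CFS** (correlation-based feature selection): subset merit
  `k·r̄_cf / sqrt(k + k(k−1)·r̄_ff)` with point-biserial feature–class and
  Pearson feature–feature correlations, driven by a genetic search.
* **Consistency-based subset evaluation** (equal-frequency 10-bin
  discretization), also driven by the genetic search.
* **Information gain** and **gain ratio** rankers after Fayyad–Irani MDL
  discretization; features scoring above 0.3 bits are retained. The
  source applies the 0.3 threshold to "individual attributes", so it
  applies to the two rankers only; the subset evaluators contribute their
  best subsets wholly.

The genetic search runs 20 generations (as published) over bit-mask
chromosomes with population 20, single-point crossover 0.6, bit-flip
mutation 0.033 and elitism 1 — the defaults of the toolkit the source
used, which states only the generation count. Candidate features are
sorted by name before the search so the result does not depend on column
order. On problems small enough to enumerate, the search is required to
match exhaustive enumeration.

## Conventional classifiers

* **Linear SVM**: degree-1 polynomial (= linear) kernel, C = 1, min-max
  normalized inputs, Platt-scaled probabilities (via `e1071::svm`).
* **Random forest**: 100 trees (`randomForest`).
* **AdaBoost.M1** over information-gain decision trees (`rpart` weak
  learners with case weights); 100 boosting rounds; class scores are the
  normalized weighted votes.
* **MLP**: the published topology grid — one to three hidden layers with
  a, a/2 or a/3 sigmoid nodes, `a = ⌊(n_features + n_classes)/2⌋` —
  trained 500 epochs with learning rate 0.2 and momentum 0.8; the best
  topology is chosen on an internal 90/10 validation split. This is
  implemented in-package because no installed MLP supports more than one
  hidden layer.

`run_comparison()` evaluates each classifier before and after selection on
a seeded 80/20 split with HCC as the positive class.

## The multi-resolution ASPP network

Input is a single-channel 56×56 patch scaled to [0, 1]. The architecture:

1. **Multi-resolution block 1**: three parallel convolutions with kernels
   3/5/7 (half-kernel padding, so resolution is preserved), NF1 filters
   each, concatenated → 3·NF1 channels at 56×56.
2. **Shortcut**: concatenation with the input → 3·NF1 + 1 channels.
3. 2×2/stride-2 max-pooling → 28×28 (channels preserved).
4. **Block 2** (NF2 filters per kernel) and its shortcut (the pooled
   volume) → 3·(NF2 + NF1) + 1 channels at 28×28; max-pool → 14×14.
5. **ASPP**: five parallel branches of NF3 channels — a 1×1 convolution;
   three 3×3 dilated convolutions at atrous rates 2/3/4 with padding equal
   to the rate; and adaptive average pooling to 1×1 followed by a 1×1
   convolution and broadcast upsampling. Concatenation → 5·NF3 channels;
   a 1×1 fusion convolution reduces back to NF3, followed by batch
   normalization and dropout (rate 0.5 by default; unstated in the
   source).
6. A single fully connected layer maps the flattened NF3×14×14 volume to
   2 logits; softmax and cross-entropy complete the model.

Design points that required a decision:

* The source's prose gives the pool-1 output depth as `3 × NF2`, which is
  inconsistent with channel-preserving pooling and with its own
  concatenation arithmetic (`3 × (NF2 + NF1 + 1)` after block 2); the
  concatenation arithmetic is self-consistent and is treated as
  authoritative. `shape_report()` probes every stage of the *built*
  network and the tests pin the whole chain.
* Every convolution is followed by ReLU then batch normalization, in that
  order, following the stated convention verbatim (including the ASPP
  branch and fusion convolutions); `relu_before_bn = FALSE` provides the
  conventional conv→BN→ReLU order.
* The FC head is a single layer (no hidden FC), and the classifier input
  is one grayscale channel.

Training follows the published protocol: Glorot-uniform initialization,
SGD with learning rate 1e-4 and momentum 0.1, mini-batches of 64, with a
validation set monitored every epoch; the returned model carries the
parameters of the best-validation-accuracy epoch. The engine (im2col +
BLAS gemm convolutions, batch-norm with running statistics, argmax-cached
pooling, full backpropagation including the transposed-convolution input
gradients) is written in C++/Armadillo in single precision — SGD gains
nothing from double precision and the workload is memory-bound. Gradients
are verified against central finite differences, and a gradient-flow test
asserts that every trainable tensor (all 12 convolutions, all batch-norm
scales/shifts, the FC layer) moves after one SGD step, which would catch a
dead ASPP branch or a disconnected shortcut.

## The speckle phantoms

No simulator is published with the protocol, so the generator implements
the standard fully-developed-speckle approximation: a complex
circular-Gaussian scattering field blurred at a `correlation_length`
(point-spread scale, px), envelope magnitude, multiplication by a smooth
multiplicative gain field of relative amplitude `heterogeneity`, log
compression, and mapping to [0, 255] with `mean_brightness` and
`contrast_scale` (1 ⇒ one speckle s.d. ≈ 30 gray levels). A phantom
composites an "HCC" texture inside a lesion polygon (blended over ~2 px to
mimic the diffuse tumor/parenchyma transition) into a "PAR" background,
and attaches the polygon as a VIA-compatible annotation.

Default study conditions (used throughout tests and the acceptance
script): lesion texture with correlation length 4, brightness 135,
heterogeneity 0.3 — coarse, bright, inhomogeneous, echoing how HCC is
described against cirrhotic parenchyma — versus background correlation
length 1.5, brightness 120, heterogeneity 0.15. Cohorts perturb the
template per patient with acquisition-level jitter (log-normal
correlation-length and heterogeneity factors with σ = 0.08 and 0.15,
brightness offsets with σ = 4 gray levels) applied to *both* tissue
classes jointly, so a null template (identical inside/outside parameters)
remains exactly null while patients still differ. All randomness descends
from one integer seed through a splittable stream.

What the phantoms do *not* emulate: attenuation with depth, the fan
geometry of convex probes, shadowing and enhancement artifacts, vessels
and other anatomy, device post-processing, or the absolute intensity
statistics of any particular scanner. Passing the end-to-end phantom
checks therefore demonstrates that the pipeline *can recover a known
texture contrast under speckle statistics*, not that clinical performance
figures would be reproduced.

## Problem sizes and numerical choices

The end-to-end experiments use a 20-patient × 3-frame separable cohort
(~1700 patches, ~1400 train / ~350 validation after the patient-grouped
80/20 split) for the scaled network (NF1=NF2=NF3=16, 10 epochs) and the
random-forest-on-47-features baseline, and a 12-patient × 2-frame null
cohort evaluated with 50/50 grouped splits over 5 seeds for the
chance-level check. These sizes keep each full run in the minutes range
on a single core while leaving wide margins to the acceptance thresholds
(observed: validation AUC > 0.99 for the scaled network against the 0.90
bound; null AUCs 0.44–0.52 against the [0.4, 0.6] band).

Numerical conventions, chosen once: batch-norm ε = 1e-5 and running-stat
momentum 0.1; ties in max-pooling resolve to the first (top-left)
maximum; `0·log 0 := 0` in every entropy; zero-variance correlations, empty
edge sets, all-zero patches and constant patches all produce defined
finite values rather than errors; AUC counts ties as ½ (equivalent to
trapezoidal ROC integration); confidence maps average the probabilities of
all windows covering a pixel (the source does not define an aggregation)
with a default stride of 14 px, a quarter window.

## Limitations

* The 47-feature inventory and several conventions (quantization depths,
  order-3 statistic generalizations, the entropy normalization) are
  pinned choices where the source under-specifies; all are documented
  above and configurable where that is meaningful.
* The transfer-learning comparison arms (VGG/ResNet/Inception/DenseNet/
  SqueezeNet) require external pretrained weights and are out of scope.
* Phantom realism is deliberately minimal (see above); clinical
  performance claims are not transferable from phantom results.
* The native training engine targets this architecture family; it is not
  a general-purpose deep-learning framework.
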