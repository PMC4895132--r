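---
title: "Lesion characterization and deep discrimination: methods and design notes"
author: "mammocad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion characterization and deep discrimination: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`mammocad` implements a complete desk-scale pipeline for discriminating
benign from malignant breast lesions on mammograms from quantitative
lesion descriptors: a phantom generator with ground truth, a feature
extractor (15 microcalcification descriptors, 26 mass descriptors, and
their 41-element combination), a stacked denoising autoencoder (SDAE)
classifier with a softmax top layer, SVM/KNN/LDA benchmark classifiers,
and an evaluation protocol (accuracy, sensitivity, specificity, AUC,
stratified 10-fold cross-validation) producing the familiar
classifier-by-metric comparison tables.

Clinical mammograms are not shipped and are not required: every empirical
statement the package's tests make is computed on synthetic phantoms or
simulated feature tables whose generating process is part of the package
and fully seeded.

# The classification model

Each autoencoder layer consists of an encoder
$h = \sigma(W_1 x + b_1)$ and a decoder
$\hat{x} = \sigma(W_2 h + b_2)$, with $\sigma(z) = 1/(1+e^{-z})$ the
logistic sigmoid, trained to minimize the mean squared reconstruction
error $\frac{1}{n}\sum_i \frac12\lVert \hat{x}^{(i)} - x^{(i)}\rVert^2$
of clean inputs reconstructed from corrupted copies (masking noise:
each coordinate independently zeroed with probability $p$). $W_2$ is an
independent decoding matrix (untied weights). The stack is pretrained
greedily — layer $k$ trains on the encoded output of layers
$1..k\!-\!1$ — after which a two-class softmax layer is added and the
whole encoder stack is fine-tuned by cross-entropy minibatch SGD; the
decoders are discarded at that point.

Inputs are min–max scaled to $[0,1]$ with training-set statistics only;
the scaler is stored in the model and applied at prediction time.

## Optimizer choices

The optimizer is plain minibatch SGD with a constant step. Three choices
matter and were fixed after explicit experiments at the package's
problem sizes, then frozen:

* **Learning rate 2 (default).** With inputs compressed into $[0,1]$
  the gradients through two sigmoid layers are small; at step sizes an
  order of magnitude lower, pretraining leaves the hidden activations
  nearly constant across cases and fine-tuning cannot leave the
  majority-class plateau even on a clean two-dimensional XOR problem.
  Step size 2 reaches the Bayes-optimal XOR accuracy on that toy.
* **Corruption in both phases (default 0.1).** Masking noise is applied
  during pretraining (the denoising objective) and to the fine-tuning
  input batches (input dropout). The latter is the standard stochastic
  regularizer for supervised SGD and measurably reduces overfitting to
  uninformative feature axes.
* **Polyak tail averaging.** The returned fine-tuned parameters are the
  average of the iterates over the final quarter of fine-tuning epochs.
  Constant-step SGD orbits its optimum at a radius proportional to the
  step size; iterate averaging removes most of that variance without a
  step-size schedule.

Weight matrices initialize uniformly in
$\pm\sqrt{6/(\text{fan}_{in}+\text{fan}_{out})}$, biases at zero, the
softmax at zero; all randomness (initialization, shuffling, corruption)
derives from the configuration seed, making the full train–predict
pipeline bit-reproducible.

The per-epoch training curve records the clean full-data reconstruction
error at the end of each epoch. The mean of corrupted batch losses is
noisy (the corruption draw alone moves it by far more than the
convergence signal); the full-data error is deterministic given the
parameters and is the quantity whose monotone decrease the tests assert.

## Benchmarks

* **SVM** — soft-margin SVM (e1071), RBF kernel, $C = 1$,
  $\gamma = 1/(d \cdot \mathrm{var}(X))$.
* **KNN** — Euclidean k-nearest neighbours, $k = 8$ by default
  ($k = 6$ for the 41-feature scenario); the malignancy score is the
  malignant fraction among the neighbours. The implementation is
  in-package because the usual library routine breaks distance ties at
  random, which would violate the package's determinism contract; it is
  cross-checked against `class::knn` in the tests.
* **LDA** — Fisher's linear discriminant in closed form with pooled
  covariance plus a ridge $\varepsilon I$
  ($\varepsilon = 10^{-6}\,\mathrm{tr}(S)/d$ by default);
  cross-checked against `MASS::lda`.

The benchmarks consume features on their native scale. LDA is affine
invariant, so scaling is irrelevant there; for the distance-based KNN
and the RBF-SVM, per-dimension spread is information. Range-normalizing
every column maps any roughly Gaussian column to the same relative
spread regardless of its variance, which provably erases the contrast
between informative and noise axes — on the simulated tables below it
drives KNN to chance. Users whose features mix wildly heterogeneous
units (pixel areas next to proportions) should standardize deliberately
before distance-based classification; the extractor's own tables are
used as generated.

# Feature definitions

All geometry follows the pixel-square model. The perimeter is the
crack-boundary length (count of exposed pixel edges). The convex
perimeter is the perimeter of the convex-hull polygon over pixel-square
corners, which is never longer than the crack boundary, so convexity
$\le 1$. The convex **area** is the pixel count of the rasterized
convex hull of pixel centers (the "convex image" convention): a filled
rectangle then has solidity exactly 1, and a smooth digital ellipse is
not penalized by the half-pixel corner band or boundary staircasing
(with a polygon-area convention a smooth 80x50 ellipse loses 2–4% of
solidity to discretization alone). Axes derive from second central
moments with the 1/12 per-pixel variance term (the ellipse of equal
moments); a single pixel therefore has well-defined, positive axes.

Circularity is $4\pi A/P^2$ with the crack perimeter corrected by the
standard $\pi/4$ factor (an axis-aligned digital disc has crack
perimeter $8r$, not $2\pi r$), clamped to $[0,1]$; without the
correction no digital disc could reach the package's roundness
threshold of 0.8.

The microcalcification vector (15): count; total area; mean and maximum
equivalent diameter ($\sqrt{4A/\pi}$); density (count per convex-hull
area of the pooled pixels); mean circularity; circularity proportion
(share of components with circularity $\ge$ 0.8); mean solidity; sandy
proportion (equivalent diameter < 3 px); linear proportion (axis ratio
$\ge$ 3); mean spiculation (crack/convex perimeter − 1); volume ratio
(calcified fraction of the region of interest); mean and SD of gray
inside the mask; eccentricity of the ellipse fitted to the pooled
cluster. An empty mask returns the all-zero vector, so mass-only cases
flow through the combined schema.

The mass vector (26): area; perimeter; solidity; elongation
(1 − minor/major); axis ratio; eccentricity; convexity; spiculation
(coefficient of variation of the radial boundary-distance signature);
heterogeneity (intensity CV inside the mask); volume ratio; mean,
maximum, minimum and SD of gray; gray relativity (mean inside over mean
of a 5-px outer dilation band); and eleven Haralick co-occurrence
statistics (entropy, inverse difference moment, difference entropy,
correlation, difference variance, sum average, sum variance, energy,
mutual information, contrast, sum entropy).

The co-occurrence matrix quantizes in-mask intensities linearly to
$G = 16$ levels over the mask's own min–max range, accumulates pairs at
distance 1 over the four symmetric offsets (0°, 45°, 90°, 135°),
symmetrizes and normalizes. Logarithms are base 2 with
$0\log 0 := 0$; the correlation of a zero-variance matrix is defined as
0; mutual information is $H(p_x)+H(p_y)-H(P)$. The 4-offset set makes
every texture feature invariant under 90° rotation; together with the
purely mask-local geometry this gives exact translation invariance and
rotation invariance at numerical precision for all 41 features, which
the test suite asserts on 20 phantom cases.

Naming caveat: the feature list includes an "inverse difference
moment"; sources sometimes label a similar slot "inverse difference
entropy", which is not a standard co-occurrence statistic — the inverse
difference moment is the stand-in here. The 15/26 lists match the
printed counts of the motivating study, whose appendix-level formula
definitions are not public; the definitions above are the package's
own, chosen from the standard shape/texture repertoire.

# The phantom generator

The generator emulates the statistical setting of a two-class lesion
cohort, not mammographic physics:

* **Background** — white Gaussian noise low-passed at
  $\sigma_{bg}$ = 2 px (default) and affinely rescaled to $[0, 250]$.
  The smoothing controls spatial autocorrelation (hence co-occurrence
  texture); the 250 cap leaves headroom so inserted lesions are always
  strictly brighter than the tissue they cover.
* **Microcalcifications** — anti-aliased discs, elongated ellipses
  (axis ratio drawn in [2, 5]) and radially perturbed irregular blobs,
  binarized at 0.5 for the truth mask; intensity is additive with a
  hard 255 clip (clinical microcalcifications saturate). Placement is
  clustered inside a disc of radius one sixth of the image
  min-dimension, non-overlapping by rejection sampling (1000 attempts,
  then an error), with accepted stamps kept one pixel apart so the
  truth mask has exactly the drawn number of 8-connected components.
  Elongated stamps are redrawn until their binarization measures as
  elongated (moment axis ratio $\ge 2$), so the shape-mix contract
  survives discretization.
* **Mass** — a filled ellipse (semi-axes (40, 25) px by default) at
  random orientation; spiculation level $s$ adds $3s$ narrow radial
  spicules with amplitude proportional to $s$, lowering solidity.
  Intensity is a soft dome with a multiplicative ceiling
  $x \mapsto x + (255-x)\,\text{stamp}\cdot c/255$, which never
  saturates.
* **Class conditionals** — benign: 3–8 calcifications, 80% round,
  smooth mass; malignant: 8–25 calcifications, 60% elongated/irregular,
  spiculation level 4. These produce the qualitative contrasts the
  features are designed to capture (higher counts, higher linear
  proportion, lower mass solidity in the malignant class), which the
  tests verify on 40 cases per class.

Defaults the study setting does not pin down were chosen once for
desk-scale operation and are stated here as the package's own: image
size 256x256 (the 1024x1024 clinical convention is supported but four
times slower per case with no change in any contract), contrast boost
230 gray levels (calcifications; the mass uses 60%), background
smoothness 2 px. The background smoothness and contrast were chosen so
that the deliberately simple plumbing detectors (below) operate in a
regime where they work; with strongly correlated backgrounds
(smoothness 8+) a global-threshold mass detector is hopeless, which is
a statement about the detector, not the features.

What the phantoms do **not** model: breast contour, pectoral muscle,
CC/MLO projection geometry, scanner noise spectra, pixel-to-mm
calibration (all sizes are in pixels), and any correlation between
calcification morphology and mass morphology within a case. Passing
tests on phantoms therefore demonstrates the correctness and the
qualitative discriminative behaviour of the pipeline, not clinical
performance.

The feature-table simulator sidesteps images entirely: two informative
dimensions carry either a linear mean shift of `effect`·σ or an
XOR-of-signs rule (cluster centers at ±effect/2, linearly inseparable
by construction); remaining dimensions are Gaussian noise at half the
informative standard deviation, a ratio chosen at design time so that
distance-based classifiers retain the signal among 39 noise axes. The
default class balance is 50/50; the study-mirror cohorts use the
composition of `study_composition()` (1000 training cases at 32.3%
malignant, 204 test cases at 52.5%).

# Detectors

The detectors are transparent plumbing, not a segmentation method: the
top-hat detector enhances bright spots with a disc structuring element
(radius 7), thresholds the response at mean + 3 SD, gates candidates at
the global mean intensity (suppressing dark-tissue false positives) and
filters component areas to [2, 400] px²; the mass detector blurs at
σ = 12 px, applies Otsu's threshold and keeps the largest component of
at least 200 px². Both are pure functions of (image, parameters).

# Evaluation protocol

Hard labels use the 0.5 malignant-probability threshold (SAE, KNN) or
the zero discriminant threshold (SVM, LDA); ROC curves use the
continuous scores with tied scores collapsed into single threshold
steps, and AUC is the trapezoid integral, which equals the Mann–Whitney
pair-counting statistic with ties counted one half (asserted to 1e-12
against a brute-force oracle). Cross-validation is stratified (the
mirrored cohort is 32.3% malignant; unstratified folds would be
unstable), with every classifier refitted per fold — including its
internal scaler, so no test-fold statistics leak.

# Problem sizes

The test suite and the acceptance script run, by the package's choice:
the qualitative-ordering comparison on a 1000/204 xor cohort with the
SDAE at hidden sizes [100, 100], 150 pretraining and 1000 fine-tuning
epochs (the [400, 400] architecture of the combined scenario remains
the `run_scenario` default; the smaller stack is used for the synthetic
cohort where it trains stably in under a minute); 10-fold
cross-validation on a 400-case linear cohort with a [50, 50] stack;
invariance checks on 20 phantom cases at 160x160; detector fidelity on
25–50 cases at 256x256; gradient checks on 5–6-case instances against
central finite differences at $10^{-5}$ relative tolerance.

# Known limitations

* The SDAE and the RBF-SVM are statistically comparable on the xor
  cohort (both approach the Bayes limit); across random cohort draws
  their ranking can flip. The packaged comparison pins a seeded cohort.
* Solidity via the convex-image convention saturates at 1 for any
  convex shape; it does not distinguish degrees of near-convexity.
* The spiculation features are signature statistics, not spicule
  counts; heavily lobulated but unspiculated masses also score high.
* `simulate_feature_table` draws feature columns independently;
  real lesion descriptors are correlated.
* No DeLong confidence intervals or significance tests between AUCs are
  provided.
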