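---
title: "Patch-based deep-feature engineering for retinopathy grading: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-based deep-feature engineering: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The procedure

Diabetic retinopathy (DR) is graded on colour fundus photographs by the load
of visible microvascular lesions: microaneurysms and hemorrhages (dark),
hard exudates (bright), and, in the proliferative stage, neovascularization.
`retinopatch` implements a feature-engineering pipeline for this grading
problem that combines one global view of the photograph with eight local,
orientation-dependent views:

1. **Canvas.** The image is resized to a fixed 256×256 canvas.
2. **Patch division.** The canvas is cut into four 128×128 quadrants. The
   upper-left and lower-right quadrants are cut *horizontally* into two
   64-row × 128-column patches each (top before bottom); the upper-right and
   lower-left quadrants are cut *vertically* into two 128-row × 64-column
   patches each (left before right). The eight patches P1…P8 tile the canvas
   exactly — every pixel belongs to exactly one patch.
3. **Deep features.** Each of the nine inputs (main canvas + 8 patches) is
   embedded by a frozen convolutional backbone; the activations of the
   1000-way classification layer (`fc`, pre-softmax) and of the 1920-unit
   global-average-pool layer (`pool`) are concatenated into a 2,920-vector
   per input, and the nine blocks into one 26,280-vector per photograph
   (order: main, P1…P8; within a block `fc` then `pool`).
4. **Normalization and selection.** Features are min–max normalized and
   weighted by neighborhood component analysis (NCA); the 500 columns with
   the largest weights are kept.
5. **Classification.** A cubic (degree-3 polynomial kernel) SVM, one-vs-one
   for the multiclass case, is trained on the selected features and
   evaluated under stratified 10-fold cross-validation and a stratified
   80:20 hold-out split.

The package reports six metrics per evaluation: accuracy, unweighted average
recall (UAR) and precision (UAP), macro F1, Cohen's kappa, and the geometric
mean of class-wise recalls (G-mean, zero if any class is entirely missed).

# The NCA feature-selection model

NCA for feature selection learns one nonnegative weight $w_l$ per feature.
Under the weighted $L_1$ distance

$$d_w(x_i, x_j) = \sum_l w_l^2\,|x_{il} - x_{jl}|,$$

sample $i$ picks a reference neighbour $j \ne i$ with softmax probability
$p_{ij} \propto \exp(-d_w(x_i, x_j)/\sigma)$, and the objective is the
expected leave-one-out accuracy of this neighbour assignment minus a ridge
penalty:

$$F(w) = \frac1n \sum_i p_i \;-\; \lambda \sum_l w_l^2,
\qquad p_i = \sum_{j:\,y_j = y_i} p_{ij}.$$

`fit_nca()` maximizes $F$ by mini-batch gradient ascent from $w = 1$ with
the analytic gradient

$$\frac{\partial F}{\partial w_l} = \frac{2 w_l}{\sigma}\cdot\frac1n \sum_i
\Big[ p_i \sum_j p_{ij} |x_{il} - x_{jl}| - \sum_{j:\,y_j=y_i} p_{ij}
|x_{il} - x_{jl}| \Big] - 2\lambda w_l,$$

clipping negative weights to zero after every step. Both the objective and
the gradient are verified in the test suite against a literal double-loop
enumeration of the formulas and against central finite differences.

## Numerical and design choices

* **Kernel width σ.** The objective depends on the distances only through
  $d/\sigma$. With $D = 26{,}280$ min–max-normalized features the pairwise
  distances at the all-ones initialization are of order $10^3$–$10^4$, so a
  unit width collapses the softmax onto the single nearest neighbour and the
  gradient carries no usable signal. `nca_params(sigma = "auto")` therefore
  resolves the width to the mean pairwise distance at initialization
  (estimated on a deterministic subsample of at most 60 rows), which keeps
  the softmax responsive at any dimensionality; the constructor default
  remains `sigma = 1`, appropriate for small feature sets. The pipeline
  configuration uses `"auto"`.
* **Regularization λ.** Defaults to $1/n$, the customary choice for this
  estimator; it shrinks uninformative weights toward zero so that top-$k$
  ranking, the quantity that matters downstream, is driven by the
  accumulated data gradient.
* **Optimizer.** Batches of 32 rows with seeded shuffling; learning rate
  $0.1/\text{epoch}$; at most 100 epochs (`nca_params()` default) with
  early stopping when the per-epoch objective improves by less than
  `tolerance`. The pipeline default is 10 epochs: on the study-scale
  problems below the selected set is stable well before that, and further
  epochs mostly shrink all weights uniformly.
* **Objective trace.** Element 1 of `objective_trace` is the exact objective
  at initialization; subsequent entries are per-epoch stochastic estimates
  (the epoch's mean mini-batch leave-one-out term minus the penalty at the
  epoch-final weights). An exact trace would double the $O(n^2 D)$ cost of
  every epoch for purely diagnostic information.
* **Numerical stabilization.** Softmax rows subtract their maximum before
  exponentiation; $p_{ii} = 0$ by construction. A class with a single member
  is permitted (its $p_i$ may be 0).
* **Ties.** `select_top_k()` breaks equal weights by ascending column index,
  making the selection reproducible.
* **Degenerate inputs.** Constant features map to 0 under min–max
  normalization (and are never informative for NCA); applying a fitted
  min–max model to unseen data may produce values outside $[0,1]$, which is
  intentional — clipping would distort distances on the test side.

# Validation protocols and leakage

The published procedure normalizes and runs NCA on the *full* dataset before
validation, then splits. `run_pipeline()` reproduces that in its default
`paper_faithful` mode. Because selection-before-split leaks test information
into the feature ranking, the pipeline also offers `leakage_safe` mode, in
which min–max and NCA are refit inside every training partition (each CV
fold, and the training side of the hold-out). Both modes are first-class;
reports record which was used. Expect `leakage_safe` estimates to be lower
and more honest; the default is faithfulness to the published procedure.

Cross-validation metrics are computed on the *pooled* out-of-fold confusion
matrix (per-fold confusions are retained in the report). Pooling rather
than averaging per-fold metrics is our documented choice: a single reported
confusion matrix per protocol implies pooled counts.

# Embedding backends

The production backend is a pretrained DenseNet201 (224×224 input,
`fc` 1000 + `pool` 1920 features per input). No deep-learning runtime ships
with this package, so `densenet201_backend()` carries the dimensions and
accepts a user-supplied `embed_fn` wrapping a real forward pass (e.g. via
reticulate and torchvision); inputs should be scaled to $[0,1]$ and
standardized with the ImageNet channel statistics. Non-square patches are
resized (bilinear) to the backend's square input side — the standard
transfer-learning treatment.

The tested backend is `stub_backend()`: a frozen, seeded random linear
projection (no bias) of the 32×32-downsampled grayscale image onto 1000- and
1920-dimensional outputs. It is deterministic, fast, linear (the zero image
embeds to zero), and spans the downsampled pixel space, so whatever class
signal survives a 32×32 grayscale thumbnail survives the stub.

Resampling (canvas resize, patch-to-backend resize) is implemented in the
package as a separable-weights resampler with the half-pixel-centre
convention $\text{src} = (\text{dst} + 0.5)\,n_{in}/n_{out} - 0.5$,
edge-clamped, with bilinear (default) and nearest-neighbour filters. Owning
the resampler makes the index-mapping convention explicit and directly
testable against an independently coded per-pixel oracle; resizing is
anisotropic (no letterboxing), which is our documented reading of the
procedure.

# The synthetic data generator

`generate_images()` produces fundus-like images so that every stage is
testable offline: a dark surround, a circular retina disc with radial
falloff, a bright optic disc on the nasal side, and `vessel_count`
curvilinear vessels random-walking out of the optic disc. Grade $g$ adds
Poisson($6g$) dark hemorrhage-like lesions and Poisson($3g$) bright
hard-exudate-like blobs; grade 0 is lesion-free. Placement follows
posterior-pole anatomy: hemorrhages cluster in the macular zone (Gaussian
around the macula, sd 6% of the canvas), exudates form a circinate ring
around it (radius 18% ± 2.3% of the canvas), vessels reflect off the disc
rim and off a foveal avascular zone, and every vessel has the same total
length so that vasculature is class-independent nuisance structure.

These placement priors are what makes the grade *mean-visible*: with
spatially uniform lesion placement the opposite-signed lesion and exudate
masses cancel in expectation and the grade signal survives only in
higher-order statistics, which a linear embedding cannot pass on. Clustered
placement concentrates signed lesion mass in known zones — which is also how
clinicians read the posterior pole. Defaults: 50 images per class, 3
classes, noise sd 5 (8-bit scale), 6 vessels, seed 42.

What the generator does **not** emulate: acquisition variability (exposure,
field of view, camera vignetting), anatomical variation, gradable-quality
artefacts, neovascular fronds, and the class imbalance of clinical datasets.
A pipeline that passes the synthetic tests is structurally correct and able
to recover a planted grade signal; nothing here certifies clinical
performance on real photographs, which additionally requires the pretrained
backbone.

`generate_planted_matrix()` is the matrix-level analogue used to test the
selector in isolation: standard-normal noise with `n_informative` columns
mean-shifted by `effect_size` per grade step, ground-truth indices returned.

# Problem sizes used in the shipped checks

The test-suite and acceptance-script runs use the study conditions: 150
synthetic images (3 × 50, seed-controlled), the full 26,280-feature stub
matrix, top-500 selection with 10 NCA epochs, and both protocols; the
planted-recovery study uses $n = 200$, $D = 50$, 10 informative columns at
effect size 1.5 over 20 seeds. Orchestration unit tests run reduced sizes
(a few images per class, 1–2 epochs) because they check contracts, not
statistics.

# Known limitations

* The DenseNet201 path needs an external runtime; only its interface and
  dimensional contract are verified here.
* NCA cost is $O(n^2 D)$ per full objective and $O(b^2 D)$ per batch;
  for datasets of thousands of images the batch path dominates and scales
  linearly in epochs, but the exact objective at initialization is still one
  full pass.
* Min–max statistics, NCA weights and the SVM are refit per partition only
  in `leakage_safe` mode; the default mode deliberately reproduces the
  published full-dataset protocol, including its optimism.
* The five-class regime is generated and classified with the same machinery,
  but the shipped statistical checks run the three-class regime.
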