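---
title: "Curvelet features and optimized extreme learning machines for glaucoma screening"
author: "curvelm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvelet features and optimized extreme learning machines for glaucoma screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvelm)
```

## The problem

Glaucoma damages the optic nerve head (ONH) and is the leading cause of
irreversible blindness. On a fundus photograph the strongest early
structural sign is an enlarged optic cup relative to the optic disc — a
raised cup-to-disc ratio (CDR). `curvelm` implements a complete,
inspectable pipeline for binary screening (healthy vs glaucoma) on small
ONH-centered regions of interest (ROIs), typically 128×128 pixels:

1. curvelet-domain texture/boundary features,
2. unsupervised then supervised dimensionality reduction,
3. an extreme learning machine (ELM) whose hidden parameters are tuned by
   a pelican optimization metaheuristic,
4. stratified repeated cross-validation, and
5. exact gradient-based saliency maps for interpretation.

Every stage is exercised end to end on synthetic fundus-like images, so
the package is fully testable without any clinical data.

## The curvelet transform with wrapping

Curvelets are a second-generation multiscale system whose elements are
anisotropic and oriented, making them efficient encoders of curved
edges — precisely the geometry of disc and cup boundaries. The discrete
transform used here (`fdctForward`) follows the wrapping construction:

1. a 2-D FFT of the image;
2. multiplication with a smooth frequency window for every scale/angle
   wedge;
3. re-indexing ("wrapping") of each windowed wedge about the origin into
   a rectangle;
4. an inverse FFT per wedge.

The number of scales follows `scaleCount(rows, cols) =
ceiling(log2(min(rows, cols)) - 3)`; a 128×128 ROI yields 4 scales. The
coarsest and finest scales are isotropic; intermediate scales are split
into angular wedges (16 at the second-coarsest scale by default),
doubling every second scale step (parabolic scaling).

Design choices worth knowing:

* **Windows.** Radial windows use the standard C-infinity compactly
  supported transition profile, assembled so that the squared magnitudes
  of all windows sum to exactly one at every frequency sample. Angular
  windows are built on the polar angle rather than a concentric-square
  perimeter coordinate: the partition-of-unity, tight-frame and wrapping
  structure is identical, and the polar profile is smooth at the square's
  corners. As a consequence the transform is numerically a *tight frame*:
  coefficient energy equals image energy and the adjoint is an exact
  inverse. The test suite asserts both at 1e-6; in practice they hold at
  machine precision (~1e-15).
* **Wrapping rectangles.** Each wedge's support box is enlarged to the
  smallest divisor of the image side (a power of two for 128-pixel
  images). The wedge sampling lattice then nests in the pixel grid, so
  translating the image by one coarse-grid step cyclically permutes the
  coarse coefficients exactly — a property the tests check.
* **Features.** For each wedge at the intermediate scales (2 and 3 for a
  128-pixel image) three statistics of the coefficient magnitudes are
  computed: mean, standard deviation, and energy. With the defaults this
  gives (16 + 32) × 3 = 144 features per image, ordered scale-major,
  wedge-minor, statistic-innermost. The end scales are excluded by
  default: the coarsest carries illumination offsets, the finest mostly
  noise. Magnitude statistics (not raw complex coefficients) are the
  standard texture usage; a full-resolution alternative would explode the
  input dimension without adding orientation information.

## Reduction: PCA, NCSOV, and the discriminant stage

The 144 features are correlated and partly redundant. The reduction
stage first fits a PCA (covariance with 1/(n−1) normalization, axes sign
fixed so the largest loading is positive). The PCA dimension `MA` can be
fixed directly (default 32) or chosen by the *normalized cumulative sum
of variance* (NCSOV): the smallest component count whose cumulative
eigenvalue fraction reaches a threshold (default 0.98, configurable —
there is no principled universal value, so it is deliberately exposed).

The supervised stage has two modes:

* **`"strict"` (default)** — classical Fisher LDA on the PCA scores,
  projecting onto the at most C−1 leading eigendirections of the
  within/between scatter ratio. For a binary problem this is one
  dimension. The PCA stage exists precisely to make the within-class
  scatter invertible (the small-sample-size problem); when it is still
  singular the error message says so and suggests remedies.
* **`"ranking"`** — each PCA axis is scored by its univariate Fisher
  ratio and the top `nKeep` axes are retained (default 28 of 32). This
  mode reproduces the dimensional bookkeeping in which a "PCA-LDA"
  cascade outputs dozens of features; it is well-defined for any class
  count and never singular.

Strict mode is the default because experiments on the synthetic data
showed the class signal is spread across many PCA axes, each with a
small univariate Fisher ratio; per-axis ranking cannot combine them,
and the end-to-end accuracy saturates ~10 points below the LDA cascade.
Ranking mode remains useful when more than one output dimension is
needed (e.g. for the saliency examples below) and as the interpretation
matching published feature counts.

## The extreme learning machine and its tuning

An ELM is a single-hidden-layer network whose input weights `W` and
biases `b` are *not* learned by backpropagation: they are drawn i.i.d.
uniform on [−1, 1], and only the output weights are computed — in closed
form, as the minimum-norm least-squares (Moore–Penrose) solution of
`H beta = T`, where `H[j,i] = act(w_i · x_j + b_i)` and `T` is the
one-hot class indicator matrix. The solve uses an SVD with relative rank
tolerance 1e-10. Training is a single decomposition; there is no epoch
loop anywhere in the code. Activations: sigmoid (default), tanh, ReLU.

Random hidden parameters are occasionally unlucky. The pelican
optimization algorithm (POA) is a two-phase population metaheuristic:

* **Exploration** — each member moves toward a *prey* point when the prey
  is fitter (`x + r (prey − I x)`, intensity `I` drawn from {1, 2}) and
  away from it otherwise (`x + r (x − prey)`), with per-coordinate
  random factors.
* **Exploitation** — a shrinking local sweep
  `x + R ((P − t)/P)(2 r − 1) x` with neighborhood constant `R = 0.2`,
  decaying linearly to zero over the `P` iterations.

Both phases accept a candidate only on strict improvement, so the
best-so-far trajectory is non-increasing by construction. The modified
variant (MOD-POA, the default) replaces the random prey by the midpoint
of the best and worst population members. Candidates are clipped to the
box bounds; random factors are drawn per coordinate for richer
exploration.

`trainModPoaELM` tunes the flattened `(W, b)` vector (dimension
`L (d + 1)`) in [−1, 1] against the misclassification rate on an inner
stratified 80:20 validation split — the natural surrogate when the
selection criterion is accuracy. The seed-derived random initialization
is injected as population member 1, so on the inner criterion the tuned
machine can never be worse than a plain random-init ELM. After the
search, output weights are refit on the full training data.

Two numerical points:

* **Feature scaling.** Reduced features are standardized (training mean
  and standard deviation) before the hidden layer, because uniform
  [−1, 1] weights presuppose comparably scaled inputs; the scaling is
  folded back into `W` and `b` afterwards, so the stored model operates
  directly on raw reduced features.
* **Conditioning.** When the hidden matrix is nearly rank-deficient
  (many hidden nodes fed by a one-dimensional input), the minimum-norm
  weights can be huge with heavy cancellation in the forward pass —
  classification is unaffected, but finite-difference comparisons of
  gradients lose digits. The saliency examples therefore use
  ranking-mode reductions with a few output dimensions.

## Evaluation protocol

Two protocols are provided: a stratified 60:40 holdout
(`holdoutSplit`) and repeated stratified k-fold cross-validation
(`crossValidate`, default 10 runs × 5 folds). Stratification deals each
shuffled class round-robin into the folds, so per-fold class counts are
within one sample of proportionality. Within every fold the reduction
and the optimizer touch only the training folds — a canary test writes a
perfect predictor into the held-out rows and asserts the fitted models
do not change. Metrics per fold: accuracy, sensitivity and specificity
in percent, with glaucoma as the positive class; undefined ratios
(a fold with no positives) surface as NaN with a warning, never as
silent zeros.

## The synthetic fundus generator

The generator (`generateFundus`) emulates what the features must
detect, not what a camera sees: a bright elliptical disc (intensity
~0.75) on a darker background (~0.35), a brighter concentric cup
(~0.95) with radius CDR × disc radius, vessel strokes dark (~0.2)
against both, a smooth illumination gradient, and additive Gaussian
noise (sd 0.02), clipped to [0, 1]. Healthy images use CDR 0.3,
glaucoma 0.7. All stochastic draws are label-independent, so equal-seed
image pairs differ *only* in cup size — the class signal is exactly the
CDR, by construction.

Parameters a reader may wish to understand:

* **Disc radius 24–28 px** (of a 128 px frame). ROI crops in screening
  pipelines are scaled relative to the disc, so the size distribution in
  a standardized crop is tight. Large radius variation mostly adds
  nuisance variance to boundary-energy features.
* **Vessels** are quadratic Bézier strokes leaving the disc alternately
  upward and downward with small angular jitter (±0.15 rad), width
  1.5–2.5 px — the superior/inferior arcade pattern of real ONH crops.
  They are rendered from the distance to the curve with a one-pixel soft
  edge: hard pixel stamping would inject aliasing energy across all
  curvelet scales, and that artifact (not anatomy) would dominate the
  features.

What the generator does *not* model: color, texture inside the disc,
peripapillary atrophy, lesions, camera vignetting, compression
artifacts. Passing tests on these images therefore demonstrate that the
pipeline recovers a geometric CDR signal through curvelet statistics
under clutter and noise — not clinical performance on real fundus
photographs.

Problem sizes used in the checks: the cross-validation demonstration
uses 50 images per class at 128×128 with a reduced optimizer budget
(population 10, 30 iterations), where the pipeline reaches ~93–98%
5-fold CV accuracy across seeds; tight-frame and reconstruction
properties are checked over 100 random images; gradient oracles over 20
pixels per image with central differences at step 1e-4.

## Saliency

Because every stage is differentiable (the curvelet stage is linear,
the reduction affine, the ELM analytic), the gradient of a class score
with respect to each input pixel is computed exactly by the chain rule;
the curvelet step back-propagates through the tight-frame adjoint,
which is the inverse transform itself. Non-smooth points (|·| at zero,
the ReLU kink) use subgradient 0.

Three standard attribution methods are built on this gradient: vanilla
gradients (absolute value), integrated gradients (midpoint-rule path
integral from a baseline, satisfying completeness: attributions sum to
the score difference), and SmoothGrad (averaged vanilla maps over
Gaussian-perturbed copies). CAM-family methods are deliberately out of
scope: they require convolutional feature maps or ReLU-specific
backprop rules that a shallow ELM does not possess, and no principled
adaptation exists.

On synthetic glaucoma images the saliency mass concentrates inside the
disc mask — the model genuinely looks at the optic nerve head, which is
where a clinician would look.

## Worked example

```{r example, eval = FALSE}
spec <- syntheticSpec()
ds <- generateDataset(spec, 50, 50, seed = 11)
X <- batchExtract(ds$images, curveletConfig(128))
cfg <- classifierConfig(U = 10, P = 30)
report <- crossValidate(X, ds$labels, cfg, runs = 1, k = 5, seed = 11)
report
#> EvaluationReport: 1 x 5-fold CV, positive class 'glaucoma'
#>   accuracy     93.00% +/- 10.37
#>   sensitivity  96.00% +/- 5.48
#>   specificity  90.00% +/- 22.36

pl <- trainPipeline(ds$images, ds$labels, cfg, seed = 1)
sal <- vanillaGradient(pl, ds$images[[60]])
renderHeatmap(sal, ds$images[[60]], file = "saliency.png")
```

## Known limitations

* The curvelet implementation targets square, even-sided images; the
  redundancy of the wrapped representation (~8× at 128 px) trades
  memory for exactness and simplicity.
* Strict-mode LDA requires the PCA dimension to stay below the
  training-sample count minus the class count; the error message guides
  the user when it does not.
* The optimizer's exploitation step contracts positions toward the
  origin, which favors objectives whose optimum lies near zero (true of
  the weight-tuning problem, whose search box is centered at zero).
* Synthetic validation bounds what can be claimed about real data; see
  the generator section above.
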