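---
title: "SpotSuite: models and methods for smFISH spot calling and barcode decoding"
author: "SpotSuite authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SpotSuite: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpotSuite)
```

# Overview

Single-molecule FISH and its multiplexed descendants (MERFISH, seqFISH, in
situ sequencing) reduce to two computational problems: finding
diffraction-limited fluorescent puncta ("spots") in images, and — in the
multiplexed case — reading each spot's on/off pattern across imaging rounds
and channels against a codebook to assign a gene identity. SpotSuite
implements a complete desk-scale pipeline for both:

1. **Classical annotators** (local maxima, difference of Gaussians,
   Laplacian of Gaussian) with subpixel refinement by isotropic 2-D
   Gaussian fitting.
2. **Weakly supervised consensus labeling**: detections from several
   annotators are clustered by proximity and a two-state Bernoulli
   generative model, fit by expectation maximization, scores each cluster's
   probability of being a true spot. This turns disagreeing heuristics into
   training labels without manual annotation.
3. **A fully convolutional detection model** with a pixel-classification
   head and a subpixel-regression head, trained on consensus (or simulated)
   labels.
4. **Probabilistic barcode decoding** with a mixture of relaxed Bernoulli
   distributions over the model's per-round spot-probability images, fit by
   gradient-based variational inference, plus Hamming-distance rescue steps.
5. **Simulators** for spot images, detection matrices and barcode traces,
   so every stage is testable offline, and **mutual-nearest-neighbor
   benchmarking** of point sets.

Everything here runs in minutes on one CPU; all randomness is seeded.

# Conventions

Coordinates are 1-based `(row, col)` with pixel centers at integer
positions, the R convention, used consistently in memory and in CSV files.
Subpixel positions are real-valued; nearest-pixel rounding is
half-away-from-zero (`roundHalfAway()`), so an offset of exactly 0.5 px is
deterministic. Barcode bits are ordered round-major (`r1c1, r1c2, ...`).

# The consensus model

Let `x[c, i] ∈ {0, 1}` record whether annotator `i` contributed a detection
to cluster `c` (clusters are connected components of the detection graph
linking detections within 1.5 px, screened to at most one member per
annotator). Each cluster carries a latent label `z[c]` (true/false spot).
Conditional on `z`, detections are independent Bernoulli draws with
per-annotator rates `TPR_i = p(x=1 | z=1)` and `FPR_i = p(x=1 | z=0)`.

The EM fit alternates:

* **E step** — posterior `p(z=1 | x, θ)` by Bayes' rule with prior 1/2 (the
  least informative choice; it cancels in the ratio);
* **M step** — maximum-likelihood rate updates from expected confusion
  counts: when `x[c,i]=1`, cluster `c` contributes `p_c` expected true
  positives and `1-p_c` expected false positives; when `x[c,i]=0` it
  contributes `p_c` expected false negatives and `1-p_c` expected true
  negatives; then `TPR = ΣETP/(ΣETP+ΣEFN)` and `FPR = ΣEFP/(ΣEFP+ΣETN)`.

Defaults follow the annotation protocol the model was designed around:
initial rates 0.9/0.1, prior 0.5, 20 iterations (ample for convergence at
these problem sizes — the observed-data log-likelihood trace is stored and
non-decreasing by the EM guarantee). Clusters with posterior above 0.9
become consensus spots at the cluster centroid.

Numerical choices: likelihoods in log space; rates clamped to
`[1e-4, 1-1e-4]` after each M step so no likelihood is exactly zero;
degenerate denominators (possible only on pathological inputs) fall back to
0.5 with a warning; screening ties broken by input order.

A practical identifiability note: matrices built from real detections
anchor the false class only through low-agreement clusters — disagreement
is the model's information source. A panel of detectors that fire on
essentially the same set of clusters (e.g. three well-tuned blob detectors
on clean images) leaves the false-positive rates unidentifiable and the
posteriors near the prior; the annotator panel should be diverse in its
failure modes. With three annotators the posterior of a fully agreeing
cluster may not clear 0.9; with the five annotators of the intended
protocol, clusters detected by at least four annotators pass comfortably. The package pools matrices across
images into one annotator model by default (`runConsensus`), with
per-image fitting available by calling `fitEM` on per-image matrices.

# Subpixel Gaussian refinement

Pixel-level candidates are refined on a 10×10 crop by bounded
Levenberg–Marquardt least squares of
`A·exp(-((r-r0)² + (c-c0)²)/(2σ²)) + b`. Initialization: mean at the
candidate pixel, amplitude 1 (images are min-max normalized), σ = 0.5 px;
constraints: mean inside the central 20% of the crop, σ ∈ (0, 3]. The even
window spans `[r-5, r+4]` and is shifted at image borders; when the shift
leaves the candidate outside the central band the constraint cannot hold
and the candidate is returned unrefined (flagged). A constant-offset term
is included so nonzero background does not bias σ. On noiseless rendered
spots with σ ∈ [0.8, 2.5] the localization RMSE is below 0.01 px; with
additive Gaussian noise of sd 0.05 it stays below 0.15 px.

# The detection model

The detector is a fully convolutional network whose receptive field is an
explicit hyperparameter: `(RF-1)/2` blocks of 3×3 convolution (stride 1,
zero padding), batch normalization and ReLU — each block adds 2 px of
receptive field — followed by two 1×1 heads: a classification head
producing the pixel-wise spot-probability logit and a regression head
producing the signed row/column offsets to the nearest spot. Default RF 13.
The plain 3×3 stack is the simplest translation-equivariant design meeting
the receptive-field contract. Convolutions, batch norm and their gradients
run in compiled code (RcppArmadillo); backpropagation is verified against
finite differences in the test suite.

**Targets** (`makeTargets`): one-hot classification image (one positive
pixel per spot at the nearest pixel), regression images holding
`spot − pixel` per axis, computed for every pixel within 2 px (Euclidean)
of a spot, and a validity mask. Offsets at positive pixels are ≤ 0.5 px by
construction. The regression images are defined everywhere inside the
neighborhood and the loss is masked to it — the masked-loss reading of the
"distance to the nearest spot" encoding.

**Loss**: weighted binary cross entropy over all pixels (positive class
weighted by the per-batch background/spot ratio, capped at 100 — spots
occupy well under 1% of pixels) plus mean squared error of the regression
maps restricted to the mask.

**Training** (`trainSpotNet`): SGD with Nesterov momentum (lr 0.01,
momentum 0.9), 90/10 train/validation split, per-image augmentation with
rotation 0–180°, flips and 0.8–1.2× scaling (bilinear resampling; spot
coordinates transformed with the same affine map and targets regenerated).
Deterministic given the seed. Default 20 epochs, batch 8, 8 filters per
layer — sized so the full benchmark (below) trains in ~10 minutes on one
CPU core; the filter count is configurable upward for more complex data.

**Postprocessing** (`postprocessPrediction`): strict local maxima of the
probability map above 0.95 via maximum filtering, then each peak's
coordinate is the pixel plus the predicted regression offsets. The
target-encoding/postprocessing pair round-trips subpixel coordinates to
below 1e-6 px on ideal predictions.

# Barcode decoding

Per round and channel, the detector's probability images are stacked into
an `H × W × (R·C)` array. Pixels whose max projection exceeds 0.01 are
decodable; each carries a trace of `R·C` values in (0, 1).

The generative model: a latent gene identity per trace (uniform categorical
prior over codebook rows, including an appended all-zero **background**
barcode that absorbs false detections), and per-bit likelihoods chosen by
the barcode bit — a shared "spot" distribution where the bit is on and a
shared "background" distribution where it is off, independent across bits,
parameters shared across genes. The default per-bit family is the **relaxed
Bernoulli** (binary Concrete) distribution on (0, 1) with density

`f(x; α, λ) = λ r x^{-λ-1} (1-x)^{-λ-1} / (r x^{-λ} + (1-x)^{-λ})²`,
`r = α/(1-α)`,

whose probability parameters `α` (one per bit and state — the codebook ties
each mixture component's logits to the spot or background parameter) and a
single shared learned temperature `λ` are fit by maximizing the evidence
with Adam (stochastic gradient variational inference; the discrete latent
is marginalized exactly, so the bound is tight). Analytic gradients; traces
clamped to `[1e-4, 1-1e-4]` (the open-interval support); 1000 steps at
learning rate 0.01 with minibatches of 1024 by default; deterministic given
the seed. A label-switching guard swaps any bit whose background parameter
exceeds its spot parameter after fitting. `bernoulli` (binarized) and
`gaussian` per-bit families are available as alternatives, fit by EM.

**Assignment**: per-trace posteriors over all codebook rows; the MAP row is
assigned when its posterior reaches 0.95, otherwise the trace is
`unknown`; the background row yields `background`.

**Rescues**: (i) *error rescue* — unassigned traces binarized at 0.5 are
reassigned to a real gene when the minimal Hamming distance is ≤ 1 and
achieved uniquely (ties stay unassigned); (ii) *mixed rescue* — traces
whose MAP gene is real but below threshold have that barcode's bits
subtracted; a unique Hamming-≤1 match of the residual records a second
transcript at the same location (both flagged `rescued_mixed`; a
replace-only mode is available). Binarization at 0.5 is the package's
reading of "pixel values" for Hamming comparisons.

**Extraction**: decoded pixels mask the max-projected probability image;
local maxima within the mask become transcripts inheriting the pixel's
gene. Exact-tie plateaus are deduplicated per gene, while equal-valued
neighbors decoded to different genes remain distinct transcripts. Bright
autofluorescent structures can be removed with a min-max-normalized
background image thresholded at 0.5 (or a user mask), and transcripts
aggregate per segmented cell into a sparse cell-by-gene matrix.

# Simulators

The simulators define the benchmark conditions:

* **Spot images**: isotropic Gaussians at uniform random subpixel
  locations; count uniform in [30, 80] per 128×128 image (matching the
  "up to ~200 spots per image" regime at desk scale); amplitude ~
  Normal(1.0, 0.2) truncated above 0.1; width ~ Normal(1.5, 0.3) px
  truncated above 0.5 px — a diffraction-limited point-spread function at a
  ~110 nm pixel pitch; flat background 0.1 (a supplied autofluorescence
  image may replace it); optional additive Gaussian noise, sd 0.01.
  Overlaps are allowed by default (`minSeparation = 0`); a margin option
  can keep spots off the borders. Not modeled: Airy rings, astigmatism,
  Poisson shot noise — so passing benchmarks here demonstrate correctness
  of the machinery, not robustness to every optical artifact of real data.
* **Detection matrices**: latent labels Bernoulli(prior), entries Bernoulli
  per the annotator's TPR/FPR. All-zero rows are kept (the matrix *builder*
  from real clusters can never produce them, but dropping them would bias
  the column means away from `prior·TPR + (1-prior)·FPR`).
* **Barcode traces**: on bits draw Beta(20, 2), off bits Beta(2, 20) —
  strictly inside (0, 1), compatible with the relaxed-Bernoulli likelihood
  and resembling confident probability outputs; each on bit is replaced by
  an off draw with the dropout probability.

# Benchmarks the package ships

The test suite and `scripts/acceptance.R` recompute, from scratch:

* EM recovery of TPR/FPR within ±0.03 and ≥95% label accuracy on 10,000
  simulated clusters (4 annotators, rates 0.9/0.1), with a non-decreasing
  likelihood trace; label accuracy non-decreasing over 3→5→7 annotators.
* Exact agreement of the clustering with a brute-force union-find oracle
  and of the matcher with an exhaustive mutual-NN oracle.
* Subpixel localization RMSE (500 rendered spots) < 0.05 px noiseless,
  < 0.15 px at noise sd 0.05.
* Detector end-to-end: trained on 200 simulated 128×128 images for 20
  epochs (batch 8), pooled F1 ≥ 0.8 at a 1.5 px mutual-NN threshold on 20
  held-out images (observed ≈ 0.95).
* Decoder: ≥95% assignment accuracy at zero dropout on 5,000 traces with a
  16-bit, 4-on-bit, 40-gene, minimum-distance-4 codebook; rescue-enabled
  accuracy at least matches rescue-disabled at dropout 0.1/0.2/0.3; every
  unassigned trace at Hamming distance exactly 1 from a unique barcode is
  rescued.

# Known limitations

* Image registration across rounds is out of scope; inputs are assumed
  registered (`runMultiplex` takes pre-aligned images or probability
  stacks).
* Cell segmentation is consumed as an external integer label mask.
* The annotator model is two-state (true/false) with one parameter set per
  dataset; per-image annotator parameters are not modeled.
* Channel/round correlations are ignored by design (independence
  assumption); codebook construction itself is not provided beyond the
  constant-weight random generator.
* 2-D only.
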