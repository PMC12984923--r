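---
title: "Entropy-based texture features and metaheuristic wrapper selection for MRI region classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based texture features and metaheuristic wrapper selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

`entrosel` classifies localized grayscale MRI regions of interest (ROIs) as
tumor or non-tumor tissue. The premise is physiological: tumor tissue shows
more heterogeneous, irregular intensity texture than healthy brain
parenchyma, and irregularity is exactly what entropy measures quantify. The
pipeline has four stages:

1. **Preprocessing.** Each ROI (a bounding-box crop, supplied in YOLO
   center-format normalized coordinates by an upstream detector or by the
   synthetic generator) is denoised with a truncated Gaussian kernel,
   resized to a standard square with bilinear align-corners interpolation,
   rescaled to the fixed intensity range $[0, 255]$, and rasterized
   row-major into a 1-D signal.
2. **Entropy bank.** 39 descriptors $F_1..F_{39}$ are computed per signal:
   approximate/sample/fuzzy entropy families at several embedding
   dimensions, symbolic measures (permutation, dispersion, slope),
   spectral and distributional measures, multiscale composites, and ten
   *cross*-signal variants that measure asynchrony between the ROI and a
   reference region from the same image.
3. **Wrapper feature selection.** A population metaheuristic — the superb
   fairy-wren optimizer (SFOA) by default; particle swarm (PSO), Harris
   hawks (HHO) and a puma-style optimizer (PO) as baselines — searches
   $[0,1]^{39}$; positions binarize at a 0.8 threshold into feature masks
   scored by the fitness
   $$\mathrm{fit} = \alpha\,(1 - \mathrm{Acc}) + (1-\alpha)\,N_s/N_t,$$
   where $\mathrm{Acc}$ is validation accuracy of a 1-nearest-neighbor
   classifier on the masked features, $N_s$ the selected count, $N_t = 39$,
   and $\alpha = 0.99$. Lower is better.
4. **Classification.** The selected subset feeds a $k{=}1$ kNN (Euclidean,
   uniform weights, z-scored features; a linear SVM at box constraint 1 is
   available for comparison), evaluated with stratified 10-fold
   cross-validation, confusion-matrix metrics (accuracy, macro
   precision/recall/F1) and ROC/AUC.

The fitting interface is the classic modelling idiom: `entrosel(x, y)`
returns a classed object with `print()`, `summary()`, `coef()` (the 0/1
selection mask), `predict()` and `plot()` (convergence curve) methods.

## SFOA update rules

Each individual $X_i$ keeps its previous-iteration position. Per iteration
each individual independently draws one of three stages (uniform thirds;
the stage-selection rule is an interpretation, exposed as
`stage_probs`):

* **Growth** (exploration): $X' = X + \mathrm{rand}\,(X - X^{prev})$ with
  one $U(0,1)$ draw applied to all coordinates (`rand_mode = "scalar"`;
  per-coordinate draws available).
* **Breeding** (exploitation): $X' = X_b + C\,p\,(X - X_b)$ with the
  population best $X_b$, constant $C = 0.8$, and maturity
  $p = \mathrm{FEs}/\mathrm{MaxFES}$.
* **Enemy avoidance** (escape): $X' = X + l\,k\,(X_b - X)$ with a Mantegna
  Lévy step $l$ ($\beta = 1.5$) and flight coefficient
  $k = 0.2\sin(\pi/2 - \omega)$, $\omega = (\pi/2)\,\mathrm{FEs}/\mathrm{MaxFES}$,
  so $k$ decays from 0.2 to 0.

Candidates are clipped into $[0,1]^D$ and accepted greedily (strict
fitness improvement). The budget counts every candidate evaluation,
including initialization, toward $\mathrm{MaxFES} = N(T+1)$ for population
size $N$ and $T$ iterations. Fixed seeds make runs bit-reproducible. The
baselines share the binarization and fitness path and differ only in their
update rules: PSO uses linearly decaying inertia $0.9 \to 0.4$ with
$c_1 = c_2 = 2$; HHO the canonical escape-energy branches
($E = 2E_0(1 - t/T)$) with Lévy rapid dives; PO is a simplified rendering
of the puma optimizer's phase logic — exploration by dimension-wise
recombination of random individuals, exploitation by best-guided
contraction with occasional Lévy kicks, the phase chosen by a running
score of recent improvements.

### A note on search behavior

With the update rules above, the breeding stage contracts the population
onto the current best mask quickly, and under greedy acceptance the growth
stage proposes no movement until an individual has accepted at least one
move. The search is therefore strongly local in mask space: it refines
masks near the best-known one rather than sampling the $2^{39}$ lattice
broadly. In the strong-signal regime this package targets — planted
synthetic classes whose entropy descriptors separate nearly perfectly,
matching the near-saturated accuracies the method is designed for — many
masks tie near the optimum and the local search reliably reaches one. On
weak-signal problems where near-optimal masks are rare, the optimizer can
stagnate; users who need global guarantees at small dimension should use
exhaustive enumeration (`evaluate_mask` over all masks), which the test
suite uses as the oracle.

## Parameter defaults and their origin

None of the entropy measures' parameters are dictated by the application;
the registry uses each measure's literature defaults, overridable via
`feature_registry(params = ...)`:

* tolerance $r = 0.2\,\mathrm{SD}$(primary signal) for the
  approximate/sample/fuzzy/multiscale families and their cross variants
  (the classic regularity-statistics convention); embedding delay
  $\tau = 1$ throughout;
* permutation $m = 3$; dispersion $m = 2$, $c = 6$ classes;
  distribution entropy $m = 2$ with 512 distance bins; bubble $m = 10$;
  cosine-similarity $m = 2$, angular tolerance 0.1; corrected conditional
  entropy 6 quantization bins, $m = 2$; diversity $m = 2$, 5 similarity
  bins; entropy-of-entropy 5-sample windows, 5 levels; gridded
  distribution $3\times 3$ Poincaré grid; phase entropy 4 sectors of the
  second-order difference plot; slope entropy thresholds 5.0 and 0.001
  intensity units; Shannon histogram 256 bins over $[0,255]$.
* **Range entropy** uses $r = 0.2$ on its own *normalized* distance scale
  (its range distance lies in $[0,1]$ by construction); an SD-scaled
  tolerance on $[0,255]$ signals would accept every template pair and
  degenerate the measure to 0.

Two degenerate-case conventions keep feature vectors finite where
possible: the $m = 0$ entries use the generalized formulas (zero-length
templates match universally, so $\Phi^0 = 0$ and the $m$-template count
is all pairs), and a sample-entropy numerator of zero returns the finite
cap $\ln B + \ln(N - m)$ with a `capped` flag instead of infinity.
Cross-approximate entropy can still be non-finite on short signals (a
template may match no reference template, giving $\ln 0$); such raw
values become `NA` in `extract_features()` and `feature_table()` imputes
them with the per-feature median of the finite values, recording the
positions in an `imputed` attribute. The cross measures' reference signal
is the complementary region of the same source image (tumor ROI paired
with background tissue and vice versa); the pairing is a documented
choice, configurable by constructing `sample_pair()` objects directly.

The wrapper defaults follow the experimental configuration the method was
designed around: population 50, 100 iterations, dimension 39, bounds
$[0,1]$, binarization threshold 0.8, $C = 0.8$; $\alpha = 0.99$ is the
standard wrapper-selection weighting (the application itself never states
it). Fitness inside the wrapper uses a stratified 1/3 holdout by default
(`validation = "holdout"`), matching the notion of accuracy "on the
validation set"; k-fold fitness is available (`validation = "cv"`), and
the final reported evaluation is always stratified 10-fold
cross-validation. Since a $k{=}1$ vote yields no graded score, ROC curves
for kNN use the signed distance margin (nearest other-class distance
minus nearest voted-class distance) — an interpretation, documented here.
Macro-averaging over the two classes is used for precision/recall/F1; on
near-balanced data this makes precision ≈ recall ≈ accuracy.

## The synthetic generator

The generator is first-class, tested code that emulates the *structure*
of a detector-annotated MRI dataset without any real data: per-image
tumor and non-tumor ROIs where tumor regions carry irregular high-entropy
texture. Backgrounds are a smooth AR(1) texture (coefficient 0.95) on an
elliptical "brain" disk over a dark field; tumor blobs are ellipses of
white noise mixed with multiplicative exponential speckle (weight 0.5).
Blobs sit in the upper half of the disk and background boxes in the lower
half, so the two regions of an image never overlap. `"study"` mode fixes
834 images split 583/123/128 (train/validation/test) *before* ROI
extraction — no source image contributes ROIs to two subsets — and the
test split yields a 256-row, class-balanced feature table (two ROIs per
image). `"quick"` mode uses small counts with stratified 70/15/15
fractions. `generate_signal_pair()` is a 1-D shortcut producing the same
texture contrast for unit tests.

What the generator does *not* emulate: anatomy, scanner physics, partial
volume effects, intensity nonstandardization across scanners, detector
localization error, or ambiguous tumor boundaries. Its classes are far
better separated than difficult clinical data; passing tests demonstrate
the pipeline's mechanics and its ability to recover planted structure,
not clinical performance.

## Numerical choices

* Denoising: separable convolution, kernel truncated at $4\sigma$
  (default $\sigma = 1$ px), edge-inclusive reflected padding; constants
  preserved exactly and interior mass conserved to $10^{-6}$ relative.
* Resizing: align-corners mapping so output corners sample input corners
  exactly; resizing to the same size is the identity.
* Box denormalization: 0-based half-open pixel intervals, round half up;
  crops below $2\times 2$ pixels raise a degenerate-ROI error.
* Standard ROI size 64×64 (4096-sample signals), configurable; the
  test suite runs mostly at 32×32, which the maintainers chose to keep
  the full suite and the study-scale structural checks fast while
  exercising identical code paths (row counts and contracts are
  size-invariant). Wrapper-recovery tests use 256-sample synthetic
  signals, population 20 and 30 iterations.
* Ordinal patterns break ties by order of occurrence (stable `order()`);
  the binarization fallback (no coordinate above threshold) selects the
  single largest coordinate, lowest index on ties, and flags the mask.
* kNN distance and vote ties resolve to the lowest training index; at
  even $k$ a split vote falls back to the nearest neighbor's label.
* All stochastic stages draw from R's RNG under explicitly passed seeds;
  optimizer runs, dataset generation and cross-validation restore the
  caller's RNG state.

## Limitations

* The entropy bank is $O(N^2)$ in signal length for the template-matching
  measures (compiled kernels); 64×64 ROIs cost a few seconds per sample,
  so large studies should batch or reduce the standard ROI size.
* The cross-Kolmogorov (K2-style) estimator is the least standardized
  measure in the bank and is sensitive to its tolerance; treat its
  absolute values with caution.
* The optimizer comparison inherits each baseline's published defaults
  where the application states none; the PO baseline in particular is a
  simplified, clearly-versioned rendering of its published description.
* Wrapper selection optimizes validation accuracy of a 1-NN classifier;
  with small validation sets the selected masks can overfit the split.
  The reported 10-fold CV metrics mitigate but do not eliminate this.
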