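---
title: "Methods: wavelet-based decision support for melanocytic lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet-based decision support for melanocytic lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermwave)
```

# The problem and the model

dermwave classifies polarised dermoscopic images of melanocytic lesions by
the management decision an expert dermatologist would take — excise or do
not excise — rather than by diagnosis. The pipeline is deliberately modular:
image standardisation, a wavelet texture feature bank, instance-based
feature ranking, linear feature extraction, and a kernel classifier. Each
stage can be swapped independently, and each is exposed as a plain function
as well as through the umbrella fit `dermwave_fit()`.

This vignette records the model, its assumptions, the numerical choices, and
the places where the design was genuinely open, so that a maintainer can see
*why* the defaults are what they are.

# Preprocessing and segmentation

Every image is first rescaled so its maximal dimension is 1000 px
(bilinear, aspect preserved, round-half-up on the other dimension). Images
smaller than the target are *upscaled*: the downstream wavelet statistics
compare textures across lesions, so a uniform spatial scale matters more
than avoiding interpolation. No hair removal, specular suppression or
histogram normalisation is applied.

Segmentation is a two-region, vector-valued Chan-Vese active contour: the
level-set function $\varphi$ partitions the frame into $D$ (inside) and
$\Omega \setminus D$, and the energy

$$f(c_1, c_2, \Psi) = \mu_1 L(\Psi) + \mu_2 A(D)
 + \lambda_1 \sum_{\text{ch}} \sum_{D} |F - c_1|^2
 + \lambda_2 \sum_{\text{ch}} \sum_{\Omega\setminus D} |F - c_2|^2$$

is minimised with $c_1, c_2$ the per-channel region means, recomputed every
iteration. The colour extension sums the fidelity terms over R, G and B with
a shared contour. Parameter defaults are the classic settings
$\mu_1 = 0.25$, $\mu_2 = 0$, $\lambda_1 = \lambda_2 = 1$: the length penalty
is the only regulariser a dermoscopic lesion needs, and an area penalty
would bias lesion size. All are configurable via `chan_vese_params()`.

Numerics: the descent uses a smoothed Heaviside/Dirac pair with
$\varepsilon = 1$ px, a checkerboard initial level set (no seeding
information is assumed), explicit gradient steps with the curvature term
discretised by central differences, and — the one non-textbook choice — a
per-step backtracking line search on the smoothed energy. Backtracking makes
the energy monotone non-increasing by construction, which turns an informal
expectation into a testable invariant. Iteration stops when the relative
level-set change falls below `tol`, when the energy stalls (three
consecutive steps improving by less than `tol/100` relative), or at
`max_iter` with a warning. After the descent, a piecewise-constant
refinement alternates the two closed-form minimisers (region means; nearest
level per pixel) to a fixed point: it removes islands left by the
initialisation and gives exact pixel classification on two-level images,
where the region means then equal the generating values exactly. The lesion
is the region with the lower mean luminance — pigmented lesions are darker
than surrounding skin.

The full-image chain (`preprocess_image()`) segments at a reduced working
resolution (max dimension 256 by default) and upsamples the mask before
cropping: the contour only feeds a bounding box that is subsequently
resampled, so sub-pixel contour precision at 1000 px buys nothing. The crop
is padded symmetrically with blank (zero/black) pixels to a square and
bilinearly resampled to $2^9 \times 2^9 = 512 \times 512$. Padding with
zeros (rather than skin colour) is a declared convention: the padding is
*not* masked out downstream, and the zero-variance handling in the feature
statistics keeps constant regions finite. Whether the original frame should
be resampled before or after padding is not decidable from first principles;
both orders are supported (`pad_then_resize`), with pad-then-resample the
default since an arbitrary crop cannot hit 512 exactly without a resample.

# The wavelet feature bank

Each of the R, G, B and luminance channels (Rec.601 luma,
$0.299R + 0.587G + 0.114B$) is decomposed six levels deep with the standard
Mallat pyramid: at each level the four sub-bands LL, LH, HL, HH are produced
by separable low/high-pass filtering with stride-2 downsampling and periodic
boundary extension, and the LL band is decomposed further. For a 512 × 512
frame the level-6 bands are 8 × 8.

The default wavelet is the Shannon (ideal half-band) wavelet, applied
*exactly* in the Fourier domain: on the periodic power-of-two frames used
here the ideal split is alias-free, orthonormal (the boundary frequency bins
are shared between the bands as their real and imaginary parts), and
exactly invertible. The published name of the original transform carries a
family index whose filter taps have no public coefficient table; rather than
guess taps, the package implements the Shannon wavelet exactly and exposes a
registry of orthonormal FIR alternatives (`haar`, `d4`, `sym4`) so the
wavelet is a configuration choice, as it should be in a modular pipeline.
The printed textbook form of the forward transform carries a leading factor
2 and an index shift of two samples — a non-orthonormal convention. The
package defaults to the orthonormal convention (normalisation inside the
filter taps); `literal_normalisation = TRUE` applies the printed form. All
sub-band statistics are scale-covariant, and ReliefF range-normalises
features, so the ranking behaviour is unaffected by this choice.

Every sub-band contributes twelve statistics: mean, absolute mean, energy,
variance over all coefficients, plus the mean and variance of the per-row
and per-column skewness and kurtosis. Conventions, each of which was an open
choice:

* *energy* is the **mean** of squared coefficients — scale-free across
  levels, so level-6 bands (64 coefficients) are comparable with level-1
  bands (65536);
* moments are **population** (biased) estimators; kurtosis is **raw**, not
  excess;
* a row or column with zero variance has undefined skewness/kurtosis and
  contributes **0** — this is what keeps blank padding finite rather than
  NaN.

The ordering is level (outermost), band (LL, LH, HL, HH), channel (R, G, B,
Luma), statistic: $6 \times 4 \times 4 \times 12 = 1152$ features, named
`L{level}_{band}_{channel}_{stat}` (`feature_schema()`). The CSV reader
accepts any 1152-column numeric table with an optional header or ID column,
since the exact dialect of externally produced tables varies.

# Feature ranking and the plateau

`relieff_rank()` is standard two-class ReliefF: every instance is visited
(exhaustive passes — deterministic, no sampling), its $k = 10$ nearest
same-class hits and $k$ nearest other-class misses are found by Manhattan
distance on range-normalised features, and each feature's weight accumulates
mean miss-differences minus mean hit-differences, landing in $[-1, 1]$.
The neighbour count and the exhaustive policy are this package's choices —
$k = 10$ is the conventional default and the exhaustive pass removes a
source of randomness at these sample sizes (hundreds of lesions). Ties in
the ranking break by ascending feature index for determinism.

`sweep_feature_count()` traces cross-validated performance (mean of
sensitivity and specificity) against the cumulative count of top-ranked
features. The plateau is reported as the smallest count within 0.005 of the
sweep maximum — reported, never silently applied, since plateau reading is a
judgement call. At the original study's scale the plateau sits near 125
native features, which is the default `top_n` of the umbrella fit.

# PCA feature extraction

`fit_pca()` standardises the training table to zero mean and unit variance
(sample, $n-1$ standard deviations) and takes the SVD $X = W D V^\top$; the
principal components are $PC_{train} = X V$ and the covariance eigenvalues
are $d_i^2/(p-1)$. The train/test contract is strict: test rows are
standardised with the *training* mean and standard deviation and projected
onto the training loadings, $PC_{test} = Y V$ — a single lesion is the
one-row case. Nothing is ever refit on test data, and the tests assert this
asymmetry directly. Sign ambiguity of singular vectors is resolved by making
the largest-magnitude entry of each loading positive, so results are
deterministic across BLAS implementations. Constant columns cannot be
standardised and are dropped with a warning (or an error in strict mode).

The default of 22 components reflects the operating point of the
eigenvalue curve at the study scale (decay flattening around 25); 16
maximises sensitivity and the 7–40 range is worth sweeping on new data. No
additional scaling is applied after PCA — the components are already
variance-ordered, and rescaling them would discard exactly the information
PCA ordered them by; this was left as a flagged sensitivity choice.

# Classifiers and probabilities

The primary classifier is a soft-margin SVM with the Gaussian RBF kernel
$K(x, x') = \exp(-\gamma \lVert x - x'\rVert^2)$, $C = 30$,
$\gamma = 0.007$ at the operating point (e1071/libsvm underneath).
Probabilities are Platt-scaled; the sigmoid is fitted by internal
cross-validation, which makes probabilities (not margins) slightly seed
dependent — the fitting functions therefore take an explicit seed.
Decisions compare $P(\text{excise})$ with a 0.5 cut-off; a probability
exactly at the threshold maps to *excise*, the clinically conservative
direction. The excise class is the positive class everywhere.

Random forest (`n_trees`, minimum leaf size 1) and penalised logistic
regression (L1/L2, with `reg_param` interpreted as the penalty strength
$\lambda$ — stated explicitly because the opposite, inverse-regularisation
convention exists) are provided as comparators behind the same interface.

# Cross-validation protocol

`cross_validate()` refits *every* stage — ReliefF ranking and the PCA
projection — inside each training fold, so no held-out information leaks
into selection or extraction. Folds are stratified by default: with a
165/85 imbalance, unstratified folds occasionally starve the minority class
and destabilise specificity. Leave-one-out is `folds = p`; it runs once
(its fold structure is deterministic) and pools sensitivity and specificity
over the $p$ held-out predictions, since per-fold metrics are undefined at
$n = 1$. Whether the original protocol refit the selection inside folds is
not recoverable; the leak-free variant is the default and
`global_selection = TRUE` reproduces the optimistic alternative — the two
can differ by a few $\times 10^{-2}$ in error, which is why both are
reported side by side where relevant.

ROC curves sweep the unique predicted probabilities and use trapezoidal
AUC. The diagnostic odds ratio
$\mathrm{DOR} = \frac{\text{sens}\cdot\text{spec}}
{(1-\text{sens})(1-\text{spec})}$ requires both inputs strictly inside
$(0,1)$; boundary values raise an explicit infinite-DOR error. At the ROC
operating point (sensitivity 0.97, specificity 0.89) the closed form gives
261.6.

# Synthetic data: what it does and does not show

`simulate_lesion_image()` draws a skin-toned canvas with a darker elliptical
lesion, a sinusoidally perturbed border (harmonics 3–6, seeded phases) and
four octaves of value noise from lattice scales of side/64 up to per-pixel.
The excise class has strictly larger fine-octave texture amplitude and
border irregularity than the benign class, so the classes differ in exactly
the quantities the wavelet bank measures. Skin and lesion base colours are
fixed plausible dermoscopy tones; their exact values affect realism, not
correctness. `simulate_feature_table()` generates feature tables directly: a
shared-factor model gives blocks of 12 features a within-block correlation
of 0.5 (emulating the strong linear relationships between decomposition
levels and between statistics of one band), and the excise class is shifted
by `delta` standard deviations on `n_informative` features. Defaults follow
the study conditions: 165/85 class sizes, 1152 features, 20 informative
features at `delta = 2`.

What passing tests on these generators shows: the pipeline's mechanics —
segmentation fidelity, feature cardinality and determinism, ranking
recovery, the train/test PCA contract, leak-free cross-validation — behave
correctly at the study's scale and imbalance. What it does not show: real
dermoscopic performance. The planted effect of two standard deviations on
twenty features is cleanly separable, so synthetic CV metrics saturate near
1.0 and must not be read as the study's 0.93/0.87 operating point, which
depends on the original images. The generator deliberately omits hair,
ruler marks, specular reflections and colour variegation — the original
study excluded severely compromised images rather than model them.

# Problem sizes and runtime choices

The shipped tests and the acceptance script choose problem sizes that
exercise every claim at full fidelity where it matters (512 × 512 frames for
the feature bank and the disk-segmentation check; 250 × 1152 tables for the
pipeline) while keeping simulation counts modest elsewhere: repeated CV uses
5 repeats rather than the study's 50 (the repeat-to-repeat spread of
stratified 10-fold means at these sizes is far smaller than the tolerances
being checked), Monte-Carlo checks use a few thousand draws, and unit-level
segmentation tests run at 96–256 px. These are the package's own choices of
test scale; all sizes are parameters, and nothing in the implementation
depends on them.

# Known limitations

* Chan-Vese with a checkerboard initialisation finds high-contrast lesions
  reliably but is a local method: very low-contrast or multi-focal lesions
  can converge to partitions other than the intended one.
* The Shannon wavelet's ideal-band split assumes periodic frames; on
  non-periodic content its effective impulse response is long, which is the
  usual trade-off against short FIR filters (provided as alternatives).
* Platt probabilities are calibrated on the training folds of a small
  internal CV; with very small training sets the calibration is noisy even
  when the margin ranking is stable.
* The package evaluates tables it is given; claims about the original
  study's images require the original supplementary tables, which are not
  shipped. `reproduce_study()` implements that exact protocol for anyone
  holding them.
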