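---
title: "Auditing photometric robustness of image classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing photometric robustness of image classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photosens)
```

## The model and its assumptions

photosens treats a trained image classifier as a fixed black box
$Y = f(X)$ where $Y$ is the predicted probability of the positive class
(melanoma, in the motivating dermoscopy setting) and
$X = (X_1, \dots, X_5)$ is a vector of photometric acquisition factors:
brightness, contrast, sharpness, saturation and hue. The question is a
risk-analysis question, not an explanation question: over the whole
space of plausible acquisition conditions, which factors drive the
variance of the prediction?

Variance-based global sensitivity analysis answers it with two
per-factor summaries. The first-order index

$$S_{1,i} = \frac{V_{X_i}\!\left(E_{X_{\sim i}}(Y \mid X_i)\right)}{V(Y)}$$

is the fraction of output variance attributable to factor $i$ alone; the
total-order index

$$S_{T,i} = \frac{E_{X_{\sim i}}\!\left(V_{X_i}(Y \mid X_{\sim i})\right)}{V(Y)}$$

adds every interaction involving the factor, so $S_{T,i} - S_{1,i}$
measures interaction strength and $S_{1,i} = S_{T,i}$ exactly for
additive models.

Two assumptions are built in and should be kept in mind when reading
results. First, the factors are sampled **independently** on their
bounded ranges. This is a modeling choice that makes the variance
decomposition well defined and reproducible; in real acquisition some
correlation between factors (e.g. brightness and contrast under
changing illumination) is expected, so the indices are first-order risk
indicators that may understate compound effects. Dependence-aware
indices are deliberately out of scope. Second, the predictor must be
**deterministic in the input bytes**; the predictor adapter verifies
this, along with output range and batch-order preservation, on a canary
batch before any audit runs.

## Factor bounds

The default bounds are multiplicative ±50% for brightness and
saturation, ±20% for contrast and sharpness, and a ±0.1 normalized
circular shift for hue. They encode a trade-off: wide enough that the
measured variance reflects genuine operational variability (sensor
differences, ambient light temperature, lens-to-skin distance), narrow
enough that no perturbed image becomes non-diagnostic — hue especially
is held to a tight range because larger shifts destroy the diagnostic
color of a pigmented lesion. All bounds are configurable per run and
are serialized into the run manifest.

## The perturbation pipeline and its numerics

Every evaluation applies, in a fixed sequential order: bilinear resize
to the working resolution (128×128 by default), brightness, contrast,
sharpness and saturation enhancements, then the hue shift. Each stage
operates on 8-bit integers, rounds half away from zero, and clips to
[0, 255], so the pipeline is bit-reproducible across platforms; the
kernels are compiled (Rcpp) and the semantics are normative for this
package:

* each enhancement computes
  `round_clip((1 − factor) · degenerate + factor · original)` against a
  degenerate image — all-black for brightness, the uniform rounded mean
  integer-luma image for contrast (luma weights 299/587/114), the
  per-pixel integer-luma grayscale for saturation, and a 3×3-kernel
  ([[1,1,1],[1,5,1],[1,1,1]]/13) smoothed copy with the border ring
  copied unchanged for sharpness. Degenerate images are quantized to
  8 bits before interpolation, so every intermediate is itself a valid
  image;
* the hue stage converts to 8-bit HSV (hexcone, all three channels on
  [0, 255]) and applies
  $H_\text{new} = (H_\text{old} + \text{round}(\Delta H \cdot 255)) \bmod 256$,
  leaving S and V untouched. A zero integer shift is a byte-exact
  identity, shifts compose additively modulo 256 on the hue channel,
  and a shift followed by its negation restores hue up to the one-unit
  quantization of the HSV round trip (measured RGB round-trip error on
  dermoscopy-like fixtures: at most 3 units per channel);
* the nominal sample (1, 1, 1, 1, 0) therefore reproduces the resized
  image byte-for-byte, which anchors the baseline prediction used by
  the decision metrics.

The stage **order matters**: enhancements do not commute on 8-bit data
(the tests demonstrate brightness∘contrast ≠ contrast∘brightness on a
gradient image), which is why the order is fixed and documented rather
than configurable.

Where the enhancement semantics left genuine choices — the rounding
convention (half away from zero), bilinear resize interpolation, the
8-bit quantization of all three HSV channels, border handling for the
smoothing kernel, and rounding the contrast mean before interpolation —
this package fixes one option each and treats the formulas above as the
specification, so results are reproducible from this document alone.

## Sampling design and estimators

Indices are estimated from the Saltelli paired-matrix design: two
independent $N \times D$ matrices $A$ and $B$ plus the $D$ hybrids
$AB_i$, giving $N(D+2)$ evaluations per image — 1792 at the default
$N = 256$, $D = 5$, and 1,675,520 model inferences for a 935-image test
set. The serialized evaluation order ($A$, then $B$, then
$AB_1 \dots AB_D$) is part of the contract and is what response vectors
align to.

Points come from a Sobol' low-discrepancy sequence (gray-code
construction, Joe–Kuo direction numbers, 30-bit precision) in $2D$
dimensions, mapped affinely onto the bounds. The seed applies a random
digital shift (per-dimension XOR scramble) drawn reproducibly from the
seed, so identical seeds give bitwise-identical designs while different
seeds decorrelate replicate audits; the dyadic stratification of every
1-d projection is preserved by the scramble and is property-tested. The
default seed is 2021. Whether to scramble at all, and with which
convention, was an open choice; the digital shift was chosen because it
keeps the net structure exact while making the seed meaningful. Exact
numeric reproduction of any other implementation's sample points is not
claimed. Non-power-of-two $N$ degrades the balance properties of the
sequence and triggers a warning rather than an error.

$S_1$ uses the Saltelli-2010 estimator
$\text{mean}(f(B)(f(AB_i) - f(A))) / V(Y)$ and $S_T$ the Jansen
estimator $\text{mean}((f(A) - f(AB_i))^2) / (2 V(Y))$, with $V(Y)$
from the pooled $A$ and $B$ evaluations. Raw estimates can fall
slightly outside $[0, 1]$ by Monte-Carlo noise; they are reported raw
with a clipped companion view, because silent clipping would hide
estimator noise. A response variance below $10^{-12}$ (on the
probability scale) sets a degenerate flag and returns zero indices with
a warning instead of dividing by near-zero.

The estimators are validated three ways: closed-form recovery on the
Ishigami function ($a = 7$, $b = 0.1$; $S_1 \approx (0.314, 0.442, 0)$)
and the Sobol g-function at $N = 4096$; equivalence with an independent
double-loop Monte-Carlo oracle that samples the conditional
expectations literally (desk-scale only, $D \le 4$, budget-guarded);
and the additive identity $|S_T - S_1| \le 3$ standard errors on linear
models.

## Per-image runs and aggregation

Indices are computed per image and then aggregated by unweighted
arithmetic mean with cross-image sample SDs ($n-1$ denominator) and
normal-approximation 95% confidence half-widths $1.96\,\sigma/\sqrt{M}$
— the CI convention was unspecified territory and this is the package's
fixed choice. One design is generated per run and reused across images,
so cross-image differences in indices are attributable to the images
rather than to sampling noise; this too was an open choice and is
logged in the manifest. Degenerate images are excluded from means (not
zero-filled) with exact accounting of input/used/degenerate counts.
Stratified tables (diagnostic class, sex, age, localization, or any
metadata column) reuse the same per-image results.

## Decision metrics

Because clinical decisions are thresholded, the continuous variance
decomposition is complemented by: the flip rate
$\Pr(\mathbf{1}\{p(X) \ge t\} \ne \mathbf{1}\{p(\tilde X) \ge t\})$
against the baseline prediction on the nominal (resized) image, with
$t = 0.5$ and ties counting as positive; the Gini dispersion
$2\hat p(1-\hat p)$ of the binary perturbed predictions (twice the
Bernoulli variance, on $[0, 0.5]$); and the Brier score of the baseline
predictions against the labels (the perturbed-set Brier is a flag away).
The dataset-level flip rate pools all image×perturbation pairs, i.e. an
evaluation-weighted mean of per-image rates. One-at-a-time sweeps use
$n$ evenly spaced grid points spanning a factor's bounds inclusive
(default 5), all other factors nominal.

## Surrogate Shapley attribution

As an independent cross-check of the Sobol ranking, a random-forest
surrogate (ranger, 300 trees, seeded, single-threaded for
reproducibility) is fitted per image to the perturbation-response table
harvested during the GSA run, with a seeded 80/20 split reporting
out-of-sample $R^2$. Shapley values are then computed **exactly** by
enumerating all $2^D$ coalitions (32 at $D = 5$) under the
interventional value function — coalition members fixed to the
explained sample, the rest drawn from a background of the table's own
rows. Exact enumeration was chosen over a tree-specific algorithm
because it is feasible at this dimension and independent of any one
ensemble's internals; the efficiency, symmetry and dummy axioms are
verified in the tests, and a permutation-sampling estimator provides an
internal cross-check. The background is capped at 200 seeded rows and
50 explained rows per image by default (40 in the acceptance runs) to
bound cost; attribution is aggregated as the per-factor mean absolute
Shapley value across explained rows and images, and compared to the
mean-$S_T$ ranking by Kendall's $\tau$ and top-1 agreement.

## The synthetic data generator

The fixture generator emulates the features of dermoscopy photographs
that the perturbation model acts on: a warm skin-tone background
(sampled hue around 0.07 with a mid-bright value level of ~165/255,
leaving headroom so a +50% brightness perturbation does not clip the
whole frame), a smooth illumination gradient and low-frequency
mottling, fine-grained micro-texture standing in for the pigment
network (without it, images are unrealistically smooth and the
sharpness factor has nothing to act on), one elliptical pigmented blob
with a soft radial edge — darker and more color-variegated when
labelled melanoma — and occasional dark hair strokes. Metadata columns
are sampled from the standard dermoscopy vocabulary and the binary
label is 1 exactly when dx is melanoma. Generation is fully
deterministic given the spec's seed.

What the generator does **not** emulate: real lesion morphology
(asymmetry, border irregularity, dermoscopic structures), camera noise
models, vignetting, rulers/markers, or any correlation between
appearance and metadata. Passing tests on synthetic data therefore
demonstrate that the *pipeline* is correct — perturbations have their
exact documented semantics, estimators recover known sensitivity
structure, rankings are stable — not that any particular real
classifier is robust. Auditing a real model requires plugging that
model in behind the predictor contract.

The probe predictors close the loop end-to-end: each computes a scalar
statistic matched to one factor (mean HSV value for brightness;
value-channel coefficient of variation for contrast; mean saturation;
circular mean hue; mean absolute Laplacian of luma normalized by mean
luma for sharpness) through a logistic response. The contrast and
sharpness statistics are normalized by the mean level deliberately: a
raw dispersion or raw gradient magnitude scales under the ±50%
brightness factor more than the ±20% contrast/sharpness ranges can
move it, so un-normalized statistics could not isolate their designed
factor; the normalized forms are scale-invariant under brightness. With
the default bounds each probe's designed factor dominates the
total-order ranking — except sharpness, whose statistic genuinely
couples to contrast (which rescales texture amplitude) and, through the
luma contrast of chromatic edges, to hue; the sharpness probe is
therefore only required to outrank the factors with no pathway into its
statistic (brightness and saturation).

## Subsampling stability

The stability of the aggregated ranking under data reduction is tested
by drawing 20 independent stratified subsamples at fractions 0.1–0.8,
recomputing the mean-$S_T$ ranking, and reporting the fraction of
replicates reproducing the full-data ranking plus the mean Kendall
$\tau$. Replicates in which a stratum empties are dropped from the
denominator with a warning.

## Problem sizes

The package's own test and acceptance runs use: analytic recovery at
$N = 4096$; oracle comparisons at $10^6$-evaluation budgets; end-to-end
probe audits on 8 synthetic 128×128 images at $N = 128$ (896
evaluations per image per probe, perturbations shared across the probe
battery); Shapley attribution with 100 background and 40 explained rows
per image. These sizes give Monte-Carlo error comfortably inside the
asserted tolerances while keeping a full run in minutes on one core;
production audits of real models scale the same code to $N = 256$ and
hundreds of images.

## Known limitations

* Independence of factors is assumed; correlated-input indices are not
  implemented.
* Second-order indices and interaction Shapley values are not computed;
  interactions are summarized only through $S_T - S_1$.
* The Sobol' generator supports up to 10 dimensions (5 factors), which
  covers the photometric model but not arbitrary factor sets.
* Per-image index estimates carry no per-response confidence intervals;
  uncertainty is quantified across images, not within one image's
  Monte-Carlo estimate.
* Bit-exact equivalence with other imaging toolkits' enhancement
  operators is not claimed; the semantics above are this package's own
  normative definition.
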