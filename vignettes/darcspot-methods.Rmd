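---
title: "Counting apoptosing retinal cells: the darcspot pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting apoptosing retinal cells: the darcspot pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darcspot)
```

## The problem

DARC (Detection of Apoptosing Retinal Cells) imaging labels apoptotic
retinal ganglion cells with a fluorescent Annexin V conjugate and images
them in vivo with a confocal scanning laser ophthalmoscope. Apoptosing
cells appear as small bright, roughly circular spots on a retinal
background whose mean luminance and local contrast drift across the
field, with granular texture and occasional bright vasculature. Counting
those spots by hand takes minutes per image and is subject to
inter-operator variability; `darcspot` implements an automated counting
pipeline with fixed, pre-registered parameters, plus the synthetic-image
machinery and agreement statistics needed to validate it without access
to clinical images.

## The model

### Stage 1: local gain control and band-pass filtering

A global threshold cannot work on an image whose background statistics
drift, so each pixel grey level is first converted into a *local
z-score*. With $G_s$ a 2D Gaussian of standard deviation $s$ pixels:

$$\mu = G_s \otimes I, \qquad
  \sigma = \sqrt{G_s \otimes I^2 - \mu^2}, \qquad
  Z = \frac{I - \mu}{\sigma}$$

`local_gain_control()` computes exactly this, with two guards: the
variance is clamped at zero before the square root (convolution rounding
can produce tiny negatives), and a small floor is added to $\sigma$
(default $10^{-6}$ of the image dynamic range) so flat regions do not
divide by zero. A region with no contrast carries no structure, so its
z-scores are defined as zero; an exactly constant image short-circuits to
an all-zero result. $Z$ is invariant to affine luminance changes
$aI + b$ and, because $\mu$ and $\sigma$ are *local*, to any luminance or
contrast modulation that varies slowly relative to $s$.

The z-score image is then convolved with a Laplacian-of-Gaussian (LoG)
band-pass filter of scale $u$ pixels, which responds maximally to
isotropic blob-like structure of roughly that radius. The kernel in
`log_kernel()` is the analytic LoG sampled at integer offsets, truncated
at $4u$, mean-corrected so it sums to exactly zero (a constant image maps
to zero response), and *negated* so that bright spots produce positive
central responses — this polarity makes the one-sided threshold below
select cell centres. The sampled LoG is algebraically rank-2 separable
($a(x)g(y) + g(x)a(y)$), so `log_filter()` runs as two separable passes
that equal the explicit 2D convolution to machine precision; the test
suite verifies both filters against literal double-loop convolution
oracles.

Defaults, as fixed for 600-pixel-square images: $s = 64$, $u = 1.5$.

### Stage 2: threshold, components, classification

The filtered response is thresholded at $T = \bar{r} + k\,\mathrm{sd}(r)$
over all pixels of the response ($k = 1.8$); pixels at or below $T$ are
zeroed. The threshold is one-sided: the LoG response of a bright spot is
ringed by a negative surround, and a two-sided "far from the mean" rule
would resurrect those rings as spurious blobs. Surviving pixels are
grouped into connected components (8-connectivity by default,
configurable to 4), and each component is reduced to the features of its
moment-equivalent ellipse: area $A$ (pixel count), centroid, and axis
lengths $L_{maj} = 4\sqrt{\lambda_1}$, $L_{min} = 4\sqrt{\lambda_2}$,
where $\lambda_i$ are the eigenvalues of the second-central-moment matrix
of the pixel coordinates with $1/12$ (the variance of a unit pixel
extent) added to each diagonal term. The correction keeps $L_{min} > 0$
even for single-pixel-wide blobs, so the aspect ratio is always defined,
and reproduces the standard region-properties definition: a single pixel
has $L = 4\sqrt{1/12} \approx 1.155$, an $n$-pixel straight line has
aspect exactly $n$.

Classification applies two strict inequalities in a fixed order:

* $A < A_{min}$ (default 9.0 square pixels) → **noise**;
* otherwise $L_{maj}/L_{min} > Aspect_{min}$ (default 3.0) → **vessel**;
* otherwise → **cell**.

The area rule is evaluated first, so a small elongated fragment is noise,
not a vessel. Both boundaries are exclusive: a blob of area exactly 9 is
a candidate cell, and aspect exactly 3 is not a vessel. The acceptance
suite pins these boundaries by sweeping constructed blobs through the
classifier.

### Pre-analysis geometry

Clinical frames carry caption bands and peripheral noise; the workflow is
crop first (user-supplied box — automatic caption detection is out of
scope), then bilinear resize to a 600-pixel square, the resolution the
five parameters were fixed for. `resize_bilinear()` uses the
align-corners-false convention (output pixel centres back-projected at
half-pixel offsets, border samples clamped); one convention had to be
picked and is documented so the tests can be exact. Non-square inputs are
stretched, not letter-boxed. Throughout the package, pixel coordinates
are 1-based row/column indices with pixel centres on the integer grid,
matching how R indexes the image matrices the package returns.

## The synthetic image model

`generate_image()` builds scenes as

$$I = L(x)\,\bigl[\,b + \textstyle\sum_i \mathrm{spot}_i +
  \sum_j \mathrm{vessel}_j + \eta(x)\,\bigr]$$

* **Spots** are 2D Gaussian intensity profiles (the imaged cells are
  diffraction-blurred point-ish sources; no published profile exists, so
  the simplest smooth unimodal model is used) with per-spot radius
  (profile SD) drawn from 2–3 px and peak amplitude from 0.15–0.35 above
  a background of 0.2. An optional per-spot axis stretch models
  aberration-elongated cells.
* **Vessels** are straight constant-width bright ridges (Gaussian
  cross-profile, half-width 3 px) crossing the whole frame — elongated
  blobs are the only vessel property the classifier uses.
* **Noise** $\eta$ is white Gaussian noise smoothed with a 0.5-px
  Gaussian and renormalized to SD 0.01, producing speckle grains of
  about one pixel extent (kernel FWHM $\approx 1.2$ px), the "granular"
  background texture of the real images.
* **$L(x)$** is a multiplicative low-frequency luminance field
  ($1 + 0.3\,S(x)$ by default, $S$ a sum of two random cosine waves of
  0.25–0.6 cycles per image, peak-normalized) — vignetting-style uneven
  illumination under which mean luminance and local contrast drift
  together. An optional independent contrast field modulates the noise
  alone.

Every draw is governed by a single integer seed through the
Mersenne-Twister generator (inversion normal sampling), recorded in the
spec; the same spec is bit-reproducible and the caller's RNG state is
restored.

**Why 126 spots by default.** The detection threshold is a multiple of
the *whole-image* response SD, so the operating point depends on how much
structure the scene contains: in a nearly empty frame the threshold sits
at a fixed percentile of the background noise distribution and thousands
of noise pixels survive it, while in a frame with realistic cell density
the spot responses inflate the SD and push the threshold far above the
noise. The validated images average 126 cells per frame, and the default
spec reproduces that density (126 spots at 600²; smaller test frames use
proportionally fewer). This is a genuine property of
relative-to-SD thresholding worth knowing when applying the method to
sparse images — not an artifact of the simulation.

**Failure-mode variants.** `generate_edge_case()` reproduces the
documented miscounting conditions: `aberrated_elongated_spots` (stretch
factor 4 — the aspect rule labels them vessels), `dim_small_spots`
(profile SD ~1 px, amplitude 2–3.5× the noise SD — they land under the
threshold or under $A_{min}$ and are lost), `granular_background`
(coarser, stronger speckle), and `luminance_gradient` (amplitude-0.9
vignetting with ordinary spots — the condition Stage 1 exists to
neutralize; the acceptance suite checks that recall with gain control is
at least the recall without it on every seed).

**What the generator does not model**, and hence what passing tests do
not establish about clinical data: real confocal speckle statistics and
spatial correlation, non-Gaussian cell profiles and partially overlapping
cells, curved and branching vasculature, injection artifacts and
hemorrhage shadows, quantization of the acquisition chain, and any
difference between this implementation's resampling arithmetic and the
original acquisition software's.

**Scoring.** `score_detection()` matches detected cell centroids to true
centres greedily by increasing distance within a 3-px default radius,
one-to-one. Precision with zero detections is defined as 1 (no false
claims), recall with zero true spots likewise.

## The agreement statistics

`agreement_report()` compares per-image counts between methods the way a
method-comparison study would: Pearson $r$ (and $r^2$), the intraclass
correlation, Cronbach's alpha, a paired $t$-test, and percent-difference
Bland–Altman limits of agreement, for every method pair including a
derived `mean_manual` gold standard (the unweighted mean of the operator
columns). Two conventions had to be chosen and are printed in the report
header:

* **ICC form**: two-way model, single measurement. The
  absolute-agreement form ICC(A,1) is reported as the headline (it
  penalizes systematic offsets between raters, the relevant property for
  interchangeable counting methods), with the consistency form ICC(C,1)
  alongside. Confidence intervals use the standard F-based formulas
  (McGraw & Wong); estimates are verified in the tests against both an
  ANOVA-by-hand oracle and reference values from an independent
  implementation. The identity alpha = ICC(C,k) is used as a
  cross-check.
* **Bland–Altman denominator**: the pairwise mean of the two methods,
  $d_i = 100\,(x_i - y_i)\,/\,\bigl((x_i+y_i)/2\bigr)$, the standard
  percent-difference form for counts spanning a wide range; bias is
  $\bar{d}$ and the 95% limits of agreement $\bar{d} \pm 1.96\,
  \mathrm{sd}(d)$. Pairs with zero mean are excluded with a warning.

One subtlety: the percent-difference bias is a ratio of noisy
quantities, so even an exactly unbiased counter shows a small positive
expected percent bias against noisy raters (Jensen's inequality,
$\approx 50\,E[\varepsilon^2]$ for relative rater error $\varepsilon$).
The unbiasedness check in the acceptance suite therefore tests the
*mean difference* in cells (automated − mean manual), which is exactly
zero in expectation under the simulation's generative model (operator
counts Poisson around the truth, automated equal to the truth).

p-values below $10^{-15}$ are printed as "<1e-15" rather than 0.

## Numerical choices

* All convolutions use reflect (half-sample symmetric) boundary
  extension — zero padding would inject a dark border into $\mu$ and
  $\sigma$ and create rim artifacts. Kernels are truncated at 4 SD
  (omitted mass $< 10^{-4}$).
* Convolution along an axis is implemented as multiplication by a dense
  folded operator matrix, so the heavy $s = 64$ blurs run through BLAS;
  the brute-force oracle tests pin the semantics.
* Blobs touching the image border are kept and classified normally; the
  global mean/SD for the threshold include border pixels.
* Thresholding treats a response whose SD is at the rounding level of
  its values ($\le 10^{-12}$ of the maximum magnitude) as structureless
  and returns all zeros.
* Component labels are assigned in column-major scan order of each
  component's first pixel, making every output deterministic bit-for-bit.

## Problem sizes in the test suite

The suite validates convolution and labeling oracles on ≤15×15 grids
(exhaustive double loops), boundary semantics by parameter sweeps and
bisection, ground-truth recovery on one hundred seeded 600-pixel-square
default scenes (exact count required on at least 95, mean precision and
recall at least 0.95), the gain-control ablation on ten seeded gradient
scenes, and statistical unbiasedness on two hundred simulated 66-image
count tables. These sizes were chosen to exercise each property at full
operating resolution while keeping the default `R CMD check` run in the
minutes range.

## Known limitations

* Touching cells are counted as one blob (no watershed splitting), and
  centroids are unweighted by intensity.
* The aspect rule misclassifies genuinely elongated cells as vessels;
  the threshold and area rules miss small dim cells. These are inherent
  to the fixed-parameter design and are reproduced, not patched, by this
  implementation.
* Sparse scenes (few bright objects) push the relative threshold into
  the noise tail; counts there include noise-excursion false positives.
* The original analysis environment's exact Gaussian normalization,
  truncation and resampling are unpublished; this implementation is
  self-consistent and oracle-verified rather than bit-matched to it.
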