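---
title: "SpectASC: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SpectASC: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpectASC)
```

# Scope

`SpectASC` studies how attenuation and scatter correction (ASC) affects the
binary categorization of dopamine transporter SPECT — normal versus
Parkinson-typical reduced striatal uptake — when the categorization is
driven by the semi-quantitative putamen specific binding ratio (SBR).
Clinical raw data for this question are not openly available, so the
package pairs the analysis chain with a digital striatal phantom generator
that reproduces the *statistical structure* the analysis relies on: a
two-class cohort, a center-weighted attenuation loss, broad scatter
contamination, finite resolution, and Poisson counting noise.  This
vignette documents the models, every tunable parameter that matters, the
numerical choices, and what the simulation does and does not establish.

# The phantom and its forward model

A subject is an ellipsoidal "brain" of uniform nonspecific activity
(background 1 by convention) containing four ellipsoidal striatal
structures (left/right caudate and putamen) whose activity is
`background * (1 + trueSBR)`.  The default anatomy places the putamina at
(±27, −2, 0) mm with semi-axes (8, 16, 9) mm (≈ 4.8 ml) and the caudate
heads at (±13, 14, 8) mm with semi-axes (6, 13, 9) mm (≈ 2.9 ml) inside a
brain of semi-axes (65, 80, 55) mm, on a 2 mm isotropic grid.  These are
simplified stand-ins at anatomically plausible coordinates; no external
atlas is used.

Two matched emission images are generated per subject:

* **without ASC**:
  `Poisson(countScale * blurPSF(A·activity + sf · broadblur(A·activity)))`
* **with ASC**:
  `Poisson(countScale * blurPSF(C·A·activity))`

with

* `A(x)` — the angle-averaged Chang survival factors of the *true* brain
  contour (forward attenuation);
* `sf` — the scatter fraction, default 0.3, applied to a copy of the
  attenuated image convolved with a broad Gaussian (default FWHM 80 mm).
  This emulates the contrast-degrading effect of scatter at desk scale;
  it is not a Monte Carlo transport simulation;
* `C(x)` — the first-order Chang correction factors computed from the
  *automatically delineated* contour, so that delineation error propagates
  into the corrected arm exactly as it would in practice.  The corrected
  arm carries no scatter term, emulating an effective scatter correction;
* `blurPSF` — a 7 mm FWHM isotropic Gaussian, the resolution/post-filter
  of the emulated reconstruction;
* `countScale` — expected counts per unit activity per voxel, default 20
  (roughly 3 million counts in the brain, a realistic clinical budget).
  `countScale = Inf` switches sampling off and returns expected-value
  images; the exactness tests require this mode.

Noise sub-seeds are fixed by rule: a single scan uses `seed` for the
without-ASC arm and `seed + 1` for the with-ASC arm; scan *i* of a cohort
uses `cohortSeed + 2i` and `cohortSeed + 2i + 1`.  Every simulation is
reproducible from its spec.

The image-domain placement of the Chang correction is a deliberate
simplification: clinically, ASC operates inside iterative reconstruction.
Image-domain correction changes absolute intensities but preserves the
with/without-ASC contrast structure that the downstream analysis studies,
which is the property of interest here.

## Cohorts and the target-SBR calibration

A cohort is a two-class mixture: each scan is reduced with probability
`prevalenceReduced` (default 0.478) and draws a target minimum putamen SBR
from its class Gaussian truncated at zero — defaults: reduced mean 0.579,
SD 0.157; normal mean 1.577, SD 0.320, the two-Gaussian decomposition of a
large published clinical sample measured *with* ASC.  The worse hemisphere
receives the drawn value; the better hemisphere receives it times
`asymmetry` (default 1.3), so the minimum-over-hemispheres summary is
always exercised.  In reduced scans the caudate tracks the putamen at a
ratio of 1.5 (relative caudate preservation, as in early nigrostriatal
degeneration); in normal scans it tracks 1:1.

The published class distributions describe *measured* SBR values, whereas
the phantom's `trueSBR` is an activity contrast that the measurement chain
(resolution blur, scatter, hottest-voxel averaging over an oversized mask)
compresses by roughly a factor of three.  The generator therefore
calibrates, once per cohort geometry, the affine response of the noise-free
with-ASC measurement (probing three contrast levels and inverting the
fitted line), and builds each phantom so that its with-ASC measurement hits
the drawn target.  The without-ASC arm is *not* calibrated — it lands
wherever attenuation and scatter put it, which is the comparison the
package exists to study.  All subjects of a cohort share the phantom
geometry (only binding varies), so the attenuation map, the delineated
contour, the Chang factors and the blurred per-structure basis images are
computed once and each scan is a linear combination plus Poisson noise;
this is what makes cohorts of thousands of scans tractable, and it is
scientifically consistent with the generator's fixed digital anatomy.

# Head-contour delineation

The clinical tool this emulates smooths the uncorrected image with a 25 mm
FWHM Gaussian and fits an ellipse to the 30% iso-contour separately in each
transaxial plane.  Two numerical facts shape the implementation:

1. Thresholding a smoothed step edge at fraction `f` of the plateau places
   the contour `sigma * qnorm(1 - f)` *outside* the true boundary — about
   5.6 mm at the defaults.  A moment fit to the supra-threshold region
   therefore systematically overestimates the head.
2. Smoothing pulls the apparent edge of a *convex* boundary inward by
   about `sigma^2/2` times its curvature.

The implementation consequently proceeds in three steps per slice: moment
fit to the supra-threshold region (initialization), shrinkage by the
theoretical step-edge offset, then an edge-localization refinement: along
32 radial profiles of the smoothed slice the model
`(p0 + p1*(rb - r)) * pnorm((rb - r)/sigma)` is fitted by least squares
(the sloped plateau absorbs gently varying interiors such as the central
sag of attenuated images), the boundary points are corrected for in-plane
curvature, and an ellipse is refitted to them by direct least squares
(the numerically stable Halir–Flusser variant of Fitzgibbon's method).
On sharply delimited convex bodies this recovers the boundary to about
half a voxel, and forward-attenuation followed by Chang correction with the
*delineated* contour recovers a disc phantom's activity to about 1%.

Known limitation: near the poles of an ellipsoid the 3-D smoothing mixes
slices of rapidly changing cross-section, and no per-slice method can
recover the analytic cross-section there; the fitted ellipses are biased
outward at extreme slices.  The striatum sits at the equatorial band, where
the contour is sub-voxel accurate, so the effect on the SBR analysis is
negligible.  Slices whose raw maximum is below 1% of the volume maximum
receive no ellipse (empty-slice guard).

Whether the clinical tool references the 30% threshold to the slice or the
volume maximum is not documented; the package uses the *slice* maximum
(per-slice fitting implies per-slice scaling) and exposes the fraction as
an argument.

# Chang attenuation factors

For voxels inside the contour,
`A(x) = mean_theta exp(-mu * l_theta(x))` over 64 equally spaced transaxial
directions, with `mu = 0.146/cm` (narrow-beam, 159 keV) and `l_theta(x)`
the distance to the contour boundary.  Because the contour is an ellipse in
every slice, the ray lengths are computed in closed form by ray–ellipse
intersection — exact and fully vectorized.  An independent fixed-step
mask-walking tracer is kept as the cross-check oracle in the test suite.
The correction divides by `A(x)` with a configurable cap (default 10),
engaged only where `A < 1/cap`.  First-order Chang only; no iterative
refinement, matching the uniform-map usage emulated here.

# DVR scaling and the hottest-voxel SBR

Scans are scaled to distribution-volume-ratio units by dividing by the 75th
percentile of the voxel intensities in the reference region (the brain
minus all striatal structures dilated by 4 mm — the phantom analogue of
"whole brain without striata and ventricles").  The percentile uses the
linear-interpolation convention (`quantile` type 7), pinned by a test
(values 1..100 give 75.25).  The putamen SBR is the mean of the hottest
`round(10 ml / voxelVolume)` voxels (1250 at 2 mm) inside an oversized
unilateral putamen mask (structure dilated by 6 mm, caudate neighborhood
excluded), minus 1; ties at the selection boundary are broken by voxel
index, making the selection deterministic.  The scan's summary value is the
minimum over hemispheres.

# Two-Gaussian calibration

The SBR histogram (bin width 0.1, edges anchored at multiples of the bin
width starting at 0, negative values clamped into the first bin, all
values retained) is fitted by the sum of two Gaussians, minimizing the sum
of squared count residuals at the bin centers with Nelder–Mead.  The paper
trail behind this choice specifies a derivative-free simplex with default
settings; the package adds deterministic multi-start initialization (splits
at the 40th/50th/60th percentile bins, moment start values per fragment,
three simplex polishing restarts each, best SSE wins) so the headline fit
has no seed dependence, and log-parameterizes amplitudes and SDs so
positivity is structural.  Components are relabeled so `M1 < M2`.  A
noiseless model histogram is recovered to machine precision; 2000 sampled
values recover the generating means and SDs to well within ±0.05.

Derived quantities: effect size `d = (M2 - M1)/sqrt((SD1^2 + SD2^2)/2)` and
cutoff `c = (SD2*M1 + SD1*M2)/(SD1 + SD2)` — the point halfway between the
means in units of each component's SD.  A scan is *reduced* iff its minimum
putamen SBR is strictly below `c`; ties are *normal*.  In the end-to-end
experiment the two arms are calibrated *independently* (separate
histograms, fits and cutoffs), mirroring the design of the clinical
comparison.

# Agreement and power statistics

Cohen's kappa on 2x2 tables uses the asymptotic Fleiss–Cohen–Everitt
variance for its standard error (the reference results report kappa with a
standard error but name no formula; this standard choice reproduces the
published 0.006 on the published cross table).  The k x 2 homogeneity test
is the Pearson chi-square without continuity correction.

McNemar post-hoc power is computed by the exact unconditional method: the
discordant count is `D ~ Binomial(n, p_d)`; given `D`, the exact one-sided
binomial test (null p = 1/2, level alpha) is applied against the
alternative `p = OR/(OR + 1)`; the reported power is the average of the
conditional power over `D`.  The discordant-cell split follows directly
from the odds ratio: `p12 = p_d*OR/(1+OR)`, `p21 = p_d/(1+OR)`.  The method
behind the published power figures is not documented; the exact
unconditional method reproduces all six published values to the printed
decimal, which is why it is the primary method.  A normal-approximation
variant is exposed (`method = "asymptotic"`) for sensitivity analysis; it
agrees with the exact method to within 2 percentage points once
`n * p_d >= 80`.

The simulated-reader model (threshold on the SBR scale plus Gaussian
perceptual noise and bias, ties normal) exists to exercise the agreement
machinery — majority votes, intra-reader consensus with third-read
tie-breaks — not to model human perception.

# Problem sizes and reproducibility

The test suite runs cohorts of up to 2000 scans on the default 70x86x60
grid; a cohort of that size completes in a few minutes on one CPU because
of the shared-geometry basis decomposition.  Scan-level exactness tests
(Chang inversion, blur conservation, DVR idempotence) run noise-free on
miniature 24^3 or 64^3 phantoms.  Every stochastic test and simulation is
seeded; rerunning any experiment with the same spec reproduces every
number exactly.

# What the simulation does and does not show

The generator reproduces: the two-class mixture structure with the
published class distributions, hemispheric asymmetry, center-weighted
attenuation loss with realistic depth, scatter-induced contrast loss,
partial-volume compression of the SBR by finite resolution, and Poisson
noise at a clinical count budget.  It does not reproduce: anatomical
variability between subjects, stereotactic normalization error, septal
penetration of high-energy photons, collimator-detector response beyond a
Gaussian, projection-domain physics, or human readers.  Consequently the
package treats cohort-level discrepancy rates between the arms as
*qualitative* outcomes (concordance is high when the class separation is
large) and makes no claim that the published cohort-level discrepancy
percentage is reproducible from phantoms — that number depends on clinical
image statistics the phantom does not model.  The quantities the package
does reproduce exactly are the statistical ones: effect sizes and cutoffs
from fitted parameters, kappa and discrepancy values from cross tables,
chi-square homogeneity p-values, and the exact McNemar power figures.
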