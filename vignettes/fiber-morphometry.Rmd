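---
title: "Quantifying myelinated-fiber ultrastructure: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myelinated-fiber ultrastructure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibermorph)
```

## The problem

Myelinated white-matter fibers appear in a two-dimensional electron-microscopy
section as an axon cross-section wrapped in a myelin sheath. Three quantities
summarise a fiber: its axon diameter $d$, its outer fiber diameter $D$
(axon plus sheath), and the g-ratio $g = d / D$. From these, conduction
velocity can be estimated. fibermorph implements the full quantitative chain
downstream of a semantic segmentation: per-fiber instance extraction,
ellipse-based morphometry, population modeling, velocity estimation, and the
validation protocol that quantifies how trustworthy the segmentation-derived
measurements are.

The semantic predictor itself (a CNN in typical practice) is deliberately out
of scope: the package consumes per-pixel class scores for
background/axon/myelin from any source, and its phantom generator produces
such maps with known ground truth so every stage can be tested quantitatively.

## Instance segmentation

Class scores are thresholded by per-pixel argmax (a fixed 0.5 threshold on
the foreground channels gives the same result on well-calibrated maps and is
available as a fallback). Binary clean-up uses a morphological opening on the
axon mask and a closing plus hole-filling on the myelin mask, with a
structuring-element radius of 1 px and removal of connected components below
`min_object_area` (default 10 px). These specific operations are a design
choice: which binary corrections to apply is genuinely open, and the
defaults are the mildest set that repairs single-pixel noise without moving
object boundaries by more than one pixel.

Touching ("kissing") sheaths are separated by the classic distance-transform
watershed: the Euclidean distance transform of the joined axon+myelin mask is
inverted and flooded from its peaks, so basin boundaries fall along the
waist where two sheaths meet. Two parameters matter:

* `tolerance` (default 1 px) — minimum peak height for a separate seed;
  suppresses duplicate seeds from rasterization roughness.
* `peak_min_distance` (default 10 px) — adjacent basins whose peaks lie
  closer than this are merged, keeping the higher peak. At the default
  working resolution of 17.28 nm/px, 10 px is 173 nm, well below the
  smallest plausible fiber diameter, so genuine neighbours are never merged.

Each basin is split back into axon and myelin compartments with the binary
masks. Basins whose axon compartment is empty (fully degraded sheath
interior) are flagged rather than silently measured.

After measurement, records pass a plausibility filter. Defaults: axon minor
axis 0.1–15 µm, outer minor axis 0.2–20 µm, g-ratio in (0, 1], fibers
touching the image border dropped (their ellipses are truncated, so any
measurement would be biased). Every rejection carries a reason code; the
filter is monotone (loosening a bound never loses a fiber).

## Morphometry

Each region is summarised by the ellipse with the same area-normalized
second central moments as its pixel set. The pixel coordinates' covariance
matrix is formed with the population divisor; the full axes are
$4\sqrt{\lambda_{1,2}}$ for its eigenvalues. For an ideal disk of radius $R$
this gives exactly $2R$, and no discrete-pixel correction is applied — at
the working resolution the residual bias is far below the 2-px tolerance the
package promises.

The minor axis is the primary diameter estimate because a plane cutting a
tube at angle $\theta$ from its normal produces an ellipse whose minor axis
equals the true tube diameter for every $\theta$, while the major axis grows
as $1/\cos\theta$. The g-ratio is the ratio of the axon-ellipse minor axis
to the outer-ellipse minor axis, which makes it cut-angle invariant too.

The outer ellipse is fitted on the *filled union* of axon and myelin, not on
the myelin annulus alone. The second-moment ellipse of an ideal annulus has
semi-axis $\sqrt{R_{\text{out}}^2 + R_{\text{in}}^2}$ — systematically
larger than the outer boundary it is meant to trace — whereas the filled
region's moment ellipse tracks the outer outline. Whether the original
protocol used the annulus or the filled region is not decidable from its
description; the filled union is this package's choice, and
`outer_mode = "annulus"` is retained for sensitivity analysis.

Two alternative estimators are computed for every fiber:

* equivalent-circle diameter $2\sqrt{A/\pi}$, which equals the minor axis
  only for circular sections and overestimates obliquely cut fibers with
  growing eccentricity;
* skeleton-based myelin thickness: twice the mean Euclidean distance
  transform along the Zhang–Suen skeleton of the myelin mask. Regions
  nowhere wider than ~3 px return `NA` (flagged), since their skeleton
  carries no thickness information.

Moment fits on regions below `min_region_px = 10` pixels raise a
degenerate-region condition: at 17.28 nm/px such regions are below 0.003 µm²
and their moments are numerically meaningless.

## The phantom generator

The phantom emulates what the measurement chain actually sees: obliquely cut
tubular fibers rendered as concentric ellipses on a canvas, with class
scores that are exactly one-hot before degradation. Its population laws are
the study conditions:

* axon diameters follow a GEV law, by default $\mu = 0.5$ µm,
  $\sigma = 0.15$ µm, $\xi = 0.1$. The real fitted values for human white
  matter are published only graphically, so these defaults are documented,
  configurable placeholders of realistic magnitude — parameter-recovery
  claims are always made against the generator's own settings, never
  against published curves.
* g-ratios follow a normal law truncated to (0, 1), centered at 0.54 (the
  reported mean in both short- and long-range human white matter) with
  default sd 0.06, chosen to mimic the reported histogram width while
  keeping essentially all mass in (0.3, 0.8).
* cut angles are uniform on [0°, 60°]. The true distribution of cut angles
  in tissue is unknown (oblique cuts are merely expected to be more common
  in superficial white matter), so it is a free parameter; beyond ~60° the
  rasterized annulus thins below reliable measurement at this resolution,
  which sets the default upper bound.
* pixel size defaults to 17.28 nm — 4.32-nm acquisition downsampled
  fourfold per axis, the resolution the emulated pipeline operates at.

Degradation emulates the dominant artifacts of aged post-mortem EM material:
angular myelin-sheath gaps (sector removal in the parametric ellipse angle,
so a 90° arc removes exactly a quarter of the annulus area at any cut
angle), tangentially placed kissing pairs (1-px shared overlap, so the
watershed genuinely has to separate them), boundary jitter, and Gaussian
blurring of the class scores with renormalization.

What the phantom does *not* emulate: EM texture and staining contrast,
non-elliptical fiber profiles, debris and non-fiber organelles, and
correlated prediction errors of a real CNN. Tests passing on phantoms
therefore demonstrate the correctness of the measurement chain given
reasonable semantic input — not the accuracy of any particular semantic
predictor on real tissue.

## Bayesian GEV modeling

Diameter populations are modeled with the generalized extreme value family

$$G(x) = \frac{1}{\sigma} t^{\xi+1} e^{-t}, \qquad
  t = \Bigl(1 + \xi\frac{x-\mu}{\sigma}\Bigr)^{-1/\xi},$$

whose shape parameter captures the long right tail of diameter
distributions. Numerically, the Gumbel branch $t = e^{-(x-\mu)/\sigma}$ is
taken for $|\xi| < 10^{-8}$ to avoid catastrophic cancellation.

The fit is Bayesian. Priors (defaults of `gev_priors()`): $\mu$ normal(0.5,
0.5) truncated positive (µm), $\sigma$ half-normal(0.5), $\xi$ normal(0,
0.3). The original analysis used weakly informative priors whose exact
hyperparameters are not published; these are this package's explicit
choices, wide relative to any plausible axon-diameter population, and fully
overridable.

The sampler is an independence Metropolis–Hastings chain whose
multivariate-t proposal (df 4, scale 1.3× the Laplace covariance) is
calibrated at the posterior mode found by BFGS on $(\mu, \log\sigma, \xi)$.
With thousands of observations the posterior is nearly Gaussian, acceptance
sits around 0.7, and autocorrelation is negligible — effective sample sizes
are a large fraction of the 4 × 1000 kept draws, comfortably meeting the
diagnostics gate (split-$\hat R < 1.01$, ESS > 400 per parameter). If
warm-up acceptance falls below 0.15 the sampler falls back to an adaptive
random walk. Observations outside a candidate's support get $-\infty$
log-likelihood, so the support constraint is enforced exactly. Credible
intervals are 99% HPD intervals by a narrowest-window scan over sorted
pooled draws. Prior and posterior predictive checks (`predictive_check()`)
simulate datasets of the observed size and overlay their pointwise-mean
density.

## Conduction velocity

The generalized Rushton relation gives relative velocity
$v \propto d(-\ln g)^\alpha$ with $d = gD$; internode length follows
$L \propto d(-\ln g)^{1/2}$. Absolute scale uses $s = 7.5\ \mu s^{-1}$
(extracted in the source literature from biophysical simulation), so with
$D$ in µm, $v = s\,gD(-\ln g)^\alpha$ is in m/s. The exponent defaults to
the empirically optimized $\alpha = 0.68$; reversing the optimal-g argument
at an observed mean $g$ gives $\alpha = -\ln g$ (`derive_alpha()`; 0.62 at
$g = 0.54$), and both values are first-class configuration because the two
disagree only at the few-percent level (`velocity_ratio()` quantifies the
effect). Per-fiber velocity distributions use each fiber's own measured $g$
by default — whether published distribution figures used per-fiber or
population-mean g is not stated, so `fiber_velocities()` offers both modes.

## Validation protocol

Per-pixel agreement is quantified by IoU, Dice and the 95th-percentile
symmetric Hausdorff distance over boundary pixels (µm). Two empty masks
count as perfect agreement; one empty mask gives IoU 0 and infinite HD95.

Instance matching treats fibers with more than 40% overlapping areas as the
same fiber. The published rule does not name the denominator of "overlap";
this package requires intersection/gt-area *and* intersection/pred-area to
both exceed the threshold (preventing one oversized blob from matching
everything), with single-sided modes available. Candidates are taken
greedily by descending overlap; when one ground-truth fiber exceeds the
threshold against two predictions, the higher overlap wins and the loser
becomes a false positive. Unmatched predictions and ground-truth fibers are
false positives and negatives respectively.

Paired agreement per measure follows Bland–Altman on the raw measurement
scale: deltas are validation − prediction, with mean difference, limits of
agreement (±1.96 sd), mean absolute error, and deltas stratified by
ground-truth axon diameter to expose size-dependent bias.

## Reference problem sizes

The test suite exercises the chain at sizes chosen to give stable statistics
while keeping a full run lightweight: single-fiber rasters for geometric
identities; 20–50-fiber phantoms (≤1024² px) for segmentation properties;
one 2000-fiber phantom on a 5120² px canvas for end-to-end population
recovery (mean g-ratio within 0.01 of a degenerate truth; GEV posterior
covering the generator's law at 99% credibility); and MCMC recovery at
n = 10000 per shape-parameter setting. Published population statistics from
real tissue (fiber counts in the hundreds of thousands) are inputs and
context, not reproduction targets: they depend on the original EM material.

## Known limitations

* Ellipse morphometry cannot distinguish a round, obliquely cut fiber from
  a genuinely oval, orthogonally cut one; the minor axis underestimates the
  diameter of truly oval fibers.
* The watershed assumes roughly convex fiber sections; strongly concave
  damaged sheaths can be over-split before filtering.
* Instance ids above 65535 require 32-bit label output
  (`write_label_map(..., bits = 32)`).
* The phantom's artifact model is stylized; validation numbers on phantoms
  bound what the chain itself introduces, not what a CNN predictor would
  add on real tissue.
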