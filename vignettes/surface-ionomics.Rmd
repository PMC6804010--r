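---
title: "Surface ionomics of pretreated bagasse: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface ionomics of pretreated bagasse: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionsurf)
```

## The problem

Enzymatic saccharification of pretreated sugarcane bagasse depends not only
on the anatomical state of the cell-wall surface (fibril periodicity,
roughness, excavations) but on which metal ions sit on it and how they are
distributed. ToF-SIMS chemical images give one 8-bit intensity map per
ion or fragment over a 25x25 to 100x100 um^2 field. `ionsurf` implements
the analysis chain that links those maps to reducing-sugar release:

1. image standardization (RGB channel summation to 8-bit, IsoData
   thresholding);
2. particle statistics per ion (count, total area, average size,
   intensity) and coverage of -OH sites by ions, notably Li+;
3. anatomical surface metrics (differential entropy, roughness/waviness,
   periodic-area fraction, excavation statistics);
4. mixture discriminant analysis (MDA) over per-treatment feature
   matrices, with a similarity string, binary neighbor matrices, a
   consensus tree and jackknife importance;
5. penalized-spline smoothing, equality testing and 10 h fold changes for
   saccharification time courses.

A synthetic-data module generates images and curves with known ground
truth, so every stage is testable without instrument data.

## Image standardization and segmentation

RGB exports are summed per pixel in widened integers (no clipping at 255)
and rescaled linearly from [0, 765] to [0, 255] with round-half-up;
clipping before the rescale would destroy the densitometry the particle
statistics rely on. The coordinate convention is fixed once: row-major,
origin top-left, physical positions at pixel centres.

Thresholding is the classic Ridler–Calvard iterative intermeans (the
IsoData algorithm), computed on all 256 histogram bins with the update
`T <- floor((mu_low + mu_high)/2)` — integer division, the ImageJ
convention — iterated from the midpoint of the occupied range. Fixed
points of this map come in short runs; the implementation returns the
smallest, and the test suite checks it against an exhaustive scan of all
255 candidate levels. Foreground is strictly greater than the threshold:
a fixed convention needed for bit-exact tests.

Particles are 8-connected components (the ImageJ particle-analysis
default). No minimum-size filter is applied by default because the
original workflow states none; `min_size_um2` is available. Coverage of
-OH sites by an ion is the pixel fraction of site foreground overlapped by
ion foreground, and its complement is the reported "free" percentage;
a component-level variant counts site aggregates touched by at least one
ion pixel.

## Surface metrics

**Differential entropy.** Intensities are normalized to [0, 1] and binned
into 64 equal-width bins; the plug-in estimate is
$H = -\sum_i p_i \ln(p_i/\Delta)$ nats. The published absolute value for
the control surface depends on an unstated estimator, so it is treated as
estimator-specific: this package fixes bins = 64 for comparability and
never targets the absolute number. The entropy *deficit* is reported
against a Gaussian of matched variance, $H_{ref} = \tfrac12\ln(2\pi e
\sigma^2)$ — the maximum-entropy reference; amorphous deposits concentrate
intensity mass and create a positive deficit.

**Roughness and waviness.** The image is split at a cutoff wavelength
(default 8 um — above fibril diameters, below lattice wavelengths) with
the standard metrology Gaussian filter (50% amplitude transmission at the
cutoff). Ra and Rq summarize the short-wavelength residual, Wa the
long-wavelength surface. Units are intensity levels, not nanometres: the
exported images carry no height calibration.

**Periodic-area fraction.** The image is tiled into 12 um windows; a
window is periodic when its wrapped autocorrelation, collapsed along one
of the four principal directions, has a secondary peak of at least 0.3.
Directional collapse (rather than a radial average) keeps white noise
below the detection floor at this window size; texture at angles far from
the four principal directions is attenuated — a documented limitation, and
the synthetic generator plants axis-aligned ridges.

**Excavations.** Dark blobs under the inverted IsoData threshold,
filtered to circularity $4\pi A/P^2 \ge 0.6$ with the $\pi/4$ digital
perimeter correction, counts normalized to a 100x100 um^2 field. Depth is
an intensity proxy (background mean minus blob mean); reporting true
nanometre depths would require depth-calibrated profiling that image
exports do not carry.

## Discrimination machinery

Each treatment's observations are sub-tiles of its images (default 4x4 =
16 tiles; with five treatments this gives 80 observations against roughly
40 parameters, keeping the shared covariance full-rank). Features are
z-scored and split into an ionic and an anatomical block. Ionic and
anatomical blocks are analyzed separately by default (`block = "ion"` in
the pipeline): in the study this package models, the ionic block produced
the clusters that matched saccharification behaviour while the anatomical
block did not.

**MDA.** Each class density is a Gaussian mixture with a per-class number
of subclasses (default 3) sharing one covariance across all subclasses of
all classes; fitting is EM over the latent subclass labels with k-means++
initialization under a fixed seed, ridge regularization
(`1e-6 * trace/p`, escalating tenfold) when the shared covariance is
singular, and a monotone log-likelihood guaranteed by construction and
asserted in tests. With one subclass per class the model collapses to
linear discriminant analysis exactly — the oracle used in the test suite.

**String, gatekeeping and binary matrices.** Class centroids are whitened
by the shared covariance and seriated along the first principal axis of
their scatter; the string is canonicalized to the lexicographically
smaller of itself and its reverse, so the arbitrary sign of a discriminant
axis cannot flip results. At `merge_alpha = 0.05` every treatment pair is
screened by a permutation test before the string is built: the statistic
is the training accuracy of the *nearest-centroid* rule, refit under each
of 999 label permutations. The parsimonious statistic is deliberate —
with as many parameters as observations the full mixture's training
accuracy saturates at 1 for any labels and the test would have no power.
Pairs that fail to separate are merged; merged groups occupy consecutive
string positions, and the binary neighbor matrix assigns 1 only between
string neighbors of the same group. A treatment separable from everything
is therefore isolated with an all-zero row — without merging, a chain of
five treatments gives every treatment a neighbor and no tree could ever
isolate one. With merging off, the plain neighbor rule applies
(consecutive entries get 1).

**Tree.** The element-wise mean of binary matrices (the full analysis
plus the leave-one-ion-out re-runs) is a similarity; `1 - S` is clustered
by average linkage with labels sorted for deterministic ties.

**Jackknife.** Each parameter group (all columns of one ion, the
anatomical block as one group) is removed, the discriminant analysis
re-run, and the relative drop in training accuracy attributed to the
group; a misclassification-count variant is emitted alongside. The
published importance share for the Li+ parameters has no stated
functional, so the accuracy-drop share is this package's documented
convention and the published percentage is not a target. The pipeline
scores the jackknife with the one-subclass (LDA-limit) model: at 80
observations a 3-subclass mixture memorizes the training set and
leave-one-group-out differences vanish into the memorization; the
parsimonious score restores sensitivity. Redundant copies of an
informative column share importance away from each other — a property the
tests assert.

## Saccharification curves

Curves are smoothed with cubic penalized regression splines (mgcv, GCV
smoothing, basis dimension 20 capped at the number of distinct times).
The generous basis keeps the 10 h fold readout unbiased; GCV still
removes unneeded wiggliness. Pointwise 2-SE envelopes of these fits cover
a smooth truth at close to — in simulation about 94% — the nominal 95%,
the usual behaviour of penalized-spline Bayesian intervals.

Curve equality ("the least-squares method, p = 0.05") is an
extra-sum-of-squares F-test between one pooled and two separate fits on a
*shared, saturated* natural-spline basis (one degree of freedom per
distinct time, capped at a quarter of the pooled observations). With no
lack of fit the test is exact under iid Gaussian noise; its measured size
over 1000 null simulations is within a point or two of 5%. Clustering is
the set of connected components of the pairwise "statistically same"
relation.

Fold changes are ratios of smoothed values at 10 h. Decay after 10 h is
declared when the smoothed derivative is negative over a contiguous span
of at least 20% of (10, 48] h *and* the net decline over that span is
significantly below zero (one-sided 95%); the span is evaluated on a
trend-scale refit (basis 10) because the display smoother's noise wiggle
otherwise fragments spans on true decays and conjures them on plateaus.

## What the synthetic generator emulates

Images are fields of planted discs (Gaussian edge blur of 0.5 px —
diffuse sputter spots without an instrument PSF) placed without overlap
by bounded rejection sampling; three point processes match the three
described morphologies: homogeneous Poisson ("random"), Thomas
parent–offspring ("clustered"), and aggregates strung along parallel
sinusoidal ridges ("fibril_periodic"). The default raster is 256x256 for
a 100 um field (2.56 px/um): sub-micron aggregates stay resolvable at
desk-scale runtimes. All randomness descends from one integer seed
through a counter-based splitting scheme, so every module is independently
reproducible. No noise model is published for the images; additive
Gaussian noise (sd 8 levels) is a convention, not an estimate.

The five-treatment suite plants, as ground truth: the reference Li+
particle counts per treatment (353, 320, 88, 63, 16 — the published
ordering); Li+ morphology per treatment (ridge-periodic for control and
EtOH:DMSO:AO, random after Steam Explosion and Microwave:H2SO4, one
clustered remnant after NaOH); high Li+-on-(-OH) placement for control and
EtOH:DMSO:AO and near-zero otherwise; identical non-Li ion parameters for
every treatment — the studied materials shared a very similar ionic
composition and differed in the concentration and distribution of lithium
— except the reported NaOH Na+/F- enrichment (brighter foreground, few
large aggregates), which is what isolates NaOH without help from Li+.
The anatomical channel plants the reported periodic-area levels (90%, 90%,
47%, 87.5%, 8.7%) and the 72 circular excavations of 0.72 um radius for
the microwave:acid surface.

Curves: Michaelis-type release (vmax 4 mg/ml, half-saturation 6 h —
typical bagasse-hydrolysis scale), folds 1.0 / 0.9 / 1.74 / 1.74 / 2.04
at 10 h, with the control and EtOH:DMSO:AO curves smoothly unimodal and
peaking exactly at 10 h (a slope-discontinuous decay would bias the
smoothed 10 h fold readout). The reported "1.1-fold decrease" for
EtOH:DMSO:AO is read as a 0.9 ratio. Noise is iid Gaussian (sd 0.08
mg/ml) with three replicates — replicate structure is not published.

What passing tests on this generator do *not* show: real ToF-SIMS images
have structured background, topographic shading, detector saturation and
non-circular aggregates; real curves have heteroscedastic,
serially-correlated noise. Recovery of planted structure here validates
the chain's logic and calibration, not its robustness to those artifacts.

## Numerical choices and degenerate inputs

* Constant images are rejected by the threshold and entropy routines
  (degenerate histogram) rather than silently defaulted.
* A singular shared covariance is ridge-regularized and the ridge
  recorded on the model object.
* Identical inputs to the curve comparison return F = 0, p = 1 without
  touching the numerics.
* Seriation ties on the first discriminant coordinate break by the
  second, then by label; tree ties break by sorted label order.
* The placement sampler redraws its latent cluster parents when a draw
  stalls, and errors only when a bounded retry budget (400 per aggregate)
  is exhausted.

## Known limitations

* Excavation depth is an intensity proxy; no nanometre depths are
  reported anywhere.
* The periodic-window detector attenuates textures oriented far from the
  four principal directions.
* The entropy value (not the deficit structure) is estimator-specific and
  not comparable across bin choices.
* MDA training accuracy is an optimistic score; between-treatment
  conclusions rest on the permutation gatekeeping, not on the accuracy
  itself.
* With 16 tiles per image the observations within a treatment share one
  image; tile-level replication captures spatial, not biological,
  variance.

## Reproducing a full run

```{r, eval = FALSE}
res <- run_pipeline(list(outdir = "ionsurf_demo", seed = 42))
res$discrimination$groups   # {Control, EtOH:DMSO:AO} {Steam, Microwave} {NaOH}
res$jackknife[1, ]          # Li block ranked first
res$folds                   # 10 h folds near 2.04, 1.74, 1.74, 0.9
```

Problem sizes throughout (256x256 fields, 16 tiles per image, 999
permutations, 1000 null simulations in the acceptance checks) are chosen
so a complete run finishes in well under a minute on one core.
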