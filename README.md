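# ionsurf

Surface ionomics of pretreated lignocellulose from ToF-SIMS chemical
images, linked to enzymatic saccharification yields.

## The problem

Pretreatments of sugarcane bagasse (steam explosion, microwave:H₂SO₄,
ethanol:DMSO:ammonium-oxalate organosolv, NaOH) change not only the
anatomy of the cell-wall surface but the identity, concentration and
spatial distribution of the metal ions bound to it. Time-of-flight
secondary-ion mass spectrometry (ToF-SIMS) images each ion or fragment as
an 8-bit intensity map over a micrometre-scale field. The question this
package operationalizes: which surface parameters — ionic or anatomical —
discriminate the pretreatments, and do those same parameters group
treatments the way their reducing-sugar release curves do? In the study
this package models, the answer was the lithium block: Li⁺ count, area,
aggregate size and Li⁺ coverage of –OH sites, with pretreatments that
strip Li⁺ from –OH sites giving up to 2.04-fold more reducing sugars than
the control at 10 h.

It is written for analysts of chemical images (ToF-SIMS, and any
export-as-8-bit raster modality) who want a scripted, testable version of
the ImageJ/Gwyddion + discriminant-analysis workflow.

## What is inside

* **Image standardization** — RGB channel summation into 8-bit with
  round-half-up rescale, calibrated `chem_image` containers, TIFF/PNG IO
  with YAML sidecars.
* **Segmentation** — IsoData (Ridler–Calvard iterative intermeans,
  `T ← ⌊(μ_low + μ_high)/2⌋`) thresholding, 8-connected particle
  statistics (count *N*, area µm², average size µm², intensities),
  pixel- and component-level coverage of –OH sites by ions.
* **Surface metrics** — plug-in differential entropy (nats) with a
  matched-variance Gaussian deficit, Gaussian-filter roughness/waviness
  split (Ra, Rq, Wa), autocorrelation-based periodic-area fraction,
  circular-excavation statistics.
* **Discrimination** — mixture discriminant analysis (per-class Gaussian
  mixtures, shared covariance, EM with k-means++ initialization),
  treatment seriation into a similarity string, permutation-gatekept
  merging at *p* = 0.05, binary neighbor matrices, average-linkage
  consensus trees, jackknife (leave-one-parameter-group-out) importance.
* **Saccharification curves** — penalized-spline smoothing (GCV),
  exact extra-sum-of-squares F-tests for curve equality, 10 h fold
  changes, decay detection, curve clustering, and ingestion of
  ion-in-solution enzyme-activity tables.
* **Synthetic data** — ion-map and curve generators with planted ground
  truth (aggregate positions/radii, coverage fractions, fold effects),
  so the whole chain is testable offline.
* **Pipeline** — `run_pipeline()` sequences everything from one config
  (list or YAML) and one seed into a stamped, byte-reproducible artifact
  bundle.

## Worked example

```r
library(ionsurf)
res <- run_pipeline(list(outdir = "ionsurf_demo", seed = 42))
```

The demo generates the five-treatment synthetic suite (10 channels per
treatment, 256×256 px, 100 µm fields), segments and tiles it, and runs
the discriminant and curve analyses. `ionsurf_demo/summary.txt` then
reads:

```
treatments: Control, EtOH_DMSO_AO, Microwave_H2SO4, NaOH, SteamExplosion
discrimination string: Control - EtOH_DMSO_AO - SteamExplosion - Microwave_H2SO4 - NaOH
merged groups: Control+EtOH_DMSO_AO | SteamExplosion+Microwave_H2SO4 | NaOH
training accuracy: 0.988
top jackknife group: Li (20.0%)
fold vs control at 10 h: Control=1.00, EtOH_DMSO_AO=0.91, Microwave_H2SO4=1.75, NaOH=2.05, SteamExplosion=1.73
```

Reading those lines: the ionic feature matrix seriates the five
treatments into a string in which statistically indistinguishable
neighbors merge — the control pairs with the organosolv pretreatment,
steam explosion with microwave:acid, and NaOH stands alone, the grouping
the original analysis reported. The jackknife attributes the largest
share of that discrimination (20%, rank 1 of 9 parameter groups) to the
lithium block, which is exactly the ground truth the generator planted.
The smoothed curves recover the planted 10 h fold effects (2.04, 1.74,
1.74, 0.9) to within a few percent. `tree.nwk` holds the consensus
dendrogram — `{Control, EtOH:DMSO:AO}` and `{Steam, Microwave}` merge
first and NaOH joins last — and `jackknife.csv`, `fold_changes.csv`,
`curve_partition.json` hold the tables behind each line.

Individual stages are plain functions if you bring your own images:

```r
img <- read_chem_image("field.tif", pixel_size_um = 100/256, channel = "Li")
bm  <- binarize(img)                    # IsoData threshold
label_particles(bm)                     # count / area / average size
#> <particle_stats> count 353, area 55.237 um^2, average size 0.156 um^2
```

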