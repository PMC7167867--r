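---
title: "Quantifying widefield OCTA slabs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying widefield OCTA slabs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octaquant)
```

## What the package computes

En-face OCT-angiography exports one 8-bit grayscale slab per vascular bed:
the superficial capillary plexus (SCP, inner limiting membrane to inner
plexiform layer), the deep capillary plexus (DCP, IPL to outer plexiform
layer), and the choriocapillaris (CC, a thin slab under the retinal pigment
epithelium). From a 12 x 12 mm widefield scan the package computes, per
region of a six-region grid:

* **Perfusion density (PD)** — the percentage of analyzed area classified
  as flow: $\mathrm{PD} = 100 \cdot |V \cap A| / |A|$, where $V$ is the
  binarized vessel set and $A$ the analyzed (non-excluded) region pixels.
* **Vessel length density (VLD)** — centerline length per analyzed area
  (mm/mm^2), measured on the skeletonized vessel map.

and then a case-control statistical layer: Shapiro-Wilk-gated two-sample
comparisons with controls-minus-cases mean differences, Pearson correlation
tables between central and peripheral sectors, a group-by-age interaction
check, and the noncentral-t power/sample-size calculation.

## Binarization

Retinal slabs (SCP, DCP) are duplicated and binarized twice:

* **Huang fuzzy-entropy global threshold.** For a candidate level $t$ the
  classes $g \le t$ and $g > t$ get mean levels $\mu_0, \mu_1$; each pixel's
  membership is $u = 1/(1 + |g - \mu|/C)$ with $C$ the dynamic range, and
  the level minimizing the summed Shannon entropy
  $-u\log u - (1-u)\log(1-u)$ is chosen. All levels between the image
  minimum and maximum are searched; ties break to the lower level; constant
  images are a hard error.
* **Local-median threshold.** A pixel is vessel iff it strictly exceeds the
  median of its 31 x 31 px window plus an offset (default 0).

The two maps are combined by **logical AND**: a pixel counts as vessel only
under both thresholds. This follows the established dual-threshold OCTA
convention; the global threshold anchors the overall level while the local
one adapts to illumination, and conjunction suppresses each method's
distinct false positives. The CC slab instead gets the **Phansalkar**
threshold, designed for low-contrast flow images: with intensities
normalized to $[0,1]$ and local mean $m$ and standard deviation $s$ over a
disc of radius 15 px, a pixel is flow iff
$I > m\,(1 + p\,e^{-q m} + k\,(s/r - 1))$ with $k = 0.25$, $r = 0.5$,
$p = 2$, $q = 10$, followed by removal of 8-connected particles under
10 px. All windowed operators use reflective (half-sample symmetric)
padding, and every threshold is a strict inequality so ties resolve
deterministically toward background.

A practical limitation worth knowing: wherever local vessel coverage
exceeds 50% of the median window, the window median reaches the vessel
intensity and the local-median branch can no longer mark vessels
(saturation). Dense plexuses therefore lose pixels under the AND rule —
an intrinsic property of the dual recipe, which is why wide bright
structures are handled by the separate exclusion step below, and why the
package's recovery validation (see "Validation") runs at sparse-to-moderate
coverage where the operators are in their regime.

## Large-vessel exclusion

Major superficial vessels cast shadow/projection artifacts onto the deeper
slabs, so their footprint is excluded from DCP and CC analysis. Detection
runs on the *global-threshold* SCP map (the local-median branch hollows out
exactly the wide structures we need): a morphological opening with a disc
of radius $\lfloor w_{\min}/2 \rfloor$ keeps structures at least
$w_{\min}$ px wide (default 6 px, about 70 microns at 85 px/mm), a geodesic
reconstruction capped at that same radius restores the rim the opening
eroded, and a 2 px dilation adds a safety margin. The cap on reconstruction
is deliberate: a full reconstruction would regrow every capillary touching
a large vessel — in a connected vascular bed, essentially everything.

Exclusion is stored as a mask consulted at metric time, never as pixel
deletion: PD and VLD drop excluded pixels from both numerator and
denominator, so masking shrinks the analyzed area rather than diluting the
density, and the same binary map supports masked and unmasked analyses.

## ROI geometry

The macular region is three mutually exclusive concentric shells centred on
the fovea — tight central ring (disc, diameter 1.5 mm), medium central ring
(annulus, 1.5-3 mm), large central ring (annulus, 3-5 mm) — read as
exclusive shells because the regions are reported separately. The periphery
is three 3-mm circles externally tangent to the 5-mm circle (centre
distance 2.5 + 1.5 = 4 mm): superior, inferior, and temporal, the last
resolved by an explicit laterality flag (right eye: image left, assuming
fundus orientation). Pixel membership uses the pixel-centre distance, with
boundary ties going to the inner region; at 85.3 px/mm the pixel-counted
areas match the analytic values (1.7671, 5.3014, 12.566, 3 x 7.0686 mm^2)
well within a one-pixel boundary band.

## Skeleton length

Binary maps are thinned to 1-px centerlines with Guo-Hall thinning
(homotopy-preserving, 8-connected). Length is the sum over skeleton
adjacencies of one pixel pitch for axial steps and $\sqrt 2$ for diagonal
steps, with one refinement: a diagonal adjacency whose two pixels share an
axial skeleton neighbour is a staircase shortcut already traced by its two
axial edges, and is not counted. Without that rule every corner is counted
twice (once around, once across) and lengths inflate by tens of percent.
The estimator retains the classic digitization bias of $\pm$ a few percent
at intermediate orientations (up to +8% for straight runs near 22.5
degrees); raw pixel counting, by contrast, biases diagonal vessels by up to
41%, which is why the weighted step sum is used.

## The synthetic-data generator

No clinical images ship with the package, so validation runs on synthetic
angiograms with exact ground truth. Capillary beds grow as biased random
walks: 50-micron steps, heading perturbed by N(0, 0.12 rad), branching at
0.3 per mm (new tip at 45-60 degrees), terminating at 0.5 per mm, from 150
uniformly placed roots with respawning until the length budget
(target VLD x field area) is spent. Like a planar capillary bed the network
anastomoses instead of crossing itself: a tip stepping onto an occupied
35-micron cell of an occupancy grid ends there. These choices were fixed on
realism grounds — capillary segments are nearly straight between junctions,
and planar beds meet at junctions rather than crossing freely — and they
matter quantitatively: free-crossing, strongly coiled walks merge when
rasterized and depress measured VLD by 10-20% relative to polyline truth.

Rasterization strokes each polyline at its calibre (round caps, half-pixel
floor so sub-pixel capillaries stay connected) onto a two-level 8-bit image
(background 50, vessel 200), followed by seeded Gaussian speckle (sigma 20,
clipped to [0, 255]). The 12-mm field defaults to 1024 x 1024 px
(85.3 px/mm), a configurable stand-in for the device's unspecified export
size. Large arcade vessels (default four, 120-micron calibre) are added to
the SCP, and their footprint attenuates the deeper slabs by a factor 0.35 —
strong enough that binarization genuinely loses shadowed vessels, giving
the exclusion step something real to remove.

Cohorts draw per-eye density targets per plexus from normal distributions:
healthy means of VLD (19.5, 22.3, 10.8 mm^-1) and PD (42.0, 45.6, 84.3%)
for SCP/DCP/CC; case eyes are reduced by 18% of the control mean by
default, with the between-eye SD calibrated so that effect/SD = 18/17,
matching the emulated study's power assumption (18% expected difference,
pooled SD 17, 80% power, alpha 5%). Because rendered coverage depends on
stroke overlap, the calibre needed to hit an eye's PD target is calibrated
on the realized network (geometry is calibre-independent, so this is exact
up to interpolation). Synthetic eyes are regionally homogeneous up to
explicit per-region effect overrides — real eyes are not, so passing tests
show correct computation, not anatomical realism.

## Statistical layer

Comparisons report controls minus cases. The gate runs Shapiro-Wilk per
group at 0.05: both compatible with normality leads to the pooled-variance
Student t-test (as the emulated analysis specifies; Welch is available
behind a flag), otherwise Mann-Whitney. The 95% CI always comes from the
pooled-t interval; with eyes treated as independent units, mirroring the
emulated analysis (20 eyes of 12 patients), published CIs that may account
for within-patient clustering are not reproducible from summary rows, so
the package reproduces mean-difference columns exactly and computes its own
CIs. No multiple-testing correction is applied, again mirroring the
emulated analysis. `sample_size_two_means()` searches the smallest integer
group size whose noncentral-t power reaches the target: delta 18, SD 17,
power 80%, alpha 5% gives n = 16; at the study's actual 20 eyes per group
the attained power is 0.904, i.e. the published 20 includes a margin over
the calculation it reports.

## Validation protocol and problem sizes

The test suite validates every operator against independent naive oracles
(explicit window sorts, per-pixel threshold formulas, flood-fill labeling,
per-pixel fuzzy-entropy search, all-pairs U statistics, exact
polyline-disc clipping) on batches of random fixtures, and checks end-to-end
recovery on noise-free synthetic angiograms at 85.3 px/mm with target VLD
10 mm^-1 and 15-micron calibre, where per-region VLD lands within 5% of
polyline truth and PD is exact; a 2x calibre sweep on identical geometry
moves field-wide VLD by under 5% while PD rises everywhere. Statistical
properties (gate routing, interval coverage, empirical power 0.90 and
type-I error 5% at 20 eyes/group, nominal size at zero effect) use 200-400
simulated cohorts; rendered-image runs use 3 + 3 eyes at 256-512 px. These
sizes are the package's validation choices: large enough for binomial noise
to sit well inside the asserted margins, small enough to run routinely.

## Known limitations

* The dual AND binarization under-segments wherever local coverage exceeds
  the median window's 50% point; measured PD/VLD of dense beds (CC
  especially) are estimator-scale quantities, not absolute anatomy.
* Skeleton length carries an orientation-dependent digitization bias of a
  few percent; junction merging at high density biases VLD downward.
* Synthetic eyes are regionally homogeneous and speckle is Gaussian, not
  multiplicative; passing recovery tests demonstrates computational
  correctness, not robustness to real acquisition artifacts (motion,
  defocus, segmentation error).
* Eyes are treated as independent; within-patient correlation of fellow
  eyes is out of scope, as is any layer-segmentation or acquisition step.
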