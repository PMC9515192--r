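---
title: "Quantifying insect and fungal wood decomposition from CT scans: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying insect and fungal wood decomposition from CT scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Deadwood decomposition is driven by two very different agents. Beetles
remove wood mechanically: their larvae excavate air-filled galleries in the
bark and sapwood. Fungi degrade wood chemically: decayed regions become
less dense (darker in CT) or, when recently colonized and moist, denser
(brighter), and brown rot produces characteristic perpendicular crack
systems. Classical measures — dry-mass loss of the whole log, or of a disc
cut from it — destroy the sample, integrate over all agents at once, and
inherit large errors from within-log heterogeneity when subsampling.

X-ray computed tomography measures a density proxy (Hounsfield Units,
water = 0 HU, air = -1000 HU) for the entire log without touching it. This
package implements the two complementary image-analysis routes on top of
such scans:

* **Beetle tunnels** (classical segmentation): galleries are air-filled,
  high-contrast, and can be found by thresholding plus morphology; the
  challenge is separating them from other cavities (shrinkage cracks,
  drill holes from increment sampling).
* **Fungal decay** (learned segmentation): decay presents as a diverse mix
  of gray levels and textures that defeats fixed thresholds; a patch-based
  convolutional classifier predicts a per-pixel decay probability which is
  binarized at an F1-optimal threshold.

Everything is validated end-to-end on synthetic log phantoms with exact
per-voxel ground truth.

## Conventions

Volumes are base-R arrays with dim `(y, x, z)`, 1-based, the longitudinal
stem axis third; image rows count top-to-bottom. Voxel geometry is carried
as in-plane `pixel_spacing` (mm) and `slice_thickness` (mm). Connectivity
is 26-neighborhood in 3-D and 8 (or 4, where stated) within a slice,
everywhere.

## Preprocessing

The scanner bed is a horizontal band of synthetic material below the log,
constant across slices. `remove_table()` averages over all slices and
looks for the topmost image row in which at least half the pixels exceed a
characteristic opacity (default 200 HU — far above any wood, which ends
near -100 HU); that row and everything below is set to air. The operation
is idempotent and a no-op (with a message) when nothing matches.

Intensities are normalized as `clip((HU + offset)/factor, 0, 1)` with
defaults `offset = +1000` HU and `factor = 2500` HU. The offset is chosen
so air maps to 0; only then does the upper bound 1.0 correspond to
1500 HU = 250% of water attenuation, which fixes the otherwise
unidentified offset. Both are parameters (`normalization_params()`)
because offset correction could plausibly be per-scanner.

## Approach 1: beetle tunnels

1. **Solid detection** — hysteresis thresholding (seeds at `high = 0.20`,
   grown through `low = 0.12` by 26-connectivity), binary closing
   (radius 1), small-component removal. The thresholds sit between air (0)
   and moist wood (about 0.24–0.36 normalized) and are configuration, not
   constants: they were calibrated on phantoms and belong in
   `hysteresis_params()`.
2. **Hull and bark/wood split** — the hull is the solid after a generous
   in-plane closing (radius 6 voxels, enough to span crack and drill-hole
   openings) and slicewise hole filling. Per slice, voxel depth below the
   surface is an exact in-plane Euclidean distance transform; the depth
   profile of mean intensity is scanned for the change point maximizing
   outer-vs-inner mean separation (bark is about 190 HU darker than the
   early/latewood mix). A shell is only accepted if that separation
   exceeds 0.05 normalized (125 HU) — growth-ring oscillation alone stays
   below 0.04, which is why a simple largest-jump rule fails and the
   change-point form is used. The boundary layer is then refined by
   intensity. A barkless log therefore yields an empty bark mask rather
   than a fake one-voxel shell.
3. **Cavity detection** — dark hysteresis (seeds `<= 0.06`, kept
   `<= 0.12`) inside the hull.
4. **Crack / drill / tunnel discrimination** — purely geometric, on
   26-connected components:
   * *Drill pre-pass*: drill holes (8 mm augers, so radius well above
     gallery radii) survive a deep in-plane erosion even when a gallery
     touches the hole; each eroded core that is straight
     (end-to-end/arc-length of its binned centerline >= 0.85) and long
     (>= 12 mm) is grown back inside the cavity mask and accepted as a
     drill hole if the reconstructed radius (from volume/length) falls in
     the configured band (2.5–6 mm).
   * *Thin/thick split*: a radius-1 opening separates thin sheets from
     tubes, so a crack touching a gallery is classified on its own.
   * *Cracks* are thin sheets (second/third principal-axis ratio >= 2.5),
     radially aligned (sheet normal within 53 degrees of the tangential
     direction), and connected to the log surface.
   * Everything else is a beetle tunnel, assigned to bark or wood by the
     majority compartment of its voxels.
   The classifier is a pure function of per-component shape descriptors
   (`classify_cavities()` returns the full descriptor table), so the rules
   are unit-testable in isolation.
5. **Larvae** — bright components (0.40–0.60 normalized, i.e. moist
   tissue) kept only when 26-connected to a detected cavity and within a
   size band; this rejects moisture pockets of identical intensity. Larvae
   are counted toward tunnel volume by default (they occupy excavated
   space); a flag controls this.
6. **Quantification** — voxel counts times voxel volume; relative tunnel
   volume is tunnel/(bark + wood + tunnel) voxels, reported per
   compartment and for the whole log. The denominator definition is a
   documented choice; nothing in the quantities forces one.
7. **Bark unrolling** — per slice and angle, the bark shell is sampled
   along the radial ray from the per-slice hull silhouette inward
   (class-priority projection for label volumes, min-intensity for HU so
   air-filled galleries stand out), giving the (slice x angle) radial view
   used to inspect bark-beetle galleries.

Known, deliberate limitations mirrored from the field workflow: refilled
(frass-packed) tunnels are not detected; detached bark inflates and lost
bark deflates the bark-compartment estimate; decay regions in heavily
rotted logs are misclassified as tunnels by this route — that failure mode
is exactly why Approach 2 exists.

## Approach 2: fungal decay

Slices are normalized as above and processed in 48 x 48 px patches
anchored every 12 px (75% overlap between neighbors), with final anchors
clamped to the image border rather than padding — border context is never
fabricated, and border pixels are instead down-weighted: predictions are
recombined as a weighted average with a radial raised-cosine window
`(cos(pi d/D)+1)/2` (distance `d` from patch center, `D` the corner
distance, floored at 1e-3 so corners keep positive weight). Because the
weights are renormalized per pixel, recombination is a partition of unity
— any strictly positive center-peaked window would be equally correct; the
cosine form is the conventional choice.

The classifier is a compact encoder–decoder network with skip connections
(three resolution levels, 48 → 24 → 12 px, 3 x 3 kernels, ReLU, 1 x 1
sigmoid head), trained with binary cross-entropy and Adam. It is
implemented natively (compiled convolution kernels plus an R training
loop) and verified against finite-difference gradients; training is
deterministic given the config seed. The architecture is a faithful
contract-level stand-in for a U-Net-style model, not a replica of any
specific published layer table; `train_config()` exposes all
hyperparameters.

The binarization threshold is chosen by exhaustive search over
0.01…0.99 (step 0.01) maximizing F1 on the validation split, ties broken
toward the lower (more sensitive) threshold. Validation folds are assigned
per slice, never per patch, so overlapping patches of one slice cannot
leak across folds (`assign_cv_folds()`, default 5 folds). Undefined
metrics (zero denominators) are reported as `NA`, never silently as 0 or
1 — a silent default would corrupt threshold selection.

Because a 2-D classifier is slice-independent, binarized fractions can
jitter between adjacent slices; `smooth_longitudinal()` applies a 1-D
Gaussian along the stem axis only (decay spreads predominantly
longitudinally, so this respects the anatomy; sigma = 0 is the identity).
`quantify_decay()` binarizes, removes crack voxels (cracks are not decayed
wood), and reports decayed wood as percent of wood volume.

## The synthetic phantom generator

`generate_phantom()` carves a labeled cylindrical spruce-like log:
bark annulus, concentric early/latewood rings, tortuous galleries
(correlated random walks, guild-constrained: bark-beetle style confined to
the bark shell, wood-borer style penetrating sapwood), radial shrinkage
cracks (1–2 voxel wedges reaching the surface), straight drill holes
perpendicular to the stem axis, bright larvae touching gallery ends, and
decay regions (ellipsoids, darker or brighter than sound wood, optionally
with perpendicular crack systems), plus additive Gaussian HU noise. The
label volume records every structure before noise; generation is
deterministic given `(spec, seed)`.

The default HU palette (air -1000, bark -500, earlywood -400, latewood
-100, larva +60, decay contrast +-150, noise sigma 10 HU) is invented;
only its ordering is asserted anywhere (air < dark decay < wood < larva).
What the phantoms do *not* emulate: partial-volume effects at structure
boundaries, beam hardening and scanner artifacts, real gallery
architectures of particular species, bark loss/detachment, and the full
textural diversity of real decay. Passing phantom tests therefore
demonstrates the correctness and internal consistency of the algorithms,
not field-data performance; the published field scores require the
original scans and labels.

## The simulated experiment

`simulate_experiment()` reproduces the field design exactly: 61 mesocosms
(26 control, 20 bark beetles, 15 wood-borers), two logs each (122 logs,
16–20 cm diameter, 53 cm long with a 3 cm disc), one log harvested per
mesocosm at each of two time points. Per-guild effects
(`guild_effects()`): bark beetles excavate little and almost exclusively
in the bark (default mean fraction 0.004, 90% in bark); wood-borers
excavate several-fold more and penetrate the wood (0.02, 30% in bark);
fractions vary lognormally (CV 0.4). These magnitudes were chosen so the
measured contrasts (control near the false-positive floor, bark beetles
modestly above it, wood-borers several times higher) sit in the regime the
field study reports.

Mass bookkeeping uses voxel mass proportional to (HU + 1000) — invented,
but monotone in density, which is all the correlation structure needs.
Mass loss = tunnel fraction + 0.3 x decay fraction + noise. The disc
estimator `dry mass log = (fresh log / fresh disc) x dry disc` inherits
error from the moisture-ratio mismatch between disc and log
(`moisture_sd`); the default 0.02 was calibrated once so the rank
correlation between tunnel fraction and apparent mass loss lands near 0.5
(the moderate-correlation regime of the field data), and it produces
occasional negative apparent mass loss, as observed in practice. Balance
resolution (0.1 g) is part of the noise model so the zero-noise limit is
exactly rank-faithful.

## Numerical choices and degenerate inputs

* Hysteresis with `low = high` is disallowed (`0 <= low < high <= 1`).
* Component descriptors add a quarter-voxel ridge to covariance
  eigenvalues so single-plane components have finite planarity.
* An all-air volume raises "no log found"; a slice without solid yields
  empty masks for that slice; an empty wood mask makes relative decay an
  error, not 0/0.
* Thresholds tied in F1 resolve to the lowest candidate; max-pool ties
  route gradients to the first maximum.
* The Spearman p-value is exact (full permutation enumeration, ties
  included) for n <= 10 and a t-approximation above; the statistic itself
  is Pearson on average ranks.
* DICOM support is a minimal explicit-VR little-endian reader/writer for
  uncompressed single-frame CT series — enough to round-trip scanner-style
  exports; NIfTI and TIFF(+JSON sidecar) are the primary containers.

## Problem sizes used in the shipped tests

The test suite and the acceptance script exercise the full pipelines at
reduced scale, chosen as the smallest sizes at which every structure is
several voxels across: oracle-equivalence phantoms of about 187 x 187 x 48
voxels at 0.75 mm/2 mm spacing; decay training on 50 annotated 95 x 95
slices, 200 patches, 20 epochs; fraction recovery over 20 logs; guild
contrast over 11 rendered log sections. At these sizes the whole suite
runs in minutes on one CPU; all sizes are parameters, and nothing in the
algorithms depends on them.
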