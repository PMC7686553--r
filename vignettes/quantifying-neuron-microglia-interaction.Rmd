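---
title: "Quantifying layer-specific neuronal activation and neuron-microglia interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying layer-specific neuronal activation and neuron-microglia interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfcquant)
```

# Scope and model

`pfcquant` quantifies four readouts that together characterise cortical
circuit hyperactivation and the microglial response to it:

1. **Nuclear activation**: c-Fos immunopositive nuclei detected in projected
   fluorescence stacks and classified by a dual area/intensity threshold,
   with counts and densities per cortical layer.
2. **Microglial network morphology**: binarization and skeletonization of
   the membrane-marker channel, soma-centered 2D Sholl profiles of the
   *non-isolated* network, and statistics over single-cell vs inter-cellular
   zones.
3. **Neuron-microglia interaction**: the same Sholl machinery centered on
   activated vs inactive neuronal nuclei in 2D, 26-connected shell-cluster
   counts on the thresholded membrane volume in 3D, and soma-contact
   fractions.
4. **Behaviour and release**: trajectory metrics (binned distance, epoch
   velocity, rotations, Y-maze spontaneous alternation) and superfusion
   fractional-release arithmetic.

Everything is exercised on synthetic data with exhaustive ground truth; the
generator is a first-class module, not a test fixture.

# Nucleus detection and classification

Detection operates on a 2D projection (`project_stack()`, maximal projection
for fluorescence, sum of slices for brightfield DAB material). The
foreground is produced by an automatic threshold — Otsu by default, the
method is configurable and recorded in output provenance since different
acquisitions may favour different rules — and segmented into 8-connected
components. 8-connectivity is stated explicitly because every reported count
depends on it. The mean gray value of each object is measured on the
*unthresholded* image over the object mask, so the threshold only selects
pixels and never biases the intensity estimate.

Classification is deliberately minimal: an object is strongly activated
(`cfos_plusplus`) iff `area > min_area` **and** `mean_gray > min_intensity`,
both strict, so boundary objects fall to the weaker class
(`cfos_plus`). The conventional anchors are 200 µm² and 400 mean gray;
`thresholds_high_intensity()` carries the alternative 100 µm² / 1100 pair
used with brighter staining protocols. Strictness makes the classification
reproducible from the stored `(area, mean_gray)` pairs alone, and raising
either threshold can only shrink the strong class (a property the test
suite asserts over threshold grids).

Layers are half-open bands `[start, start + width)` measured from the
midline edge. Published layer widths are ranges (I: 120–140 µm, V:
320–350 µm, VI: "minimum 280"); the configuration carries a single value per
layer, defaulting to the midpoint (130, 335) and to 280 for VI. Nuclei
beyond the last band receive the sentinel `beyond_VI` rather than being
dropped, so per-layer counts always partition the detections.

# The non-isolated Sholl profile

Thin imaging stacks cut microglial branches, so reconstructing single cells
is not reliable; the package instead skeletonizes the whole network and
runs Sholl analysis on it. The profile of a network is not the classical
bell curve: as the radius grows, circles collect branches of additional
cells and the crossing count rises roughly linearly. The identity baseline
`N(r) − r` (`identity_baseline()`) makes deviations from that linear growth
visible, and zone statistics compare the first 20 µm (single-cell
arborisation) with 20–40 µm (inter-cellular territory) between experimental
groups.

## Numerical definition of a crossing

A crossing at radius `r` is a maximal 8-connected cluster of skeleton pixels
on the rasterized circle of radius `r`. Two rasterization subtleties were
resolved during development and are part of the definition:

* The ring is the **supercover circle**: every pixel whose closed unit
  square the continuous circle touches. Rings defined by classic circle
  drawing algorithms are 8-connected curves, and an 8-connected skeleton
  branch can pass *between* two diagonal ring pixels without sharing one —
  a 5-armed star then counts 3 at some radii. The supercover ring provably
  intercepts every 8-connected path from inside the circle to outside, so a
  k-armed star counts exactly k at every radius where the arms are
  separated, and a straight line through the centre counts exactly 2.
  Published drawing algorithms also differ between textbook variants in the
  exact pixel set they emit, which would make "the ring" ill-defined for
  cross-checking; the supercover rule is declarative and can be re-derived
  by a naive per-pixel scan.
* Counting clusters spatially (rather than runs along the ring in angular
  order) makes the count independent of traversal order; at small radii two
  ring pixels can be 8-adjacent without being consecutive along the ring.

The test suite checks the implementation against a brute-force oracle
(independent ring scan + breadth-first flood fill) on dozens of random
skeletons, plus rotation invariance and monotonicity under added foreground.

## Skeletonization

No installed package provides topology-preserving binary thinning, so
Zhang–Suen thinning is implemented directly (vectorized over foreground
indices). Its contract — idempotence and preservation of the 8-connected
component count — is enforced by tests on random arbor masks rather than
assumed.

## Rank tests and ties

Zone comparisons use the two-sided Mann–Whitney U test: exact when both
groups have at most 8 centres and the pooled values are tie-free, otherwise
the tie-corrected normal approximation with continuity correction. When
every pooled value is identical the test is degenerate; the package returns
p = 1 (no evidence of a shift) instead of NaN.

# 3D shell analysis and soma contacts

The 3D analysis runs on the thresholded membrane volume, not a skeleton:
the membrane outline is the biologically meaningful boundary for branch
counts around a nucleus. For each radius the shell collects foreground
voxels whose centre distance (in µm, so per-axis anisotropy is respected)
lies in `[r − dr/2, r + dr/2)`, and reports the number of 26-connected
clusters — each cluster is one branch piercing the shell. Whether published
3D counts were components or voxel crossings is generally not reported by
plugin-based workflows; the components definition is adopted here and
recorded in output provenance. Defaults: `dr` = 1 µm, `r_max` = 15 µm.
Volumes thinner than `2 r_max` along z are refused unless explicitly
forced, and centres for the 3D analysis should come from the central 15 µm
of the stack (`filter_central_z()`), so shells stay inside the tissue.

Soma contact uses a distance-transform criterion: a nucleus contacts a
microglial soma when its mask, dilated by the contact margin, overlaps the
soma mask. Manual "physical contact" scoring has no numeric margin; the
default is one pixel (0.5 µm at the default sampling), surfaced as a
parameter.

# The synthetic cortical field

The generator renders three channels (nuclear marker, activation marker,
microglial membrane) with every object recorded in the ground truth before
noise:

* **Nuclei** are ellipses (axis ratio 0.75–1) with a bounded radial taper:
  intensity falls linearly to 85% of the peak at the rim and the level is
  rescaled so the mean over the mask equals the drawn class mean exactly.
  An unbounded Gaussian taper was rejected: with soft edges the thresholded
  mask (hence the measured area and mean) depends on the threshold level,
  which would break the guarantee that ground-truth labels are reproducible
  from the rendered image at zero noise. Class areas and intensities are
  drawn from truncated normals with margins around the classification
  thresholds wide enough that rendering quantisation cannot flip a label.
  The class intensity distributions are free parameters of the simulation,
  not estimates of real staining distributions.
* **Microglia** are somata on a jittered grid (quasi-regular, as in cortex)
  with two independently controlled process populations: random binary
  trees truncated at the single-cell radius (20 µm), and inter-cellular
  segments confined to the territory at 20–40 µm from the parent soma *and*
  at least 20 µm (+ a margin absorbing the rendered branch thickness) from
  every soma. The margin matters: without it, segments hugging the 20 µm
  boundary bleed rendered pixels into the single-cell zone and a density
  manipulation contaminates the zone that should stay constant.
  `intercell_branch_density` scales the second population only, which is
  what makes zone-resolved recovery tests meaningful.
* **Attraction**: optionally, each activated nucleus receives
  `activation_attraction` extra short branches placed within
  `attraction_radius` (default 8 µm), modelling preferential microglial
  process recruitment around hyperactive neurons.
* **Noise** is additive Gaussian clipped at zero; there is no PSF
  convolution, bleaching or autofluorescence model, because the analysis
  operates on thresholded images and photometric realism would add
  parameters without adding test power. Consequences: passing tests show
  correctness of the measurement chain on well-separated, blob-like
  objects; they do not show robustness to optical blur, touching nuclei
  (no watershed splitting is attempted) or staining gradients.
* Default voxel size is 0.5 µm in-plane and 1 µm axial, matching common
  confocal z-stack settings; all draws of one call flow from a single seed,
  and identical parameters give bit-identical stacks.

Trajectories are either scripted (waypoint lists, reproduced exactly —
used for hand-enumerable behavioural cases) or persistent-heading random
walks reflected inside the arena. The release simulator draws a constant
per-sample hazard on the remaining pool with a multiplicative bump at the
stimulation sample, conserving total activity to floating precision.

# Behavioural scoring choices

"Successful alternation" is computed as sliding triplets over *entries*
(three consecutive entries visiting three distinct arms), the standard
definition; the percentage divides by entries − 2. Scoring over changes
rather than entries is equivalent here because repeated same-arm entries
are collapsed before scoring (a centre-and-back into the same arm is a
single exploration). The entry criterion is penetration of the central body
point beyond 20% of the arm length; animals with fewer than 20 alternations
are flagged, not silently dropped. With fewer than three entries the
percentage is reported as missing rather than zero.

Rotation counting has no published algorithmic definition in
tracking-software workflows, so the rule is stated explicitly: headings are
taken between path anchors at least 0.5 cm apart (suppressing jitter spins),
one unsigned rotation is counted per accumulated 360° without a >90°
reversal, minus a small allowance for the discretisation shortfall of a
sampled loop, and a counted rotation must span a configurable minimum
radius.

# Release arithmetic

The only measurable anchor after a superfusion experiment is the tissue
content remaining at the end, so the tissue content at the start of sample
k is reconstructed backward: residue plus everything released from k
onward. Fractional release divides by that reconstruction, which makes all
fractional quantities invariant to rescaling the absolute activities (a
property the tests assert). Basal outflow averages the two drug-free
samples immediately before the stimulus; evoked release subtracts basal
from the mean over a response window defaulting to the stimulation sample
plus the two that follow (the window is configuration — published net
release values rarely state it).

# Statistical layer

`compare_two()` provides Welch's t and Mann–Whitney;
`two_way_anova_bonferroni()` fits `value ~ A * B` with sum contrasts and
Type-III sums of squares (layouts here are routinely unbalanced; the choice
is recorded in the output), then compares factor-combination cells with the
classical post hoc t on the residual mean square, Bonferroni-adjusted
(raw p × number of comparisons, capped at 1). Under a null simulation the
family-wise error of the adjusted comparisons stays below the nominal 5%
(asserted over 500 replicates). Imaging measures are often pseudo-replicated
(many cells per animal); `grouped_measure()` keeps both levels and
`animal_level()` collapses to per-animal means so analyses can be run and
labelled at either level.

# Problem sizes and determinism

The simulation studies in the test suite use fields of 260–500 µm at
0.5 µm sampling with 30–42 microglial somata and 24–50 nuclei, 20
replicates per condition, and 200–500 replicates for the statistical null —
sizes at which every study completes comfortably on one CPU while leaving
the effects far from borderline. The zone-effect study deliberately uses a
sparse soma grid (~70 µm spacing) so the 20–40 µm annulus of one cell
contains no single-cell branches of its neighbours; at realistic packing
the inter-cellular contrast is diluted by neighbour arbors, which is a
property of the tissue, not of the estimator. All simulation seeds are
explicit; the acceptance script derives every stream from its `--seed`
argument.

# Known limitations

* No optics: blur, bleaching and depth attenuation are not modelled, and
  nuclei never touch; real data will need the (configurable) auto-threshold
  and minimum-area settings revisited.
* The 2D Sholl crossing definition counts clusters on a one-pixel-radius
  ring; extremely tangential branches can contribute two clusters on one
  ring if they exit and re-enter, which is faithful to the geometric
  definition but differs from a human counting "branches".
* Single-cell reconstruction, branch-order metrics and time-resolved
  contact dynamics are out of scope.
* Tests validate the pipeline against its own generative model; agreement
  with manual expert counts on real material is a separate validation that
  text-only fixtures cannot provide.
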