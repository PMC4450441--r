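---
title: "rootquant: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rootquant: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rootquant)
```

# Scope

rootquant quantifies nuclear reporter fluorescence per cell in confocal
z-stacks of plant root meristems, where the cell-wall stain delineates
cells but no 3D segmentation is available directly: cells are segmented
plane by plane and then reconstructed in 3D by linking 2D regions across
neighbouring planes. Downstream, per-cell means feed an ON/OFF mixture
classifier, clonal cell-file statistics, and a two-reporter test that
discriminates cis- from trans-encoded epigenetic memory. A synthetic
root generator with voxel-level ground truth supports every stage.

# The measurement model

A stack is a set of channels on a common voxel grid (row, column,
plane), plane 1 being the first-acquired (shallowest) focal plane.
Calibration defaults reflect a 20x confocal setup: 0.249 µm per pixel
in-plane and a 3 µm z-step, at which nuclei (~7 µm diameter) intersect
2–3 consecutive planes.

Per-cell mean intensity is total reporter intensity inside the
reconstructed cell across its member planes divided by the total member
region area (the volume proxy). There is no background subtraction,
flat-field correction or bleaching correction: means are raw, and the
depth filter handles bleaching by exclusion rather than correction.

# Segmentation (per plane)

*Masking.* The stated intent is a morphological isolation of root tissue;
the concrete recipe here is Gaussian smoothing, global Otsu threshold,
closing with a 5 px disc, retention of the largest connected component,
and hole filling. Cell interiors are holes in the wall signal, so hole
filling is what turns a wall skeleton into a solid tissue mask.

*Wall detection.* Gaussian smoothing with sigma = 2 px, then a
median-based local threshold with radius 40 px. A pure median rule marks
half of any flat region as foreground, so a pixel counts as wall only if
it exceeds the local median by an offset of 2% of the image dynamic
range (configurable, `thresholdOffset`). The window radius is clamped to
fit small images.

*Skeletonization and labelling.* The binary wall is thinned to 1 px
ridges (Zhang–Suen, compiled code; no installed package provides binary
thinning). Candidate cell regions are the 4-connected components of the
skeleton complement inside the mask — the flood-fill equivalent of a
watershed on this topography. 4-connectivity of the complement is what
guarantees that an 8-connected skeleton curve always separates the
regions on either side. Skeleton pixels belong to no cell; thick-wall
pixels off the skeleton are absorbed by the adjacent regions, which is
the main systematic (few percent) inflation of region areas relative to
ground truth. Regions under `minRegionArea` (50 px², configurable) are
dropped; regions touching the image border are kept but flagged so that
analyses can exclude them.

# 3D reconstruction

Two regions in adjacent planes may belong to the same cell when their
centroids are within 20 px and their relative area difference
|a1 − a2| / max(a1, a2) is at most 0.5; the symmetric max-denominator is
a choice (the criterion's base is otherwise ambiguous) and makes the
test order-independent. Within each plane pair the matching is a
minimum-total-centroid-distance optimal assignment over admissible pairs
(Hungarian algorithm in compiled code), not a greedy scan: greedy
matchings depend on iteration order and can strand matchable regions.
Distance ties break by smaller area difference, then lower labels,
implemented as lexicographic epsilon terms in the assignment cost
(1e-5, 1e-8, 1e-10 — far below any physically meaningful distance
difference). The test suite pins this behaviour to an independent
exhaustive-enumeration oracle on hundreds of random instances.

Chains are cut after 6 planes (18 µm at the 3 µm step), starting a new
cell — the simplest reading of a z-extent cap. Cells must span at least
2 planes by default (`minPlanes`): nuclei span 2–3 planes, so
single-plane fragments are mostly segmentation noise; the threshold is
configurable to 1. Linking never skips planes. A post-hoc audit
(`auditLinkCriteria`) re-checks every adjacent pair in every
reconstructed cell independently of the matching code path.

Cell depth is the mean of (plane − 1) · z-step over member planes, i.e.
the mean distance from the top focal plane.

# Depth filter

Acquisition goes top to bottom, so depth and acquisition time are
confounded and photobleaching depresses deep intensities. The
"approximately constant" plateau is operationalised as: compute the mean
of per-cell means at each depth; the cut depth is the deepest depth at
which the cell-count-weighted running mean still reaches (1 − tol) of
the shallowest depth's mean, tol = 0.15 by default. Count weighting
stops sparse depth bins (single stray chains) from dominating. A manual
cut depth is supported, fewer than 3 distinct depths disables filtering
with a warning, and re-filtering a filtered table is a no-op. Note that
with mixed ON/OFF populations and few files, per-depth means confound
expression sampling noise with bleaching; profiles should be pooled over
enough cells (or computed at uniform expression) to isolate bleaching.

# ON/OFF classification

States are called from a two-component Gaussian mixture on log mean
intensities (mclust), assigning each cell to its MAP component; the
component with the larger mean is ON. The population counts as bimodal
only if (i) BIC prefers two components over one, (ii) the fitted means
differ by at least one pooled within-component SD, and (iii) the modes
differ by at least 2-fold in intensity (`minFold`). The first two guards
reject the EM failure mode of splitting one Gaussian into overlapping
halves; the fold-change floor rejects the complementary failure mode of
shaving a narrow tail off a unimodal population with a tiny absolute
separation. Silencing contrasts are on the order of 10-fold, so 2-fold
is conservative. If the population is unimodal, all cells receive the
single state given by comparing the median against an absolute
`fallbackThreshold` (10 a.u. by default — instrument-specific, matched
to the generator's intensity scale, and the one deliberately "magic"
number in the chain; there is no way to orient a single mode without an
absolute anchor). Classification is invariant under moderate monotone
affine rescaling of intensities while the modes remain separated;
extreme offsets compress fold changes and can push a bimodal population
under the fold-change floor by design.

# File coherence and the cis/trans test

Clonal files should be state-homogeneous; the coherence score is the
mean fraction of cells agreeing with their file's majority state over
files of length ≥ 2 (expectation 1 − e under i.i.d. call error e).

The two-reporter test formalises the cis-vs-trans argument. Under the
trans null every file is ON/ON (probability p̂, estimated from the
file-level calls) or OFF/OFF, and mixed ON/OFF or OFF/ON files arise
only through per-cell call error, estimated as the within-file
discordance ê. The statistic is the observed fraction of mixed-state
files (file state per reporter = majority call; ties called ON, a
deterministic convention mirrored exactly in the null simulation). Its
null distribution comes from a parametric bootstrap (B = 999 by
default): draw file states, draw per-cell flip counts Binomial(n_f, ê)
per reporter, re-take majorities. The p-value uses the (1 + #{sim ≥
obs}) / (B + 1) convention, which keeps the test conservative. A second
read-out is an exact two-sided binomial test of the ON/OFF vs OFF/ON
count symmetry: cis memory with exchangeable copies predicts equal
rates, so a significant asymmetry flags copy-specific silencing rather
than locus-autonomous memory. Both statistics are constructions of this
package, not classical named tests.

# The synthetic generator

The generator renders what the pipeline needs and nothing more: an
idealised meristem of rectangular cells in parallel longitudinal files,
arranged in z-layers (`zPlanes / cellDepthPlanes` layers of
`cellDepthPlanes` planes each, 3 layers of 12 µm by default), with
alternate layers offset axially by half a cell length. The offset (25 px
by default) exceeds the 20 px linking radius, so correctly reconstructed
cells never chain across layer boundaries — the synthetic analogue of
staggered cell layers in real roots. Each 3D column of cells in one
layer is a clonal file; total files = `nFiles` × layers.

Expression: each file draws ON with probability `pOn` (per reporter
under cis memory, shared under trans memory); a per-cell switching-noise
parameter (default 0) exists for robustness testing.
`pOnFromColdWeeks()` maps cold duration to `pOn` through a logistic
decay (half-silencing at 6 weeks, slope 1.3 weeks), reproducing the
qualitative series: nearly all ON without cold, bimodal around 6–8
weeks, nearly all silenced at 10 weeks.

Rendering: walls are 2 px bright ridges (200 a.u.) over dim tissue
(30 a.u.); nuclei are spheres of radius 3.5 µm (the nuclear diameter is
not constrained by anything except the 2–3-plane span, which a 7 µm
sphere satisfies deterministically at a 3 µm step) jittered within the
cell; nuclear intensity is 100 a.u. (ON) or 10 a.u. (OFF) times a
per-cell lognormal factor (CV 0.2, truncated to [0.5, 2] so the ON and
OFF ground-truth populations can never overlap); a tissue
autofluorescence baseline of 5 a.u. covers the whole tissue in the
reporter channels. The baseline matters: detector noise is additive
Gaussian (sd 5 a.u.) clipped at zero, and without a baseline the
clipping inflates near-zero OFF-cell means by a bias comparable to the
signal itself — as in real detectors, the background sits above the
clip point. Bleaching multiplies each plane by (1 − `bleachRate`)^(plane
− 1) (default 0.01), modelling the depth/time confound of sequential
acquisition.

Ground truth defines the true mean of a cell on the noise-free,
bleach-free rendering (baseline + nuclear signal diluted over the cell
volume); bleaching and noise corrupt only the rendered stack, so the
accuracy audit charges them to the pipeline's error budget exactly as a
manual reference measurement on a clean acquisition would.

Randomness uses one master seed split into three sub-streams (states,
geometric jitter, noise), so expression states are reproducible
independently of the noise realisation. Identical inputs give
bit-identical stacks and truth tables.

What the generator does **not** emulate: optics (no point-spread
function), curved root morphology and non-rectangular cell shapes, cell
division and growth, elongation-zone endoreduplication, uneven
illumination, and wall-stain variability. Passing tests therefore
demonstrate correctness of the operators under the assumed statistical
structure, not performance on real microscopy; the published ~80%
per-cell accuracy on real data is the realistic expectation, and the
synthetic audit (98–100% at the same 20% tolerance) is an upper bound in
the absence of morphological irregularity.

# Validation

Automated cells pair to the true cell owning the majority (≥ 50%) of
their pixels, at most one automated cell per true cell (largest overlap
wins). The audit samples cells at random (seeded) and scores a cell
accurate when its automated mean is within a 20% relative error of the
ground-truth mean — the tolerance is a package decision (a manual
validation's notion of "accurate" must be made explicit to be testable)
and is configurable. Unpaired automated cells are incorrectly segmented
and count as inaccurate wherever they are sampled.
`syntheticBatchAudit()` runs the whole loop — generation, full pipeline,
depth filter, pooled 50-cell audit — across a batch of roots; the
acceptance script uses 8 roots of the default 144-cell geometry (1152
true cells), a size chosen to exercise the complete pipeline in well
under a minute.

# Problem sizes used by the test suite

Unit tests run on 3-file × 6-cell, 8-plane roots (36 cells). The
statistical checks use: 500 random linking instances against the
exhaustive oracle; 24-file × 7-cell geometries (504 cells, 72 files) ×
10 seeds per ON-probability level for recovery of `pOn` within ±0.05;
20 seeds per level for bimodality flags; and 200 replicate seeds each
for the cis/trans test's power (cis, 100 files × 10 cells) and type-I
error (trans, 5% injected call error), with B = 499 bootstrap
replicates. These sizes make every statistical expectation sharp enough
that the assertions are not borderline, while the whole suite stays in
the minutes range.

# Known limitations

* File tracking on real images (assigning reconstructed cells to files
  through the label maps) is out of scope; file-grouped analyses take
  file ids from synthetic truth or user annotation.
* The wall-channel requirement means the pipeline cannot segment stacks
  where the wall stain is incompatible with a reporter (the two-reporter
  test therefore runs on state calls, not on two segmented channels).
* The plateau depth filter assumes the shallowest depth is unbleached
  and that expression composition is homogeneous across depths.
* Registration (`alignStack`) estimates integer translations only and is
  off by default; synthetic stacks are pre-aligned, and the staggered
  layer structure means consecutive synthetic planes are not suitable
  registration targets anyway.
* The unimodal fallback threshold is an absolute intensity and must be
  re-tuned per instrument/reporter.
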