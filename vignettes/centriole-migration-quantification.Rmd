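---
title: "Quantifying centriole-group migration: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying centriole-group migration: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centriolr)
```

# The measurement problem

Olfactory sensory neurons assemble their sensory cilia from centrioles
that are produced near the basal lamina and migrate, in groups of several
centrioles each, up the extending dendrite to the apical dendritic knob.
Quantifying this process from confocal fluorescence imaging decomposes
into five measurements, each of which this package implements as an
explicit, testable model:

1. how many centrioles and cilia a dendritic knob carries, and what
   fraction of centrioles bears a cilium;
2. how centrioles partition into migrating groups and how far the leading
   group lags behind the dendrite tip;
3. how fast groups move, and in which direction, in live explants;
4. where groups sit relative to epithelial landmarks, normalized so that
   differently sized tissue pieces are comparable;
5. whether a drug shifts those normalized counts, judged by a paired
   resampling test.

Because annotated ground truth does not exist for real tissue, the
package carries a synthetic-scene generator whose output has the
statistical structure the analysis assumes. Every stage is validated
against that ground truth; the generator is therefore first-class,
tested code, not a fixture.

# Conventions

Arrays are ordered `(t, c, z, y, x)`. Physical coordinates are `0`-based
voxel index times spacing, in micrometres of the *acquisition* frame (for
expansion-microscopy scenes, the expanded gel). "Apical" is the direction
of decreasing `z` unless a `voxel_grid` says otherwise; apical
displacement is therefore positive when `z` decreases. Reports can be
rescaled to biological (pre-expansion) units by dividing lengths by the
scene's `expansion_factor` (default 4, the reproducible expansion factor
of the protocol being emulated); the conversion is deliberately explicit
and never applied silently.

A deliberate design decision concerns the point-spread function. The gel
expands the *specimen*, not the optics: in the acquisition frame the PSF
is simply the microscope's, here `psf_sigma_um = (0.35, 0.15, 0.15)` µm
for `(z, y, x)` — typical spinning-disk confocal values. Treating the PSF
as if it expanded with the sample (multiplying it by the expansion
factor) would make ~36 puncta spaced at realistic docking distances
unresolvable by *any* detector, contradicting the very counts expansion
microscopy exists to enable. Structure sizes, by contrast, are expanded:
a centriole barrel appears with an intrinsic Gaussian width
`centriole_sigma_um = 0.25` µm and a ciliary axoneme with
`cilium_sigma_um = 0.2` µm, both on the expanded scale, and both
convolved with the PSF at render time.

# The synthetic scenes

## Knob scenes

`generate_knob_scene(config, n_centrioles, n_cilia)` renders two
channels: `"centrin"` (puncta) and `"actub"` (cilia).

* **Docking geometry.** Centrioles are placed on the apical dome shell of
  a spherical knob (radius `knob_radius_um = 4` µm expanded ≈ 1 µm
  radius biological, polar angle ≤ 105° from the apical pole, shell
  thickness 30 % of the radius). Placement enforces a hard-core minimum
  separation (`min_separation_um = 1.5` µm, roughly one expanded barrel
  diameter plus clearance) *and* an anisotropic constraint that forbids
  two barrels from stacking vertically closer than 2.4 µm: docked basal
  bodies sit side by side on the membrane, not on top of each other.
  The anisotropic term also keeps the scene within what the optics can
  distinguish along `z`, so recovery failures indicate detector defects
  rather than physically impossible configurations.
* **Cilium geometry.** Each cilium emerges along the local surface normal
  of the dome (blended with the apical direction), then rises as a
  gently waving ray, steered upward near the lateral image boundary and
  outward near the apical face — a diverging "fountain", the way cilia
  fan out from the knob in en-face views. The tangent field is
  integrated at a 0.25 µm arc step, so the recorded ground-truth arc
  length equals the drawn length exactly. Lengths are uniform on
  `cilium_length_range_um = (2, 10)` µm. A quadratic-Bézier bundle was
  tried first and rejected: from a realistically crowded knob, Bézier
  tubes cross each other so often that they fuse under the anisotropic
  PSF, and no tracer can count them — the divergence of the fountain
  field is what makes the scene resolvable, just as real cilia spread
  apart as they leave the knob.
* **Noise.** `Poisson(signal + background) + Normal(0, read_sigma)`, the
  simplest model matching photon-limited confocal data
  (`background_level = 50`, `read_sigma = 3`). `snr` sets the peak
  amplitude in units of the background noise SD (default 10);
  `snr = Inf` disables noise entirely and returns the clean render, which
  the tests exploit for exactness checks.

## Time-lapses

`generate_timelapse()` renders moving clusters of 3–12 puncta whose
centroids travel at assigned velocities (µm/min, apical positive) with
i.i.d. per-frame jitter, plus one static fiducial cluster, mirroring the
use of a mature neuron's docked centrioles as a drift reference. A
`drift_um_per_min` option applies a common drift to everything, which the
fiducial correction must cancel. Velocities above 1 µm/min are rejected
as a sanity bound — observed group rates are an order of magnitude
slower.

## Count tables

`generate_count_table()` emits one paired (control, drug) record per
animal × timepoint × compartment. Counts are Poisson with mean
`density × length / 100 × multiplier`; each record draws its own scored
basal-lamina length from `length_um_range = (900, 1150)` µm, matching the
per-explant lengths of a real scoring session, and the default control
density of 2.9 groups per 100 µm matches the scored explant data this
emulates. Multipliers can be per-compartment or per-compartment ×
timepoint.

## What the generator does *not* emulate

Real tissue adds autofluorescent background structure, intensity
variation between centrioles, partial antibody labelling, gel-expansion
anisotropy, stage drift beyond the uniform option, and cilia far longer
than 10 µm whose distal segments leave the imaged volume. Passing the
recovery tests therefore shows the algorithms are correct under the
stated noise and geometry model — it does not certify performance on
arbitrary tissue, where the review-table mechanism of `detect_spots()`
(a keep/drop CSV applied to detections) exists to make the manual
inspection step of semi-automated counting reproducible.

# Detection models

## Spots

`detect_spots()` is a multi-scale Laplacian-of-Gaussian detector. At each
of `n_scales = 3` geometrically spaced lateral scales in
`scale_range_um = (0.25, 0.5)` µm (bracketing the expanded centriole
radius), the channel is smoothed anisotropically (axial sigma =
`axial_ratio = 1.5` × lateral, the PSF's axial elongation) and the
scale-normalized negative Laplacian is computed by finite differences.
Local 26-neighbourhood maxima above threshold become candidates; maxima
within one sigma of a volume face are discarded because edge replication
inflates the response there. The default threshold is Otsu's threshold on
the positive response, floored at `noise_k = 6` robust noise SDs
(1.4826 × MAD) — the floor is what keeps pure-noise volumes empty, since
Otsu alone always splits a unimodal histogram somewhere. Candidates are
refined to sub-voxel positions by response-weighted centroids over a
one-sigma window and de-duplicated greedily (descending response) with an
exclusion distance of 0.7 × the summed scales, measured with the axial
coordinate divided by `axial_ratio` so the rule matches the anisotropic
resolution. Counts are monotone non-increasing in the absolute threshold
by construction.

## Cilia

`detect_cilia()` extracts filaments in five steps, each motivated by a
failure mode observed while building it:

1. **Threshold** the lightly smoothed channel halfway between the
   background (median) and the bright signal (99.9th percentile). With
   tubes of uniform plateau brightness, the half level places the mask
   boundary at the tube's true endpoint (the blurred end profile crosses
   half-maximum exactly at the end of the line source).
2. **Tubeness gate**: Hessian eigenvalues are computed at mask voxels
   (closed-form symmetric 3×3 eigensolver, finite-difference Hessian);
   a voxel survives if its two smallest eigenvalues are strongly
   negative (`lambda2 < gate_frac * lambda1` with `gate_frac = 0.4`).
   Between two nearby parallel filaments the midline is a saddle
   (`lambda2` near zero), so the gate severs blur bridges that would
   otherwise merge neighbours into one component. Components use plain
   26-connectivity — a wider reach would re-bridge exactly those cuts.
3. **Path tracing**: each component's backbone is the geodesic diameter
   path (double Dijkstra sweep over the voxel adjacency graph with
   physical edge lengths). Components can contain junctions where
   filaments cross; the residual voxels beyond an anisotropic clearance
   of the traced path (0.75 µm axial, 0.45 µm lateral — the mask is
   thicker along z) are re-traced recursively, and fragment ends that
   continue each other across a junction (close, anti-parallel end
   tangents) are stitched back together.
4. **Spine re-centering**: a geodesic trace may cut diagonally across the
   blur envelope (worst for short filaments, where the corner-to-corner
   diagonal materially inflates the length). Each path sample is
   replaced by the intensity centroid of its perpendicular disc
   (radius 0.55 µm), twice, pulling the trace onto the filament axis.
5. **End refinement and filtering**: both ends are trimmed or extended to
   the half-maximum crossing of the intensity profile along the local
   tangent; paths shorter than `min_length_um = 2` µm (expanded) are
   discarded, excluding puncta elongated by the PSF. The base is the
   endpoint nearer the bright voxels of the spot channel — a rule that
   survives cilia whose far tip bends back over the knob, where the
   distance to a single cloud centroid does not.

## Association

`associate()` solves a one-to-one minimum-distance assignment between
cilium bases and spots, restricted to pairs within
`capture_radius_um = 0.5` µm (expanded; the geometric definition of
"associated with a cilium", configurable because it is a modelling
choice, not a measured constant). The solver is a dense O(n³) Hungarian
implementation written for this package — no linear-assignment solver is
available among the supported dependencies — and is tested against
brute-force enumeration on all instances up to 6×6. Maximizing the number
of in-radius matches takes precedence over total distance (forbidden
pairs carry an effectively infinite cost).

# Grouping and lag

`cluster_groups()` is single linkage at `linkage_cutoff_um = 2` µm
(expanded ≈ 0.5 µm biological): two centrioles share a group when a chain
of pairwise distances at or below the cutoff connects them. The default
separates intra-group spacing (~1–2 µm expanded) from the several-µm
gaps between groups in a dendrite, and is a first-class parameter because
the biological literature gives no numeric criterion. Clusters need
`min_group_size = 2` members; smaller clusters are singletons with group
id −1, reported separately because single centrioles travelling between
groups are a real observation, not noise. `stats::hclust` provides the
linkage; the partition is property-tested against a union-find oracle
and refines monotonically as the cutoff decreases.

`measure_lag()` projects a group centroid orthogonally onto a dendrite
path polyline (tolerance 2 µm) and returns the arc distance to the
path's apical endpoint. It is invariant under rigid motions applied to
path and centroid together.

# Tracking

Linking is greedy closest-pair-first within `gating_radius_um = 3` µm
per frame transition, with gaps up to `max_gap = 2` frames bridged.
Greedy linking was chosen over global assignment for transparency — at
the observed speeds (≤ 0.2 µm/min, frames minutes apart) displacements
are far smaller than inter-group spacing, and the recovery tests bound
its error on synthetic data. If a fiducial track is named, its
interpolated per-frame position is subtracted from every track before
rates are computed, cancelling common drift exactly; a fiducial missing
from more than half the frames is an error.

The net rate is `(last − first corrected apical position) / elapsed`,
deliberately *not* a regression over all frames, so that intermittent
pauses do not bias the net figure; the least-squares rate is reported in
a clearly labelled secondary column for robustness. Direction is apical
or basal when the net displacement exceeds
`displacement_threshold_um = 0.5` µm (about ten times the per-frame
jitter scale), else "none".

`build_kymograph()` samples the side-view projection along a polyline by
bilinear interpolation, averaging across `width_um` perpendicular to it,
one row per frame; `kymograph_ridge_slope()` regresses the per-row
maximum position on time, and the recovery tests require the slope to
match the configured velocity within 10 % at 0.05 µm jitter.

# Compartments

`classify_compartment()` interpolates the three landmark polylines
(apical surface, lower boundary of the sustentacular nuclei, basal
lamina) at the point's lateral coordinate. The subapical compartment is
the closed band `[apical surface, sustentacular boundary]`; the
middle/basal band is `(sustentacular boundary, basal lamina]`. A point
exactly on a boundary belongs to the more apical compartment — an
explicit tie-break, since scoring conventions never state one. Counts are
normalized per 100 µm of basal-lamina arc length so that differently
sized explants are comparable; `linear_density()` applies the same
normalization to EdU-positive nuclei. `read_count_table()` accepts
externally scored CSVs (per-animal, per-compartment counts with scored
lengths) so that archived scoring spreadsheets feed the same test path.

# The paired permutation test

Explants vary strongly between animals, so drug effects are judged within
matched pairs (two halves of the same septum). The statistic is the mean
paired difference of normalized counts, drug − control — the simplest
paired statistic; its name is recorded in the result object for
provenance. The null distribution flips each pair's labels
independently. With `2^n_pairs ≤ n_resamples` every sign pattern is
enumerated and the p-value is the exact tail proportion (a multiple of
`1/2^n_pairs`); otherwise `n_resamples` random patterns are drawn and the
add-one estimate `(1 + hits) / (1 + B)` is used, which can never return
zero. Ties are counted as extreme via a `1e-12` tolerance. Two-sided by
`|T|` is the default; one-sided alternatives are available by flag.

The pairing key is an argument (`pair_on`), not a constant: pairs can be
formed per animal × timepoint × compartment or on any subset, and the
choice matters. Pooling compartments when only one carries an effect
halves the effective signal — with 8 pooled pairs of which 4 carry the
effect, roughly the sign patterns of the 4 null pairs tie or beat the
observed statistic, and the attainable p rarely clears 0.05. The power
property in the test suite therefore evaluates an 8-pair design on the
stratum carrying the effect (4 animals × 2 timepoints, subapical),
where the exact test is essentially always significant at a 2.5-fold
enrichment at the observed density scale; the type-I-error property uses
the same 8-pair layout under the null and must reject at a rate inside
[0.03, 0.07] at α = 0.05.

# Numerical choices and degenerate inputs

* Separable Gaussian filtering is implemented as banded matrix products
  (BLAS does the work); second derivatives are finite differences on the
  smoothed volume, with replicated edges — hence the explicit border
  exclusion in the spot detector.
* `summary_stats()` uses the n−1 standard deviation; SEM = SD/√n. A
  single observation yields `NA` SD/SEM with an explicit flag rather
  than a silent zero. Densities and traversal times are rounded to two
  decimals only for reporting; CSV outputs keep full precision.
* Generators take mandatory seeds and save/restore the global RNG state,
  so library code never perturbs a session's randomness; the pipeline
  derives per-stage seeds from one global seed by hashing stage names, so
  stages can be rerun in isolation.
* Degenerate inputs fail loudly: empty label sets, non-positive lengths
  and cutoffs, crossing annotation polylines (reported with the violated
  lateral interval), missing pair members, trajectories that outrun the
  rendered volume (warned), and knobs too crowded for the requested
  minimum separation (error after bounded retries).

# Problem sizes

The recovery properties run at the full study conditions — 36 centrioles
and 31 cilia per scene at SNR 10 — on 50 scenes for the detection
property and on cohorts of 22 tracks, 12 lags, and 1000/300 simulated
tables for the tracking and statistical properties; unit tests use
smaller knobs (8–12 centrioles) so the whole suite stays fast on a single
CPU. These sizes are the package's own validation design and are recorded
alongside every reported value by `scripts/acceptance.R`.

# Known limitations

* The cilium tracer resolves filaments down to the separation the
  anisotropic PSF permits; filaments that run parallel within roughly a
  micrometre for most of their length fuse irrecoverably, which is a
  physical limit, not an algorithmic one. The association fraction on
  crowded knobs is accordingly recovered to within a few percentage
  points, not exactly.
* Dendrite paths and epithelial landmark polylines are inputs
  (annotation or synthetic truth); automatic dendrite tracing and
  landmark segmentation are out of scope.
* The tracker follows groups, not individual centrioles within a moving
  cluster.
* Proprietary microscope formats are not read; convert to TIFF upstream.
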