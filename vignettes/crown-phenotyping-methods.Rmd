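---
title: "Methods: 3D phenotyping of cassava root crowns from photogrammetry meshes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D phenotyping of cassava root crowns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crc3d)
```

## The problem

A cassava root crown (CRC) is the whole cluster of storage roots attached to
the stem base of one plant. Breeding programmes select on crown size and
architecture, but field phenotyping has historically been limited to weight,
a root count and a visual impression, because excavated crowns deteriorate
within days and every measurement is manual. Close-range photogrammetry
changes this: an excavated crown laid on a background sheet next to a cuboid
reference box, photographed from 25-40 positions, yields a textured triangle
mesh of the whole organ. `crc3d` takes over from there — it consumes the
exported mesh and produces a reproducible trait table.

The pipeline mirrors the manual 3D-modelling workflow it automates:

1. noise clearing (`remove_noise_components`) and watertight repair
   (`close_holes`),
2. scale calibration against the reference box (`calibrate_scale`),
3. orientation into a canonical frame, stem up (`orient_crown`), and stem
   removal at the soil line (`remove_stem`),
4. whole-crown traits, with the crown volume measured by the split-half
   protocol (`crown_volume_split`, `compute_all_traits`),
5. digital dissection into individual storage roots (`segment_roots`) with
   per-root length, basal angle and diameter,
6. trial statistics: validation regression, trait correlations, PCA,
   augmented-RCBD adjusted means and broad-sense heritability.

Every stage is testable without field data through the synthetic-crown
generator (`generate_crown`), whose ground truth comes from a voxel oracle.

## Mesh geometry

A `triangle_mesh` stores vertices (cm once calibrated), 1-based face index
triples with consistent outward orientation, and a `unit_scale`. Volume is
the divergence-theorem sum of signed tetrahedra; for a union of disjoint
closed components this counts each enclosing surface once, which is why the
volume oracle and the remesher, not `signed_volume`, are used on the
generator's overlapping part assemblies. Watertightness is the strict
edge-manifold test: every undirected edge on exactly two faces.

`plane_cut` clips triangles exactly (crossing points computed once per mesh
edge, so adjacent triangles chain without tolerance matching), then caps
each cross-section boundary loop by ear clipping in the cut plane. Loop
orientation is inherited from the cut triangles, so annular sections cap
with correct signs and volume is conserved to round-off.

## The voxel oracle

Ground truth volume for synthetic crowns is `voxel_volume`: cast one ray
per voxel column, accumulate signed crossings (a face counts +1 or -1 by
the sign of its normal along the ray), and count voxel centres whose
winding is at least one. At the default 1 mm grid this stands in for the
water-displacement measurements used to validate the original workflow.
Halving the voxel size changes the oracle by under 1% on the standard
suite, which the test suite asserts. The grid origin is offset by irrational
fractions of the cell size so rays never graze axis-aligned edges.

## Watertight repair (`close_holes`)

The repair emulates a smooth volumetric remesh at octree depth `d`
(default 8, cell size = bounding-box diagonal / 2^d):

* **Occupancy.** Signed ray-crossing parity along each of the three grid
  axes, combined by majority vote. For a closed surface all three agree
  exactly; across an open defect (the photographic blind area) the two
  directions that still see intact surface outvote the broken one. A flat
  open sheet encloses nothing under the vote, giving the documented
  "no enclosed volume" error.
* **Closing.** A two-cell morphological closing (dilate, erode) is applied
  to the occupancy. Smooth remeshers cannot represent gaps narrower than
  their cell size; the closing reproduces that amalgamation of narrow
  inter-root spaces. This matters scientifically: amalgamation is the
  documented source of the intact-crown volume inflation that the
  split-half protocol exists to reduce. On convex or well-separated
  geometry the closing is a no-op (an already-closed icosphere changes
  volume by about 0.001%, far inside the 2% contract).
* **Extraction and smoothing.** The boundary between occupied and empty
  cells is emitted as quads (after resolving diagonal "hinge" cells that
  would break edge-manifoldness) and relaxed by a few Taubin passes, which
  smooth the staircase while approximately preserving volume.

## The split-half volume protocol

`crown_volume_split` cuts the crown by the vertical plane that contains
the stem axis and is normal to the support-side direction (default -y,
the side the crown rested on during photography), re-closes each half
independently, and sums the halves. For a watertight mesh the cut is the
exact `plane_cut` and the protocol agrees with the direct volume to 0.5%.
For a defective mesh each half is rebuilt volumetrically; two
implementation details matter:

* the cut cross-section is capped exactly before remeshing, and the
  remesh lattice is snapped onto the cut plane, so the flat cut costs no
  quantisation error;
* each half is rasterised on its own, smaller grid, so the amalgamation
  scale shrinks and the crowded hub region is exposed exactly at the cut.

On the benchmark cohort (`simulate_defect_cohort`: twenty crowns of 9-14
storage roots at unconstrained azimuths — colliding, crowding roots as in
field-grown crowns — with a 1.5 cm blind-area defect) the intact-mesh
estimate is systematically inflated and the split-half estimate beats it
on the large majority of crowns, reproducing the qualitative field
finding that motivated the protocol. The defect depth is a benchmark
parameter: no quantitative model of blind-area size exists, so 1.5 cm
(roughly one root radius) was fixed once as a plausible contact band.

## Traits

* **Crown diameter** is the maximum pairwise distance among vertices
  projected to the soil plane — a top-view caliper, so a deep vertical
  root cannot inflate it.
* **Cylinder soil volume** is pi r^2 h of the minimal *vertical* cylinder
  around the stem axis (r = maximal radial vertex distance, h = vertical
  extent). The cylinder is deliberately constrained to the stem axis
  because the trait models occupied soil space under the plant, not a
  free minimal enclosure.
* **Compactness** = 100 x crown volume / cylinder soil volume, in (0, 100].
* **Root density** = 1000 x weight[kg] / volume[cm^3], in g/cm^3.
* **Surface-to-volume ratio** = area / volume (1/cm); low values mean
  short or thick roots.

`compute_all_traits` aggregates these plus the dissection summaries and
records every setting in a provenance block; failed sub-analyses leave
`NA` fields listed in `$missing` rather than aborting the crown.

## Digital dissection

`segment_roots` removes every face within `hub_radius` (default 5 cm) of
the stem axis — a cylindrical clearance mirroring the manual dissection —
and treats each remaining edge-connected component above a 5 cm^3 volume
floor as one storage root, closed by capping its boundary loops. Root
measurement slices the segment perpendicular to its principal axis, then
re-slices perpendicular to the local tangent of the centroid polyline
(re-estimated over a five-section window). Sections within one tube radius
of the ends are dropped from the polyline (end caps and the oblique hub-cut
mouth skew their centroids) and the length is completed by extending the
end tangents — to the extreme vertex at the tip, and back to the hub
clearance cylinder at the base. Leading or trailing polyline steps that
disagree with their local run by more than 7 degrees are discarded;
genuine root curvature at 1 cm steps stays well below that threshold.

The **basal angle** is measured between the first quarter of the
centerline and the horizontal soil plane (0 = horizontal, 90 = straight
down). The source workflow never defines its angle datum; the horizontal
convention is used here because the crown-level summary averages the
*three lowest* angles, which under this datum selects the shallowest,
widest-spreading roots. **Maximum diameter** is the largest
equivalent-circle diameter 2 sqrt(area/pi) over cross-sections. A segment
whose sections repeatedly contain two or more disjoint loops is flagged
`fused` (two roots merged into one surface, which only happens after
volumetric remeshing — raw generator components stay distinct).

## The synthetic-crown generator

`generate_crown` builds a crown as a union of closed parts: a hub sphere
just below the soil line, one tapered tube per storage root (curvature
bends the run downward with arc length), and a stem cylinder. Defaults
emulate harvest-stage field crowns: root lengths 15-35 cm, basal radii
2.5-4.5 cm (diameters 5-9 cm), tips 0.5-1.2 cm, inclinations 15-55 degrees
below horizontal, azimuths jittered on a uniform circle (or unconstrained,
colliding, when a crowded cohort is requested). Everything except the stem
sits below z = 0, so stem removal at the soil line removes exactly the
stem cylinder. The ledger records the voxel-oracle volume (parts overlap
at the hub, so analytic sums would be wrong), per-root lengths and angles
both total and *outside the hub clearance* (what dissection can actually
see), the enclosing-cylinder volume and compactness. The surface-area
entry is the triangle-area sum of the parts and slightly over-counts
hub-buried patches; it is a consistency reference, not a union area.

Defect models: `inject_blind_area_defect` removes faces within a band of
the support plane (an open hole where the crown met the background sheet);
`jitter_vertices` adds seeded Gaussian noise at reconstruction scale;
`add_floating_noise` scatters small floaters for the noise-clearing stage.

What the generator does **not** emulate: real photogrammetry noise is
spatially correlated and texture-dependent, real blind areas are ragged
low-quality surface rather than cleanly missing faces, fibrous roots are
absent, and root cross-sections are perfectly circular. Passing tests
therefore demonstrate correctness of the measurement machinery under
controlled geometry, not end-to-end accuracy on field reconstructions.

## Orientation

Crowns are photographed lying on their side, so `orient_crown` must find
the stem. The implemented search follows the crown's anatomy: storage
roots angle downward, so the mean unit offset of vertices from the
centroid points toward the stem side. From that starting direction the
algorithm repeatedly takes the topmost laterally-central vertex as the
stem tip, then scans the radius profile down from the tip; the stub ends
where the radius jumps past 1.5 x the tip-median radius (the hub or the
first root shoulder), and the stub's first principal component is the
axis. A slab-and-balance search over principal-axis candidates serves as
fallback, and `stem_axis` can be supplied manually for irregular crowns.
Recovery is within 5 degrees on randomly rotated synthetic crowns; the
junction height (where the horizontal spread jumps above 2.5 x the stem
radius) sets z = 0.

## Scale calibration

The reference box lies at arbitrary pose, so calibration uses its minimal
oriented bounding box, not axis-aligned extents: candidate box normals are
the mesh's own area-weighted face normals plus the vertex principal axes;
for each candidate a rotating-calipers minimum-area rectangle completes
the box; the smallest-volume candidate wins. For cuboid meshes this is
exact. The operator chooses which sorted extent corresponds to the known
dimension (`longest` by default — the workflow's 34 cm box height); the
whole scene is then scaled so that extent matches, after which
coordinates are in cm and `unit_scale` is 1.

## Trial statistics

* `validation_regression` keeps correlation and accuracy separate: R^2 is
  the squared Pearson correlation, while accuracy is the mean and maximum
  absolute percentage error against the reference values. "Error rate" is
  not a standard quantity; this package reports both and gates on the
  mean.
* `correlation_matrix` reports Pearson r with two-sided P from
  t = r sqrt(df/(1-r^2)), df = n-2, and stars at 0.05 / 0.01 / 0.001.
  P values are raw by default (matching the usual trait-correlation
  charts); `bonferroni = TRUE` adjusts across pairs.
* `pca_traits` decomposes the correlation matrix (eigenvalues sum to the
  number of variables), reports loadings as variable-PC correlations with
  each column oriented so its largest-magnitude entry is positive, and
  flags contributors at |loading| > 0.45.
* `augmented_rcbd_adjust` is Federer's method with centred block effects:
  block effect = block mean of checks minus the grand check mean
  (summing to zero over blocks); test entries are adjusted by subtracting
  their block's effect. The ANOVA is the sequential block-then-genotype
  decomposition — its three main lines add exactly to the total sum of
  squares — with the genotype line partitioned into among-checks,
  among-tests and checks-vs-tests, and the residual coming entirely from
  check replication.
* `broad_sense_heritability` uses H^2 = s2G / (s2G + s2e) with s2e from
  the check-replication residual mean square. The genotypic variance
  subtracts the *full* error carried by an adjusted test value,
  s2e (1 + (1/c)(1 - 1/J)) for c checks and J blocks, because the block
  adjustment itself is estimated from c check plots; subtracting s2e
  alone would inflate H^2 at low heritability. Negative estimates are
  floored at zero (flagged), which leaves a small upward bias near
  H^2 = 0 — the Monte-Carlo recovery check bounds it below 0.1 at the
  field design size (9 blocks, 5 checks, 29 test lines).

## Numerical choices and degenerate inputs

* Floating comparisons on mesh predicates use 1e-9 of the model scale;
  vertices within 1e-9 are merged at load.
* `plane_cut` nudges exactly-on-plane vertices to the positive side,
  avoiding degenerate zero-length cut segments.
* Degenerate (zero-area) faces are dropped at construction.
* A sphere-like segment with fewer than two valid cross-sections raises
  an error rather than reporting a meaningless length.
* Compactness and density reject non-positive inputs; a crown volume
  exceeding its enclosing cylinder is an inconsistency error.
* Problem sizes in the shipped tests: 20-crown defect cohorts, 5-crown
  dissection suites at 0.5 cm oracle resolution, 200-replicate
  heritability recovery — sizes at which every stochastic check is stable
  under seed changes while the whole suite stays comfortably fast.

## Known limitations

* The stem-axis search assumes roots predominantly angle downward; crowns
  with strongly upturned roots need the manual override.
* Centerline lengths on roots shorter than about three tube diameters are
  unreliable (too few valid sections); such stubs are better captured by
  the volume filter.
* The minimal-OBB search is exact for boxes but heuristic for general
  shapes — adequate for reference objects, not a general OBB routine.
* Mixed-model (REML) analysis of augmented designs, spatial field-trend
  correction and multiple-testing control beyond Bonferroni are out of
  scope.
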