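---
title: "Methods and design of phenokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of phenokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

phenokit measures plant shoot phenotypes from raster images. This vignette
explains the models and procedures each module implements, the parameters
that matter and their defaults, what the synthetic-scene generator does and
does not emulate, and the numerical choices made where the methods leave
room. It states no empirical result beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

## Conventions

Pixel grids are `[row, col(, channel)]` arrays of 8-bit values. Public
coordinates are 0-based `(x, y)` = (column, row) with the origin at the
top-left, the convention of most imaging libraries. Foreground is
8-connected and background 4-connected — the standard duality, chosen so a
one-pixel-wide diagonal petiole still joins its leaf to the plant. Binary
masks hold only 0 (background) and 255 (foreground). Images are converted
to RGB channel order at read time; whatever order the file stores is
hidden from callers. Every operation can emit an annotated intermediate
image for debugging (`options(phenokit.debug = "<dir>")`); emission is off
by default because writing image files dominates runtime in batch
processing.

## Illumination normalization and smoothing

**White balance.** Each channel is scaled by `255 / max_ROI(channel)` and
clipped, so the reference region (a white standard, or the whole frame)
reaches 255 in every channel. The reference statistic is literally the
channel maximum; a `percentile` argument (default 100) lets users trade
exactness for robustness to isolated hot pixels. Because the reference
reaches 255 after one application, the operation is idempotent — applying
it twice changes nothing, which the tests assert bit-exactly.

**Median and Gaussian blur.** The median filter replaces each pixel by the
median of its odd-sized square neighborhood; the Gaussian filter convolves
with a normalized sampled Gaussian. Both replicate the border rows/columns
outward, so constant images pass through unchanged and the total intensity
of an interior impulse is conserved up to rounding. A sigma of 0 selects
the conventional kernel-size-derived default `0.3((k-1)/2 - 1) + 0.8`.

**Geometry.** `rotate_img` rotates about the image center on a fixed
canvas (no auto-expansion), because downstream grid clustering assumes a
fixed frame; vacated regions are zero-filled. Intensity images are
resampled bilinearly; masks use nearest-neighbor so they stay strictly
binary. `resize` (nearest-neighbor) and `crop_position_mask` exist to
transfer a VIS-derived plant mask onto a lower-contrast NIR frame: the
scale factors are user-measured from a reference object visible to both
cameras — the tool deliberately does not auto-calibrate, since a single
pair of factors per camera rig is stable and auditable.

## Automatic thresholding

All thresholds use the strict comparison `gray > t` for light objects and
`gray < t` for dark ones, so masks are bit-reproducible.

**Triangle (Zack).** On the 256-bin histogram, a line is drawn from the
peak bin to the last occupied bin on the object-side tail; the threshold
is the level between them whose `(level, count)` point lies farthest from
that line. Empty tail bins carry no information, so the line ends at the
last *occupied* bin rather than bin 255. The `xstep` parameter evaluates
candidate levels at that stride, shifting where the distance is computed —
a cheap way to nudge an unsatisfying threshold. The result object carries
the threshold and the histogram so the geometry can be inspected.

**Otsu.** The threshold minimizes the weighted within-class variance over
all 256 split points (equivalently, maximizes between-class variance),
computed in closed form from cumulative moments. On a flat valley between
two modes every split in the valley ties; the midpoint of the tied run is
returned, which places the threshold between the peaks instead of on the
lower mode — on a two-delta histogram the lower mode itself would
otherwise be returned, and a dark-polarity mask thresholded there would be
empty.

**Adaptive mean/Gaussian.** The per-pixel reference is the plain or
Gaussian-weighted mean of the surrounding `block_size` square. Light
objects pass where `gray > reference + offset`, dark where
`gray < reference − offset`: symmetric polarities in which a positive
offset suppresses flat-field noise (a uniform image yields an empty mask).
`block_size` has no default on purpose — it is scale-dependent and must
reflect the expected object size.

## Size markers

`report_size_marker_area` either treats the ROI itself as the marker
(`define`) or thresholds a chosen channel inside the ROI and reports the
largest detected object (`detect`). Largest-object selection tolerates
specks and small marker movement inside the ROI. The area is reported, not
consumed: dividing plant area by marker area is the caller's analysis
step, kept outside the tool so the normalization is explicit in the user's
records.

## Multi-plant detection

`cluster_contours` divides the frame into an `nrow × ncol` grid of equal
cells that act as approximate per-plant ROIs. Each contour is assigned to
the cell containing its *centroid*: fragments of one plant regroup, and a
leaf overhanging a neighboring cell does not split its plant. Cells may be
empty. `cluster_contour_split_img` emits one image per nonempty group with
all other pixels blanked, keeping the full tray canvas so every split
image shares one coordinate frame (an optional flag crops to the bounding
box instead). Labels come from a genotype names file in row-major order;
on a count mismatch the function warns, consumes the names it has, and
labels the remainder positionally (`"row_col"`) — a loud, lossless
fallback. Conservation is exact: the union of split foregrounds equals the
original foreground with no pixel duplicated, which the tests assert
pixel-for-pixel.

## Watershed organ counting

The mask's Euclidean distance map (EDM) is computed; its local maxima
become markers; flooding the negated EDM from the markers, constrained to
the mask, partitions every foreground pixel into one segment, and the
segment count estimates the organ (leaf) count. Two choices matter:

* **Peak windows are Euclidean disks** of radius `min_distance`, not
  squares. Candidate suppression is then isotropic and exactly consistent
  with the Euclidean pairwise-separation rule used when thinning peaks, so
  the method's one tunable has a single geometric meaning: no two markers
  within `min_distance` of each other.
* **Ties and plateaus.** A discrete EDM has exactly-equal values; tied
  candidates are grouped by connectivity and each plateau contributes one
  marker at the pixel nearest its centroid (topmost-leftmost on exact
  symmetry). Thinning proceeds per connected component in order of
  decreasing peak height (scan order on ties), which guarantees every
  foreground component keeps at least one marker and label maps are
  bit-reproducible. A `peak_tolerance` (default strict) can widen
  candidacy to near-flat shoulders if desired.

The distance map is computed on the raw mask; users who want pre-smoothing
can blur the mask first. The count is non-increasing in `min_distance` on
a fixed mask, asserted as a property test.

## Landmarks

**Acute regions (Type II).** Each contour position receives an angle
score: the angle at that point between chords to the points `window`
positions away on either side of the ring, computed by the law of cosines
and clamped to [0, 180]°; zero-length chords (duplicate points) score 180
so they never spawn corners. Consecutive runs below `angle_threshold` are
acute regions; runs wrap across the ring seam so a cluster spanning the
start/end is one landmark, not two; the middle element (index
`floor(n/2)`, traversal order) of each run is the landmark. `pt_val` is
the mean mask value inside the convex hull of the run *extended by one
chord arm on each side* — the extension makes a tip's hull cover solid
foreground (high `pt_val`) and an axil's hull span the concave notch
(low), which is what lets convex and concave landmarks be told apart
downstream. `window` tunes the structural scale: large windows find lobes,
small ones serrations. `acute_vertex` is the same definition evaluated
only at every `search_stride`-th contour position; stride 1 reproduces
`acute` exactly, asserted in the tests.

**Axis pseudo-landmarks (Type III).** The object's extent along the
scanned axis is divided into 20 equal-width bins (half-open on the left,
the last closed, so each column belongs to exactly one bin; a connected
object's projection is an interval, so no bin is empty). Each bin yields
its minimum extent, maximum extent, and foreground centroid: 60
semi-landmarks per axis in three 20-point roles. Objects narrower than 20
pixels along the axis are rejected rather than silently producing empty
bins.

**Rescaling and reference distances.** `scale_features` maps the object's
bounding box onto the unit square (each axis independently) and applies
the same map to the landmarks, the object centroid, and the plant-base
point, so differently sized and placed plants become comparable. The base
point — "the centroid localized to the base" — is defined here as the
centroid of the foreground in the bottom 5% of the object's row span
(configurable). `landmark_reference_pt_dist` then reports Δx, Δy,
Euclidean distance, and `atan2` angle from every landmark to both
references, with per-feature means attached. Landmark tables export as
tab-delimited `(role, x, y, pt_val)` text for external morphometrics
software; Procrustes analysis and shape PCA are deliberately out of scope.

## Naive Bayes pixel classification

Training samples are converted to HSV (full-byte scaling, hue in [0, 255])
and each class × channel receives a Gaussian kernel density estimate
(Scott's-rule bandwidth, floored at 1 for degenerate samples), evaluated
at the 256 integer bins and renormalized to sum to 1. Two-class training
pools all image/mask pairs and draws a seeded sample of 10% of the
foreground pixels plus an equal count of background pixels; the equal
counts make the uniform class prior consistent with the data. Multiclass
training uses every sample of its tab-delimited table (one class per
column, `"R,G,B"` cells).

Classification scores each pixel under each class as the sum of the three
log densities at the pixel's bins (uniform prior; densities floored at
1e-10 so a finite training sample can never hard-zero a class) and assigns
the argmax; ties go to the first class and are reported. The per-class
masks are mutually exclusive and jointly exhaustive by construction.

Treating hue as a linear variable is a known limitation: hues that wrap
around red (byte 0/255) would split their density across the ends.
Green-centered plant hues sit mid-range and are unaffected; classifying
red-magenta targets would require a circular density.

## Pipeline runner and results store

Filename metadata is parsed against a user template built from a
restricted vocabulary (`plantbarcode`, `timestamp`, `camera`, …,
extensible via the template's `extra` argument); a field-count or
timestamp mismatch is a warning-plus-skip, never an abort. Each image is
processed independently — one process per task, no shared mutable state —
and writes one JSON temp file; only after all images finish does a single
aggregator process touch the SQLite file. That serialization is what makes
database content provably invariant to worker count, and it is asserted by
comparing full table dumps for 1 versus 4 workers. A failing image becomes
one `failures` row; the run continues.

The store is a deliberately minimal three-table schema — `runinfo` (one
row per aggregation), `metadata` (one row per image, one column per
vocabulary term; unknown terms stay empty, so new camera systems need no
new tables), and `features` (long format: image, trait, value) — plus the
`failures` log. Export produces a wide, R-ready TSV with deterministic
column order and per-element number formatting, so re-exporting an
unchanged database is byte-identical.

## The synthetic-scene generator

`generate_scene` exists so every module can be tested against exact ground
truth without external images. It emulates: a rosette plant (spatulate
blades — a trapezoidal taper into a rounded elliptical cap — radiating
from a thin central ring), single-pot and tray (grid) layouts with
positional and angular jitter, per-class HSV Gaussian pixel color with
stated means and spread (the noise model every classifier recovery test
assumes), flat or horizontally graded backgrounds, and an optional white
disk size marker. All randomness flows through one seed; a fixed spec is
byte-reproducible, and the caller's RNG state is untouched.

The blade-on-ring geometry is a design choice with a specific purpose:
the open center means the distance map has no central peak, and the
monotone ridge of a tapered blade has a single compact maximum, so the
number of distance-map-separable lobes equals the leaf count *by
construction*. A junction of straight petioles at a point — the obvious
alternative — creates a central distance peak that cannot be suppressed at
high leaf counts without also suppressing neighboring leaf peaks. Blade
width narrows with leaf count by default (18/14/12/10 px full width for
≤5/≤8/≤10/≤12 leaves), the way crowded rosettes grow narrower leaves;
`scene_spec` rejects geometry whose blades could collide under worst-case
jitter ("separability"), and this construction was validated once against
the watershed module across leaf counts 3–12 and many seeds when the
defaults were frozen.

What the generator does **not** emulate — and therefore what passing tests
do not show about real images: occlusion and leaf overlap, perspective and
lens distortion, specular highlights and shadows, soil texture
heterogeneity, and the color drift of real lighting. Results on synthetic
scenes bound the method's behavior under its stated assumptions; they do
not certify field performance.

## Problem sizes and tolerances

The test suite and acceptance script use 160×160 single-plant scenes,
240×360 trays, 50-rosette watershed batches (leaf counts 3–12), 100
random histograms for threshold-oracle equivalence, 200 images of 120×120
for the classifier-versus-threshold area correlation, and 20-image
pipeline runs — sizes chosen so the full suite exercises every code path
at realistic plant scales while remaining quick to run routinely.
Geometric assertions use rasterization tolerances (2% on areas and
unit-frame coordinates, 2° on angles); threshold and labeling assertions
are exact.

## Known limitations

* Distance-map watershed undercounts heavily overlapped canopies; it is
  designed for plants whose organs are locally thick and joined by thin
  necks.
* Hue is linear, not circular (see above).
* Grid clustering assumes an approximately axis-aligned arrangement; skewed
  trays should be straightened with `rotate_img`/`shift_img` first.
  Arrangement-independent clustering is out of scope.
* VIS→NIR transfer assumes the pot position shifts consistently between
  cameras; there is no image registration.
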