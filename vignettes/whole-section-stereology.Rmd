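---
title: "Whole-section stereology of pancreatic islets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-section stereology of pancreatic islets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletscope)
```

## The measurement model

The quantity of interest is endocrine cell mass expressed as an area
fraction: the pixels positive for any hormone channel, divided by the
pancreas tissue area, times 100. Two modeling commitments follow from this
definition and drive the whole design.

First, **normalization dominates accuracy**. Large vessels, ducts,
peripancreatic fat and empty inter-lobe space can occupy a substantial part
of a section; leaving them inside the denominator deflates the estimate,
excluding tissue around islets inflates it. The tissue mask is therefore the
manually drawn pancreas outline minus every exclusion polygon whose
rasterized area exceeds a configurable fraction of the outline area
(`exclusion_min_fraction`, default 0.0005, i.e. the "more than 0.05% of the
section" rule with a strictly-greater comparison). Exclusions below the
cutoff are deliberately ignored: tiny holes are part of normal tissue
texture, and removing them would make the denominator operator-dependent.

Second, **whole-section analysis is the reference estimator**. Every
simulation in the package (panel selection, point counting, block schemes)
is an estimator of the same area fraction, and each is compared to the
whole-section value computed on identical masks. The selection-curve
invariant — at `k = all panels` the curve equals the whole-section estimate
bit-exactly — is the formal statement of that reference role, and is tested.

## Pipeline stages and their parameters

**Background subtraction** (`subtract_background`). The smooth background of
each channel is estimated as the grayscale morphological opening with a disc
of `background_radius` pixels (default 50 px) and subtracted; output is
clamped at 0. The radius must exceed the largest genuine structure; 50 px at
~1 um/px is several cell diameters above the 7.5 um cell radius. The
operation is applied to the full raster with no regional selection. EBImage
performs the opening; because its grayscale morphology clips intensities to
[0, 1], the channel is affinely rescaled into [0, 1] and back, which is
exact since grayscale opening is affine-equivariant.

**Thresholding** (`auto_threshold`, `binarize`). Manual per-channel
thresholds are the primary mode, mirroring practice where an operator sets
and saves threshold values per channel; `auto_threshold` provides Otsu's
method as the automatic option. Two numerical choices are explicit because
no convention is universal:

* The comparison is inclusive (`channel >= threshold`).
* `auto_threshold` is an exact exhaustive search: every cut between
  histogram bins (default 256 levels over the observed range) is scored by
  the between-class variance `w1 w2 (mu1 - mu2)^2`; ties average the tied
  bin centers. When the optimal threshold coincides with an observed gray
  value, it is nudged into the empty gap above, so that the inclusive
  comparison reproduces the optimal partition exactly. For integer data with
  one level per gray value the search is provably exact, which the test
  suite exploits by comparing against an independent brute-force scan over
  all cuts of the raw values.

Otsu assumes a bimodal histogram. On channels where the positive class is a
tiny fraction of pixels (a sparse hormone in a large section), the automatic
threshold can latch onto structure within the background; manual thresholds
are recommended there, and the ground-truth recovery tests use the manual
mode at half the rendered signal level for exactly this reason.

**Islet segmentation** (`segment_islets`). How individual endocrine cells
group into "one islet" is under-determined by the image alone; the package's
rule is: morphological closing with a disc of `close_radius_um` (default
5 um) to bridge intra-islet gaps, hole filling to annex unstained
intra-islet pixels (capillaries), then 8-connected components. Each
component with filled area at least `min_area_um2` becomes one islet record.
The default `min_area_um2 = 0` keeps single endocrine cells, so records span
singlets to large islets; on noisy data a small floor (a fraction of the
178 um^2 single-cell area, e.g. 20 um^2) removes speckle components without
touching real singlets. Components are numbered 1..N in raster-scan order of
their first pixel — deterministic, no randomness anywhere in the pipeline.
Both areas are reported per islet: `endocrine_area_um2` (stained pixels) and
`total_islet_area_um2` (filled structure); conservation of the former
against the composite mask is exact and tested. Size analytics default to
the filled area, configurable.

**Shape metrics** (`islet_metrics`). The perimeter is the length of the
component's traced boundary polygon (marching squares at level 0.5) after
Douglas-Peucker simplification with a 1 px tolerance. The simplification
step is load-bearing: the raw staircase polygon overestimates a smooth
contour's length by ~5-10%, which would cap circularity of a perfect disk
near 0.9. With the 1 px tolerance, rasterized disks of radius 10/30/100 px
give circularities rising monotonically toward 1 (within 2% at r = 100)
while a rasterized square stays within 3% of the exact pi/4 and elongated
bars keep their low values — the three regimes that anchor the estimator.
Circularity is clipped at 1, since rasterization can push it slightly above.
The Feret diameter is the maximum pairwise distance between boundary pixel
centers plus one pixel for pixel extent, computed by convex-hull reduction
and verified against the O(n^2) brute force.

**Nucleus segmentation and cell typing** (`segment_nuclei`,
`classify_nuclei`). Nuclei come from a distance-transform watershed: seeds
are local maxima of the Euclidean distance transform with a minimum
separation of `min_separation_um` (default 4.9 um = 0.7 x a typical 7 um
nucleus diameter; plateau maxima are merged, residual close seeds fused),
and seeded region growing assigns every foreground pixel to exactly one
nucleus. Each nucleus is typed by the perinuclear ring rule: the nucleus
region is expanded by `ring_width_px` (default 1 px, ~1 um) and the hormone
with the strictly largest positive-pixel count in the ring wins. The ring
excludes all nucleus bodies, not just the focal one, so a neighbour's
nucleus never contributes votes. All-zero votes give `"unclassified"` — the
correct outcome for exocrine and endothelial nuclei, which stay in the
table. Exact vote ties are resolved by a configured priority order (default:
channel order) and flagged, so ties can be audited rather than silently
broken.

**Stereology** (`make_grid`, `point_count_estimate`, `make_panels`,
`selection_curve`, `block_selection_estimates`, `largest_n_ratios`). The
point-counting estimator reports `100 * positive / total vertices`, rounded
half-up to two decimals alongside the exact value. Panels default to
868 x 662 um (a typical 10x field); only relative selection behavior
matters, and ragged edge panels are kept so every pixel lies in exactly one
panel. Panel percent normalizes to tissue-within-panel, consistent with the
package's normalization doctrine. The five block-selection schemes — all
blocks (truth), single block, one block per region, one region only, k
random blocks — are this package's concrete reading of "every possible
selection" over a head/body/tail organ; each is exposed individually so
users can redefine the set. Random-k draws are seeded and replicated
(default 5).

**Analytics** (`log_size_histogram`, `shape_scatter`). Islet sizes are
binned on a log10 scale of cell-equivalents (area / 178 um^2 by default)
with `bin_width = 0.25` log units: fine bins where small islets are
plentiful, wide bins where large islets are rare. Composition fractions are
averaged per islet (each islet is one sample, with SEM across islets), not
pooled over cells; pooled counts remain available from the table. The 3-D
size/shape scatter standardizes each axis (z-score) and scores density as
the inverse mean distance to the k nearest neighbours (default 10) —
bandwidth-free and directly checkable against brute-force kNN.

## The synthetic generator

`generate_section` renders sections that exercise every stage with known
truth: log-normal islet cell counts (median 8 cells, log-sd 1.2 by default,
spanning singlets to hundreds at the default 2000 x 2000 um frame), cells as
7.53 um cytoplasm discs (the 178 um^2 nominal cell) packed hexagonally with
concentric 3.2 um nuclei, composition 0.8/0.15/0.05 at the median size with
a +0.08/decade alpha-fraction slope emulating the size-dependent
architecture of human islets, uniform or clustered islet placement, a linear
background gradient plus Gaussian noise (defaults 20 and 5 on a signal of
200, i.e. recovery is tested up to a noise sd of 10% of signal), scattered
hormone-negative exocrine nuclei, and signal-free exclusion discs large
enough to trigger the exclusion rule. All draws flow from one seed;
generation is bit-reproducible and the noise-free signal masks are part of
the ground truth, so at zero noise thresholding recovers them exactly.

What the generator does **not** emulate — and hence what passing tests do
not certify on real data: point-spread blur and chromatic aberration,
stitching seams between optical panels, autofluorescence texture of exocrine
tissue, irregular (non-disc) cell and islet shapes, partial-volume effects
at 5 um section thickness, and staining gradients that correlate with
structure. Parameter-recovery results on synthetic sections bound algorithmic
error, not immunohistochemical variability.

Two light-weight generators support the sampling simulations without
rendering images: `generate_islet_population` (the statistical layer alone,
for analytics at large N) and `generate_organ_blocks` (per-block areas with
head : body : tail mean densities of roughly 1 : 1 : 2 and log-normal
block-to-block variation).

## Problem sizes and numerical conventions

The test suite validates on 900 x 900 to 2000 x 2000 px sections at
1 um/px with 14-60 islets — one of these runs in seconds while exhibiting
every phenomenon of interest (singlets, large islets, exclusions, exocrine
nuclei, 10% noise). Coordinates are 0-based pixel indices, origin top-left,
x = column, y = row; a pixel belongs to a polygon when its center is inside
(even-odd rule); micrometers are pixels times `pixel_size`. Integer images
round-trip bit-exactly through 16-bit TIFF; GeoJSON is the canonical contour
format (text, diffable), with ImageJ `.roi` polygons read and written for
compatibility. Rounding of reported percentages is half-up (half away from
zero), stated explicitly because R's `round()` rounds half to even.

## Known limitations

* Otsu thresholds are unreliable for channels with very sparse signal (see
  above); use manual thresholds for rare hormones such as PP.
* The perimeter estimator's 1 px simplification erases genuine boundary
  detail below ~1 px; circularity of structures only a few pixels across is
  dominated by rasterization.
* Cell counts rely on nuclei lying inside their cell's cytoplasm; cytoplasm
  overlap beyond ~10% of the cell diameter begins to contaminate perinuclear
  rings, and intensity-weighted (soft) classification is out of scope.
* Islet grouping via a fixed closing radius is a convention: structures
  separated by less than twice the radius merge. The radius is configurable
  and recovery is only count-exact when islet gaps exceed that bound.
* The package analyzes single 2-D sections; serial-section reconstruction
  and islet tracking are out of scope.
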