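---
title: "Methods: segmenting and measuring root systems in soil μCT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmenting and measuring root systems in soil μCT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rootct)
```

This vignette explains the models and numerical choices behind `rootct`,
in the spirit of a methods section: what each stage assumes, which
parameters matter and why their defaults are what they are, what the
synthetic phantom does and does not emulate, and where the design was
genuinely open.

## Conventions

Volumes are numeric 3D arrays indexed `(z, y, x)`, `z` being depth with
slice 1 at the top of the column. Voxels are isotropic with a side length
in μm; anisotropic voxels are not supported (the imaging protocols this
pipeline targets reconstruct isotropically). Lengths are reported in cm,
root length density (RLD) in cm·cm⁻³, depths in mm; all conversions are
centralized in the reporting functions.

## Grey normalization and stitching

Sequential scans of one column assign systematically offset grey values
("drift") due to subtle compositional differences. `align_peaks()` models
this drift as purely additive: it locates the dominant histogram peak —
the soil peak, in soil columns — and shifts the whole volume so the peak
lands on a user-chosen reference grey. A shift is the minimal transform
consistent with the assumption that the grey-value *variance* is stable
between scans; when that assumption fails (e.g. abrupt density changes
between soil horizons) a gain correction or histogram equalization would
be needed, and is deliberately out of scope.

Peak detection smooths the counts with a centered moving average
(default width 5 bins; partial windows at the array ends) and takes the
highest interior local maximum inside the search window, breaking ties
toward the lower grey value — deterministic by construction. Histograms
default to 1024 bins over the data range, appropriate for full-size scans
with millions of voxels; for small volumes the bin count should be reduced
so the peak bin stays well populated (the package's own tests use 256 bins
on ~30k-voxel test columns for exactly this reason), since the mode
estimate jitters by roughly a bin when bins hold few counts.

`stitch()` assumes the scanner repositions the column axially between
scans with no lateral shift or rotation, so duplicated slices are
*identical* up to noise and drift. For every candidate overlap `k` it
scores the mean per-slice Pearson correlation between the last `k` slices
of the upper scan and the first `k` of the lower one, and keeps the best
`k` if its similarity clears `min_similarity` (default 0.9); otherwise it
raises an explicit "no overlap detected" error rather than concatenating
silently. The upper scan's slices are kept in the overlap — with aligned
greys the choice is immaterial up to noise, but it is fixed and
documented.

## Segmentation

The stage order is fixed: upsample ×2 → Sobel gradient → PVE mask →
bilevel threshold → 3D median → optional erosion → seeded extraction →
re-bin. The partial-volume mask is computed on the *upsampled* grey
volume, before any thresholding.

**Upsampling.** Each axis is doubled; even output indices carry the
original samples, odd ones linear midpoints (the final midpoint
replicates the last sample). Constant volumes stay constant, and each
root's diameter doubles in voxel units, which is what later protects fine
roots from the median filter and erosion. The voxel side length is
halved, and seed coordinates given at original resolution map to
`2s − 1`.

**PVE masking.** Air:soil interfaces produce the steepest grey gradients
in a soil column; root:soil and air:root interfaces are much subtler
because root tissue sits close to soil in attenuation. A per-slice Sobel
magnitude (`sqrt(Gx² + Gy²)`, edge replication at borders) followed by an
isodata threshold on the gradient distribution therefore removes the
air:soil PVE voxels while leaving root boundaries intact. The isodata
threshold iterates `T ← (mean(values ≤ T) + mean(values > T))/2` from the
midrange until the update falls below 0.5 grey levels; for volumes above
10⁶ voxels the means are accumulated on a 0.1-grey-wide grid, which keeps
every pass O(bins) while remaining far inside the convergence tolerance.
An all-constant gradient (noise-free synthetic input) yields an empty
mask by convention rather than an error.

**Bilevel threshold.** The root grey range `[lo, hi]` is inclusive on
both bounds (the convention is documented because off-by-one at the
bounds is a classic source of irreproducibility). A practical way to set
it, used throughout the package's own experiments: place it symmetrically
around the root phase grey with a half-width of half the root–soil
contrast, which accepts partial-volume voxels that are at least half root.

**Median and erosion.** The 3×3×3 median on binary data is implemented
as a 27-neighborhood majority vote (mathematically identical), with edge
replication. Erosion uses a diameter-3 structuring element; "diameter 3"
is read as the 6-face-neighbor cross (a full 3×3×3 cube has diameter
greater than 3 along its diagonals), with the cube available as an
option. Outside the array counts as background for erosion, so border
voxels erode. Erosion is off by default: it is worthwhile only when
fine connected pore networks must be cut away, and every iteration costs
the finest root fraction.

**Extraction.** Region growing on an already-binary volume reduces to
pure connectivity. 26-connectivity is the default because thin oblique
roots frequently connect only through voxel corners; 6 and 18 are
available. A background seed raises an error that reports the nearest
foreground voxel, since a fat-fingered seed is the most common user
error. The final 2×2×2 max re-bin marks a block foreground if any of its
voxels is, guaranteeing the upsampled structure survives the return to
the original resolution.

`run_pipeline()` reports per-stage voxel counts, the isodata threshold,
alignment shifts and the stitch overlap, and flags the run when the
extracted component is below a configurable fraction (default 5%) of the
pre-extraction foreground — the signature of a seed placed on a stray
pore rather than the root system.

## Skeletonization and metrics

Thinning peels border voxels from the six axis directions in turn,
deleting only *simple* points — voxels whose removal provably preserves
local 26/6 digital topology (one 26-component of foreground in the
neighborhood, one 6-component of adjacent background) — and never
endpoint voxels (a single skeleton neighbor). Deletions are re-checked
sequentially, so connectivity of every component is preserved exactly.

Iterative thinning retracts the skeleton by roughly one radius at blunt
root ends. Each resulting tip is therefore extended along its local
branch direction (estimated from up to 4 path steps behind the tip),
marching in sub-voxel increments while still inside the original
foreground. The extension is capped by the local root radius (measured at
the tip) so a spurious tip on a rough surface cannot run far through the
root interior; a genuine end tip regains exactly the retracted length.

Skeleton voxels are classified by 26-neighbor count: 1 = tip, 2 = slab,
≥3 = junction. Junction voxels that touch each other form one *branching
site* (junction cluster) for branching-density purposes; the handling of
neighbor counts above 3 — common in thinned data, rare in idealized
drawings — is subsumed by the same rule. Isolated voxels are labelled
tips and reported.

**Branch lengths.** Branches are maximal slab paths between
tips/junctions; every slab voxel belongs to exactly one branch. A
branch's length is the polyline length of its centerline after a light
centered moving average of the path coordinates (default window 5
voxels, windows shrinking symmetrically at the ends so endpoints are
fixed). The smoothing matters: a digital centerline through a noisy
segmentation wobbles laterally by one voxel, turning axial steps into
diagonal ones and inflating raw Euclidean step sums by roughly 10% on a
perfectly straight root — an inflation the package's phantom experiments
measure directly, and which the window-5 smoothing removes while leaving
exactly straight or exactly diagonal paths unchanged (collinear points
average onto their own line). Real root curvature, at millimetre scales,
is untouched by a 5-voxel window. `smooth_window = 1` restores raw step
sums, and `length_mode = "count"` reproduces plain voxel counting for
comparison with counting-based protocols.

**Conservation.** The per-step lengths computed at decomposition are the
single source of truth: the depth profile assigns half of each step to
the slice of each endpoint, and the RLD map assigns the same halves to
cubic bins (default 2 mm). Total branch length, depth-profile sum and RLD
mass therefore agree to floating-point precision, and the package asserts
agreement to 10⁻⁶ relative.

**Branch angles** are computed at a vertex from two labelled points
(parent, branch) as the arccos of the normalized dot product in physical
coordinates — invariant under rigid motion and uniform scaling. Picking
the points is intentionally manual (a batch CSV interface replaces
interactive clicking); automatic angle extraction from the skeleton graph
is a non-goal, and the overlay volume (`overlay_skeleton()`: background
0, root 1, slab 2, junction 3, tip 4) supports picking in any external
viewer.

## The phantom: what it emulates, and what it does not

`phantom_spec()` describes a soil column with capsule-shaped root
segments (hemispherical caps make junctions watertight), non-overlapping
spherical pores placed by seeded rejection sampling and kept clear of the
roots, and three phase greys defaulting to air 5000, root 22000, soil
30000 on a 16-bit scale with Gaussian noise of SD 800. The ordering —
air ≪ root < soil, with the root:soil contrast much smaller than
air:soil — reproduces the qualitative contrast structure of real soil
scans, which is precisely what the Sobel/isodata mask exploits; the
absolute values are the package's own calibration, since published scans
rarely report phase greys.

Rendering supersamples only boundary voxels (default 4³ sub-voxels),
deciding clearly-inside/outside voxels analytically, so partial-volume
voxels carry genuine block-averaged greys at a fraction of the cost of
full supersampled rasterization. Identical spec and seed give
bit-identical volumes. `split_scans()` then cuts the column into
overlapping sub-scans with per-scan additive drift — the exact situation
`align_peaks()` + `stitch()` must invert.

The phantom does *not* simulate X-ray physics: no beam hardening,
cupping, ring artifacts, scatter, or projection-space reconstruction
noise; its noise is white and Gaussian, whereas reconstruction noise is
spatially correlated. Soil is a uniform phase with spherical pores, not a
granular texture. Passing the phantom experiments therefore demonstrates
the pipeline's geometric and topological correctness and its behavior
under PVE, drift and additive noise — it does not certify performance on
scans dominated by reconstruction artifacts or strongly textured soils,
where the bilevel range and erosion count need case-by-case tuning.

## Experiment sizes and defaults

The built-in detection-limit experiment (`detection_limit_sweep()`) uses
128×128×256-voxel columns — large enough that a root spans hundreds of
slices while a full sweep over six diameters runs in minutes on one CPU —
at 65 μm voxels with the default noise and pore settings, a bilevel band
of [18000, 26000] (root grey ± half the root–soil contrast), no erosion
(a single-root column has no pore bridges to cut), and a seed on the root
axis. Diameters of 2–8 voxels bracket the expected recovery threshold of
4–5 voxel diameters for connectivity-based extraction under partial
volume effects.

## Known limitations

- Stitching is axial-only; lateral or rotational misalignment between
  scans is not corrected.
- The additive grey model cannot normalize scans whose histogram *shape*
  changes (gain drift, density discontinuities).
- Closed skeleton loops (possible in touching root tangles) are measured
  but reported as `closed` branches without attempting to break them.
- Slice-wise RLD divides by the full slice volume (cross-section ×
  thickness), not a soil-only volume; with significant pot-wall or
  free-air voxels in the field of view the per-slice RLD is
  correspondingly diluted.
- Root diameters, root orders and time-series tracking are out of scope.
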