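# rootct

Segmentation and architecture analysis of plant root systems in 3D X-ray
micro-computed tomography (μCT) volumes of soil.

## The problem

Roots in soil are soft biological tissue threaded through a heterogeneous
matrix of mineral grains, water and air-filled pores. In a μCT
reconstruction their grey values overlap badly with the *partial volume
effect* (PVE): a voxel straddling an air:soil boundary receives the average
grey of both phases, which lands exactly in the "root" grey range. Global
thresholding therefore fails, and tall columns are scanned in several
overlapping parts whose grey assignments drift between scans.

`rootct` implements a complete, scriptable pipeline for this situation,
aimed at root biologists and soil scientists doing non-destructive root
phenotyping:

1. **Normalization and stitching** — the grey histogram of each scan is
   aligned by moving its dominant (soil) peak to a user-chosen reference
   grey (a pure additive shift), then duplicated boundary slices between
   consecutive scans are detected by normalized cross-correlation and
   removed.
2. **Partial-volume-aware segmentation** — the volume is upsampled ×2 by
   linear interpolation (so later filters cannot fragment fine roots), a
   per-slice Sobel gradient with an isodata (iterative intermeans)
   auto-threshold masks the sharp air:soil interfaces, a user-set bilevel
   grey range `[lo, hi]` selects root-range voxels outside that mask, a
   3×3×3 median filter and optional 3D erosions remove fine pore bridges,
   and the root system is extracted as the 26-connected component of a
   single seed voxel, then re-binned (2×2×2 maximum) to the original
   resolution.
3. **Skeleton metrics** — topology-preserving 3D thinning reduces the
   binary root volume to a unit-width centerline; voxels with 1 / 2 / ≥3
   skeleton neighbors are classified as tips / slabs / junctions; the
   skeleton decomposes into branches with calibrated polyline lengths,
   from which total root length, slice-wise depth profiles of root length
   density (RLD, cm·cm⁻³) and branching density, and 3D RLD maps are
   computed. Branch angles are measured from (parent, vertex, branch)
   point triplets.
4. **Synthetic phantoms** — a generator builds soil columns with capsule
   roots, spherical pores, genuine partial-volume boundary voxels
   (supersampled block averaging), Gaussian noise and per-scan grey
   drift, together with exact analytic ground truth — so every stage of
   the pipeline is validated against known geometry.

All volumes are 3D arrays indexed `(z, y, x)` (z = depth) with an
isotropic voxel side length in μm.

## Worked example

A 12.8 mm soil column (128×64×64 voxels at 100 μm) containing one vertical
500 μm root, scanned in two drifted overlapping parts, then normalized,
stitched, segmented and measured:

```r
library(rootct)

spec <- phantom_spec(
  dims_voxels = c(128, 64, 64), voxel_size_um = 100,
  root_segments = list(root_segment(c(1.5, 3.2, 3.2), c(11.3, 3.2, 3.2),
                                    diameter_um = 500)),
  rng_seed = 7)
truth <- build_geometry(spec)
vol   <- render_phantom(spec)

scans    <- split_scans(vol, n_scans = 2, overlap_slices = 10, drifts = c(400, -250))
aligned  <- align_peaks(scans, target_grey = 30000)
stitched <- stitch(aligned[[1]], aligned[[2]], max_overlap = 15)
attr(stitched, "overlap")
#> [1] 10

params <- segmentation_params(root_grey_lo = 18000, root_grey_hi = 26000,
                              seed_voxel = c(64, 32, 32))
seg <- run_pipeline(stitched, params)
seg$report
#> # A tibble: 7 × 3
#>   stage             foreground_voxels detail
#>   <chr>                         <dbl> <chr>
#> 1 align_peaks                      NA ...
#> 2 stitch                           NA overlap 10, similarity 1.000
#> 3 upsample2x                       NA 256x128x128
#> 4 pve_mask                     ~2.2e5 isodata threshold ~25300
#> 5 bilevel_threshold             ~2.3e4 <NA>
#> 6 median3d                      ~1.4e4 <NA>
#> 7 extract_connected             ~1.4e4 97.7% of thresholded foreground

skel     <- classify_voxels(skeletonize3d(seg$root))
branches <- branch_decompose(skel)
skel
#> <root_skeleton> 104 voxels (2 tips, 102 slabs, 0 junctions), 100 um/voxel
sprintf("recovered %.2f mm, true centerline %.2f mm",
        total_length(branches) * 10, truth$total_length_mm)
#> [1] "recovered 10.47 mm, true centerline 9.80 mm"
```

The recovered length slightly exceeds the analytic axis length because the
phantom's roots are capsules: the skeleton legitimately reaches into the
two hemispherical end caps (+0.25 mm each) that the axis-to-axis ground
truth does not count.

Depth profiles and 3D RLD maps follow directly:

```r
prof <- depth_profile(skel, column_cross_section_mm2 = 6.4^2)
plot_depth_profile(prof)
rmap <- rld_map(skel, bin_size_mm = 2)
```

A thin command-line wrapper over the same functions is installed with the
package (`system.file("cli", "rootct.R", package = "rootct")`) with
subcommands `phantom`, `stitch`, `segment`, `skeleton` and `angles`.

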