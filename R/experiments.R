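#' Detection-limit sweep over synthetic root diameters
#'
#' Builds, for each diameter, a soil column phantom containing a single
#' vertical root (default noise and pore settings of [phantom_spec()]),
#' runs the full segmentation pipeline, skeletonizes the extracted root
#' volume, and compares the recovered skeleton length with the analytic
#' centerline length. The sweep reproduces, on synthetic data, the
#' resolution experiment that determines the smallest recoverable root
#' diameter relative to the voxel size.
#'
#' The bilevel root band defaults to the phantom's root grey plus/minus
#' half the root-soil contrast — the band a user would set from the
#' histogram phase positions — with no erosion, since a single-root column
#' has no tenuous pore bridges to cut.
#'
#' @param diameters_voxels root diameters to test, in voxel units.
#' @param dims_voxels phantom dimensions `(z, y, x)`; default
#'   `c(256, 128, 128)`.
#' @param voxel_size_um voxel side length (default 65).
#' @param rng_seed integer seed; each diameter uses `rng_seed + index`.
#' @param root_grey_lo,root_grey_hi bilevel band (defaults 18000, 26000).
#' @param erosion_iterations erosion passes (default 0).
#' @param margin_mm axial clearance of the root ends from the column top
#'   and bottom (default 1.5).
#' @param ... further arguments passed to [phantom_spec()] (noise, pores,
#'   greys).
#' @return A tibble with one row per diameter: `diameter_voxels`,
#'   `diameter_um`, `true_length_mm`, `recovered_length_mm`, `recovery`.
#' @export
detection_limit_sweep <- function(diameters_voxels,
                                  dims_voxels = c(256L, 128L, 128L),
                                  voxel_size_um = 65,
                                  rng_seed = 1L,
                                  root_grey_lo = 18000,
                                  root_grey_hi = 26000,
                                  erosion_iterations = 0L,
                                  margin_mm = 1.5, ...) {
  rows <- lapply(seq_along(diameters_voxels), function(i) {
    d_vox <- diameters_voxels[i]
    d_um <- d_vox * voxel_size_um
    vs_mm <- voxel_size_um / 1000
    ext <- dims_voxels * vs_mm
    cy <- ext[2] / 2; cx <- ext[3] / 2
    seg <- root_segment(c(margin_mm, cy, cx), c(ext[1] - margin_mm, cy, cx),
                        d_um)
    spec <- phantom_spec(dims_voxels, voxel_size_um, list(seg),
                         rng_seed = rng_seed + i, ...)
    true_mm <- ext[1] - 2 * margin_mm
    vol <- render_phantom(spec)
    seed <- c(round(dims_voxels[1] / 2),
              round(dims_voxels[2] / 2), round(dims_voxels[3] / 2))
    params <- segmentation_params(root_grey_lo, root_grey_hi, seed,
                                  erosion_iterations = erosion_iterations)
    rec_mm <- tryCatch({
      seg_out <- run_pipeline(vol, params)
      skel <- classify_voxels(skeletonize3d(seg_out$root))
      total_length(branch_decompose(skel)) * 10
    }, error = function(e) 0)
    tibble::tibble(diameter_voxels = d_vox, diameter_um = d_um,
                   true_length_mm = true_mm, recovered_length_mm = rec_mm,
                   recovery = rec_mm / true_mm)
  })
  do.call(rbind, rows)
}

#' Smallest recovered diameter of a sweep
#'
#' @param sweep result of [detection_limit_sweep()].
#' @param min_recovery recovery threshold (default 0.9).
#' @param units `"um"` or `"voxels"`.
#' @return The smallest diameter whose recovery meets the threshold, or
#'   `NA` if none does.
#' @export
detection_limit <- function(sweep, min_recovery = 0.9, units = c("um", "voxels")) {
  units <- match.arg(units)
  ok <- sweep$recovery >= min_recovery
  if (!any(ok)) return(NA_real_)
  col <- if (units == "um") sweep$diameter_um else sweep$diameter_voxels
  min(col[ok])
}
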