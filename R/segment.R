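#' Segmentation parameters
#'
#' Bundles the user-set parameters of the root segmentation sequence: the
#' bilevel "root" grey range (bounds inclusive), the number of optional 3D
#' erosion passes, and the seed voxel (given at the original resolution;
#' scaled internally when the volume is upsampled).
#'
#' @param root_grey_lo,root_grey_hi inclusive grey bounds of root tissue.
#' @param seed_voxel integer `(z, y, x)` coordinate of a voxel inside the
#'   root system, at original resolution.
#' @param erosion_iterations non-negative erosion count (default 0).
#' @param connectivity region-growing connectivity: 6, 18 or 26 (default 26).
#' @param erosion_kernel `"cross"` (digital ball of diameter 3, default) or
#'   `"cube"` (full 3x3x3).
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(root_grey_lo, root_grey_hi, seed_voxel,
                                erosion_iterations = 0L,
                                connectivity = 26L,
                                erosion_kernel = c("cross", "cube")) {
  if (root_grey_lo >= root_grey_hi) stop("root_grey_lo must be < root_grey_hi")
  if (length(seed_voxel) != 3L || any(seed_voxel < 1) ||
      any(seed_voxel != round(seed_voxel)))
    stop("`seed_voxel` must be positive integer (z, y, x)")
  if (erosion_iterations < 0) stop("`erosion_iterations` must be >= 0")
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  structure(list(root_grey_lo = root_grey_lo, root_grey_hi = root_grey_hi,
                 seed_voxel = as.integer(seed_voxel),
                 erosion_iterations = as.integer(erosion_iterations),
                 connectivity = as.integer(connectivity),
                 erosion_kernel = match.arg(erosion_kernel),
                 upsample_factor = 2L),
            class = "segmentation_params")
}

up_axis1 <- function(a) {
  n <- dim(a)[1]
  lo <- rep(seq_len(n), each = 2)
  hi <- pmin(lo + rep(c(0L, 1L), n), n)
  (a[lo, , , drop = FALSE] + a[hi, , , drop = FALSE]) / 2
}

#' Double the voxel resolution of a volume by linear interpolation
#'
#' Each axis is doubled so the voxel count grows by a factor of 8. Even
#' output indices hold the original samples and odd ones linear midpoints
#' (the final midpoint replicates the last sample), which keeps constant
#' volumes constant and increases the number of voxels across each root so
#' that later filtering and erosion do not fragment fine roots. The voxel
#' side length is halved.
#'
#' @param volume a [ct_volume].
#' @return The upsampled [ct_volume] (32-bit, since midpoints may be
#'   fractional).
#' @export
upsample2x <- function(volume) {
  stopifnot(inherits(volume, "ct_volume"))
  a <- unclass(volume)
  a <- up_axis1(a)
  a <- aperm(up_axis1(aperm(a, c(2, 3, 1))), c(3, 1, 2))
  a <- aperm(up_axis1(aperm(a, c(3, 1, 2))), c(2, 3, 1))
  ct_volume(a, voxel_size_um(volume) / 2, bit_depth = 32L)
}

#' Per-slice Sobel gradient magnitude
#'
#' Applies the standard 3x3 Sobel kernel pair to every z-slice and returns
#' `sqrt(Gx^2 + Gy^2)` with edge replication at slice borders. Steep
#' gradients mark the air:soil interface, whose partial-volume voxels share
#' the grey range of root tissue.
#'
#' @param volume a [ct_volume] with slices at least 3x3.
#' @return A [ct_volume] of gradient magnitudes (32-bit).
#' @export
sobel_edges2d <- function(volume) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume)
  if (d[2] < 3L || d[3] < 3L) stop("slices must be at least 3x3")
  g <- cpp_sobel2d(as.vector(unclass(volume)), d[1], d[2], d[3])
  ct_volume(array(g, d), voxel_size_um(volume), bit_depth = 32L)
}

#' Isodata (iterative intermeans) automatic threshold
#'
#' Finds the threshold `T` satisfying the intermeans fixed point
#' `T = (mean(values <= T) + mean(values > T)) / 2`, iterating from the
#' midrange until the update is below 0.5 grey levels.
#'
#' @param values a [ct_volume] or numeric vector with at least two distinct
#'   values.
#' @return The threshold (numeric scalar).
#' @export
isodata_threshold <- function(values) {
  v <- as.vector(unclass(values))
  lo <- min(v); hi <- max(v)
  if (lo == hi) stop("degenerate distribution: all values identical")
  if (length(v) > 1e6) {
    # large volumes: accumulate on a fine grid (bin width <= 0.1 grey, far
    # inside the 0.5-grey convergence tolerance) so each intermeans pass is
    # O(bins) instead of O(voxels)
    nb <- min(2^21, max(2L, ceiling((hi - lo) / 0.1)))
    width <- (hi - lo) / nb
    idx <- pmin(pmax(ceiling((v - lo) / width), 1L), nb)
    cnt <- tabulate(idx, nbins = nb)
    centers <- lo + (seq_len(nb) - 0.5) * width
    csum_n <- cumsum(cnt)
    csum_v <- cumsum(cnt * centers)
    n <- length(v); tot <- csum_v[nb]
    t <- (lo + hi) / 2
    for (i in seq_len(1000L)) {
      k <- pmin(pmax(floor((t - lo) / width), 1L), nb)
      n1 <- csum_n[k]
      m1 <- if (n1 > 0) csum_v[k] / n1 else lo
      m2 <- if (n1 < n) (tot - csum_v[k]) / (n - n1) else hi
      t_new <- (m1 + m2) / 2
      if (abs(t_new - t) < 0.5) { t <- t_new; break }
      t <- t_new
    }
    return(t)
  }
  t <- (lo + hi) / 2
  for (i in seq_len(1000L)) {
    below <- v <= t
    m1 <- if (any(below)) mean(v[below]) else lo
    m2 <- if (any(!below)) mean(v[!below]) else hi
    t_new <- (m1 + m2) / 2
    if (abs(t_new - t) < 0.5) { t <- t_new; break }
    t <- t_new
  }
  t
}

#' Partial-volume-effect exclusion mask
#'
#' Thresholds a Sobel gradient-magnitude volume at its isodata threshold:
#' voxels with gradient above the threshold (the sharp air:soil interfaces)
#' are masked out of the later bilevel threshold, leaving the subtler
#' air:root and root:soil gradients untouched. An all-constant gradient
#' (e.g. a synthetic noiseless volume) yields an empty mask by convention.
#'
#' @param gradient gradient-magnitude [ct_volume] from [sobel_edges2d()].
#' @return A `pve_mask`: a [ct_binary] (1 = excluded voxel) with attribute
#'   `threshold_used` (NA for the degenerate empty-mask case).
#' @export
pve_mask <- function(gradient) {
  stopifnot(inherits(gradient, "ct_volume"))
  t <- tryCatch(isodata_threshold(gradient), error = function(e) NA_real_)
  m <- if (is.na(t)) array(0L, dim(gradient)) else
    array(as.integer(unclass(gradient) > t), dim(gradient))
  out <- ct_binary(m, voxel_size_um(gradient))
  attr(out, "threshold_used") <- t
  class(out) <- c("pve_mask", class(out))
  out
}

#' Bilevel grey threshold with partial-volume exclusion
#'
#' Keeps voxels whose grey value lies within the inclusive root range and
#' which are not excluded by the partial-volume mask.
#'
#' @param volume a [ct_volume].
#' @param params a [segmentation_params] (or a numeric `c(lo, hi)`).
#' @param mask optional `pve_mask` of identical dimensions.
#' @return A [ct_binary].
#' @export
bilevel_threshold <- function(volume, params, mask = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  if (inherits(params, "segmentation_params")) {
    lo <- params$root_grey_lo; hi <- params$root_grey_hi
  } else {
    lo <- params[1]; hi <- params[2]
  }
  fg <- unclass(volume) >= lo & unclass(volume) <= hi
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(volume))) stop("mask dimensions differ from volume")
    fg <- fg & !(unclass(mask) > 0L)
  }
  ct_binary(array(as.integer(fg), dim(volume)), voxel_size_um(volume))
}

#' 3D median filter on a binary volume
#'
#' Majority vote over the 3x3x3 neighborhood (equivalent to the median for
#' binary data), with edge replication at the borders. Removes small-scale
#' structures and fine connecting voxel threads while keeping large
#' structures intact.
#'
#' @param binary a [ct_binary].
#' @return The filtered [ct_binary].
#' @export
median3d <- function(binary) {
  stopifnot(inherits(binary, "ct_binary"))
  d <- dim(binary)
  out <- cpp_median3d(as.vector(unclass(binary)), d[1], d[2], d[3])
  ct_binary(array(out, d), voxel_size_um(binary))
}

#' 3D morphological erosion
#'
#' Erodes with a structuring element of diameter 3 voxels: by default the
#' 6-face-neighbor cross (digital ball; a full cube has diameter > 3 along
#' its diagonals), optionally the full 3x3x3 cube. Voxels outside the
#' array count as background. Zero iterations is the identity.
#'
#' @param binary a [ct_binary].
#' @param iterations non-negative erosion count.
#' @param kernel `"cross"` (default) or `"cube"`.
#' @return The eroded [ct_binary].
#' @export
erode3d <- function(binary, iterations, kernel = c("cross", "cube")) {
  stopifnot(inherits(binary, "ct_binary"), iterations >= 0)
  kernel <- match.arg(kernel)
  if (iterations == 0L) return(binary)
  d <- dim(binary)
  out <- cpp_erode3d(as.vector(unclass(binary)), d[1], d[2], d[3],
                     as.integer(iterations), kernel == "cube")
  ct_binary(array(out, d), voxel_size_um(binary))
}

#' Extract the connected component containing a seed voxel
#'
#' Region growing on an already-binary volume reduces to pure connectivity:
#' the output keeps exactly the component (26-connected by default)
#' containing the seed, dropping all disconnected pore space.
#'
#' @param binary a [ct_binary].
#' @param seed_voxel integer `(z, y, x)`; must be a foreground voxel, else
#'   an error reports the nearest foreground voxel as a suggestion.
#' @param connectivity 6, 18 or 26 (default 26, retaining thin diagonal
#'   roots).
#' @return A [ct_binary] with a single connected component.
#' @export
extract_connected <- function(binary, seed_voxel, connectivity = 26L) {
  stopifnot(inherits(binary, "ct_binary"))
  d <- dim(binary)
  s <- as.integer(seed_voxel)
  if (length(s) != 3L || any(s < 1L) || any(s > d))
    stop("seed voxel out of volume bounds")
  if (binary[s[1], s[2], s[3]] == 0L) {
    near <- cpp_nearest_fg(as.vector(unclass(binary)), d[1], d[2], d[3],
                           s[1] - 1L, s[2] - 1L, s[3] - 1L)
    sugg <- if (near[1] >= 0)
      sprintf("; nearest foreground voxel is (%d, %d, %d)",
              near[1] + 1L, near[2] + 1L, near[3] + 1L)
    else "; volume has no foreground"
    stop("seed voxel (", paste(s, collapse = ", "),
         ") is background", sugg)
  }
  out <- cpp_flood(as.vector(unclass(binary)), d[1], d[2], d[3],
                   s[1] - 1L, s[2] - 1L, s[3] - 1L, as.integer(connectivity))
  ct_binary(array(out, d), voxel_size_um(binary))
}

#' Re-bin a binary volume by 2x2x2 maximum
#'
#' Maps every 2x2x2 block to its maximum, so a block is foreground if any
#' of its voxels is — preserving root structure while reducing file size
#' back to the pre-upsampling dimensions. Odd dimensions are padded with
#' background. The voxel side length doubles.
#'
#' @param binary a [ct_binary].
#' @param factor block size; fixed at 2.
#' @return The re-binned [ct_binary].
#' @export
bin_max <- function(binary, factor = 2L) {
  stopifnot(inherits(binary, "ct_binary"), factor == 2L)
  a <- unclass(binary)
  d <- dim(a)
  dp <- ceiling(d / 2) * 2L
  if (any(dp != d)) {
    b <- array(0L, dp)
    b[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- a
    a <- b
  }
  o1 <- seq(1L, dp[1], 2L); o2 <- seq(1L, dp[2], 2L); o3 <- seq(1L, dp[3], 2L)
  out <- array(0L, dp / 2L)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
    out <- pmax(out, a[o1 + dz, o2 + dy, o3 + dx])
  ct_binary(out, voxel_size_um(binary) * 2)
}

count_components <- function(binary, connectivity = 26L) {
  d <- dim(binary)
  max(cpp_label_components(as.vector(unclass(binary)), d[1], d[2], d[3],
                           as.integer(connectivity)))
}

#' Run the full root segmentation pipeline
#'
#' Executes the fixed stage sequence on one or more scans: histogram peak
#' alignment and stitching (when several scans are given), two-fold
#' upsampling, per-slice Sobel gradient, partial-volume mask (computed on
#' the upsampled grey volume), bilevel threshold, 3D median, optional 3D
#' erosion, seeded connectivity extraction (seed scaled to the upsampled
#' grid), and 2x2x2 max re-binning back to the original resolution. A
#' per-stage report (voxel counts, thresholds, shifts, overlap) is
#' returned alongside the binary root volume.
#'
#' @param scans a [ct_volume] or list of them (ordered top to bottom).
#' @param params a [segmentation_params].
#' @param target_grey reference grey for peak alignment (required when more
#'   than one scan is given).
#' @param max_overlap,min_similarity stitching controls (see [stitch()]).
#' @param search_window,smooth_width,n_bins peak-detection controls (see
#'   [align_peaks()]).
#' @param sanity_fraction if the extracted component is smaller than this
#'   fraction of the pre-extraction foreground, the report flags it
#'   (default 0.05) — a typical symptom of a seed placed on a stray pore.
#' @return A `root_segmentation` list: `root` (a [ct_binary] at original
#'   resolution) and `report` (a tibble of per-stage accounting).
#' @export
run_pipeline <- function(scans, params, target_grey = NULL,
                         max_overlap = 20L, min_similarity = 0.9,
                         search_window = NULL, smooth_width = 5L,
                         n_bins = 1024L, sanity_fraction = 0.05) {
  stopifnot(inherits(params, "segmentation_params"))
  if (inherits(scans, "ct_volume")) scans <- list(scans)
  report <- list()
  note <- function(stage, voxels, detail = NA_character_)
    tibble::tibble(stage = stage, foreground_voxels = as.numeric(voxels),
                   detail = detail)

  vol <- scans[[1]]
  if (length(scans) > 1L) {
    if (is.null(target_grey))
      stop("stage align_peaks: `target_grey` required for multiple scans")
    aligned <- withCallingHandlers(
      align_peaks(scans, target_grey, search_window, smooth_width, n_bins),
      error = function(e) stop("stage align_peaks: ", conditionMessage(e)))
    shifts <- vapply(aligned, attr, 0, "grey_shift")
    report[[length(report) + 1L]] <-
      note("align_peaks", NA, paste(sprintf("%.1f", shifts), collapse = ", "))
    vol <- aligned[[1]]
    for (i in seq_along(aligned)[-1]) {
      vol <- tryCatch(stitch(vol, aligned[[i]], max_overlap, min_similarity),
                      error = function(e) stop("stage stitch: ", conditionMessage(e)))
      report[[length(report) + 1L]] <-
        note("stitch", NA, sprintf("overlap %d, similarity %.3f",
                                   attr(vol, "overlap"), attr(vol, "similarity")))
    }
  }

  up <- upsample2x(vol)
  report[[length(report) + 1L]] <- note("upsample2x", NA,
                                        paste(dim(up), collapse = "x"))
  grad <- sobel_edges2d(up)
  mask <- pve_mask(grad)
  report[[length(report) + 1L]] <-
    note("pve_mask", sum(mask), sprintf("isodata threshold %.1f",
                                        attr(mask, "threshold_used")))
  rm(grad)
  bin <- bilevel_threshold(up, params, mask)
  rm(up, mask)
  report[[length(report) + 1L]] <- note("bilevel_threshold", sum(bin))
  bin <- median3d(bin)
  report[[length(report) + 1L]] <- note("median3d", sum(bin))
  if (params$erosion_iterations > 0L) {
    bin <- erode3d(bin, params$erosion_iterations, params$erosion_kernel)
    report[[length(report) + 1L]] <-
      note("erode3d", sum(bin), sprintf("%d iteration(s)", params$erosion_iterations))
  }
  pre_extract <- sum(bin)
  seed_up <- params$seed_voxel * 2L - 1L
  root <- tryCatch(extract_connected(bin, seed_up, params$connectivity),
                   error = function(e) stop("stage extract_connected: ",
                                            conditionMessage(e)))
  frac <- if (pre_extract > 0) sum(root) / pre_extract else 0
  flagged <- frac < sanity_fraction
  report[[length(report) + 1L]] <-
    note("extract_connected", sum(root),
         sprintf("%.1f%% of thresholded foreground%s", 100 * frac,
                 if (flagged) " [FLAG: below sanity fraction]" else ""))
  rm(bin)
  root <- bin_max(root)
  report[[length(report) + 1L]] <- note("bin_max", sum(root))

  structure(list(root = root,
                 report = do.call(rbind, report),
                 component_fraction = frac,
                 flagged = flagged),
            class = "root_segmentation")
}

#' @export
print.root_segmentation <- function(x, ...) {
  cat("<root_segmentation>\n")
  print(x$report)
  invisible(x)
}
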