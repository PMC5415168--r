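#' Grey-value histogram of a volume
#'
#' Bins span the full data range `[min, max]`; the top bin is closed so the
#' maximum value is counted. A constant volume yields a single occupied bin.
#'
#' @param volume a [ct_volume].
#' @param n_bins number of bins (default 1024).
#' @return A `grey_histogram`: list with `bin_edges` (length `n_bins + 1`),
#'   `counts` and `bin_centers`.
#' @export
grey_histogram <- function(volume, n_bins = 1024L) {
  stopifnot(inherits(volume, "ct_volume") || is.numeric(volume))
  if (n_bins < 2L) stop("`n_bins` must be >= 2")
  v <- as.vector(unclass(volume))
  lo <- min(v); hi <- max(v)
  if (hi == lo) { lo <- lo - 0.5; hi <- hi + 0.5 }   # constant volume
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  idx <- findInterval(v, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges = edges,
                 counts = counts,
                 bin_centers = (edges[-1] + edges[-length(edges)]) / 2),
            class = "grey_histogram")
}

#' @export
print.grey_histogram <- function(x, ...) {
  cat(sprintf("<grey_histogram> %d bins over [%g, %g], %d voxels\n",
              length(x$counts), min(x$bin_edges), max(x$bin_edges),
              sum(x$counts)))
  invisible(x)
}

#' Locate the dominant local histogram peak (typically the soil peak)
#'
#' Smooths the counts with a centered moving average (partial windows at the
#' array ends) and returns the bin center of the highest local maximum
#' inside `search_window`. Ties break toward the lower grey value. Bins at
#' the extreme ends of the histogram are not considered local maxima, so
#' counts monotone across the window raise a "no peak" error.
#'
#' @param hist a `grey_histogram`.
#' @param search_window grey range `c(lo, hi)` to search; default full range.
#' @param smooth_width odd positive moving-average width in bins (default 5).
#' @return A `peak_info`: list with `peak_grey`, `prominence`,
#'   `search_window`.
#' @export
find_peak <- function(hist, search_window = NULL, smooth_width = 5L) {
  stopifnot(inherits(hist, "grey_histogram"))
  if (smooth_width < 1L || smooth_width %% 2L == 0L)
    stop("`smooth_width` must be odd and positive")
  centers <- hist$bin_centers
  if (is.null(search_window))
    search_window <- range(hist$bin_edges)
  if (search_window[2] < min(centers) || search_window[1] > max(centers))
    stop("search window does not overlap histogram support")

  counts <- as.numeric(hist$counts)
  n <- length(counts)
  half <- (smooth_width - 1L) %/% 2L
  # moving average with partial windows at the ends
  cs <- cumsum(c(0, counts))
  lo_i <- pmax(seq_len(n) - half, 1L)
  hi_i <- pmin(seq_len(n) + half, n)
  smoothed <- (cs[hi_i + 1L] - cs[lo_i]) / (hi_i - lo_i + 1L)

  in_win <- centers >= search_window[1] & centers <= search_window[2]
  left  <- c(Inf, smoothed[-n])   # Inf sentinels: histogram-end bins excluded
  right <- c(smoothed[-1], Inf)
  is_max <- smoothed >= left & smoothed >= right & in_win
  # exclude flat stretches where both neighbors are equal and no curvature:
  # retained; ties toward lower grey handled by which.max order below
  if (!any(is_max)) stop("no peak: counts are monotone within the search window")
  cand <- which(is_max)
  best <- cand[which.max(smoothed[cand])]   # which.max -> first = lowest grey
  structure(list(peak_grey = centers[best],
                 prominence = max(smoothed[best] - min(smoothed[in_win]), 0),
                 search_window = as.numeric(search_window)),
            class = "peak_info")
}

#' Align scan histograms to a common reference grey value
#'
#' Detects the dominant (soil) histogram peak of each scan and shifts the
#' scan's grey values additively so the peak lands on `target_grey`. The
#' transform is a pure shift — no gain change — so histogram shape is
#' preserved; this assumes the grey-value variance is consistent between
#' scans. The applied shift is recorded in the `grey_shift` attribute of
#' each returned volume.
#'
#' @param volumes a list of [ct_volume]s (a single volume is also accepted).
#' @param target_grey reference grey value the peak is moved to.
#' @param search_window optional grey range restricting peak search.
#' @param smooth_width moving-average width for peak detection (bins).
#' @param n_bins histogram bins (default 1024).
#' @return List of shifted volumes, each carrying a `grey_shift` attribute.
#' @export
align_peaks <- function(volumes, target_grey, search_window = NULL,
                        smooth_width = 5L, n_bins = 1024L) {
  single <- inherits(volumes, "ct_volume")
  if (single) volumes <- list(volumes)
  out <- lapply(volumes, function(v) {
    pk <- find_peak(grey_histogram(v, n_bins), search_window, smooth_width)
    shift <- target_grey - pk$peak_grey
    shifted <- ct_volume(unclass(v) + shift, voxel_size_um(v),
                         bit_depth = 32L)
    attr(shifted, "grey_shift") <- shift
    shifted
  })
  if (single) out[[1]] else out
}

#' Stitch two vertically adjacent scans by removing duplicated slices
#'
#' Sequential scans of one column share a small axial overlap. For each
#' candidate overlap `k` in `1:max_overlap` the mean normalized
#' cross-correlation (Pearson, per slice pair) between the last `k` slices
#' of `volume_a` and the first `k` slices of `volume_b` is computed; the
#' `k` maximizing it is taken. If the best similarity is below
#' `min_similarity` an error is raised. A's slices are kept in the overlap.
#'
#' @param volume_a,volume_b [ct_volume]s sharing row/col dimensions and
#'   calibration; A is the upper scan.
#' @param max_overlap maximum overlap considered (slices); must be smaller
#'   than both depths.
#' @param min_similarity minimum acceptable mean correlation in `[0, 1]`.
#' @return The stitched [ct_volume] with attributes `overlap` (slices
#'   removed) and `similarity`.
#' @export
stitch <- function(volume_a, volume_b, max_overlap, min_similarity = 0.9) {
  stopifnot(inherits(volume_a, "ct_volume"), inherits(volume_b, "ct_volume"))
  da <- dim(volume_a); db <- dim(volume_b)
  if (!all(da[2:3] == db[2:3])) stop("row/col dimensions differ between scans")
  if (!isTRUE(all.equal(voxel_size_um(volume_a), voxel_size_um(volume_b))))
    stop("voxel calibrations differ between scans")
  if (max_overlap < 1L || max_overlap >= da[1] || max_overlap >= db[1])
    stop("`max_overlap` must be in [1, depth) of both scans")

  slice_ncc <- function(a, b) {
    sa <- sd(a); sb <- sd(b)
    if (sa == 0 || sb == 0) return(as.numeric(isTRUE(all.equal(a, b))))
    cor(a, b)
  }
  sims <- vapply(seq_len(max_overlap), function(k) {
    mean(vapply(seq_len(k), function(i) {
      slice_ncc(as.vector(volume_a[da[1] - k + i, , ]),
                as.vector(volume_b[i, , ]))
    }, 0))
  }, 0)
  k <- which.max(sims)
  if (!is.finite(sims[k]) || sims[k] < min_similarity)
    stop(sprintf("no overlap detected: best similarity %.3f (k = %d) below %.3f",
                 sims[k], k, min_similarity))
  merged <- array(0, c(da[1] + db[1] - k, da[2], da[3]))
  merged[seq_len(da[1]), , ] <- volume_a          # A's slices kept in overlap
  merged[(da[1] + 1):(da[1] + db[1] - k), , ] <- volume_b[(k + 1):db[1], , ]
  out <- ct_volume(merged, voxel_size_um(volume_a), bit_depth = 32L)
  attr(out, "overlap") <- k
  attr(out, "similarity") <- sims[k]
  out
}
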