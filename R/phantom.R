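#' Describe one root segment of a synthetic phantom
#'
#' Segments are capsules (cylinders with hemispherical caps, so junctions
#' between touching segments are watertight) given by their axis endpoints
#' in physical mm coordinates, `(z, y, x)` order, and their diameter.
#'
#' @param start_mm,end_mm numeric `(z, y, x)` axis endpoints in mm.
#' @param diameter_um positive root diameter in micrometres.
#' @return A `root_segment` list.
#' @export
root_segment <- function(start_mm, end_mm, diameter_um) {
  stopifnot(length(start_mm) == 3L, length(end_mm) == 3L, diameter_um > 0)
  structure(list(start_mm = as.numeric(start_mm), end_mm = as.numeric(end_mm),
                 diameter_um = as.numeric(diameter_um)),
            class = "root_segment")
}

#' Specification of a synthetic soil-root phantom
#'
#' Parametric description of a soil column with embedded root capsules,
#' spherical pores, partial-volume boundary voxels (via supersampled block
#' averaging) and Gaussian noise. The default phase greys mimic typical
#' scans: air far below root tissue, root slightly below soil, so the
#' air:soil contrast is much stronger than the root:soil contrast and an
#' edge mask removes the former but not the latter.
#'
#' @param dims_voxels integer `(z, y, x)` volume dimensions.
#' @param voxel_size_um isotropic voxel side length in micrometres.
#' @param root_segments list of [root_segment()]s, all within the column.
#' @param grey_soil,grey_root,grey_air phase grey values (16-bit scale
#'   defaults: 30000, 22000, 5000).
#' @param pore_fraction target volume fraction of spherical pores, in
#'   `[0, 0.5)` (default 0.05).
#' @param pore_radius_range_voxels pore radius range in voxels (default
#'   `c(2, 5)`).
#' @param noise_sd Gaussian noise standard deviation in grey levels
#'   (default 800).
#' @param supersample sub-voxel sampling per axis for partial-volume
#'   rendering, integer >= 2 (default 4).
#' @param rng_seed integer seed controlling pore placement and noise.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dims_voxels, voxel_size_um, root_segments,
                         grey_soil = 30000, grey_root = 22000,
                         grey_air = 5000, pore_fraction = 0.05,
                         pore_radius_range_voxels = c(2, 5),
                         noise_sd = 800, supersample = 4L, rng_seed = 1L) {
  stopifnot(length(dims_voxels) == 3L, all(dims_voxels >= 1),
            voxel_size_um > 0, supersample >= 2L,
            pore_fraction >= 0, pore_fraction < 0.5, noise_sd >= 0)
  if (inherits(root_segments, "root_segment")) root_segments <- list(root_segments)
  ext_mm <- dims_voxels * voxel_size_um / 1000
  for (s in root_segments) {
    stopifnot(inherits(s, "root_segment"))
    r_mm <- s$diameter_um / 2000
    pts <- rbind(s$start_mm, s$end_mm)
    if (any(pts < r_mm) || any(t(t(pts) > ext_mm - r_mm)))
      stop("root segment (including its radius) extends outside the column")
  }
  structure(list(dims_voxels = as.integer(dims_voxels),
                 voxel_size_um = voxel_size_um,
                 root_segments = root_segments,
                 grey_soil = grey_soil, grey_root = grey_root,
                 grey_air = grey_air,
                 pore_fraction = pore_fraction,
                 pore_radius_range_voxels = pore_radius_range_voxels,
                 noise_sd = noise_sd,
                 supersample = as.integer(supersample),
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# distance from points (n x 3 matrix, mm) to a segment axis
dist_to_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(rowSums(sweep(p, 2, a)^2)))
  t <- (sweep(p, 2, a) %*% ab) / len2
  t <- pmin(pmax(t, 0), 1)
  proj <- cbind(a[1] + t * ab[1], a[2] + t * ab[2], a[3] + t * ab[3])
  sqrt(rowSums((p - proj)^2))
}

# per-voxel volume fraction occupied by one capsule / sphere, adaptive:
# voxels clearly inside/outside are decided by the center distance, boundary
# voxels are supersampled. Returns list(idx = linear indices, frac).
fraction_of_shape <- function(dims, vs_mm, supersample, dist_fun, center_lo,
                              center_hi, radius_mm) {
  lo <- pmax(floor(center_lo / vs_mm - radius_mm / vs_mm - 1), 0) + 1
  hi <- pmin(ceiling(center_hi / vs_mm + radius_mm / vs_mm + 1), dims)
  if (any(lo > hi)) return(list(idx = integer(0), frac = numeric(0)))
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  g <- expand.grid(z = zi, y = yi, x = xi)
  centers <- cbind((g$z - 0.5) * vs_mm, (g$y - 0.5) * vs_mm, (g$x - 0.5) * vs_mm)
  d <- dist_fun(centers)
  h <- vs_mm * sqrt(3) / 2
  frac <- as.numeric(d <= radius_mm)
  bnd <- which(abs(d - radius_mm) < h)
  if (length(bnd) > 0) {
    s <- supersample
    off1 <- ((seq_len(s) - 0.5) / s - 0.5) * vs_mm
    sub <- as.matrix(expand.grid(off1, off1, off1))
    acc <- numeric(length(bnd))
    for (k in seq_len(nrow(sub))) {
      pc <- centers[bnd, , drop = FALSE]
      pc[, 1] <- pc[, 1] + sub[k, 1]
      pc[, 2] <- pc[, 2] + sub[k, 2]
      pc[, 3] <- pc[, 3] + sub[k, 3]
      acc <- acc + (dist_fun(pc) <= radius_mm)
    }
    frac[bnd] <- acc / nrow(sub)
  }
  keep <- frac > 0
  idx <- g$z[keep] + dims[1] * ((g$y[keep] - 1) + dims[2] * (g$x[keep] - 1))
  list(idx = idx, frac = frac[keep])
}

root_fraction <- function(spec) {
  dims <- spec$dims_voxels
  vs_mm <- spec$voxel_size_um / 1000
  f <- numeric(prod(dims))
  for (s in spec$root_segments) {
    r_mm <- s$diameter_um / 2000
    part <- fraction_of_shape(dims, vs_mm, spec$supersample,
                              function(p) dist_to_segment(p, s$start_mm, s$end_mm),
                              pmin(s$start_mm, s$end_mm),
                              pmax(s$start_mm, s$end_mm), r_mm)
    f[part$idx] <- pmax(f[part$idx], part$frac)
  }
  array(f, dims)
}

#' Analytic ground truth of a phantom
#'
#' Computes the exact centerline lengths (Euclidean endpoint distances),
#' branch points (axis endpoints shared by two or more segments), branch
#' angles (between segment direction vectors oriented away from the shared
#' point) and the true root mask (voxels with more than half their volume
#' inside a root capsule, at supersampled precision).
#'
#' @param spec a [phantom_spec].
#' @return A `phantom_truth` list: `segments` tibble (with `length_mm`),
#'   `total_length_mm`, `branch_points` tibble, `branch_angles` tibble and
#'   `root_mask` ([ct_binary]).
#' @export
build_geometry <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  segs <- spec$root_segments
  seg_tb <- tibble::tibble(
    segment = seq_along(segs),
    z0 = vapply(segs, function(s) s$start_mm[1], 0),
    y0 = vapply(segs, function(s) s$start_mm[2], 0),
    x0 = vapply(segs, function(s) s$start_mm[3], 0),
    z1 = vapply(segs, function(s) s$end_mm[1], 0),
    y1 = vapply(segs, function(s) s$end_mm[2], 0),
    x1 = vapply(segs, function(s) s$end_mm[3], 0),
    diameter_um = vapply(segs, function(s) s$diameter_um, 0),
    length_mm = vapply(segs, function(s)
      sqrt(sum((s$end_mm - s$start_mm)^2)), 0))

  # shared endpoints -> branch points and angles
  ends <- rbind(as.matrix(seg_tb[, c("z0", "y0", "x0")]),
                as.matrix(seg_tb[, c("z1", "y1", "x1")]))
  seg_of <- rep(seg_tb$segment, 2)
  bp <- list(); ba <- list()
  if (nrow(ends) > 1) {
    for (i in seq_len(nrow(ends) - 1)) {
      for (j in (i + 1):nrow(ends)) {
        if (seg_of[i] == seg_of[j]) next
        if (sqrt(sum((ends[i, ] - ends[j, ])^2)) > 1e-9) next
        p <- ends[i, ]
        dir_away <- function(k) {
          s <- segs[[seg_of[k]]]
          other <- if (sqrt(sum((s$start_mm - p)^2)) < 1e-9) s$end_mm else s$start_mm
          v <- other - p
          v / sqrt(sum(v^2))
        }
        u <- dir_away(i); v <- dir_away(j)
        ang <- acos(min(max(sum(u * v), -1), 1)) * 180 / pi
        bp[[length(bp) + 1L]] <- tibble::tibble(z = p[1], y = p[2], x = p[3])
        ba[[length(ba) + 1L]] <- tibble::tibble(
          segment_a = seg_of[i], segment_b = seg_of[j],
          z = p[1], y = p[2], x = p[3], angle_deg = ang)
      }
    }
  }
  branch_points <- if (length(bp)) unique(do.call(rbind, bp)) else
    tibble::tibble(z = numeric(0), y = numeric(0), x = numeric(0))
  branch_angles <- if (length(ba)) do.call(rbind, ba) else
    tibble::tibble(segment_a = integer(0), segment_b = integer(0),
                   z = numeric(0), y = numeric(0), x = numeric(0),
                   angle_deg = numeric(0))

  mask <- ct_binary(array(as.integer(root_fraction(spec) > 0.5),
                          spec$dims_voxels), spec$voxel_size_um)
  structure(list(segments = seg_tb,
                 total_length_mm = sum(seg_tb$length_mm),
                 branch_points = branch_points,
                 branch_angles = branch_angles,
                 root_mask = mask),
            class = "phantom_truth")
}

# seeded rejection sampling of non-overlapping pores clear of the roots
sample_pores <- function(spec) {
  dims <- spec$dims_voxels
  vs_mm <- spec$voxel_size_um / 1000
  ext <- dims * vs_mm
  target <- spec$pore_fraction * prod(ext)
  if (target <= 0) return(list())
  rr <- spec$pore_radius_range_voxels * vs_mm
  pores <- list(); vol <- 0; attempts <- 0L
  max_attempts <- 5000L + 200L * ceiling(target / (4 / 3 * pi * mean(rr)^3))
  while (vol < target && attempts < max_attempts) {
    attempts <- attempts + 1L
    r <- runif(1, rr[1], rr[2])
    c_mm <- c(runif(1, r, ext[1] - r), runif(1, r, ext[2] - r),
              runif(1, r, ext[3] - r))
    clear <- TRUE
    for (s in spec$root_segments) {
      d <- dist_to_segment(matrix(c_mm, 1), s$start_mm, s$end_mm)
      if (d < r + s$diameter_um / 2000 + vs_mm) { clear <- FALSE; break }
    }
    if (clear) for (p in pores) {
      if (sqrt(sum((c_mm - p$c) ^ 2)) < r + p$r) { clear <- FALSE; break }
    }
    if (!clear) next
    pores[[length(pores) + 1L]] <- list(c = c_mm, r = r)
    vol <- vol + 4 / 3 * pi * r^3
  }
  if (vol < target)
    warning(sprintf("pore packing reached %.1f%% of the target fraction",
                    100 * vol / target))
  pores
}

#' Render a phantom to a greyscale volume
#'
#' Rasterizes the phases at supersampled precision: voxels straddling a
#' phase boundary receive the block-averaged grey of their sub-voxel
#' occupancies, producing genuine partial-volume voxels. Pores are
#' non-overlapping spheres placed by the seeded RNG, kept clear of the
#' roots; Gaussian noise is added last with the same seeded stream, so an
#' identical spec gives a bit-identical volume.
#'
#' @param spec a [phantom_spec].
#' @param truth optional [build_geometry()] result (unused by rendering but
#'   accepted so calls can pass both around together).
#' @return A [ct_volume] (32-bit float).
#' @export
render_phantom <- function(spec, truth = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$dims_voxels
  vs_mm <- spec$voxel_size_um / 1000
  f_root <- as.vector(root_fraction(spec))
  with_seed(spec$rng_seed, {
    pores <- sample_pores(spec)
    f_air <- numeric(prod(dims))
    for (p in pores) {
      part <- fraction_of_shape(dims, vs_mm, spec$supersample,
                                function(q) sqrt(rowSums(sweep(q, 2, p$c)^2)),
                                p$c, p$c, p$r)
      f_air[part$idx] <- pmax(f_air[part$idx], part$frac)
    }
    f_air <- pmin(f_air, 1 - f_root)
    grey <- f_root * spec$grey_root + f_air * spec$grey_air +
      (1 - f_root - f_air) * spec$grey_soil
    if (spec$noise_sd > 0)
      grey <- grey + rnorm(length(grey), 0, spec$noise_sd)
    ct_volume(array(grey, dims), spec$voxel_size_um, bit_depth = 32L)
  })
}

#' Split a volume into overlapping sub-scans with grey drift
#'
#' Emulates a column scanned in several vertically adjacent parts:
#' consecutive sub-scans share `overlap_slices` duplicated slices, and each
#' sub-scan's grey values are offset by its drift — the situation the peak
#' alignment and stitching stages must invert.
#'
#' @param volume a [ct_volume].
#' @param n_scans number of sub-scans (>= 1).
#' @param overlap_slices duplicated slices between consecutive scans.
#' @param drifts numeric vector of per-scan grey offsets, length `n_scans`.
#' @return A list of [ct_volume]s, top to bottom.
#' @export
split_scans <- function(volume, n_scans, overlap_slices, drifts) {
  stopifnot(inherits(volume, "ct_volume"), n_scans >= 1,
            length(drifts) == n_scans)
  nz <- dim(volume)[1]
  if (n_scans == 1L) {
    out <- ct_volume(unclass(volume) + drifts[1], voxel_size_um(volume),
                     bit_depth = 32L)
    return(list(out))
  }
  if (overlap_slices < 1) stop("`overlap_slices` must be positive")
  total <- nz + (n_scans - 1L) * overlap_slices
  base <- total %/% n_scans
  lens <- rep(base, n_scans)
  extra <- total - sum(lens)
  if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  if (any(lens <= overlap_slices))
    stop("overlap too large for the volume depth")
  starts <- cumsum(c(1L, head(lens, -1) - overlap_slices))
  lapply(seq_len(n_scans), function(i) {
    sl <- volume[starts[i]:(starts[i] + lens[i] - 1L), , , drop = FALSE]
    ct_volume(sl + drifts[i], voxel_size_um(volume), bit_depth = 32L)
  })
}
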