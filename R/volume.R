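#' Calibrated 3D greyscale volume
#'
#' A `ct_volume` is a numeric 3D array with dimension order `(z, y, x)`
#' (z = depth, slice 1 = top of the column), an isotropic voxel side length
#' in micrometres, and a nominal bit depth (8, 16 or 32). For bit depths 8
#' and 16 all grey values must lie within the unsigned integer range of that
#' depth; 32 denotes floating-point data with no range restriction.
#'
#' @param data numeric 3D array indexed `(z, y, x)`.
#' @param voxel_size_um positive isotropic voxel side length in micrometres.
#' @param bit_depth one of 8, 16, 32. Defaults to 32 (float).
#' @return A `ct_volume` object (a 3D array with calibration attributes).
#' @examples
#' v <- ct_volume(array(100, c(4, 5, 6)), voxel_size_um = 65)
#' dim(v)
#' @export
ct_volume <- function(data, voxel_size_um, bit_depth = 32L) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array indexed (z, y, x)")
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a single positive number")
  if (!bit_depth %in% c(8L, 16L, 32L)) stop("`bit_depth` must be 8, 16 or 32")
  storage.mode(data) <- "double"
  if (anyNA(data) || any(!is.finite(data))) stop("grey values must be finite")
  if (bit_depth %in% c(8L, 16L)) {
    hi <- 2^bit_depth - 1
    if (any(data < 0) || any(data > hi))
      stop(sprintf("values outside [0, %d] for bit depth %d", hi, bit_depth))
  }
  structure(data,
            voxel_size_um = as.numeric(voxel_size_um),
            bit_depth = as.integer(bit_depth),
            class = c("ct_volume", "array"))
}

#' Binary 3D volume (background 0 / foreground 1)
#'
#' @param data 3D array of 0/1 (or logical) values, indexed `(z, y, x)`.
#' @param voxel_size_um positive isotropic voxel side length in micrometres.
#' @return A `ct_binary` object.
#' @export
ct_binary <- function(data, voxel_size_um) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array indexed (z, y, x)")
  if (is.logical(data)) storage.mode(data) <- "integer"
  if (!all(data %in% c(0L, 1L))) stop("binary volume may contain only 0 and 1")
  storage.mode(data) <- "integer"
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      voxel_size_um <= 0)
    stop("`voxel_size_um` must be a single positive number")
  structure(data,
            voxel_size_um = as.numeric(voxel_size_um),
            class = c("ct_binary", "array"))
}

#' Voxel side length of a volume, in micrometres
#' @param x a `ct_volume` or `ct_binary`.
#' @return Numeric scalar, micrometres.
#' @export
voxel_size_um <- function(x) {
  v <- attr(x, "voxel_size_um")
  if (is.null(v)) stop("object carries no voxel size calibration")
  v
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<ct_volume> %d x %d x %d (z,y,x), %g um/voxel, %d-bit, grey [%g, %g]\n",
              d[1], d[2], d[3], voxel_size_um(x), attr(x, "bit_depth"),
              min(x), max(x)))
  invisible(x)
}

#' @export
print.ct_binary <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<ct_binary> %d x %d x %d (z,y,x), %g um/voxel, %d foreground voxels\n",
              d[1], d[2], d[3], voxel_size_um(x), sum(x)))
  invisible(x)
}

#' Rescale a volume to 16-bit depth
#'
#' Linearly maps the grey range `[range_lo, range_hi]` onto `[0, 65535]`,
#' clipping values outside the range to the nearest bound. Rounding is
#' round-half-up, so the midpoint of the range maps to 32768. This is the
#' conversion applied to 32-bit reconstructions before histogram alignment.
#'
#' @param volume a `ct_volume`.
#' @param range_lo,range_hi grey values mapped to 0 and 65535 (`range_hi`
#'   must exceed `range_lo`).
#' @return A 16-bit `ct_volume`.
#' @examples
#' v <- ct_volume(array(c(0, 50, 100), c(3, 1, 1)), 65)
#' as.vector(convert_to_16bit(v, 0, 100))
#' @export
convert_to_16bit <- function(volume, range_lo, range_hi) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!is.finite(range_lo) || !is.finite(range_hi) || range_hi <= range_lo)
    stop("degenerate range: `range_hi` must exceed `range_lo`")
  scaled <- (unclass(volume) - range_lo) / (range_hi - range_lo) * 65535
  out <- floor(scaled + 0.5)            # round half up
  out[out < 0] <- 0
  out[out > 65535] <- 65535
  ct_volume(out, voxel_size_um(volume), bit_depth = 16L)
}

#' Convert a scanner resolution in dots per inch to a pixel side length
#'
#' @param dpi positive resolution in dots per inch.
#' @return Pixel side length in micrometres (`25400 / dpi`).
#' @examples
#' dpi_to_um(600)  # ~42 um, the flatbed calibration used for washed roots
#' @export
dpi_to_um <- function(dpi) {
  if (!is.numeric(dpi) || any(dpi <= 0)) stop("`dpi` must be positive")
  25400 / dpi
}
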