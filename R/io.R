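#' Read a calibrated 3D volume from disk
#'
#' Reads either a multi-page greyscale TIFF stack (8/16-bit integer, or
#' float data stored in `[0, 1]`) or a raw little-endian binary file with a
#' JSON sidecar (`<path>.json` holding `dims`, `dtype` and `voxel_size_um`).
#' Slices are stacked along the first (z) axis, slice 1 first; within a
#' slice, rows map to y and columns to x.
#'
#' The voxel calibration is taken from the JSON sidecar when present; an
#' explicit `voxel_size_um` argument overrides it (with a warning if the two
#' disagree) and is required when no sidecar exists.
#'
#' @param path path to a `.tif`/`.tiff` stack or a `.raw` binary file.
#' @param voxel_size_um isotropic voxel side length in micrometres; optional
#'   if a sidecar provides it.
#' @return A [ct_volume].
#' @seealso [write_stack()]
#' @export
read_stack <- function(path, voxel_size_um = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else NULL
  if (!is.null(meta) && !is.null(meta$voxel_size_um)) {
    if (is.null(voxel_size_um)) {
      voxel_size_um <- meta$voxel_size_um
    } else if (!isTRUE(all.equal(voxel_size_um, meta$voxel_size_um))) {
      warning("voxel_size_um argument overrides a different sidecar value")
    }
  }
  if (is.null(voxel_size_um))
    stop("voxel_size_um not given and no sidecar metadata found")

  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
    if (length(unique(shapes)) != 1L)
      stop("inconsistent slice shape across TIFF pages")
    d <- dim(pages[[1]])
    if (length(d) != 2L) stop("only single-channel greyscale stacks are supported")
    bd <- attr(pages[[1]], "bits.per.sample")
    if (is.null(bd)) bd <- if (is.integer(pages[[1]])) 16L else 32L
    if (!bd %in% c(8L, 16L, 32L)) stop("unsupported bit depth: ", bd)
    vol <- array(0, c(length(pages), d[1], d[2]))
    for (z in seq_along(pages)) vol[z, , ] <- pages[[z]]
    return(ct_volume(vol, voxel_size_um, bit_depth = as.integer(bd)))
  }

  # raw binary + sidecar
  if (is.null(meta) || is.null(meta$dims) || is.null(meta$dtype))
    stop("raw volumes require a JSON sidecar with dims and dtype")
  dims <- as.integer(meta$dims)
  n <- prod(dims)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- switch(meta$dtype,
    uint8   = as.double(readBin(con, "integer", n, size = 1, signed = FALSE, endian = "little")),
    uint16  = as.double(readBin(con, "integer", n, size = 2, signed = FALSE, endian = "little")),
    float32 = readBin(con, "double", n, size = 4, endian = "little"),
    stop("unsupported dtype: ", meta$dtype))
  if (length(vals) != n) stop("raw file shorter than dims imply")
  bd <- switch(meta$dtype, uint8 = 8L, uint16 = 16L, float32 = 32L)
  ct_volume(array(vals, dims), voxel_size_um, bit_depth = bd)
}

#' Write a calibrated 3D volume to disk
#'
#' 8- and 16-bit volumes are written as multi-page greyscale TIFF
#' (bit-exact round trip through [read_stack()]); 32-bit float volumes are
#' written as raw little-endian binary. In both cases a JSON sidecar
#' `<path>.json` records `dims`, `dtype` and `voxel_size_um` so the
#' calibration survives containers without a resolution tag.
#'
#' @param volume a [ct_volume] or [ct_binary] (binaries are written 8-bit).
#' @param path output path; use `.tif`/`.tiff` for 8/16-bit volumes and
#'   `.raw` for 32-bit float.
#' @return `path`, invisibly.
#' @export
write_stack <- function(volume, path) {
  if (inherits(volume, "ct_binary"))
    volume <- ct_volume(unclass(volume) * 255, voxel_size_um(volume), bit_depth = 8L)
  stopifnot(inherits(volume, "ct_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  bd <- attr(volume, "bit_depth")
  d <- dim(volume)
  is_tiff <- grepl("\\.tiff?$", path, ignore.case = TRUE)

  if (bd %in% c(8L, 16L)) {
    if (!is_tiff) stop("8/16-bit volumes are written as TIFF; use a .tif path")
    denom <- 2^bd - 1
    pages <- lapply(seq_len(d[1]), function(z) matrix(volume[z, , ], d[2], d[3]) / denom)
    tiff::writeTIFF(pages, path, bits.per.sample = bd, compression = "none")
    dtype <- if (bd == 8L) "uint8" else "uint16"
  } else {
    if (is_tiff) stop("32-bit float volumes are written as raw binary; use a .raw path")
    con <- file(path, "wb")
    writeBin(as.vector(unclass(volume)), con, size = 4, endian = "little")
    close(con)
    dtype <- "float32"
  }
  jsonlite::write_json(
    list(dims = d, dtype = dtype, voxel_size_um = voxel_size_um(volume)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
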