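#' Root branch angle from three labelled points
#'
#' Computes the angle at the branch vertex between the vector towards a
#' point on the parent root and the vector towards a point on the daughter
#' branch, after scaling coordinates to physical units. The conventional
#' field measure places the parent point downstream (below) the vertex so
#' the angle is taken between the branch and the descending parent axis;
#' the function computes the geometric angle of whatever triplet is given.
#'
#' @param parent_point,vertex_point,branch_point numeric `(z, y, x)`
#'   coordinates (voxel or physical; with isotropic voxels the angle is
#'   identical).
#' @param voxel_size_um isotropic voxel size used to scale coordinates
#'   (default 1; irrelevant for isotropic grids but kept for interface
#'   symmetry).
#' @return Angle in degrees, in `[0, 180]`.
#' @examples
#' branch_angle(c(0, 0, 1), c(0, 0, 0), c(0, 1, 1))  # 45
#' @export
branch_angle <- function(parent_point, vertex_point, branch_point,
                         voxel_size_um = 1) {
  p <- (as.numeric(parent_point) - as.numeric(vertex_point)) * voxel_size_um
  b <- (as.numeric(branch_point) - as.numeric(vertex_point)) * voxel_size_um
  np <- sqrt(sum(p^2)); nb <- sqrt(sum(b^2))
  if (np == 0 || nb == 0)
    stop("degenerate triplet: parent and branch points must differ from the vertex")
  cosang <- sum(p * b) / (np * nb)
  cosang <- min(max(cosang, -1), 1)
  acos(cosang) * 180 / pi
}

#' Batch branch-angle measurement
#'
#' Replaces interactive three-click picking with a batch interface: a data
#' frame of point triplets in, a tibble of angles out. Columns follow the
#' `(z, y, x)` order used everywhere in the package.
#'
#' @param triplets data frame with columns `pz, py, px, vz, vy, vx, bz, by,
#'   bx` (and optionally `id`).
#' @param voxel_size_um isotropic voxel size (default 1).
#' @return A tibble with `id` and `angle_deg` (rounded to 2 decimals).
#' @export
branch_angles <- function(triplets, voxel_size_um = 1) {
  need <- c("pz", "py", "px", "vz", "vy", "vx", "bz", "by", "bx")
  if (!all(need %in% names(triplets)))
    stop("triplets need columns: ", paste(need, collapse = ", "))
  ids <- if ("id" %in% names(triplets)) triplets$id else seq_len(nrow(triplets))
  ang <- vapply(seq_len(nrow(triplets)), function(i) {
    branch_angle(c(triplets$pz[i], triplets$py[i], triplets$px[i]),
                 c(triplets$vz[i], triplets$vy[i], triplets$vx[i]),
                 c(triplets$bz[i], triplets$by[i], triplets$bx[i]),
                 voxel_size_um)
  }, 0)
  tibble::tibble(id = ids, angle_deg = round(ang, 2))
}

#' Superimpose a classified skeleton onto the root volume
#'
#' Produces a labelled volume for external point picking: background 0,
#' root 1, skeleton slab 2, junction 3, tip 4.
#'
#' @param root a [ct_binary] root volume.
#' @param skeleton a `root_skeleton` with matching dimensions.
#' @return A [ct_volume] (8-bit) of labels.
#' @export
overlay_skeleton <- function(root, skeleton) {
  stopifnot(inherits(root, "ct_binary"), inherits(skeleton, "root_skeleton"))
  if (!all(dim(root) == skeleton$dims))
    stop("root volume and skeleton dimensions differ")
  lab <- array(as.double(unclass(root)), dim(root))
  v <- skeleton$voxels
  code <- c(slab = 2, junction = 3, tip = 4)
  lab[cbind(v$z, v$y, v$x)] <- code[v$class]
  ct_volume(lab, voxel_size_um(root), bit_depth = 8L)
}
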