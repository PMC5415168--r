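#' Plot a grey-value histogram with an optional detected peak
#'
#' @param hist a `grey_histogram`.
#' @param peak optional `peak_info` from [find_peak()]; drawn as a vertical
#'   line.
#' @return A ggplot object.
#' @export
plot_grey_histogram <- function(hist, peak = NULL) {
  df <- tibble::tibble(grey = hist$bin_centers, count = hist$counts)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$grey, y = .data$count)) +
    ggplot2::geom_col(width = diff(hist$bin_edges)[1], fill = "grey40") +
    ggplot2::labs(x = "grey value", y = "voxel count")
  if (!is.null(peak))
    p <- p + ggplot2::geom_vline(xintercept = peak$peak_grey,
                                 colour = "red", linetype = 2)
  p
}

#' Plot a depth profile of root length density
#'
#' Depth increases downward, the orientation soil scientists expect.
#'
#' @param profile tibble from [depth_profile()].
#' @return A ggplot object.
#' @export
plot_depth_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$rld, y = .data$depth_mm)) +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = expression(RLD ~ (cm ~ cm^-3)), y = "depth (mm)")
}

#' Plot the branch length distribution
#'
#' @param branches tibble from [branch_decompose()].
#' @param bins histogram bin count (default 30).
#' @return A ggplot object.
#' @export
plot_branch_lengths <- function(branches, bins = 30) {
  df <- tibble::tibble(length_mm = branches$length_um / 1000)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length_mm)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40", colour = "white") +
    ggplot2::labs(x = "branch length (mm)", y = "count")
}
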