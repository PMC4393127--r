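# ggplot2 visualisations of detection results and endpoint trajectories.

#' Overlay detected nuclei and inclusions on a channel
#'
#' Raster of the chosen channel with nucleus outlines (centroid rings
#' sized by equivalent radius) and detected inclusions colored by
#' compartment. A quick visual check, not a publication figure.
#'
#' @param img Background channel matrix (e.g. EM48 or DAPI).
#' @param nuclei A `nucleus_set` (optional).
#' @param spots A `spot_set` (optional).
#' @return A ggplot object.
#' @export
plot_scene_overlay <- function(img, nuclei = NULL, spots = NULL) {
  df <- tibble::tibble(row = rep(seq_len(nrow(img)), ncol(img)),
                       col = rep(seq_len(ncol(img)), each = nrow(img)),
                       value = as.vector(img))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "col (px)", y = "row (px)", fill = "intensity")
  if (!is.null(nuclei) && nrow(nuclei$cells)) {
    nd <- dplyr::mutate(nuclei$cells, r = sqrt(.data$area_px / pi))
    p <- p + ggplot2::geom_point(
      data = nd, ggplot2::aes(x = .data$centroid_col, y = .data$centroid_row,
                              size = .data$r),
      shape = 1, colour = "deepskyblue", show.legend = FALSE)
  }
  if (!is.null(spots) && nrow(spots$spots)) {
    p <- p + ggplot2::geom_point(
      data = spots$spots,
      ggplot2::aes(x = .data$centroid_col, y = .data$centroid_row,
                   colour = .data$compartment), shape = 3, size = 2)
  }
  p
}

#' Plot endpoint trajectories across groups
#'
#' One panel per endpoint, one point per (animal, group) with a group-mean
#' line — the standard dot-plot view of an age series.
#'
#' @param object An `endpoint_table` (rows from one or more runs).
#' @param endpoints Endpoint columns to show (default the per-cell rate and
#'   mean inclusion size).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.endpoint_table <- function(object,
                                    endpoints = c("nuclear_inclusions_per_cell",
                                                  "mean_inclusion_size_um2"),
                                    ...) {
  endpoints <- intersect(endpoints, names(object))
  long <- tidyr::pivot_longer(
    dplyr::as_tibble(object)[, c("animal", "group", endpoints)],
    dplyr::all_of(endpoints), names_to = "endpoint")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.08),
                        alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "firebrick", linewidth = 0.3) +
    ggplot2::facet_wrap(~endpoint, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot pairwise comparisons of a group-stats fit
#'
#' Estimates with Sidak-adjusted significance tiers per endpoint.
#'
#' @param object An `htt_group_stats` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.htt_group_stats <- function(object, ...) {
  pw <- dplyr::mutate(object$pairwise,
                      contrast = paste(.data$group2, "-", .data$group1))
  ggplot2::ggplot(pw, ggplot2::aes(x = .data$estimate, y = .data$contrast)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$signif)) +
    ggplot2::facet_wrap(~endpoint, scales = "free_x") +
    ggplot2::labs(x = "difference of group means", y = NULL,
                  fill = "Sidak-adjusted")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
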