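# ggplot2 visualisations for the main result types. Occurrence tables,
# RMSF profiles and histograms are plain tibbles, so these are exported
# plot_*() helpers; fitted objects get autoplot() methods instead.

#' Plot an interaction occurrence table
#'
#' Residue-by-interaction-type heat map of occurrence percentages, coloured
#' by interaction type and shaded by occurrence.
#'
#' @param occ tibble from [occurrence_table()].
#' @return a ggplot object.
#' @export
plot_occurrence <- function(occ) {
  occ <- mutate(occ,
                residue = paste0(.data$resname, .data$resid, "/",
                                 .data$chain))
  ggplot2::ggplot(occ, ggplot2::aes(x = .data$type, y = .data$residue,
                                    fill = .data$percent)) +
    ggplot2::geom_tile(colour = "grey90") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.0f", .data$percent)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#3B6FB6",
                                 limits = c(0, 100),
                                 name = "% of frames") +
    ggplot2::labs(x = "Interaction type", y = "Residue") +
    ggplot2::theme_minimal()
}

#' Plot a per-residue RMSF profile
#'
#' @param rmsf tibble from [rmsf_per_residue()].
#' @return a ggplot object.
#' @export
plot_rmsf <- function(rmsf) {
  ggplot2::ggplot(rmsf, ggplot2::aes(x = .data$resid, y = .data$rmsf,
                                     colour = .data$chain)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Residue", y = "RMSF (Å)", colour = "Chain") +
    ggplot2::theme_minimal()
}

#' Plot the unique-model histogram
#'
#' Frequency of each distinct per-frame pharmacophore model against its
#' feature count, mirroring the usual unique-model scatter of dynamic
#' pharmacophore analyses.
#'
#' @param hist tibble from [model_histogram()].
#' @return a ggplot object.
#' @export
plot_model_histogram <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$n_features,
                                     y = .data$count)) +
    ggplot2::geom_point(alpha = 0.7, colour = "#3B6FB6") +
    ggplot2::labs(x = "Interaction features in model",
                  y = "Frequency (frames)") +
    ggplot2::theme_minimal()
}

#' 2D projection of a pharmacophore model
#'
#' Projects feature centers and exclusion volumes onto a chosen coordinate
#' plane; features are coloured by type, essential features outlined.
#'
#' @param object a `dynopharm_model`.
#' @param plane two coordinate names, e.g. `c("x", "y")`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dynopharm_model <- function(object, plane = c("x", "y"), ...) {
  ft <- left_join(object$features, feature_types(), by = "type")
  ev <- object$exclusion_volumes
  p <- ggplot2::ggplot()
  if (nrow(ev) > 0) {
    p <- p + ggplot2::geom_point(
      data = ev,
      ggplot2::aes(x = .data[[plane[1]]], y = .data[[plane[2]]]),
      colour = "grey70", size = 3, alpha = 0.5)
  }
  p +
    ggplot2::geom_point(
      data = ft,
      ggplot2::aes(x = .data[[plane[1]]], y = .data[[plane[2]]],
                   colour = .data$label,
                   shape = .data$flag,
                   size = .data$radius)) +
    ggplot2::scale_colour_manual(
      values = setNames(feature_types()$color, feature_types()$label),
      name = "Feature") +
    ggplot2::scale_shape_manual(values = c(essential = 17,
                                           optional = 16),
                                name = "Flag") +
    ggplot2::scale_size_continuous(range = c(3, 6), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste(plane[1], "(Å)"),
                  y = paste(plane[2], "(Å)")) +
    ggplot2::theme_minimal()
}
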