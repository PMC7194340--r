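#' Plot a spatial expression pattern over the bin geometry
#'
#' Lateral view of the embryo (x = anterior-posterior, z =
#' dorso-ventral), bins colored by the pattern value of one gene. Works
#' for atlas genes and for reconstructed outgroup patterns alike.
#'
#' @param patterns a [predicted_patterns()], [reference_atlas()] or bare
#'   bins-by-genes matrix.
#' @param geometry geometry tibble with matching bin count.
#' @param gene gene name to display.
#' @return a ggplot object.
#' @export
plot_pattern <- function(patterns, geometry, gene) {
  m <- if (inherits(patterns, "predicted_patterns")) patterns$values
       else if (inherits(patterns, "reference_atlas")) patterns$values
       else as.matrix(patterns)
  if (nrow(m) != nrow(geometry)) abort("pattern/geometry bin counts differ")
  if (!gene %in% colnames(m)) abort(sprintf("gene %s not in patterns", gene))
  df <- dplyr::mutate(geometry, value = m[, gene])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z, colour = .data$value)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_colour_viridis_c(name = gene) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "anterior-posterior (x)", y = "dorso-ventral (z)",
                  title = sprintf("Spatial pattern of %s", gene)) +
    ggplot2::theme_minimal()
}

#' Plot the performance-vs-iteration curve of a mapping
#' @param trace tibble from [performance_trace()].
#' @return a ggplot object.
#' @export
plot_performance_trace <- function(trace) {
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$iteration, y = .data$performance)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(breaks = trace$iteration) +
    ggplot2::labs(x = "iteration", y = "well-predicted cells (%)",
                  title = "Iterative refinement of cell positions") +
    ggplot2::theme_minimal()
}

#' Histogram of random-set baseline performance with the selected set marked
#' @param baseline tibble from [random_baseline()].
#' @param selected_performance performance (%) of the entropy-selected
#'   set, drawn as a vertical line; `NULL` to omit.
#' @return a ggplot object.
#' @export
plot_baseline <- function(baseline, selected_performance = NULL) {
  p <- ggplot2::ggplot(baseline, ggplot2::aes(x = .data$performance)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey65", colour = "grey30") +
    ggplot2::labs(x = "well-predicted cells (%)", y = "random gene sets",
                  title = "Random-set performance baseline") +
    ggplot2::theme_minimal()
  if (!is.null(selected_performance))
    p <- p + ggplot2::geom_vline(xintercept = selected_performance,
                                 colour = "red", linetype = 2)
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.cell_mapping <- function(object, ...) {
  best <- tibble::tibble(score = apply(unclass(object$scores), 1, max))
  ggplot2::ggplot(best, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey65", colour = "grey30") +
    ggplot2::labs(x = "best composite score per cell", y = "cells",
                  title = "Distribution of best-bin scores") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.position_eval <- function(object, ...) {
  df <- dplyr::count(object$per_cell, hit = factor(.data$hit, c(0, 1),
                                                   c("missed", "well predicted")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hit, y = .data$n)) +
    ggplot2::geom_col(fill = "grey65", colour = "grey30") +
    ggplot2::labs(x = NULL, y = "cells",
                  title = sprintf("%.1f%% of cells well predicted", object$performance)) +
    ggplot2::theme_minimal()
}
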