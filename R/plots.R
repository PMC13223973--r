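#' Violin plot of a signature score by group
#'
#' @param scores Tibble with `cell_id`, a score column, and a grouping
#'   column.
#' @param score Score column name (string).
#' @param group Grouping column name (string).
#' @return A ggplot.
#' @export
plot_score_violin <- function(scores, score, group) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data[[group]], y = .data[[score]],
                                       fill = .data[[group]])) +
    ggplot2::geom_violin(scale = "width", show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = score) +
    ggplot2::theme_minimal()
}

#' Gate diagnostic: score distributions with the malignancy threshold
#'
#' @param x A [malignancy_gate()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.malignancy_gate <- function(x, ...) {
  ggplot2::ggplot(x$calls, ggplot2::aes(x = .data$score, fill = .data$condition)) +
    ggplot2::geom_histogram(bins = 60, alpha = 0.6, position = "identity") +
    ggplot2::geom_vline(xintercept = x$threshold, linetype = "dashed") +
    ggplot2::labs(x = "malignancy score",
                  subtitle = sprintf("gate threshold = %.3f", x$threshold)) +
    ggplot2::theme_minimal()
}

#' Windowed CNV heatmap
#'
#' Cells by genomic windows, faceted by chromosome; red gains, blue losses.
#'
#' @param x A [infer_cnv_windows()] object.
#' @param max_cells Downsample cap for display (default 300).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cnv_profile <- function(x, max_cells = 300, ...) {
  cells <- rownames(x$scores)
  if (length(cells) > max_cells) cells <- cells[seq(1, length(cells), length.out = max_cells)]
  long <- as_tibble(x$scores[cells, , drop = FALSE], rownames = "cell_id") |>
    pivot_longer(-"cell_id", names_to = "window_id", values_to = "score") |>
    left_join(x$windows, by = "window_id")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$start_index, y = .data$cell_id,
                                     fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chromosome),
                        scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank()) +
    ggplot2::labs(x = "genomic window", y = "cell", fill = "CNV score")
}

#' Dot plot of communication probabilities
#'
#' @param result A [permutation_significance()] result.
#' @param max_p Show pairs with p at or below this (default 0.05).
#' @return A ggplot.
#' @export
plot_communication <- function(result, max_p = 0.05) {
  dat <- filter(result, .data$p_value <= max_p, .data$prob > 0) |>
    mutate(pair = paste(.data$ligand, .data$receptor, sep = " -> "),
           route = paste(.data$source, .data$target, sep = " -> "))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$route, y = .data$pair,
                                    size = .data$prob,
                                    color = -log10(.data$p_value))) +
    ggplot2::geom_point() +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, size = "probability", color = "-log10 p")
}

#' Neighborhood enrichment heatmap
#'
#' @param x A [neighborhood_enrichment()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.neighborhood_enrichment <- function(x, ...) {
  ggplot2::ggplot(tidy(x), ggplot2::aes(x = .data$type_a, y = .data$type_b,
                                        fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "z")
}

#' Spatial scatter of cells colored by a label
#'
#' @param cells Tibble with `x_um`, `y_um`.
#' @param color Column name to color by (string), e.g. `"type"` or
#'   `"niche"`.
#' @return A ggplot.
#' @export
plot_spatial <- function(cells, color) {
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                      color = factor(.data[[color]]))) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(color = color, x = "x (µm)", y = "y (µm)")
}
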