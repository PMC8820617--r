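## ggplot2 visualizations for the pipeline's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot descriptor importances
#'
#' Lollipop chart of the top descriptors by mean decrease in Gini
#' impurity.
#'
#' @param object An `importance_profile`.
#' @param top_n Number of descriptors to show (default 30).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot importance_profile
#' @export
autoplot.importance_profile <- function(object, top_n = 30, ...) {
  d <- tidy(object) |> dplyr::slice_head(n = top_n)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$descriptor, .data$importance)
  )) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = stats::reorder(
      .data$descriptor, .data$importance)), linewidth = 0.3) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(x = "mean decrease in Gini impurity", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cross-validation surface
#'
#' Mean CV accuracy against the scanned hyperparameters.
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  d <- tidy(object)
  hp <- setdiff(names(d), c("mean_accuracy", "sd_accuracy", "n_folds"))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data[[hp[1]]], y = .data$mean_accuracy,
    colour = factor(.data[[hp[2]]]), group = factor(.data[[hp[2]]])
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(y = "mean CV accuracy", colour = hp[2]) +
    ggplot2::theme_minimal()
}

#' Plot the screening cascade
#'
#' Bar chart of candidate counts at each cascade stage.
#'
#' @param object A `screen_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot screen_report
#' @export
autoplot.screen_report <- function(object, ...) {
  d <- object$counts |>
    dplyr::mutate(stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "molecules") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Two-component PCA projection of chemical space
#'
#' Projects a descriptor matrix onto its first two principal
#' components (computed on centered, unit-variance columns) for
#' chemical-space visualization, e.g. to compare training and test
#' sets or a screening library against the training domain.
#'
#' @param matrix Descriptor tibble.
#' @param labels Optional grouping vector aligned with the rows.
#' @return Tibble `id`, `PC1`, `PC2` (plus `label` when given), with
#'   the explained-variance fractions as attribute `explained`.
#' @export
pca_projection <- function(matrix, labels = NULL) {
  vals <- as.matrix(matrix[, setdiff(names(matrix), "id"), drop = FALSE])
  keep <- apply(vals, 2, sd) > 0
  pc <- stats::prcomp(vals[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  out <- tibble::tibble(id = matrix$id, PC1 = pc$x[, 1], PC2 = pc$x[, 2])
  if (!is.null(labels)) out$label <- as.character(labels)
  attr(out, "explained") <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  out
}

#' Plot a PCA chemical-space projection
#'
#' @param projection Output of [pca_projection()].
#' @return A ggplot.
#' @export
plot_chemical_space <- function(projection) {
  expl <- attr(projection, "explained")
  p <- ggplot2::ggplot(projection, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if ("label" %in% names(projection)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$label),
                                 alpha = 0.6, size = 1)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.6, size = 1)
  }
  p +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * expl[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * expl[2])
    ) +
    ggplot2::theme_minimal()
}
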