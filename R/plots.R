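#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heat-map of a class-activation map
#'
#' One panel per branch, grid cells coloured by normalised importance;
#' deeper colour, larger influence on the predicted interaction.
#'
#' @param object An [compute_cam()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot epi_cam
#' @export
autoplot.epi_cam <- function(object, ...) {
  grid_df <- function(m, branch) {
    tibble::tibble(
      branch = branch,
      row = rep(seq_len(nrow(m)), times = ncol(m)),
      col = rep(seq_len(ncol(m)), each = nrow(m)),
      importance = as.vector(m)
    )
  }
  df <- dplyr::bind_rows(grid_df(object$enhancer_grid, "enhancer"),
                         grid_df(object$promoter_grid, "promoter"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$importance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "red3",
                                 limits = c(0, 1)) +
    ggplot2::facet_wrap(~branch, scales = "free") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "importance",
                  title = sprintf("p(interaction) = %.3f", object$prob)) +
    ggplot2::theme_minimal()
}

#' Training curves of a fitted classifier
#'
#' @param object A trained `epi_cnn`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss by epoch.
#' @method autoplot epi_cnn
#' @export
autoplot.epi_cnn <- function(object, ...) {
  h <- tidy(object)
  df <- tidyr::pivot_longer(h[, c("epoch", "train_loss", "val_loss")],
                            -"epoch", names_to = "set", values_to = "loss")
  df <- df[!is.na(df$loss), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object$history, "best_epoch"),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy") +
    ggplot2::theme_minimal()
}

#' Heat-map of cross-cell-line performance
#'
#' @param object An [cross_cell_line_grid()] result.
#' @param metric `"aupr"` (default) or `"auc"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot epi_grid_result
#' @export
autoplot.epi_grid_result <- function(object, metric = c("aupr", "auc"), ...) {
  metric <- match.arg(metric)
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$train_cell_line,
                                   y = .data$test_cell_line,
                                   fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data[[metric]]))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "train cell line", y = "test cell line", fill = metric) +
    ggplot2::theme_minimal()
}

#' Heat-map of an overlap report
#'
#' @param object An [count_overlaps()] result.
#' @param ... Unused.
#' @return A ggplot of the pairwise overlap counts.
#' @method autoplot overlap_report
#' @export
autoplot.overlap_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comparison, y = .data$target,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "darkorange3") +
    ggplot2::labs(x = "comparison line", y = "target line",
                  title = sprintf("shared EPIs at omega0 = %g", object$omega0)) +
    ggplot2::theme_minimal()
}
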