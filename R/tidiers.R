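#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an overlap report
#'
#' @param x An [count_overlaps()] result.
#' @param ... Unused.
#' @return Long tibble: `target`, `comparison`, `target_total`,
#'   `comparison_total`, `count`, `omega0` (diagonal rows omitted).
#' @method tidy overlap_report
#' @export
tidy.overlap_report <- function(x, ...) {
  lines <- rownames(x$counts)
  g <- expand.grid(target = lines, comparison = lines,
                   stringsAsFactors = FALSE)
  g <- g[g$target != g$comparison, , drop = FALSE]
  tibble::tibble(
    target = g$target, comparison = g$comparison,
    target_total = unname(x$totals[g$target]),
    comparison_total = unname(x$totals[g$comparison]),
    count = x$counts[cbind(g$target, g$comparison)],
    omega0 = x$omega0
  )
}

#' Tidy a cross-cell-line grid
#'
#' @param x An [cross_cell_line_grid()] result.
#' @param ... Unused.
#' @return Long tibble: `test_cell_line`, `train_cell_line`, `auc`, `aupr`,
#'   `diagonal`.
#' @method tidy epi_grid_result
#' @export
tidy.epi_grid_result <- function(x, ...) {
  g <- expand.grid(test_cell_line = x$lines, train_cell_line = x$lines,
                   stringsAsFactors = FALSE)
  tibble::tibble(
    test_cell_line = g$test_cell_line,
    train_cell_line = g$train_cell_line,
    auc = x$auc[cbind(g$test_cell_line, g$train_cell_line)],
    aupr = x$aupr[cbind(g$test_cell_line, g$train_cell_line)],
    diagonal = g$test_cell_line == g$train_cell_line
  )
}

#' Per-epoch training history of a fitted classifier
#'
#' @param x A trained `epi_cnn`.
#' @param ... Unused.
#' @return The history tibble: `epoch`, `train_loss`, `val_loss`,
#'   `val_aupr`.
#' @method tidy epi_cnn
#' @export
tidy.epi_cnn <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history", call. = FALSE)
  tibble::as_tibble(x$history)
}

#' One-row summary of a fitted classifier
#'
#' @param x A trained `epi_cnn`.
#' @param ... Unused.
#' @return Tibble: `n_parameters`, `stopped_epoch`, `best_epoch`,
#'   `best_val_loss`, `best_val_aupr`.
#' @method glance epi_cnn
#' @export
glance.epi_cnn <- function(x, ...) {
  n_par <- sum(vapply(rapply(x$params, length, how = "unlist"), sum, numeric(1)))
  h <- x$history
  best <- if (!is.null(h)) attr(h, "best_epoch") else NA_integer_
  tibble::tibble(
    n_parameters = n_par,
    stopped_epoch = if (!is.null(h)) attr(h, "stopped_epoch") else NA_integer_,
    best_epoch = best,
    best_val_loss = if (!is.null(h) && !is.na(best) && best >= 1L)
      h$val_loss[best] else NA_real_,
    best_val_aupr = if (!is.null(h) && !is.na(best) && best >= 1L)
      h$val_aupr[best] else NA_real_
  )
}

#' @method glance epi_transfer_result
#' @export
glance.epi_transfer_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(strategy = x$plan$strategy, target = x$target,
                   pretrain_n = x$pretrain_n),
    x$evaluation
  )
}

#' Tidy a CAM into a per-position tibble
#'
#' @param x An [compute_cam()] result.
#' @param ... Unused.
#' @return Tibble: `branch`, `position`, `importance`.
#' @method tidy epi_cam
#' @export
tidy.epi_cam <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(branch = "enhancer",
                   position = seq_along(x$enhancer_positions),
                   importance = x$enhancer_positions),
    tibble::tibble(branch = "promoter",
                   position = seq_along(x$promoter_positions),
                   importance = x$promoter_positions)
  )
}
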