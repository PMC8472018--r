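#' Export an encoded tensor as TSV
#'
#' Long format, one row per non-trivial cell and channel: `row`, `col`,
#' `channel` (A/T/C/G), `value`, `curve_index`. Plain text, diff-able,
#' loadable anywhere.
#'
#' @param tensor An [encode_sequence()] result.
#' @param path Output TSV.
#' @param keep_zeros Write all cells, including zeros (default `FALSE`).
#' @export
write_tensor_tsv <- function(tensor, path, keep_zeros = FALSE) {
  stopifnot(inherits(tensor, "encoded_tensor"))
  g <- tensor$grid
  ch <- c("A", "T", "C", "G")
  df <- tibble::tibble(
    row = rep(rep(seq_len(g$side) - 1L, times = g$side), times = 4L),
    col = rep(rep(seq_len(g$side) - 1L, each = g$side), times = 4L),
    channel = rep(ch, each = g$side * g$side),
    value = as.vector(tensor$values)
  )
  df$curve_index <- g$index_of[cbind(df$row + 1L, df$col + 1L)]
  if (!keep_zeros) df <- df[df$value != 0, , drop = FALSE]
  readr::write_tsv(df, path)
  invisible(path)
}

#' Export an encoded tensor or CAM grid as PNG
#'
#' Encoded tensors render the four channels as colours (A green, T red,
#' C blue, G yellow; padding white); plain matrices render as a white-to-red
#' heat map. Pixel `(1,1)` is the grid's top-left cell, where the curve
#' starts.
#'
#' @param x An `encoded_tensor` or a numeric matrix in `[0, 1]`.
#' @param path Output PNG.
#' @export
write_png <- function(x, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("write_png() needs the png package", call. = FALSE)
  }
  if (inherits(x, "encoded_tensor")) {
    v <- x$values
    cols <- rbind(A = c(0, 0.7, 0), T = c(0.85, 0, 0),
                  C = c(0, 0.2, 0.9), G = c(0.9, 0.75, 0))
    img <- array(1, dim = c(dim(v)[1], dim(v)[2], 3))
    for (ch in 1:4) {
      for (rgb in 1:3) {
        img[, , rgb] <- img[, , rgb] - v[, , ch] * (1 - cols[ch, rgb])
      }
    }
  } else {
    m <- pmin(pmax(as.matrix(x), 0), 1)
    img <- array(1, dim = c(nrow(m), ncol(m), 3))
    img[, , 2] <- 1 - m
    img[, , 3] <- 1 - m
  }
  png::writePNG(img, path)
  invisible(path)
}
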