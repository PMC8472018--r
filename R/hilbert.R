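#' Hilbert curve grid descriptor
#'
#' A Hilbert curve of order `n` visits every cell of a `2^n x 2^n` grid
#' exactly once, with consecutive curve positions always in grid cells at
#' Manhattan distance 1. This locality is what makes the curve attractive
#' for laying a 1-D DNA sequence onto a 2-D grid: bases that are close along
#' the sequence stay close on the grid.
#'
#' The orientation is fixed package-wide: the curve starts at cell
#' `(row = 0, col = 0)` (top-left, rows indexed top-to-bottom) and ends at
#' `(row = side - 1, col = 0)`. The same orientation is used for encoding,
#' for training, and for projecting activation maps back onto sequences, so
#' the forward and inverse maps always agree.
#'
#' @param order Non-negative integer curve order `n`; the grid side is `2^n`
#'   and the curve has `4^n` cells.
#' @return An object of class `hilbert_grid` with fields `order`, `side`
#'   (`2^n`) and `n_cells` (`4^n`), plus cached forward (`rows`, `cols`,
#'   0-based, indexed by curve position) and inverse (`index_of`, a
#'   side-by-side matrix of curve indices) maps.
#' @examples
#' g <- hilbert_curve(2)
#' g$side      # 4
#' g$n_cells   # 16
#' @export
hilbert_curve <- function(order) {
  if (length(order) != 1L || is.na(order) || order < 0 || order != floor(order)) {
    stop("`order` must be a single non-negative integer", call. = FALSE)
  }
  order <- as.integer(order)
  side <- 2L^order
  n_cells <- side * side
  rc <- hilbert_d2rc(seq_len(n_cells) - 1L, order)
  index_of <- matrix(NA_integer_, side, side)
  index_of[cbind(rc$row + 1L, rc$col + 1L)] <- seq_len(n_cells) - 1L
  structure(
    list(order = order, side = side, n_cells = n_cells,
         rows = rc$row, cols = rc$col, index_of = index_of),
    class = "hilbert_grid"
  )
}

#' @export
print.hilbert_grid <- function(x, ...) {
  cat(sprintf("<hilbert_grid> order %d: %d x %d grid, %d cells\n",
              x$order, x$side, x$side, x$n_cells))
  invisible(x)
}

# Vectorised curve-index -> (row, col) via the standard bit-interleaving
# walk: peel two bits of d per level, rotate/reflect the quadrant frame.
# Orientation: d = 0 -> (0,0); d = 4^n - 1 -> (side-1, 0).
hilbert_d2rc <- function(d, order) {
  x <- integer(length(d))  # row
  y <- integer(length(d))  # col
  t <- as.double(d)        # doubles: 4^7 fits, but keep headroom for bit ops
  s <- 1
  side <- 2^order
  while (s < side) {
    rx <- floor(t / 2) %% 2
    ry <- floor(t) %% 2
    ry <- xor(ry == 1, rx == 1) * 1  # ry = bit0(t) XOR rx
    # rotate the s x s sub-square
    swap <- ry == 0
    flip <- swap & (rx == 1)
    xs <- x
    x[swap] <- y[swap]
    y[swap] <- xs[swap]
    x[flip] <- s - 1 - x[flip]
    y[flip] <- s - 1 - y[flip]
    x <- x + s * rx
    y <- y + s * ry
    t <- floor(t / 4)
    s <- s * 2
  }
  list(row = as.integer(x), col = as.integer(y))
}

#' Map Hilbert curve indices to grid cells
#'
#' Forward map of the canonical order-`n` Hilbert curve used throughout the
#' package: curve position `index` (0-based) to the 0-based `(row, col)` cell
#' it occupies. Vectorised over `index`.
#'
#' @param index Curve position(s), integers in `0 .. 4^order - 1`.
#' @param order Curve order.
#' @return A tibble with columns `index`, `row`, `col` (all 0-based).
#' @examples
#' curve_index_to_cell(0:3, order = 1)
#' @export
curve_index_to_cell <- function(index, order) {
  if (length(order) != 1L || is.na(order) || order < 0 || order != floor(order)) {
    stop("`order` must be a single non-negative integer", call. = FALSE)
  }
  n_cells <- 4^order
  if (any(is.na(index)) || any(index < 0) || any(index >= n_cells)) {
    stop(sprintf("curve index out of range [0, %d)", n_cells), call. = FALSE)
  }
  rc <- hilbert_d2rc(index, order)
  tibble::tibble(index = as.integer(index), row = rc$row, col = rc$col)
}

#' Map grid cells back to Hilbert curve indices
#'
#' Exact inverse of [curve_index_to_cell()]. Needed to carry per-cell
#' importance (activation maps) back to 1-D sequence positions.
#'
#' @param row,col 0-based cell coordinates; vectorised.
#' @param order Curve order.
#' @return Integer vector of curve indices.
#' @examples
#' cell_to_curve_index(0, 0, order = 1)  # 0
#' @export
cell_to_curve_index <- function(row, col, order) {
  if (length(order) != 1L || is.na(order) || order < 0 || order != floor(order)) {
    stop("`order` must be a single non-negative integer", call. = FALSE)
  }
  side <- 2L^order
  if (any(is.na(row)) || any(is.na(col)) ||
      any(row < 0) || any(row >= side) || any(col < 0) || any(col >= side)) {
    stop(sprintf("cell outside the %d x %d grid", side, side), call. = FALSE)
  }
  x <- as.double(row)
  y <- as.double(col)
  d <- numeric(length(x))
  s <- side / 2
  while (s >= 1) {
    rx <- (x >= s) * 1
    ry <- (y >= s) * 1
    # quadrant order under this orientation: (0,0), (0,1), (1,1), (1,0)
    q <- ifelse(rx == 0 & ry == 0, 0, ifelse(rx == 0 & ry == 1, 1,
         ifelse(rx == 1 & ry == 1, 2, 3)))
    d <- d + s * s * q
    x <- x - s * rx
    y <- y - s * ry
    # undo the sub-square rotation for the next level
    swap <- q == 0 | q == 3
    flip <- q == 3
    x[flip] <- s - 1 - x[flip]
    y[flip] <- s - 1 - y[flip]
    xs <- x
    x[swap] <- y[swap]
    y[swap] <- xs[swap]
    s <- s / 2
  }
  as.integer(d)
}

#' Smallest curve order holding a sequence
#'
#' Returns the smallest order `n` with `4^n >= sequence_length`, i.e. the
#' most compact Hilbert grid a sequence fits on. A 3000-bp enhancer and a
#' 2000-bp promoter both need order 6 (a 64 x 64 grid).
#'
#' @param sequence_length Positive integer length in bases; vectorised.
#' @return Integer order(s).
#' @examples
#' choose_order(3000)  # 6
#' choose_order(1024)  # 5
#' @export
choose_order <- function(sequence_length) {
  if (any(is.na(sequence_length)) || any(sequence_length < 1)) {
    stop("`sequence_length` must be >= 1", call. = FALSE)
  }
  vapply(sequence_length, function(len) {
    n <- 0L
    while (4^n < len) n <- n + 1L
    n
  }, integer(1))
}
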