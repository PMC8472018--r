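#' One-hot encode a nucleotide
#'
#' Channel convention, fixed package-wide: `A = [1,0,0,0]`, `T = [0,1,0,0]`,
#' `C = [0,0,1,0]`, `G = [0,0,0,1]`. Parsing is case-insensitive and `U` is
#' read as `T`; every other character (ambiguity codes, padding `N`, gaps)
#' maps to the zero vector so it contributes no channel mass.
#'
#' @param base Character vector of single characters.
#' @return A `length(base) x 4` numeric matrix with columns `A`, `T`, `C`, `G`.
#' @examples
#' encode_base(c("A", "g", "N"))
#' @export
encode_base <- function(base) {
  m <- base_onehot_matrix()
  idx <- match(toupper(base), rownames(m))
  out <- matrix(0, length(base), 4L, dimnames = list(NULL, colnames(m)))
  hit <- !is.na(idx)
  out[hit, ] <- m[idx[hit], , drop = FALSE]
  out
}

base_onehot_matrix <- function() {
  m <- rbind(
    A = c(1, 0, 0, 0),
    T = c(0, 1, 0, 0),
    C = c(0, 0, 1, 0),
    G = c(0, 0, 0, 1),
    U = c(0, 1, 0, 0)
  )
  colnames(m) <- c("A", "T", "C", "G")
  m
}

#' Encode a DNA sequence onto a Hilbert grid
#'
#' Writes base `i` of the sequence (1-based) into the grid cell at curve
#' position `i - 1` of the canonical Hilbert curve, one channel per base
#' (see [encode_base()]). Cells beyond the end of the sequence stay zero
#' (tail padding; the position map stays invertible). The total mass of the
#' tensor equals the number of unambiguous A/C/G/T characters.
#'
#' @param sequence A single DNA string.
#' @param order Curve order; defaults to [choose_order()] of the sequence
#'   length, the most compact grid that fits.
#' @return An object of class `encoded_tensor`: list with `values`
#'   (`side x side x 4` array, channels A/T/C/G), `grid` (a
#'   [hilbert_curve()] descriptor) and `seq_length`.
#' @examples
#' et <- encode_sequence("ACGT", order = 1)
#' sum(et$values)  # 4
#' @export
encode_sequence <- function(sequence, order = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  len <- nchar(sequence)
  if (len < 1L) stop("`sequence` must be non-empty", call. = FALSE)
  if (is.null(order)) order <- choose_order(len)
  grid <- hilbert_curve(order)
  if (len > grid$n_cells) {
    stop(sprintf("sequence of length %d exceeds grid capacity %d (order %d)",
                 len, grid$n_cells, order), call. = FALSE)
  }
  values <- array(0, dim = c(grid$side, grid$side, 4L))
  onehot <- encode_base(strsplit(sequence, "", fixed = TRUE)[[1]])
  rows <- grid$rows[seq_len(len)] + 1L
  cols <- grid$cols[seq_len(len)] + 1L
  for (ch in 1:4) {
    values[cbind(rows, cols, ch)] <- onehot[, ch]
  }
  structure(
    list(values = values, grid = grid, seq_length = len),
    class = "encoded_tensor"
  )
}

#' @export
print.encoded_tensor <- function(x, ...) {
  cat(sprintf("<encoded_tensor> %d x %d x 4 (order %d), %d positions, mass %g\n",
              x$grid$side, x$grid$side, x$grid$order, x$seq_length,
              sum(x$values)))
  invisible(x)
}

#' Project per-cell importance back onto sequence positions
#'
#' The inverse of the Hilbert layout: given a `side x side` grid of
#' importance scores (e.g. a class-activation map), returns the score of the
#' cell each sequence position occupies. Cells at curve index >=
#' `seq_length` carry padding, not sequence, and are discarded.
#'
#' @param importance_grid A `side x side` numeric matrix.
#' @param grid A [hilbert_curve()] descriptor (or an integer order).
#' @param seq_length Number of sequence positions actually placed.
#' @return Numeric vector of length `seq_length`; element `i` is the
#'   importance of the grid cell holding base `i`.
#' @export
cell_importance_to_positions <- function(importance_grid, grid, seq_length) {
  if (!inherits(grid, "hilbert_grid")) grid <- hilbert_curve(grid)
  if (!is.matrix(importance_grid) ||
      nrow(importance_grid) != grid$side || ncol(importance_grid) != grid$side) {
    stop(sprintf("`importance_grid` must be a %d x %d matrix",
                 grid$side, grid$side), call. = FALSE)
  }
  if (seq_length < 0 || seq_length > grid$n_cells) {
    stop("`seq_length` outside grid capacity", call. = FALSE)
  }
  if (seq_length == 0) return(numeric(0))
  idx <- seq_len(seq_length)
  importance_grid[cbind(grid$rows[idx] + 1L, grid$cols[idx] + 1L)]
}

# Encode a pairs tibble into the stacked arrays the model consumes:
# E: (side_e, side_e, 4, N), P: (side_p, side_p, 4, N), label: numeric N.
encode_pairs <- function(pairs, enhancer_order = NULL, promoter_order = NULL) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 1)
  need <- c("enhancer_seq", "promoter_seq", "label")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) {
    stop("`pairs` lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(enhancer_order)) enhancer_order <- choose_order(max(nchar(pairs$enhancer_seq)))
  if (is.null(promoter_order)) promoter_order <- choose_order(max(nchar(pairs$promoter_seq)))
  E <- encode_many(pairs$enhancer_seq, enhancer_order)
  P <- encode_many(pairs$promoter_seq, promoter_order)
  structure(
    list(E = E, P = P, label = as.numeric(pairs$label),
         enhancer_order = enhancer_order, promoter_order = promoter_order,
         enhancer_len = nchar(pairs$enhancer_seq[1]),
         promoter_len = nchar(pairs$promoter_seq[1]),
         n = nrow(pairs)),
    class = "epi_tensors"
  )
}

# Stack encodings of many same-length sequences; vectorised over positions.
encode_many <- function(seqs, order) {
  grid <- hilbert_curve(order)
  side <- grid$side
  n <- length(seqs)
  lens <- nchar(seqs)
  if (any(lens > grid$n_cells)) {
    stop("sequence exceeds grid capacity at order ", order, call. = FALSE)
  }
  out <- array(0, dim = c(side, side, 4L, n))
  m <- base_onehot_matrix()
  plane <- side * side
  for (i in seq_len(n)) {
    chars <- strsplit(toupper(seqs[i]), "", fixed = TRUE)[[1]]
    ch_idx <- match(chars, rownames(m))
    pos <- which(!is.na(ch_idx))
    if (!length(pos)) next
    channel <- max.col(m[ch_idx[pos], , drop = FALSE])  # one-hot -> column
    cell <- grid$rows[pos] + 1L + side * grid$cols[pos]  # linear index in plane
    out[(i - 1L) * 4L * plane + (channel - 1L) * plane + cell] <- 1
  }
  out
}
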