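test_that("curve origin, endpoints and the order-1 square match the fixed orientation", {
  g <- hilbert_curve(1)
  expect_equal(curve_index_to_cell(0, 1)$row, 0L)
  expect_equal(curve_index_to_cell(0, 1)$col, 0L)
  # curve ends at bottom-left under the package orientation
  expect_equal(g$rows[g$n_cells], g$side - 1L)
  expect_equal(g$cols[g$n_cells], 0L)
  # four distinct cells, consecutive ones adjacent
  rc <- curve_index_to_cell(0:3, 1)
  expect_equal(nrow(unique(rc[, c("row", "col")])), 4L)
  expect_true(all(abs(diff(rc$row)) + abs(diff(rc$col)) == 1))
})

test_that("forward and inverse maps agree with the recursive-subdivision oracle", {
  for (n in 1:4) {
    oracle <- oracle_hilbert(n)
    rc <- curve_index_to_cell(seq_len(4^n) - 1, n)
    expect_equal(rc$row, oracle[, 1], info = paste("order", n))
    expect_equal(rc$col, oracle[, 2], info = paste("order", n))
    expect_equal(cell_to_curve_index(oracle[, 1], oracle[, 2], n),
                 seq_len(4^n) - 1L, info = paste("order", n))
  }
})

test_that("bijectivity, adjacency, self-similarity and round-trip hold for orders 1-7", {
  for (n in 1:7) {
    g <- hilbert_curve(n)
    cells <- g$rows * g$side + g$cols
    expect_equal(length(unique(cells)), g$n_cells)
    expect_true(all(abs(diff(g$rows)) + abs(diff(g$cols)) == 1))
    # first quarter of the curve fills exactly one half-size quadrant
    q <- seq_len(4^(n - 1))
    expect_true(all(g$rows[q] < g$side / 2) && all(g$cols[q] < g$side / 2))
    # exact inverse
    expect_identical(cell_to_curve_index(g$rows, g$cols, n),
                     seq_len(g$n_cells) - 1L)
  }
})

test_that("out-of-range cells and indices are rejected", {
  expect_error(curve_index_to_cell(16, 2), "out of range")
  expect_error(curve_index_to_cell(-1, 2), "out of range")
  expect_error(curve_index_to_cell(0, -1), "non-negative")
  expect_error(cell_to_curve_index(4, 0, 2), "outside")
})

test_that("choose_order returns the most compact grid", {
  expect_equal(choose_order(3000), 6L)
  expect_equal(choose_order(2000), 6L)
  expect_equal(choose_order(1024), 5L)
  expect_equal(choose_order(1025), 6L)
  expect_equal(choose_order(1), 0L)
  expect_error(choose_order(0), ">= 1")
  # minimality and sufficiency across a range
  for (len in c(2, 5, 16, 17, 255, 256, 257)) {
    n <- choose_order(len)
    expect_true(4^n >= len)
    expect_true(n == 0 || 4^(n - 1) < len)
  }
})

test_that("base encoding maps ACGT to the four basis vectors and all else to zero", {
  expect_equal(encode_base("A")[1, ], c(A = 1, T = 0, C = 0, G = 0))
  expect_equal(encode_base("G")[1, ], c(A = 0, T = 0, C = 0, G = 1))
  expect_equal(unname(encode_base("N")[1, ]), rep(0, 4))
  expect_equal(unname(encode_base("-")[1, ]), rep(0, 4))
  expect_equal(encode_base("a"), encode_base("A"))  # case-insensitive
  expect_equal(encode_base("U"), encode_base("T"))  # RNA read as DNA
})

test_that("a 4-mer encodes onto the order-1 grid in curve order", {
  et <- encode_sequence("ACGT", order = 1)
  g <- hilbert_curve(1)
  expected <- list(c(1, 0, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1), c(0, 1, 0, 0))
  for (d in 1:4) {
    expect_equal(unname(et$values[g$rows[d] + 1, g$cols[d] + 1, ]), expected[[d]],
                 info = paste("curve index", d - 1))
  }
})

test_that("encoding conserves base mass and zeroes padding and ambiguity", {
  expect_equal(sum(encode_sequence(strrep("N", 10))$values), 0)
  seq3000 <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  et <- encode_sequence(seq3000)
  expect_equal(dim(et$values), c(64, 64, 4))
  expect_equal(sum(et$values), 3000)
  # per-cell channel sums are 0 or 1; all-zero beyond the sequence end
  sums <- apply(et$values, c(1, 2), sum)
  expect_true(all(sums %in% c(0, 1)))
  g <- et$grid
  tail_idx <- (et$seq_length + 1):g$n_cells
  expect_equal(sum(et$values[cbind(g$rows[tail_idx] + 1, g$cols[tail_idx] + 1, 1)]), 0)
  expect_error(encode_sequence("ACGTA", order = 1), "capacity")
})

test_that("grid importance projects back to positions losslessly", {
  g <- hilbert_curve(3)
  expect_equal(cell_importance_to_positions(matrix(0.7, 8, 8), g, 20), rep(0.7, 20))
  # single hot cell at curve index 7 -> importance at sequence position 8
  m <- matrix(0, 8, 8)
  m[g$rows[8] + 1, g$cols[8] + 1] <- 1
  v <- cell_importance_to_positions(m, g, 30)
  expect_equal(which(v == 1), 8L)
  # scatter a random vector, read it back
  L <- 50
  x <- rnorm(L)
  m2 <- matrix(0, 8, 8)
  m2[cbind(g$rows[1:L] + 1, g$cols[1:L] + 1)] <- x
  expect_equal(cell_importance_to_positions(m2, g, L), x)
  expect_error(cell_importance_to_positions(matrix(0, 4, 4), g, 10), "8 x 8")
})

test_that("the Hilbert layout keeps distant sequence offsets closer than a raster layout", {
  # raster rows have length `side`; away from multiples of the row length
  # the raster separation grows linearly with the offset while the Hilbert
  # separation grows like sqrt(offset). (Offsets at or next to a multiple of
  # `side` are the one regime where the raster wraps to a near-vertical
  # neighbour and wins.)
  n <- 6
  side <- 2^n
  g <- hilbert_curve(n)
  mean_dist <- function(k) {
    i <- seq_len(4^n - k)
    d_h <- mean(sqrt((g$rows[i] - g$rows[i + k])^2 +
                       (g$cols[i] - g$cols[i + k])^2))
    r_row <- (i - 1) %/% side
    r_col <- (i - 1) %% side
    r_row2 <- (i + k - 1) %/% side
    r_col2 <- (i + k - 1) %% side
    d_r <- mean(sqrt((r_row - r_row2)^2 + (r_col - r_col2)^2))
    c(hilbert = d_h, raster = d_r)
  }
  for (k in c(8, 16, 32, 48)) {
    d <- mean_dist(k)
    expect_lt(d["hilbert"], d["raster"])
  }
  # and on average over all within-row offsets
  avg <- rowMeans(vapply(2:63, mean_dist, numeric(2)))
  expect_lt(avg["hilbert"], avg["raster"])
})
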