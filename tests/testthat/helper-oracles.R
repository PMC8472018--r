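# Independent oracles, implemented from first principles and kept free of
# any package internals they are used to check.

# Hilbert curve by explicit recursive quadrant subdivision: the order-n
# curve is four order-(n-1) curves — transposed copy, two translated
# copies, anti-transposed copy — visited in quadrant order
# (0,0) -> (0,1) -> (1,1) -> (1,0). Returns a list of (row, col) in curve
# order, 0-based.
oracle_hilbert <- function(order) {
  if (order == 0) return(matrix(c(0, 0), 1, 2))
  prev <- oracle_hilbert(order - 1)
  s <- 2^(order - 1)
  q1 <- cbind(prev[, 2], prev[, 1])                     # transpose
  q2 <- cbind(prev[, 1], prev[, 2] + s)                 # shift right
  q3 <- cbind(prev[, 1] + s, prev[, 2] + s)             # shift down-right
  q4 <- cbind(s - 1 - prev[, 2] + s, s - 1 - prev[, 1]) # anti-transpose, down
  rbind(q1, q2, q3, q4)
}

# AUC by exhaustive pairwise comparison (ties count 1/2).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Average precision by explicit walk down the (tie-grouped) score order.
oracle_aupr <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  npos <- sum(y)
  ap <- 0
  tp <- 0
  seen <- 0
  for (v in unique(s)) {
    grp <- which(s == v)
    tp_new <- tp + sum(y[grp])
    seen_new <- seen + length(grp)
    ap <- ap + (tp_new - tp) / npos * (tp_new / seen_new)
    tp <- tp_new
    seen <- seen_new
  }
  ap
}

# Overlap-count matrix by a plain double loop over every pair of positives.
oracle_overlap_counts <- function(pairs, omega0) {
  pos <- pairs[pairs$label == 1, , drop = FALSE]
  lines <- unique(pairs$cell_line)
  ratio <- function(a, b) {
    ea <- strsplit(a$enhancer_seq, "")[[1]]; eb <- strsplit(b$enhancer_seq, "")[[1]]
    pa <- strsplit(a$promoter_seq, "")[[1]]; pb <- strsplit(b$promoter_seq, "")[[1]]
    m <- sum(ea == eb & ea != "N") + sum(pa == pb & pa != "N")
    m / (length(ea) + length(pa))
  }
  cnt <- matrix(NA_integer_, length(lines), length(lines),
                dimnames = list(lines, lines))
  for (a in lines) for (b in lines) {
    if (a == b) next
    ta <- pos[pos$cell_line == a, ]
    tb <- pos[pos$cell_line == b, ]
    n <- 0L
    for (i in seq_len(nrow(ta))) {
      for (j in seq_len(nrow(tb))) {
        if (ratio(ta[i, ], tb[j, ]) >= omega0) { n <- n + 1L; break }
      }
    }
    cnt[a, b] <- n
  }
  cnt
}

# Small deterministic pairs tibble for I/O and balancing tests.
make_toy_pairs <- function(n_pos, n_neg, enh_len = 30, prom_len = 20, seed = 1) {
  withr::with_seed(seed, {
    n <- n_pos + n_neg
    rand <- function(k, len) {
      vapply(seq_len(k), function(i)
        paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""), "")
    }
    tibble::tibble(
      enhancer_id = sprintf("e%04d", seq_len(n)),
      promoter_id = sprintf("p%04d", seq_len(n)),
      enhancer_seq = rand(n, enh_len),
      promoter_seq = rand(n, prom_len),
      label = rep(c(1L, 0L), c(n_pos, n_neg)),
      cell_line = "toy"
    )
  })
}

# Tiny model config used wherever a test only needs the mechanics, not
# predictive power.
tiny_config <- function(seed = 1, ...) {
  epi_model_config(conv_filters = c(2, 3), dense_units = 4, dropout_rate = 0,
                   learning_rate = 1e-3, batch_size = 8, max_epochs = 2,
                   early_stop_patience = 2, seed = seed, ...)
}

motif_kmers <- function(motif, k) {
  unique(substring(motif, seq_len(nchar(motif) - k + 1),
                   seq_len(nchar(motif) - k + 1) + k - 1))
}
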