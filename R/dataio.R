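#' Read a labeled enhancer-promoter pair table
#'
#' Reads a TSV/CSV pair list with one enhancer-promoter pair per row.
#' Required columns: `enhancer_id`, `promoter_id`, `enhancer_seq`,
#' `promoter_seq`, `label` (0/1); an optional `cell_line` column is kept
#' (otherwise filled with `cell_line`). Sequences are upper-cased; any
#' character outside `A/C/G/T/N` is masked to `N` with a warning. Rows with
#' a missing field or a label outside {0,1} are dropped with a warning that
#' cites their line numbers.
#'
#' @param path Path to a delimited file; delimiter guessed from the
#'   extension (`.csv` = comma, otherwise tab).
#' @param cell_line Fallback cell-line tag when the file carries none.
#' @return A tibble of pairs (possibly empty, with a warning).
#' @export
read_pairs_tsv <- function(path, cell_line = "unknown") {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  need <- c("enhancer_id", "promoter_id", "enhancer_seq", "promoter_seq", "label")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("pair file lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    warning("empty pair file: ", path, call. = FALSE)
    return(empty_pairs())
  }
  if (!"cell_line" %in% names(raw)) raw$cell_line <- cell_line

  bad_field <- !stats::complete.cases(raw[, need])
  bad_label <- !raw$label %in% c("0", "1")
  bad <- bad_field | (bad_label & !bad_field)
  if (any(bad)) {
    warning(sprintf("dropped %d malformed row(s) at line(s) %s", sum(bad),
                    paste(which(bad) + 1L, collapse = ", ")), call. = FALSE)
    raw <- raw[!bad, , drop = FALSE]
  }

  out <- tibble::tibble(
    enhancer_id = raw$enhancer_id,
    promoter_id = raw$promoter_id,
    enhancer_seq = clean_dna(raw$enhancer_seq),
    promoter_seq = clean_dna(raw$promoter_seq),
    label = as.integer(raw$label),
    cell_line = raw$cell_line
  )
  out
}

empty_pairs <- function() {
  tibble::tibble(enhancer_id = character(), promoter_id = character(),
                 enhancer_seq = character(), promoter_seq = character(),
                 label = integer(), cell_line = character())
}

clean_dna <- function(x) {
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    warning(sprintf("%d sequence(s) contained non-ACGTN characters; masked to N",
                    sum(bad)), call. = FALSE)
    x[bad] <- gsub("[^ACGTN]", "N", x[bad])
  }
  x
}

#' Build a pair dataset from BED intervals and a genome FASTA
#'
#' Resolves enhancer and promoter BED intervals (0-based half-open) against
#' a genome FASTA, reverse-complementing minus-strand intervals, and joins
#' them through a pair list (`enhancer_id`, `promoter_id`, `label`).
#' Intervals falling outside their contig and pair rows referencing an
#' absent id are skipped, with a message reporting the counts.
#'
#' @param enhancer_bed,promoter_bed BED files naming intervals (the BED
#'   `name` field is the id joined against the pair list).
#' @param pair_list TSV with columns `enhancer_id`, `promoter_id`, `label`.
#' @param genome_fasta FASTA of the reference contigs.
#' @param cell_line Cell-line tag attached to every pair.
#' @return A tibble of pairs as in [read_pairs_tsv()].
#' @export
read_pairs_bed <- function(enhancer_bed, promoter_bed, pair_list, genome_fasta,
                           cell_line = "unknown") {
  if (!requireNamespace("Biostrings", quietly = TRUE) ||
      !requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_pairs_bed() needs the Biostrings and rtracklayer packages",
         call. = FALSE)
  }
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))

  enh <- bed_to_seqs(enhancer_bed, genome)
  prom <- bed_to_seqs(promoter_bed, genome)

  pl <- readr::read_tsv(pair_list, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  ei <- match(pl$enhancer_id, names(enh))
  pi <- match(pl$promoter_id, names(prom))
  ok <- !is.na(ei) & !is.na(pi)
  if (any(!ok)) {
    message(sprintf("skipped %d pair(s) referencing unresolved intervals", sum(!ok)))
  }
  tibble::tibble(
    enhancer_id = pl$enhancer_id[ok],
    promoter_id = pl$promoter_id[ok],
    enhancer_seq = clean_dna(unname(enh[ei[ok]])),
    promoter_seq = clean_dna(unname(prom[pi[ok]])),
    label = as.integer(pl$label[ok]),
    cell_line = cell_line
  )
}

# BED (via rtracklayer, so 0-based half-open handled there) -> named
# character vector of sequences; minus strand reverse-complemented.
bed_to_seqs <- function(bed_path, genome) {
  gr <- rtracklayer::import(bed_path, format = "BED")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  starts <- GenomicRanges::start(gr)   # 1-based after import
  ends <- GenomicRanges::end(gr)
  strands <- as.character(GenomicRanges::strand(gr))
  ids <- gr$name
  out <- character(0)
  n_skip <- 0L
  for (i in seq_along(gr)) {
    ctg <- genome[[chrom[i]]]
    if (is.null(ctg) || starts[i] < 1L || ends[i] > length(ctg)) {
      n_skip <- n_skip + 1L
      next
    }
    s <- Biostrings::subseq(ctg, starts[i], ends[i])
    if (strands[i] == "-") s <- Biostrings::reverseComplement(s)
    out[ids[i]] <- as.character(s)
  }
  if (n_skip > 0L) message(sprintf("skipped %d interval(s) outside their contig", n_skip))
  out
}

#' Enforce the fixed enhancer/promoter lengths
#'
#' Trims or pads every sequence to the configured fixed lengths: longer
#' sequences are centre-trimmed (equal amounts off both flanks, the extra
#' base off the right flank when the excess is odd); shorter sequences are
#' symmetrically `N`-padded (extra `N` on the right flank when the deficit
#' is odd).
#'
#' @param pairs A pairs tibble.
#' @param enhancer_len,promoter_len Target lengths in bp (defaults 3000 and
#'   2000, the fixed lengths used throughout).
#' @return The pairs tibble with every sequence at its exact target length.
#' @export
enforce_length <- function(pairs, enhancer_len = 3000, promoter_len = 2000) {
  pairs$enhancer_seq <- fit_length(pairs$enhancer_seq, enhancer_len)
  pairs$promoter_seq <- fit_length(pairs$promoter_seq, promoter_len)
  pairs
}

fit_length <- function(seqs, target) {
  lens <- nchar(seqs)
  if (any(lens == 0L)) stop("empty sequence cannot be length-normalised", call. = FALSE)
  long <- lens > target
  if (any(long)) {
    start <- (lens[long] - target) %/% 2 + 1L
    seqs[long] <- substr(seqs[long], start, start + target - 1L)
  }
  short <- lens < target
  if (any(short)) {
    deficit <- target - lens[short]
    left <- deficit %/% 2
    right <- deficit - left
    seqs[short] <- paste0(strrep("N", left), seqs[short], strrep("N", right))
  }
  seqs
}

#' Over-sample positive pairs by replication with shift augmentation
#'
#' Balances an imbalanced dataset from the minority side: every positive
#' pair is replicated `factor` times. The first copy is the original; each
#' additional copy has its enhancer and promoter independently shifted by a
#' uniform random offset in `-shift_window .. +shift_window` bp, with
#' vacated positions filled with `N` (so the length never changes).
#' `shift_window = 0` gives exact duplication. `factor = "auto"` uses
#' `round(n_negative / n_positive)` — with the canonical 20:1 imbalance this
#' is 20, e.g. 1977 positives against 39,500 negatives become 39,540.
#'
#' @param pairs A pairs tibble.
#' @param factor Integer replication factor >= 1, or `"auto"`.
#' @param shift_window Maximum absolute shift in bp (default 50).
#' @param seed Seed for the shift offsets.
#' @return The pairs tibble with `factor` x the original positive count
#'   (negatives untouched). Augmented copies get an `_augK` id suffix.
#' @export
over_sample_positives <- function(pairs, factor = "auto", shift_window = 50,
                                  seed = 1L) {
  n_pos <- sum(pairs$label == 1)
  n_neg <- sum(pairs$label == 0)
  if (identical(factor, "auto")) {
    if (n_pos == 0L) stop("cannot auto-balance with no positives", call. = FALSE)
    factor <- round(n_neg / n_pos)
  }
  if (!is.numeric(factor) || factor < 1 || factor != floor(factor)) {
    stop("`factor` must be an integer >= 1 or \"auto\"", call. = FALSE)
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(pairs)

  pos <- pairs[pairs$label == 1, , drop = FALSE]
  neg <- pairs[pairs$label == 0, , drop = FALSE]
  copies <- vector("list", factor - 1L)
  withr::with_seed(seed, {
    for (k in seq_len(factor - 1L)) {
      cp <- pos
      cp$enhancer_seq <- shift_seqs(cp$enhancer_seq, shift_window)
      cp$promoter_seq <- shift_seqs(cp$promoter_seq, shift_window)
      cp$enhancer_id <- paste0(cp$enhancer_id, "_aug", k)
      cp$promoter_id <- paste0(cp$promoter_id, "_aug", k)
      copies[[k]] <- cp
    }
  })
  dplyr::bind_rows(pos, copies, neg)
}

# Shift each sequence by its own uniform offset in [-w, w]; N-fill vacated
# positions. Positive offset slides the sequence rightwards.
shift_seqs <- function(seqs, w) {
  if (w == 0) return(seqs)
  offs <- sample(-w:w, length(seqs), replace = TRUE)
  lens <- nchar(seqs)
  mapply(function(s, off, len) {
    if (off == 0) return(s)
    a <- abs(off)
    if (a >= len) return(strrep("N", len))
    if (off > 0) paste0(strrep("N", a), substr(s, 1L, len - a))
    else paste0(substr(s, a + 1L, len), strrep("N", a))
  }, seqs, offs, lens, USE.NAMES = FALSE)
}

#' Under-sample negative pairs
#'
#' Balances from the majority side: keeps a uniform random subset of the
#' negatives of size `min(target_count, available)`; positives are never
#' touched. Deterministic for a fixed seed.
#'
#' @param pairs A pairs tibble.
#' @param target_count Number of negatives to retain (e.g. the positive
#'   count, matching the canonical balanced sets: 39,500 negatives
#'   sub-sampled to 1977).
#' @param seed Seed for the subset draw.
#' @return The pairs tibble with at most `target_count` negatives.
#' @export
under_sample_negatives <- function(pairs, target_count, seed = 1L) {
  if (target_count < 0) stop("`target_count` must be >= 0", call. = FALSE)
  neg_idx <- which(pairs$label == 0)
  if (length(neg_idx) <= target_count) return(pairs)
  keep <- withr::with_seed(seed, sample(neg_idx, target_count))
  pairs[sort(c(which(pairs$label == 1), keep)), , drop = FALSE]
}

#' Split pairs into train/validation/test sets
#'
#' Seeded, stratified-by-label partition at the given fractions (default
#' 8:1:1). Set sizes follow largest-remainder rounding within each stratum,
#' so each split size is within one sample of its exact fraction.
#'
#' @param pairs A pairs tibble.
#' @param fractions Positive weights for train/val/test; normalised to 1.
#' @param seed Shuffle seed.
#' @param stratify Stratify by label (default `TRUE`).
#' @return A named list of tibbles: `train`, `val`, `test` — a disjoint
#'   partition of the input rows.
#' @export
split_pairs <- function(pairs, fractions = c(8, 1, 1), seed = 1L, stratify = TRUE) {
  if (nrow(pairs) == 0L) stop("cannot split an empty dataset", call. = FALSE)
  if (length(fractions) != 3L || any(fractions <= 0)) {
    stop("`fractions` must be three positive numbers", call. = FALSE)
  }
  f <- fractions / sum(fractions)
  strata <- if (stratify) split(seq_len(nrow(pairs)), pairs$label)
            else list(seq_len(nrow(pairs)))
  parts <- list(integer(0), integer(0), integer(0))
  withr::with_seed(seed, {
    for (idx in strata) {
      idx <- sample(idx)
      sizes <- largest_remainder(length(idx), f)
      cuts <- cumsum(sizes)
      parts[[1]] <- c(parts[[1]], idx[seq_len(sizes[1])])
      if (sizes[2] > 0) parts[[2]] <- c(parts[[2]], idx[(cuts[1] + 1):cuts[2]])
      if (sizes[3] > 0) parts[[3]] <- c(parts[[3]], idx[(cuts[2] + 1):cuts[3]])
    }
  })
  list(train = pairs[sort(parts[[1]]), , drop = FALSE],
       val = pairs[sort(parts[[2]]), , drop = FALSE],
       test = pairs[sort(parts[[3]]), , drop = FALSE])
}

largest_remainder <- function(n, f) {
  raw <- n * f
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Remove duplicated pairs by id
#'
#' Deduplicates on `(enhancer_id, promoter_id)`, keeping the first record —
#' applied before class balancing so replicated catalogue entries do not
#' leak extra weight.
#'
#' @param pairs A pairs tibble.
#' @return The deduplicated tibble.
#' @export
dedup_pairs <- function(pairs) {
  dplyr::distinct(pairs, .data$enhancer_id, .data$promoter_id, .keep_all = TRUE)
}
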