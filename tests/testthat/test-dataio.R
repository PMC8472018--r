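write_toy_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("enhancer_id\tpromoter_id\tenhancer_seq\tpromoter_seq\tlabel", rows),
             path)
  path
}

test_that("pair tables read with cleaning, warnings and line numbers", {
  p <- write_toy_tsv(c("e1\tp1\tACGT\tGGCC\t1",
                       "e2\tp2\tacgt\tttaa\t0",
                       "e3\tp3\tACRT\tGGCC\t1"))
  expect_warning(d <- read_pairs_tsv(p), "non-ACGTN")
  expect_equal(nrow(d), 3L)
  expect_equal(sum(d$label), 2L)
  expect_equal(d$enhancer_seq[2], "ACGT")   # lowercase uppercased
  expect_equal(d$enhancer_seq[3], "ACNT")   # ambiguity masked
  # identical tensors downstream for case variants
  expect_equal(encode_sequence(d$enhancer_seq[1], 1)$values,
               encode_sequence(d$enhancer_seq[2], 1)$values)

  p2 <- write_toy_tsv(character(0))
  expect_warning(d2 <- read_pairs_tsv(p2), "empty")
  expect_equal(nrow(d2), 0L)

  p3 <- write_toy_tsv(c("e1\tp1\tACGT\tGGCC\t1", "e2\tp2\tACGT\tGGCC\t7"))
  expect_warning(d3 <- read_pairs_tsv(p3), "line\\(s\\) 3")
  expect_equal(nrow(d3), 1L)

  writeLines("enhancer_id\tlabel", p3)
  expect_error(read_pairs_tsv(p3), "lacks column")
})

test_that("BED + FASTA extraction honours coordinates and strand", {
  skip_if_not_installed("Biostrings")
  skip_if_not_installed("rtracklayer")
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "toy.fa")
  writeLines(c(">chr1", "ACGTACGTACGTACGTACGT"), fa)
  enh_bed <- file.path(dir, "enh.bed")
  writeLines(c("chr1\t0\t10\tenhA\t0\t+",
               "chr1\t4\t8\tenhB\t0\t-",
               "chr1\t15\t30\tenhC\t0\t+"), enh_bed)  # enhC out of bounds
  prom_bed <- file.path(dir, "prom.bed")
  writeLines("chr1\t10\t20\tpromA\t0\t+", prom_bed)
  pl <- file.path(dir, "pairs.tsv")
  writeLines(c("enhancer_id\tpromoter_id\tlabel",
               "enhA\tpromA\t1",
               "enhB\tpromA\t0",
               "enhC\tpromA\t1",
               "missing\tpromA\t0"), pl)
  expect_message(expect_message(
    d <- read_pairs_bed(enh_bed, prom_bed, pl, fa, cell_line = "toy"),
    "interval"), "unresolved")
  expect_equal(nrow(d), 2L)
  expect_equal(d$enhancer_seq[1], "ACGTACGTAC")            # chr1:0-10
  expect_equal(d$enhancer_seq[2], "ACGT")                  # revcomp of ACGT
  expect_equal(d$promoter_seq[1], "GTACGTACGT")
})

test_that("length normalisation centre-trims and symmetrically N-pads", {
  p <- tibble::tibble(enhancer_id = "e", promoter_id = "p",
                      enhancer_seq = strrep("A", 3000),
                      promoter_seq = strrep("C", 2000),
                      label = 1L, cell_line = "x")
  expect_identical(enforce_length(p), p)  # already exact

  p$enhancer_seq <- paste0("GG", strrep("A", 3000), "TT")  # 3004
  out <- enforce_length(p)
  expect_equal(nchar(out$enhancer_seq), 3000L)
  expect_equal(substr(out$enhancer_seq, 1, 1), "A")        # flanks trimmed

  p$promoter_seq <- strrep("C", 1990)
  out <- enforce_length(p)
  expect_equal(nchar(out$promoter_seq), 2000L)
  expect_equal(substr(out$promoter_seq, 1, 5), "NNNNN")
  expect_equal(substr(out$promoter_seq, 1996, 2000), "NNNNN")

  # odd deficits put the extra base on the right flank
  q <- tibble::tibble(enhancer_seq = "ACGTA", promoter_seq = "AC")
  out <- enforce_length(q, enhancer_len = 4, promoter_len = 5)
  expect_equal(out$enhancer_seq, "ACGT")
  expect_equal(out$promoter_seq, "NACNN")
})

test_that("over-sampling reproduces the canonical balancing arithmetic", {
  # auto factor = round(n_neg / n_pos); the published per-line counts give 20x
  for (case in list(c(1977, 39500, 39540), c(2113, 42200, 42260),
                    c(1254, 25000, 25080))) {
    d <- make_toy_pairs(case[1], 0, enh_len = 4, prom_len = 4)
    d$label[1] <- 1L
    attr_neg <- case[2]
    # negatives only matter through their count; attach cheap stubs
    neg <- tibble::tibble(enhancer_id = sprintf("n%d", seq_len(attr_neg)),
                          promoter_id = sprintf("m%d", seq_len(attr_neg)),
                          enhancer_seq = "AAAA", promoter_seq = "CCCC",
                          label = 0L, cell_line = "toy")
    out <- over_sample_positives(dplyr::bind_rows(d, neg), factor = "auto",
                                 shift_window = 0, seed = 1)
    expect_equal(sum(out$label == 1), case[3])
    expect_equal(sum(out$label == 0), attr_neg)
  }
})

test_that("shift augmentation preserves lengths and the original first copy", {
  d <- make_toy_pairs(5, 10, enh_len = 30, prom_len = 20, seed = 3)
  out <- over_sample_positives(d, factor = 3, shift_window = 5, seed = 9)
  expect_equal(sum(out$label == 1), 15L)
  expect_true(all(nchar(out$enhancer_seq[out$label == 1]) == 30))
  expect_true(all(nchar(out$promoter_seq[out$label == 1]) == 20))
  # the unshifted originals survive verbatim
  orig <- d[d$label == 1, ]
  kept <- out[out$enhancer_id %in% orig$enhancer_id, ]
  expect_equal(kept$enhancer_seq, orig$enhancer_seq)
  # augmented copies are shifted versions: stripped of N they are substrings
  aug <- out[grepl("_aug", out$enhancer_id), ]
  core <- gsub("^N+|N+$", "", aug$enhancer_seq[1])
  expect_true(grepl(core, paste(orig$enhancer_seq, collapse = "|"), fixed = FALSE))
  # factor 1 is the identity; shift 0 duplicates exactly
  expect_identical(over_sample_positives(d, factor = 1), d)
  dup <- over_sample_positives(d, factor = 2, shift_window = 0, seed = 1)
  expect_equal(sort(unique(dup$enhancer_seq[dup$label == 1])),
               sort(unique(orig$enhancer_seq)))
  expect_error(over_sample_positives(d, factor = 0), "factor")
})

test_that("negative under-sampling is seeded, bounded and positive-preserving", {
  d <- make_toy_pairs(10, 200, seed = 5)
  out <- under_sample_negatives(d, 10, seed = 4)
  expect_equal(sum(out$label == 0), 10L)
  expect_equal(sum(out$label == 1), 10L)
  out2 <- under_sample_negatives(d, 10, seed = 4)
  expect_identical(out$enhancer_id, out2$enhancer_id)     # same seed, same subset
  out3 <- under_sample_negatives(d, 10, seed = 5)
  expect_false(identical(out$enhancer_id, out3$enhancer_id))
  expect_identical(under_sample_negatives(d, 500, seed = 1), d)  # target >= available
})

test_that("splits partition the data at the stated fractions, stratified", {
  d <- make_toy_pairs(50, 50, seed = 6)
  sp <- split_pairs(d, seed = 2)
  expect_equal(vapply(sp, nrow, 1L), c(train = 80L, val = 10L, test = 10L))
  all_ids <- sort(c(sp$train$enhancer_id, sp$val$enhancer_id, sp$test$enhancer_id))
  expect_equal(all_ids, sort(d$enhancer_id))
  # stratification keeps the class ratio in every split
  for (s in sp) expect_equal(mean(s$label), 0.5)

  # partition property over many random datasets
  withr::with_seed(8, {
    for (i in 1:300) {
      n_pos <- sample(2:20, 1)
      n_neg <- sample(2:20, 1)
      di <- make_toy_pairs(n_pos, n_neg, enh_len = 4, prom_len = 4, seed = i)
      spi <- split_pairs(di, seed = i)
      sizes <- vapply(spi, nrow, 1L)
      expect_equal(sum(sizes), n_pos + n_neg)
      ids <- c(spi$train$enhancer_id, spi$val$enhancer_id, spi$test$enhancer_id)
      expect_equal(sort(ids), sort(di$enhancer_id))  # disjoint + exhaustive
      expect_true(all(abs(sizes - (n_pos + n_neg) * c(0.8, 0.1, 0.1)) <= 2))
    }
  })
  expect_error(split_pairs(d, fractions = c(1, 0, 1)), "positive")
  expect_error(split_pairs(d[0, ]), "empty")
})

test_that("pairs deduplicate on id before balancing", {
  d <- make_toy_pairs(3, 3, seed = 7)
  dd <- dplyr::bind_rows(d, d[1:2, ])
  expect_equal(nrow(dedup_pairs(dd)), 6L)
})
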