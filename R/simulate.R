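#' Configuration for the synthetic multi-cell-line EPI generator
#'
#' The generator emulates the structure of the real EPI benchmarks: per cell
#' line, fixed-length enhancer/promoter pairs with a 20:1
#' negative-to-positive imbalance; interactions driven by compatible
#' (enhancer-motif, promoter-motif) pairs, some shared across all cell lines
#' and some line-specific (shared motifs are what makes cross-line transfer
#' learnable); optional byte-identical positive pairs planted across chosen
#' lines (ground truth for the overlap statistic).
#'
#' Desk-scale defaults: 3 cell lines, 1000 positives and 20,000 negatives
#' per line (the canonical 20:1 ratio), 512-bp enhancers and 256-bp
#' promoters, 1 shared + 1 line-specific motif pair of length 10 implanted
#' as homotypic clusters (12 enhancer / 6 promoter copies, about one site
#' per 40 bp), per-position motif mutation rate 0.05, uniform background,
#' 10% hard negatives (an unpaired single-side motif cluster, so models
#' must learn the pairing rather than mere motif presence).
#'
#' @param n_cell_lines Number of cell lines.
#' @param n_positive,n_negative Per-line class counts (default 20:1).
#' @param enhancer_len,promoter_len Sequence lengths in bp.
#' @param motif_len Motif length in bp.
#' @param enhancer_motif_copies,promoter_motif_copies Number of copies of
#'   the pair's motif implanted per sequence (homotypic site clusters, the
#'   typical architecture of strong enhancers; one site per ~40 bp by
#'   default). Each copy is mutated independently and placed uniformly.
#' @param n_shared_motif_pairs Motif pairs active in every line.
#' @param n_specific_motif_pairs Additional motif pairs private to each line.
#' @param motifs Optional explicit motif set: a list with `shared` (tibble
#'   of `enhancer_motif`, `promoter_motif`) and optionally `specific` (list
#'   of such tibbles, one per line); overrides the random motif draw.
#' @param mutation_rate Per-position substitution rate applied to each
#'   implanted motif copy; in `[0, 0.5)`.
#' @param background_probs Named base probabilities for background sequence.
#' @param hard_negative_rate Fraction of negatives carrying one unpaired
#'   motif.
#' @param n_planted_shared_pairs Byte-identical positive pairs copied across
#'   `planted_lines`.
#' @param planted_lines Indices of the lines sharing the planted pairs
#'   (default the first two).
#' @param seed Mandatory seed; the whole dataset is a pure function of the
#'   config.
#' @return An object of class `epi_sim_config`.
#' @export
sim_config <- function(n_cell_lines = 3,
                       n_positive = 1000,
                       n_negative = 20 * n_positive,
                       enhancer_len = 512,
                       promoter_len = 256,
                       motif_len = 10,
                       enhancer_motif_copies = 12,
                       promoter_motif_copies = 6,
                       n_shared_motif_pairs = 1,
                       n_specific_motif_pairs = 1,
                       motifs = NULL,
                       mutation_rate = 0.05,
                       background_probs = c(A = 0.25, T = 0.25, C = 0.25, G = 0.25),
                       hard_negative_rate = 0.1,
                       n_planted_shared_pairs = 0,
                       planted_lines = NULL,
                       seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (mutation_rate < 0 || mutation_rate >= 0.5) {
    stop("`mutation_rate` must be in [0, 0.5)", call. = FALSE)
  }
  max_motif <- if (!is.null(motifs)) {
    max(nchar(unlist(motifs, use.names = FALSE)))
  } else motif_len
  if (enhancer_len < max_motif || promoter_len < max_motif) {
    stop("sequence lengths must be >= the longest motif", call. = FALSE)
  }
  if (is.null(planted_lines)) planted_lines <- seq_len(min(2L, n_cell_lines))
  structure(
    list(n_cell_lines = n_cell_lines, n_positive = n_positive,
         n_negative = n_negative, enhancer_len = enhancer_len,
         promoter_len = promoter_len, motif_len = motif_len,
         enhancer_motif_copies = as.integer(enhancer_motif_copies),
         promoter_motif_copies = as.integer(promoter_motif_copies),
         n_shared_motif_pairs = n_shared_motif_pairs,
         n_specific_motif_pairs = n_specific_motif_pairs, motifs = motifs,
         mutation_rate = mutation_rate, background_probs = background_probs,
         hard_negative_rate = hard_negative_rate,
         n_planted_shared_pairs = n_planted_shared_pairs,
         planted_lines = planted_lines, seed = as.integer(seed)),
    class = "epi_sim_config"
  )
}

#' Simulate multi-cell-line EPI datasets with known ground truth
#'
#' See [sim_config()] for the generative model. Positives carry one
#' compatible (enhancer-motif, promoter-motif) pair implanted at uniform
#' random positions with per-position mutation; negatives carry background
#' sequence, a fraction of them a single unpaired motif; planted duplicate
#' pairs are byte-identical across the designated lines. Fully reproducible
#' from the config seed.
#'
#' @param config An [sim_config()] object.
#' @return A list of class `epi_sim`: `pairs` (one tibble over all lines,
#'   with `cell_line`), `truth` (list: `motif_pairs`, `implants`, `planted`)
#'   and `config`.
#' @export
simulate_epi <- function(config) {
  stopifnot(inherits(config, "epi_sim_config"))
  withr::with_seed(config$seed, simulate_epi_impl(config))
}

simulate_epi_impl <- function(cfg) {
  lines <- sprintf("CL%d", seq_len(cfg$n_cell_lines))
  bases <- c("A", "T", "C", "G")

  # motif vocabulary: shared pairs + line-specific pairs
  if (is.null(cfg$motifs)) {
    shared <- tibble::tibble(
      enhancer_motif = random_dna(cfg$n_shared_motif_pairs, cfg$motif_len, cfg$background_probs),
      promoter_motif = random_dna(cfg$n_shared_motif_pairs, cfg$motif_len, cfg$background_probs)
    )
    specific <- lapply(lines, function(l) tibble::tibble(
      enhancer_motif = random_dna(cfg$n_specific_motif_pairs, cfg$motif_len, cfg$background_probs),
      promoter_motif = random_dna(cfg$n_specific_motif_pairs, cfg$motif_len, cfg$background_probs)
    ))
  } else {
    shared <- tibble::as_tibble(cfg$motifs$shared)
    specific <- if (!is.null(cfg$motifs$specific)) {
      lapply(cfg$motifs$specific, tibble::as_tibble)
    } else {
      rep(list(shared[0, ]), cfg$n_cell_lines)
    }
  }
  motif_pairs <- dplyr::bind_rows(
    dplyr::mutate(shared, cell_line = NA_character_, shared = TRUE),
    dplyr::bind_rows(lapply(seq_along(lines), function(i) {
      dplyr::mutate(specific[[i]], cell_line = lines[i], shared = FALSE)
    }))
  )
  motif_pairs$pair_id <- sprintf("mp%02d", seq_len(nrow(motif_pairs)))

  # planted byte-identical positives, shared across cfg$planted_lines
  n_pl <- cfg$n_planted_shared_pairs
  planted <- NULL
  if (n_pl > 0) {
    if (n_pl > cfg$n_positive) stop("more planted pairs than positives", call. = FALSE)
    pool <- motif_pairs[motif_pairs$shared | motif_pairs$cell_line %in% lines[cfg$planted_lines], ]
    pool <- pool[pool$shared, , drop = FALSE]
    if (nrow(pool) == 0L) pool <- motif_pairs
    pick <- pool[sample(nrow(pool), n_pl, replace = TRUE), ]
    planted <- make_positives(pick, cfg, id_prefix = "shared")
  }

  all_pairs <- list()
  implants <- list()
  for (li in seq_along(lines)) {
    line <- lines[li]
    pool <- motif_pairs[motif_pairs$shared | motif_pairs$cell_line == line, ]
    pool <- pool[!is.na(pool$pair_id), , drop = FALSE]

    use_planted <- n_pl > 0 && li %in% cfg$planted_lines
    n_own <- cfg$n_positive - if (use_planted) n_pl else 0L

    pick <- pool[sample(nrow(pool), n_own, replace = TRUE), , drop = FALSE]
    own <- make_positives(pick, cfg, id_prefix = line)
    pos <- if (use_planted) {
      dplyr::bind_rows(planted$pairs, own$pairs)
    } else own$pairs
    imp <- if (use_planted) {
      dplyr::bind_rows(planted$implants, own$implants)
    } else own$implants
    imp$cell_line <- line

    neg <- make_negatives(cfg, motif_pool = pool, id_prefix = line)

    pos$label <- 1L
    neg$label <- 0L
    line_pairs <- dplyr::bind_rows(pos, neg)
    line_pairs$cell_line <- line
    all_pairs[[line]] <- line_pairs
    implants[[line]] <- imp
  }

  planted_tbl <- if (n_pl > 0) {
    tibble::tibble(enhancer_id = planted$pairs$enhancer_id,
                   promoter_id = planted$pairs$promoter_id,
                   cell_lines = paste(lines[cfg$planted_lines], collapse = ","))
  } else {
    tibble::tibble(enhancer_id = character(), promoter_id = character(),
                   cell_lines = character())
  }

  structure(
    list(pairs = dplyr::bind_rows(all_pairs),
         truth = list(motif_pairs = motif_pairs,
                      implants = dplyr::bind_rows(implants),
                      planted = planted_tbl),
         config = cfg),
    class = "epi_sim"
  )
}

# Build positive pairs for the picked motif rows: background + implanted,
# mutated motif copies at uniform positions.
make_positives <- function(pick, cfg, id_prefix) {
  n <- nrow(pick)
  if (n == 0L) {
    return(list(pairs = empty_pairs()[, 1:5], implants = tibble::tibble()))
  }
  enh <- random_dna(n, cfg$enhancer_len, cfg$background_probs)
  prom <- random_dna(n, cfg$promoter_len, cfg$background_probs)
  imp_rows <- vector("list", n)
  ids_e <- sprintf("%s_enh%04d", id_prefix, seq_len(n))
  ids_p <- sprintf("%s_prom%04d", id_prefix, seq_len(n))
  for (i in seq_len(n)) {
    e_at <- implant_copies(enh, i, pick$enhancer_motif[i],
                           cfg$enhancer_motif_copies, cfg$mutation_rate)
    enh <- e_at$seqs
    p_at <- implant_copies(prom, i, pick$promoter_motif[i],
                           cfg$promoter_motif_copies, cfg$mutation_rate)
    prom <- p_at$seqs
    imp_rows[[i]] <- tibble::tibble(
      enhancer_id = ids_e[i], promoter_id = ids_p[i],
      motif_pair_id = pick$pair_id[i],
      enhancer_motif = pick$enhancer_motif[i],
      promoter_motif = pick$promoter_motif[i],
      enhancer_pos = paste(e_at$at, collapse = ","),
      promoter_pos = paste(p_at$at, collapse = ","))
  }
  list(
    pairs = tibble::tibble(enhancer_id = ids_e, promoter_id = ids_p,
                           enhancer_seq = enh, promoter_seq = prom),
    implants = dplyr::bind_rows(imp_rows)
  )
}

make_negatives <- function(cfg, motif_pool, id_prefix) {
  n <- cfg$n_negative
  enh <- random_dna(n, cfg$enhancer_len, cfg$background_probs)
  prom <- random_dna(n, cfg$promoter_len, cfg$background_probs)
  hard <- which(stats::runif(n) < cfg$hard_negative_rate)
  for (i in hard) {
    row <- motif_pool[sample.int(nrow(motif_pool), 1L), ]
    if (stats::runif(1) < 0.5) {
      enh <- implant_copies(enh, i, row$enhancer_motif,
                            cfg$enhancer_motif_copies, cfg$mutation_rate)$seqs
    } else {
      prom <- implant_copies(prom, i, row$promoter_motif,
                             cfg$promoter_motif_copies, cfg$mutation_rate)$seqs
    }
  }
  tibble::tibble(
    enhancer_id = sprintf("%s_negenh%05d", id_prefix, seq_len(n)),
    promoter_id = sprintf("%s_negprom%05d", id_prefix, seq_len(n)),
    enhancer_seq = enh, promoter_seq = prom
  )
}

# Implant `copies` independently mutated copies of `motif` into seqs[i] at
# uniform positions (copies may overlap, as real site clusters do).
implant_copies <- function(seqs, i, motif, copies, rate) {
  L <- nchar(seqs[i])
  w <- nchar(motif)
  at <- 1L + floor(stats::runif(copies) * (L - w + 1L))
  for (a in at) {
    m <- mutate_motif(motif, rate)
    substr(seqs[i], a, a + w - 1L) <- m
  }
  list(seqs = seqs, at = sort(at))
}

random_dna <- function(n, len, probs = c(A = 0.25, T = 0.25, C = 0.25, G = 0.25)) {
  if (n == 0L) return(character(0))
  draws <- sample(names(probs), n * len, replace = TRUE, prob = probs)
  apply(matrix(draws, nrow = len), 2, paste, collapse = "")
}

mutate_motif <- function(motif, rate) {
  if (rate == 0) return(motif)
  chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "T", "C", "G"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Write a simulated dataset to a fixture directory
#'
#' Emits one TSV pair list per cell line (`pairs_<line>.tsv`, round-trips
#' losslessly through [read_pairs_tsv()]) plus ground-truth sidecars
#' (`truth_implants.tsv`, `truth_motif_pairs.tsv`, `truth_planted.tsv`) and
#' a `config.yaml` echo when the yaml package is available. Regenerating
#' from the same config yields byte-identical files.
#'
#' @param sim An [simulate_epi()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "epi_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (line in unique(sim$pairs$cell_line)) {
    readr::write_tsv(sim$pairs[sim$pairs$cell_line == line, ],
                     file.path(dir, paste0("pairs_", line, ".tsv")))
  }
  readr::write_tsv(sim$truth$implants, file.path(dir, "truth_implants.tsv"))
  readr::write_tsv(sim$truth$motif_pairs, file.path(dir, "truth_motif_pairs.tsv"))
  readr::write_tsv(sim$truth$planted, file.path(dir, "truth_planted.tsv"))
  if (requireNamespace("yaml", quietly = TRUE)) {
    cfg <- sim$config
    cfg$background_probs <- as.list(cfg$background_probs)
    yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  }
  invisible(dir)
}
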