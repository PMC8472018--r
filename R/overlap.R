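#' Overlap ratio between two enhancer-promoter pairs
#'
#' Sequence similarity of two EPIs from (possibly) different cell lines,
#' computed on length-normalised pairs as ungapped positional identity:
#' (matching enhancer positions + matching promoter positions) /
#' (enhancer length + promoter length). An `N` never matches anything.
#' `method = "minimum"` instead returns the smaller of the two per-element
#' identities (enhancer identity, promoter identity), a stricter variant.
#'
#' @param pair_a,pair_b One-row pairs tibbles (or lists with
#'   `enhancer_seq`/`promoter_seq`).
#' @param method `"concat"` (default) or `"minimum"`.
#' @return A fraction in `[0, 1]`.
#' @examples
#' a <- tibble::tibble(enhancer_seq = "AAAA", promoter_seq = "GG")
#' b <- tibble::tibble(enhancer_seq = "AAAA", promoter_seq = "TT")
#' pair_overlap_ratio(a, b)  # 4/6
#' @export
pair_overlap_ratio <- function(pair_a, pair_b, method = c("concat", "minimum")) {
  method <- match.arg(method)
  ea <- toupper(pair_a$enhancer_seq[1])
  eb <- toupper(pair_b$enhancer_seq[1])
  pa <- toupper(pair_a$promoter_seq[1])
  pb <- toupper(pair_b$promoter_seq[1])
  if (nchar(ea) != nchar(eb) || nchar(pa) != nchar(pb)) {
    stop("pairs must be length-normalised before comparison", call. = FALSE)
  }
  me <- seq_matches(ea, eb)
  mp <- seq_matches(pa, pb)
  if (method == "concat") {
    (me + mp) / (nchar(ea) + nchar(pa))
  } else {
    min(me / nchar(ea), mp / nchar(pa))
  }
}

seq_matches <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  sum(ra == rb & ra != charToRaw("N"))
}

#' Cross-cell-line EPI overlap counts
#'
#' For every ordered cell-line pair (target, comparison) counts how many of
#' the target line's positive EPIs have at least one positive EPI in the
#' comparison line with overlap ratio >= `omega0`. Each target pair is
#' counted at most once however many comparison pairs qualify
#' (`per_match = TRUE` counts every qualifying comparison pair instead).
#' Only positive pairs enter the statistic. Counts are monotone
#' non-increasing in `omega0`, bounded by the target line's positive count,
#' and symmetric at `omega0 = 1` for duplicate-free positive sets (an exact
#' match is mutual).
#'
#' @param pairs A pairs tibble spanning >= 2 cell lines.
#' @param omega0 Overlap-ratio threshold in `(0, 1]`; 1.0 demands identity,
#'   0.8 tolerates 20% mismatch.
#' @param method Similarity variant, see [pair_overlap_ratio()].
#' @param per_match Count every qualifying comparison pair.
#' @return An object of class `overlap_report`: integer `counts` matrix
#'   (rows = target line, columns = comparison line, diagonal `NA`),
#'   per-line positive-set sizes `totals`, and the threshold. `tidy()`
#'   gives the long form; `print()` the square layout with a Total-EPIs
#'   column.
#' @export
count_overlaps <- function(pairs, omega0 = 1.0, method = c("concat", "minimum"),
                           per_match = FALSE) {
  method <- match.arg(method)
  if (!(omega0 > 0 && omega0 <= 1)) {
    stop("`omega0` must be in (0, 1]", call. = FALSE)
  }
  pos <- pairs[pairs$label == 1, , drop = FALSE]
  lines <- unique(pairs$cell_line)
  if (length(lines) < 2L) stop("need at least two cell lines", call. = FALSE)
  if (nrow(pos) == 0L) warning("no positive pairs; all counts zero", call. = FALSE)

  # raw byte matrices per line: positions x n_pairs, N masked to a non-byte
  enc <- lapply(lines, function(l) {
    sub <- pos[pos$cell_line == l, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    list(e = seq_raw_matrix(sub$enhancer_seq), p = seq_raw_matrix(sub$promoter_seq),
         n = nrow(sub))
  })
  names(enc) <- lines
  totals <- vapply(enc, function(x) if (is.null(x)) 0L else x$n, integer(1))

  counts <- matrix(NA_integer_, length(lines), length(lines),
                   dimnames = list(lines, lines))
  for (a in seq_along(lines)) {
    for (b in seq_along(lines)) {
      if (a == b) next
      counts[a, b] <- overlap_count_one(enc[[a]], enc[[b]], omega0, method, per_match)
    }
  }
  structure(list(counts = counts, totals = totals, omega0 = omega0,
                 method = method, per_match = per_match),
            class = "overlap_report")
}

seq_raw_matrix <- function(seqs) {
  L <- nchar(seqs[1])
  if (any(nchar(seqs) != L)) {
    stop("positive pairs must be length-normalised before overlap analysis",
         call. = FALSE)
  }
  m <- vapply(toupper(seqs), charToRaw, raw(L), USE.NAMES = FALSE)
  m[m == charToRaw("N")] <- as.raw(0)  # N on either side can never match
  m
}

overlap_count_one <- function(target, comp, omega0, method, per_match) {
  if (is.null(target) || is.null(comp)) return(0L)
  Le <- nrow(target$e)
  Lp <- nrow(target$p)
  total <- 0L
  nmask <- as.raw(0)
  for (t in seq_len(target$n)) {
    te <- target$e[, t]
    tp <- target$p[, t]
    me <- colSums(comp$e == te & te != nmask)
    mp <- colSums(comp$p == tp & tp != nmask)
    ratio <- if (method == "concat") (me + mp) / (Le + Lp)
             else pmin(me / Le, mp / Lp)
    hits <- sum(ratio >= omega0)
    total <- total + if (per_match) hits else as.integer(hits > 0)
  }
  total
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> omega0 = %g (%s%s)\n", x$omega0, x$method,
              if (x$per_match) ", per-match counting" else ""))
  df <- cbind(`Total EPIs` = x$totals, as.data.frame(x$counts))
  print(df)
  invisible(x)
}

#' Write an overlap report as a TSV matrix
#'
#' Square lines-by-lines layout with the per-line positive totals in a
#' leading `Total EPIs` column.
#'
#' @param report An [count_overlaps()] result.
#' @param path Output TSV.
#' @export
write_overlap_report <- function(report, path) {
  stopifnot(inherits(report, "overlap_report"))
  df <- data.frame(cell_line = rownames(report$counts),
                   `Total EPIs` = report$totals,
                   report$counts, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}
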