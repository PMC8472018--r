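#' Class-activation map for one enhancer-promoter pair
#'
#' Gradient-weighted CAM on each branch's final convolutional layer: the
#' gradient of the positive-class logit w.r.t. the last conv layer's
#' (post-ReLU) activations is spatially averaged into one weight per
#' filter, the weighted activation sum is rectified, bilinearly upsampled
#' to the input grid and max-normalised to 1. (The classic CAM formulation
#' needs a global-average-pooling head this architecture lacks; the
#' gradient-weighted form reduces to it when a GAP head is present.)
#' Deterministic for a fixed model and input.
#'
#' @param model A trained `epi_cnn`.
#' @param pair A one-row pairs tibble.
#' @return An object of class `epi_cam`: per-branch importance grids
#'   (`enhancer_grid`, `promoter_grid`; values in `[0, 1]`), per-position
#'   importance vectors (`enhancer_positions`, `promoter_positions`;
#'   lengths = sequence lengths, via the exact inverse Hilbert map), the
#'   predicted probability and the pair ids.
#' @export
compute_cam <- function(model, pair) {
  stopifnot(inherits(model, "epi_cnn"))
  if (!isTRUE(model$trained)) {
    stop("`model` is untrained; fit or load it first", call. = FALSE)
  }
  stopifnot(is.data.frame(pair), nrow(pair) == 1L)
  ts <- as_tensor_set(pair, model)
  m <- tensor_matrices(ts)
  fw <- net_forward(model$params, m$E, m$P, model$specs, cache = TRUE)

  # backward from the logit only down to each branch's conv2 activations
  dz <- matrix(1, 1L, 1L)
  dH1d <- t(model$params$out$W) %*% dz
  dZ1 <- dH1d * (fw$Z1 > 0)
  dXf <- t(model$params$dense1$W) %*% dZ1
  de <- nrow(fw$be$out)
  dFe <- dXf[seq_len(de), , drop = FALSE]
  dFp <- dXf[-seq_len(de), , drop = FALSE]

  cam_e <- branch_cam(dFe, fw$be, model$specs$enhancer, model$config$conv_filters[2])
  cam_p <- branch_cam(dFp, fw$bp, model$specs$promoter, model$config$conv_filters[2])

  eg <- hilbert_curve(as.integer(log2(model$enhancer_side)))
  pg <- hilbert_curve(as.integer(log2(model$promoter_side)))
  structure(
    list(enhancer_grid = cam_e, promoter_grid = cam_p,
         enhancer_positions = cell_importance_to_positions(
           cam_e, eg, nchar(pair$enhancer_seq[1])),
         promoter_positions = cell_importance_to_positions(
           cam_p, pg, nchar(pair$promoter_seq[1])),
         prob = fw$prob,
         enhancer_id = pair$enhancer_id[1], promoter_id = pair$promoter_id[1]),
    class = "epi_cam"
  )
}

# dOut: gradient wrt pooled branch output; walk it back through pool2 to the
# conv2 activations, then Grad-CAM: per-filter spatial mean gradient weights
# the activation planes.
branch_cam <- function(dOut, fw_branch, specs, n_filters) {
  dA2 <- pool_backward(dOut, specs$pool2, fw_branch$p2)   # (plane2*F) x 1
  plane <- specs$conv2$plane
  side2 <- specs$conv2$H
  A2 <- matrix(fw_branch$c2$A[, 1L], plane, n_filters)
  G2 <- matrix(dA2[, 1L], plane, n_filters)
  alpha <- colMeans(G2)
  cam <- A2 %*% alpha
  cam[cam < 0] <- 0
  cam <- matrix(cam, side2, side2)
  cam <- upsample_bilinear(cam, side2 * 2L)
  if (max(cam) > 0) cam <- cam / max(cam)
  cam
}

# Separable bilinear upsampling (half-pixel centre alignment, edges clamped)
# of a square matrix to side_out.
upsample_bilinear <- function(m, side_out) {
  side_in <- nrow(m)
  src <- (seq_len(side_out) - 0.5) * side_in / side_out + 0.5
  lo <- floor(src)
  w <- src - lo
  lo_c <- pmin(pmax(lo, 1), side_in)
  hi_c <- pmin(pmax(lo + 1, 1), side_in)
  R <- matrix(0, side_out, side_in)
  for (i in seq_len(side_out)) {
    R[i, lo_c[i]] <- R[i, lo_c[i]] + (1 - w[i])
    R[i, hi_c[i]] <- R[i, hi_c[i]] + w[i]
  }
  R %*% m %*% t(R)
}

#' @export
print.epi_cam <- function(x, ...) {
  cat(sprintf("<epi_cam> %s x %s | p(interaction) = %.3f\n",
              x$enhancer_id, x$promoter_id, x$prob))
  invisible(x)
}

#' Salient sequence positions of a CAM
#'
#' Positions whose per-position importance is at or above the given
#' quantile of that sequence's importance distribution. Ties at the
#' threshold are all included (so a uniform map returns every position).
#'
#' @param cam An [compute_cam()] result.
#' @param branch `"enhancer"` or `"promoter"`.
#' @param quantile Threshold quantile, strictly inside (0, 1); default 0.9
#'   (the top decile).
#' @return Sorted integer vector of 1-based sequence positions.
#' @export
salient_positions <- function(cam, branch = c("enhancer", "promoter"),
                              quantile = 0.9) {
  stopifnot(inherits(cam, "epi_cam"))
  branch <- match.arg(branch)
  if (!(quantile > 0 && quantile < 1)) {
    stop("`quantile` must be strictly inside (0, 1)", call. = FALSE)
  }
  imp <- cam[[paste0(branch, "_positions")]]
  thr <- stats::quantile(imp, quantile, names = FALSE)
  which(imp >= thr)
}

#' k-mer frequencies in salient regions of positive pairs
#'
#' For every positive pair, computes the CAM, thresholds it at the salience
#' quantile, groups the salient sequence positions into maximal runs of
#' consecutive positions, and counts every k-mer fully contained in a run
#' (k-mers containing `N` are skipped). Counts are aggregated per branch
#' and per k and sorted descending, the layout of the published
#' feature-frequency tables.
#'
#' @param pairs A pairs tibble; only rows with `label == 1` are used.
#' @param model A trained `epi_cnn`.
#' @param ks k-mer lengths (default `c(3, 4)`).
#' @param quantile Salience quantile (see [salient_positions()]).
#' @return A tibble: `branch`, `k`, `kmer`, `count`, sorted by branch, k,
#'   descending count; attribute `n_samples` records how many positive
#'   pairs were aggregated.
#' @export
kmer_frequency <- function(pairs, model, ks = c(3, 4), quantile = 0.9) {
  pos <- pairs[pairs$label == 1, , drop = FALSE]
  if (nrow(pos) == 0L) {
    return(structure(tibble::tibble(branch = character(), k = integer(),
                                    kmer = character(), count = integer()),
                     n_samples = 0L))
  }
  if (any(ks > nchar(pos$enhancer_seq[1])) || any(ks > nchar(pos$promoter_seq[1]))) {
    stop("k exceeds sequence length", call. = FALSE)
  }
  tallies <- list(enhancer = list(), promoter = list())
  for (i in seq_len(nrow(pos))) {
    cam <- compute_cam(model, pos[i, , drop = FALSE])
    for (branch in c("enhancer", "promoter")) {
      sal <- salient_positions(cam, branch, quantile)
      seqs <- pos[[paste0(branch, "_seq")]][i]
      kms <- run_kmers(seqs, sal, ks)
      if (length(kms)) tallies[[branch]][[length(tallies[[branch]]) + 1L]] <- kms
    }
  }
  rows <- lapply(c("enhancer", "promoter"), function(branch) {
    kms <- unlist(tallies[[branch]], use.names = FALSE)
    if (!length(kms)) return(NULL)
    tb <- table(kms)
    tibble::tibble(branch = branch, k = nchar(names(tb)),
                   kmer = names(tb), count = as.integer(tb))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out <- dplyr::arrange(out, .data$branch, .data$k, dplyr::desc(.data$count),
                          .data$kmer)
  }
  structure(out, n_samples = nrow(pos))
}

# All k-mers fully contained in maximal runs of salient positions; ACGT only.
run_kmers <- function(sequence, salient, ks) {
  if (!length(salient)) return(character(0))
  runs <- split(salient, cumsum(c(1L, diff(salient) != 1L)))
  out <- character(0)
  for (r in runs) {
    for (k in ks) {
      if (length(r) < k) next
      starts <- r[seq_len(length(r) - k + 1L)]
      kms <- substring(sequence, starts, starts + k - 1L)
      kms <- kms[!grepl("[^ACGT]", kms)]
      out <- c(out, kms)
    }
  }
  out
}

#' Write a k-mer frequency table as TSV
#'
#' Two-column (feature, frequency) layout per branch and k.
#'
#' @param freq A [kmer_frequency()] tibble.
#' @param path Output TSV.
#' @export
write_kmer_table <- function(freq, path) {
  readr::write_tsv(
    dplyr::select(freq, feature = "kmer", frequency = "count",
                  dplyr::everything()), path)
  invisible(path)
}
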