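#' Evaluate binary classification scores
#'
#' Computes the metrics used for imbalanced EPI classification: AUC (rank
#' statistic with tie correction, i.e. the Mann-Whitney estimate), AUPR
#' (step-wise precision-recall integration, a.k.a. average precision; ties
#' are processed as one block and precision at recall 0 is the first
#' attainable precision, so no trapezoid interpolation inflates the area),
#' and precision/recall/F1 at a fixed threshold.
#'
#' @param scores Numeric vector of predicted probabilities or scores.
#' @param labels Binary labels (0/1), same length as `scores`.
#' @param threshold Decision threshold for precision/recall/F1 (default 0.5).
#' @return A one-row tibble: `auc`, `aupr`, `precision`, `recall`, `f1`,
#'   `n_pos`, `n_neg`. With single-class labels `auc`/`aupr` are `NA` (with
#'   a warning); the thresholded metrics are still returned.
#' @examples
#' evaluate_scores(c(.9, .8, .7, .4, .3, .2), c(1, 0, 1, 1, 0, 0))
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("`labels` must be 0/1", call. = FALSE)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)

  if (n_pos == 0L || n_neg == 0L) {
    warning("AUC/AUPR undefined with single-class labels", call. = FALSE)
    auc <- NA_real_
    aupr <- NA_real_
  } else {
    r <- rank(scores)  # midranks handle ties
    auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
    aupr <- average_precision(scores, labels, n_pos)
  }

  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0

  tibble::tibble(auc = auc, aupr = aupr, precision = precision,
                 recall = recall, f1 = f1,
                 n_pos = as.integer(n_pos), n_neg = as.integer(n_neg))
}

# Step-integrated PR area: walk score groups from high to low; each group of
# tied scores enters as one block, contributing (delta recall) * precision
# evaluated after the block.
average_precision <- function(scores, labels, n_pos) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  grp_end <- which(!duplicated(s, fromLast = TRUE))  # last row of each tie group
  tp <- cumsum(y)[grp_end]
  n_seen <- grp_end
  prec <- tp / n_seen
  d_tp <- diff(c(0, tp))
  sum(prec * d_tp) / n_pos
}
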