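#' Transfer-learning plan
#'
#' Two cross-cell-line protocols are supported. `transOne`: pre-train on the
#' pooled training sets of all *other* cell lines (6-8 epochs), then train
#' all layers on the target line's training set (10-15 epochs). `transTwo`:
#' pre-train on the training sets of *all* lines including the target, then
#' freeze both branches' convolutional parameters and fine-tune only the
#' post-merge layers on the target. Defaults take the midpoints of the
#' stated epoch ranges (7 and 12); other values are accepted but flagged
#' with a warning when outside the canonical ranges.
#'
#' @param strategy `"none"`, `"transOne"` or `"transTwo"`.
#' @param pretrain_epochs Pre-training epochs (canonical range 6-8).
#' @param finetune_epochs Fine-tuning epochs (canonical range 10-15).
#' @param target_cell_line Optional target tag carried for bookkeeping.
#' @return An object of class `transfer_plan`; `freeze_conv_pool` is `TRUE`
#'   exactly for `transTwo`.
#' @export
transfer_plan <- function(strategy = c("none", "transOne", "transTwo"),
                          pretrain_epochs = 7, finetune_epochs = 12,
                          target_cell_line = NULL) {
  strategy <- match.arg(strategy)
  if (strategy != "none") {
    if (pretrain_epochs > 0 && !(pretrain_epochs >= 6 && pretrain_epochs <= 8)) {
      warning("pretrain_epochs outside the canonical 6-8 range", call. = FALSE)
    }
    if (!(finetune_epochs >= 10 && finetune_epochs <= 15)) {
      warning("finetune_epochs outside the canonical 10-15 range", call. = FALSE)
    }
  }
  structure(
    list(strategy = strategy,
         pretrain_epochs = as.integer(pretrain_epochs),
         finetune_epochs = as.integer(finetune_epochs),
         freeze_conv_pool = identical(strategy, "transTwo"),
         target_cell_line = target_cell_line),
    class = "transfer_plan"
  )
}

conv_param_groups <- c("e_conv1", "e_conv2", "p_conv1", "p_conv2")

split_all_lines <- function(pairs, seed, fractions = c(8, 1, 1)) {
  lines <- unique(pairs$cell_line)
  out <- lapply(seq_along(lines), function(i) {
    split_pairs(pairs[pairs$cell_line == lines[i], , drop = FALSE],
                fractions = fractions, seed = seed + i)
  })
  names(out) <- lines
  out
}

check_transfer_inputs <- function(pairs, target_cell_line) {
  lines <- unique(pairs$cell_line)
  if (length(lines) < 2L) {
    stop("transfer learning needs at least two cell lines", call. = FALSE)
  }
  if (!target_cell_line %in% lines) {
    stop("target cell line '", target_cell_line, "' absent from the data",
         call. = FALSE)
  }
  lines
}

#' Transfer protocol one: pre-train on the other cell lines
#'
#' Pre-trains the classifier on the pooled training splits of every
#' non-target line for `plan$pretrain_epochs`, then trains *all* layers on
#' the target line's training split for `plan$finetune_epochs` (optimizer
#' state is reset between the phases; the weights carry over), and
#' evaluates on the target line's held-out test split. With
#' `pretrain_epochs = 0` this degenerates to plain training on the target.
#'
#' @param pairs A pairs tibble spanning all cell lines (pre-balanced as
#'   desired; each line is split 8:1:1 internally).
#' @param target_cell_line The line treated as new.
#' @param model_config An [epi_model_config()].
#' @param plan A [transfer_plan()] (strategy `"transOne"`).
#' @param split_seed Seed for the per-line splits.
#' @return A list of class `epi_transfer_result`: `model`, `evaluation`
#'   (an [evaluate_scores()] row on the target test split), `plan`,
#'   `target`, `pretrain_n`, `splits`.
#' @export
run_transone <- function(pairs, target_cell_line, model_config,
                         plan = transfer_plan("transOne"), split_seed = 1L) {
  lines <- check_transfer_inputs(pairs, target_cell_line)
  splits <- split_all_lines(pairs, split_seed)
  pool <- dplyr::bind_rows(lapply(setdiff(lines, target_cell_line),
                                  function(l) splits[[l]]$train))
  eo <- choose_order(max(nchar(pairs$enhancer_seq)))
  po <- choose_order(max(nchar(pairs$promoter_seq)))
  model <- build_epi_model(model_config, 2^eo, 2^po)
  if (plan$pretrain_epochs > 0L) {
    model <- train_epi_model(model, pool, epochs = plan$pretrain_epochs,
                             early_stopping = FALSE)
  }
  tgt <- splits[[target_cell_line]]
  model <- train_epi_model(model, tgt$train, val = tgt$val,
                           epochs = plan$finetune_epochs,
                           early_stopping = FALSE)
  scores <- predict(model, tgt$test)
  structure(
    list(model = model,
         evaluation = evaluate_scores(scores, tgt$test$label),
         plan = plan, target = target_cell_line,
         pretrain_n = nrow(pool), splits = splits),
    class = "epi_transfer_result"
  )
}

#' Transfer protocol two: pre-train on all lines, freeze, fine-tune
#'
#' Pre-trains on the pooled training splits of *all* cell lines (the
#' target's training split included — never its validation or test split),
#' freezes the convolutional parameters of both branches, fine-tunes only
#' the post-merge dense layers on the target's training split, and
#' evaluates on the target's test split. Frozen parameters are bit-identical
#' before and after fine-tuning.
#'
#' @inheritParams run_transone
#' @param plan A [transfer_plan()] (strategy `"transTwo"`).
#' @return As [run_transone()].
#' @export
run_transtwo <- function(pairs, target_cell_line, model_config,
                         plan = transfer_plan("transTwo"), split_seed = 1L) {
  lines <- check_transfer_inputs(pairs, target_cell_line)
  splits <- split_all_lines(pairs, split_seed)
  pool <- dplyr::bind_rows(lapply(lines, function(l) splits[[l]]$train))
  eo <- choose_order(max(nchar(pairs$enhancer_seq)))
  po <- choose_order(max(nchar(pairs$promoter_seq)))
  model <- build_epi_model(model_config, 2^eo, 2^po)
  if (plan$pretrain_epochs > 0L) {
    model <- train_epi_model(model, pool, epochs = plan$pretrain_epochs,
                             early_stopping = FALSE)
  }
  tgt <- splits[[target_cell_line]]
  model <- train_epi_model(model, tgt$train, val = tgt$val,
                           epochs = plan$finetune_epochs,
                           early_stopping = FALSE,
                           freeze = conv_param_groups)
  scores <- predict(model, tgt$test)
  structure(
    list(model = model,
         evaluation = evaluate_scores(scores, tgt$test$label),
         plan = plan, target = target_cell_line,
         pretrain_n = nrow(pool), splits = splits),
    class = "epi_transfer_result"
  )
}

#' @export
print.epi_transfer_result <- function(x, ...) {
  cat(sprintf("<epi_transfer_result> %s -> %s | test AUC %.3f, AUPR %.3f\n",
              x$plan$strategy, x$target, x$evaluation$auc, x$evaluation$aupr))
  invisible(x)
}

#' Cross-cell-line performance grid
#'
#' Trains one line-specific model per cell line (on that line's training
#' split, early-stopped on its validation split) and evaluates every model
#' on every line's test split. The diagonal is line-specific performance;
#' the off-diagonal is cross-line generalisation, which without transfer
#' learning collapses towards chance when the lines' motif vocabularies
#' differ.
#'
#' @param pairs A pairs tibble spanning >= 2 cell lines.
#' @param model_config An [epi_model_config()].
#' @param split_seed Seed for the per-line splits.
#' @param verbose Print progress.
#' @return An object of class `epi_grid_result` holding square `auc` and
#'   `aupr` matrices (rows = test line, columns = train line).
#' @export
cross_cell_line_grid <- function(pairs, model_config, split_seed = 1L,
                                 verbose = FALSE) {
  lines <- unique(pairs$cell_line)
  if (length(lines) < 2L) stop("need at least two cell lines", call. = FALSE)
  splits <- split_all_lines(pairs, split_seed)
  eo <- choose_order(max(nchar(pairs$enhancer_seq)))
  po <- choose_order(max(nchar(pairs$promoter_seq)))
  auc <- aupr <- matrix(NA_real_, length(lines), length(lines),
                        dimnames = list(test = lines, train = lines))
  for (tr in lines) {
    if (verbose) message("training on ", tr)
    model <- build_epi_model(model_config, 2^eo, 2^po)
    model <- train_epi_model(model, splits[[tr]]$train, val = splits[[tr]]$val)
    for (te in lines) {
      scores <- predict(model, splits[[te]]$test)
      ev <- evaluate_scores(scores, splits[[te]]$test$label)
      auc[te, tr] <- ev$auc
      aupr[te, tr] <- ev$aupr
    }
  }
  structure(list(auc = auc, aupr = aupr, lines = lines),
            class = "epi_grid_result")
}

#' @export
print.epi_grid_result <- function(x, ...) {
  cat("<epi_grid_result> AUPR (rows = test line, cols = train line)\n")
  print(round(x$aupr, 3))
  invisible(x)
}

#' Write a cross-line grid as TSV matrices
#'
#' @param grid An [cross_cell_line_grid()] result.
#' @param auc_path,aupr_path Output TSVs (rows = test line, columns =
#'   train line).
#' @export
write_grid <- function(grid, auc_path, aupr_path) {
  stopifnot(inherits(grid, "epi_grid_result"))
  wr <- function(m, path) {
    readr::write_tsv(tibble::as_tibble(m, rownames = "test_cell_line"), path)
  }
  wr(grid$auc, auc_path)
  wr(grid$aupr, aupr_path)
  invisible(NULL)
}
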