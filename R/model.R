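#' Model configuration for the two-branch EPI classifier
#'
#' Architecture (per branch): two 3x3 same-padding convolutions, each
#' followed by ReLU and 2x2 max-pooling; the two branches (enhancer grid,
#' promoter grid) are flattened, concatenated, passed through one dense
#' ReLU layer with dropout, and a sigmoid output unit gives the interaction
#' probability. Training minimises binary cross-entropy with Adam.
#'
#' Defaults follow the published training recipe where one is stated
#' (learning rate 3e-4, batch size 100, up to 100 epochs, 8:1:1 splits,
#' early stopping) and conventional choices elsewhere (32/64 filters,
#' 3x3 kernels, 2x2 pools, 128 dense units, dropout 0.5, patience 5 on
#' validation loss). Everything is configurable; the architecture is
#' size-agnostic as long as each grid side is a power of two >= 8 (two 2x2
#' pools need at least a 2x2 map left).
#'
#' @param conv_filters Two filter counts, first and second conv layer.
#' @param kernel_size Odd kernel side (default 3).
#' @param pool_size Pooling window (fixed at 2; kept for config echo).
#' @param dense_units Width of the merged dense layer.
#' @param dropout_rate Dropout probability on the dense layer.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param early_stop_patience Epochs without validation-loss improvement
#'   tolerated before stopping.
#' @param seed Seed controlling initialisation, shuffling and dropout.
#' @return An object of class `epi_model_config`.
#' @export
epi_model_config <- function(conv_filters = c(32, 64), kernel_size = 3,
                             pool_size = 2, dense_units = 128,
                             dropout_rate = 0.5, learning_rate = 3e-4,
                             batch_size = 100, max_epochs = 100,
                             early_stop_patience = 5, seed = 1) {
  stopifnot(length(conv_filters) == 2, all(conv_filters >= 1),
            kernel_size %% 2 == 1, learning_rate > 0,
            dropout_rate >= 0, dropout_rate < 1, batch_size >= 1)
  structure(
    list(conv_filters = as.integer(conv_filters),
         kernel_size = as.integer(kernel_size), pool_size = 2L,
         dense_units = as.integer(dense_units), dropout_rate = dropout_rate,
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         early_stop_patience = as.integer(early_stop_patience),
         seed = as.integer(seed)),
    class = "epi_model_config"
  )
}

#' Build an untrained two-branch EPI classifier
#'
#' Instantiates the architecture of [epi_model_config()] for the given
#' enhancer and promoter grid sides and seeds the parameter tensors
#' deterministically from `config$seed` (same seed, bit-identical
#' parameters).
#'
#' @param config An [epi_model_config()].
#' @param enhancer_side,promoter_side Grid sides (powers of two, >= 8).
#' @return An object of class `epi_cnn`.
#' @export
build_epi_model <- function(config, enhancer_side, promoter_side) {
  stopifnot(inherits(config, "epi_model_config"))
  for (side in c(enhancer_side, promoter_side)) {
    if (side < 8 || bitwAnd(as.integer(side), as.integer(side) - 1L) != 0L) {
      stop(sprintf(
        "grid side %d unsupported: two 2x2 pools need a power-of-two side >= 8",
        side), call. = FALSE)
    }
  }
  specs <- list(
    enhancer = branch_specs(as.integer(enhancer_side), config$conv_filters[1],
                            config$conv_filters[2], config$kernel_size),
    promoter = branch_specs(as.integer(promoter_side), config$conv_filters[1],
                            config$conv_filters[2], config$kernel_size)
  )
  params <- withr::with_seed(config$seed, init_params(config, specs))
  structure(
    list(config = config, enhancer_side = as.integer(enhancer_side),
         promoter_side = as.integer(promoter_side), specs = specs,
         params = params, history = NULL, trained = FALSE),
    class = "epi_cnn"
  )
}

#' @export
print.epi_cnn <- function(x, ...) {
  cat(sprintf(
    "<epi_cnn> enhancer %dx%d + promoter %dx%d | conv %s, dense %d | %s\n",
    x$enhancer_side, x$enhancer_side, x$promoter_side, x$promoter_side,
    paste(x$config$conv_filters, collapse = "/"), x$config$dense_units,
    if (x$trained) sprintf("trained (stopped at epoch %d)",
                           attr(x$history, "stopped_epoch")) else "untrained"))
  invisible(x)
}

as_tensor_set <- function(data, model) {
  if (inherits(data, "epi_tensors")) return(data)
  eo <- as.integer(log2(model$enhancer_side))
  po <- as.integer(log2(model$promoter_side))
  encode_pairs(data, enhancer_order = eo, promoter_order = po)
}

tensor_matrices <- function(ts) {
  E <- ts$E
  dim(E) <- c(prod(dim(ts$E)[1:3]), dim(ts$E)[4])
  P <- ts$P
  dim(P) <- c(prod(dim(ts$P)[1:3]), dim(ts$P)[4])
  list(E = E, P = P, y = ts$label)
}

#' Train the EPI classifier
#'
#' Minimises binary cross-entropy with Adam on minibatches. When a
#' validation set is given and `early_stopping = TRUE`, training stops after
#' `early_stop_patience` epochs without validation-loss improvement and the
#' best-validation-loss parameters are restored (the untrained parameters
#' count as the baseline, so a run that never improves on them restores
#' them). Fully deterministic for a fixed config seed.
#'
#' @param model An [build_epi_model()] object.
#' @param train Training data: a pairs tibble or an `epi_tensors` set.
#' @param val Optional validation data (same forms).
#' @param epochs Epoch override (default `config$max_epochs`).
#' @param early_stopping Monitor validation loss (default `TRUE` when `val`
#'   given).
#' @param freeze Character vector of parameter groups excluded from
#'   updates, among `e_conv1`, `e_conv2`, `p_conv1`, `p_conv2`, `dense1`,
#'   `out` (used by the freezing transfer protocol).
#' @param verbose Print per-epoch progress.
#' @return The model, trained, with `$history` (a tibble of per-epoch train
#'   loss, validation loss and validation AUPR, with `stopped_epoch` and
#'   `best_epoch` attributes).
#' @export
train_epi_model <- function(model, train, val = NULL, epochs = NULL,
                            early_stopping = !is.null(val),
                            freeze = character(0), verbose = FALSE) {
  stopifnot(inherits(model, "epi_cnn"))
  if (is.data.frame(train) && nrow(train) == 0L) {
    stop("empty training set", call. = FALSE)
  }
  ts <- as_tensor_set(train, model)
  if (ts$n == 0L) stop("empty training set", call. = FALSE)
  tm <- tensor_matrices(ts)
  vm <- if (!is.null(val)) tensor_matrices(as_tensor_set(val, model))
  cfg <- model$config
  n_epochs <- if (is.null(epochs)) cfg$max_epochs else as.integer(epochs)

  skip_conv <- all(conv_param_groups %in% freeze)
  withr::with_seed(cfg$seed + 1L, {
    params <- model$params
    opt <- adam_init(params)
    best <- list(params = params, loss = Inf, epoch = 0L)
    if (!is.null(vm) && early_stopping) {
      best$loss <- validation_loss(params, vm, model$specs)
    }
    wait <- 0L
    hist <- vector("list", n_epochs)
    stopped <- n_epochs
    n <- ncol(tm$E)
    for (ep in seq_len(n_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      n_batches <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        sel <- ord[start:min(start + cfg$batch_size - 1L, n)]
        nb <- length(sel)
        drop_mask <- if (cfg$dropout_rate > 0) {
          matrix((stats::runif(cfg$dense_units * nb) >= cfg$dropout_rate) /
                   (1 - cfg$dropout_rate), cfg$dense_units, nb)
        }
        fw <- net_forward(params, tm$E[, sel, drop = FALSE],
                          tm$P[, sel, drop = FALSE], model$specs,
                          drop_mask = drop_mask, cache = if (skip_conv) "dense" else TRUE)
        y <- tm$y[sel]
        ep_loss <- ep_loss + bce_loss(fw$prob, y)
        n_batches <- n_batches + 1L
        dlogit <- (fw$prob - y) / nb
        grads <- net_backward(params, fw, dlogit, model$specs, nb,
                              skip_conv = skip_conv)
        upd <- adam_step(params, grads, opt, cfg$learning_rate, frozen = freeze)
        params <- upd$params
        opt <- upd$opt
      }
      row <- tibble::tibble(epoch = ep, train_loss = ep_loss / n_batches,
                            val_loss = NA_real_, val_aupr = NA_real_)
      if (!is.null(vm)) {
        vfw <- net_forward(params, vm$E, vm$P, model$specs)
        row$val_loss <- bce_loss(vfw$prob, vm$y)
        if (length(unique(vm$y)) > 1L) {
          row$val_aupr <- suppressWarnings(
            evaluate_scores(vfw$prob, vm$y)$aupr)
        }
      }
      hist[[ep]] <- row
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %s", ep,
                        row$train_loss,
                        ifelse(is.na(row$val_loss), "-", sprintf("%.4f", row$val_loss))))
      }
      if (!is.null(vm) && early_stopping) {
        if (row$val_loss < best$loss - 1e-9) {
          best <- list(params = params, loss = row$val_loss, epoch = ep)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait > cfg$early_stop_patience) {
            stopped <- ep
            break
          }
        }
      }
    }
    if (!is.null(vm) && early_stopping && best$epoch > 0L) {
      params <- best$params
    }
    model$params <- params
    history <- dplyr::bind_rows(hist[!vapply(hist, is.null, logical(1))])
    attr(history, "stopped_epoch") <- min(stopped, nrow(history))
    attr(history, "best_epoch") <- if (!is.null(vm) && early_stopping) best$epoch
                                   else nrow(history)
    model$history <- history
    model$trained <- TRUE
  })
  model
}

validation_loss <- function(params, vm, specs) {
  fw <- net_forward(params, vm$E, vm$P, specs)
  bce_loss(fw$prob, vm$y)
}

#' Predict interaction probabilities
#'
#' Deterministic inference (dropout off), chunked so memory stays bounded
#' for large pair sets.
#'
#' @param object A trained `epi_cnn`.
#' @param newdata A pairs tibble or an `epi_tensors` set encoded at the
#'   model's grid orders.
#' @param chunk_size Pairs per forward pass.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`, one per pair.
#' @export
predict.epi_cnn <- function(object, newdata, chunk_size = 256L, ...) {
  ts <- as_tensor_set(newdata, object)
  if (dim(ts$E)[1] != object$enhancer_side || dim(ts$P)[1] != object$promoter_side) {
    stop("encoding grid does not match the model's grid orders", call. = FALSE)
  }
  m <- tensor_matrices(ts)
  n <- ncol(m$E)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk_size)) {
    sel <- start:min(start + chunk_size - 1L, n)
    fw <- net_forward(object$params, m$E[, sel, drop = FALSE],
                      m$P[, sel, drop = FALSE], object$specs)
    out[sel] <- fw$prob
  }
  out
}

#' Save / load a model checkpoint
#'
#' One archive file holding the parameters, config, grid sides and training
#' history.
#'
#' @param model An `epi_cnn`.
#' @param path Checkpoint path.
#' @return `path` (save) or the restored `epi_cnn` (load).
#' @export
save_epi_model <- function(model, path) {
  stopifnot(inherits(model, "epi_cnn"))
  saveRDS(model[c("config", "enhancer_side", "promoter_side", "params",
                  "history", "trained")], path)
  invisible(path)
}

#' @rdname save_epi_model
#' @export
load_epi_model <- function(path) {
  st <- readRDS(path)
  model <- build_epi_model(st$config, st$enhancer_side, st$promoter_side)
  model$params <- st$params
  model$history <- st$history
  model$trained <- st$trained
  model
}

#' Export a training history as TSV
#'
#' @param model A trained `epi_cnn`.
#' @param path Output TSV.
#' @export
write_history <- function(model, path) {
  stopifnot(inherits(model, "epi_cnn"), !is.null(model$history))
  readr::write_tsv(model$history, path)
  invisible(path)
}
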