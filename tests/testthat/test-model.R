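# Small, quickly separable fixture shared by the training tests: one motif
# pair implanted as 3-site clusters in 64-bp sequences (order-3 grids).
separable_fixture <- function(seed = 21) {
  sim <- simulate_epi(sim_config(
    n_cell_lines = 1, n_positive = 200, n_negative = 4000,
    enhancer_len = 64, promoter_len = 64,
    enhancer_motif_copies = 3, promoter_motif_copies = 3,
    n_shared_motif_pairs = 1, n_specific_motif_pairs = 0,
    mutation_rate = 0, hard_negative_rate = 0.1, seed = seed))
  bal <- under_sample_negatives(sim$pairs, 200, seed = seed + 1)
  split_pairs(bal, seed = seed + 2)
}

train_config <- function(seed = 24) {
  epi_model_config(conv_filters = c(8, 16), dense_units = 32,
                   dropout_rate = 0.3, learning_rate = 1.5e-3,
                   batch_size = 50, max_epochs = 20,
                   early_stop_patience = 20, seed = seed)
}

test_that("model builds deterministically with the declared geometry", {
  cfg <- tiny_config(seed = 5)
  m <- build_epi_model(cfg, 64, 16)
  expect_equal(dim(m$params$out$W), c(1L, 4L))
  expect_equal(nrow(m$params$dense1$W), 4L)
  # forward pass on an all-zero tensor gives one finite probability
  zero <- tibble::tibble(enhancer_id = "e", promoter_id = "p",
                         enhancer_seq = strrep("N", 100),
                         promoter_seq = strrep("N", 100),
                         label = 0L, cell_line = "x")
  pr <- predict(m, encode_pairs(zero, 6, 4))
  expect_length(pr, 1L)
  expect_true(is.finite(pr) && pr >= 0 && pr <= 1)
  # same seed -> bit-identical parameters; different seed -> different
  m2 <- build_epi_model(cfg, 64, 16)
  expect_identical(m$params, m2$params)
  m3 <- build_epi_model(tiny_config(seed = 6), 64, 16)
  expect_false(identical(m$params$dense1$W, m3$params$dense1$W))
  # geometry limits: two 2x2 pools need side >= 8
  expect_silent(build_epi_model(cfg, 8, 8))
  expect_error(build_epi_model(cfg, 4, 8), "side 4")
  expect_error(build_epi_model(cfg, 24, 8), "power-of-two")
})

test_that("training separates planted-motif data within 20 epochs", {
  sp <- separable_fixture()
  m <- build_epi_model(train_config(), 8, 8)
  m <- train_epi_model(m, sp$train, sp$val, early_stopping = FALSE)
  h <- tidy(m)
  expect_gt(max(h$val_aupr, na.rm = TRUE), 0.9)
  expect_equal(nrow(h), 20L)
  # training loss trends down overall
  expect_lt(mean(tail(h$train_loss, 3)), mean(head(h$train_loss, 3)))
  # scores on planted positives exceed scores on negatives on average
  sc <- predict(m, sp$test)
  expect_gt(mean(sc[sp$test$label == 1]), mean(sc[sp$test$label == 0]))
  # probabilities bounded
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("training is deterministic and prediction is dropout-free", {
  sp <- separable_fixture()
  small <- sp$train[1:40, ]
  cfg <- epi_model_config(conv_filters = c(4, 8), dense_units = 8,
                          dropout_rate = 0.5, learning_rate = 1e-3,
                          batch_size = 20, max_epochs = 3, seed = 17)
  m1 <- train_epi_model(build_epi_model(cfg, 8, 8), small, epochs = 3,
                        early_stopping = FALSE)
  m2 <- train_epi_model(build_epi_model(cfg, 8, 8), small, epochs = 3,
                        early_stopping = FALSE)
  expect_identical(m1$params, m2$params)  # strict determinism under one seed
  p1 <- predict(m1, sp$val)
  expect_identical(p1, predict(m1, sp$val))  # inference has no randomness
  expect_length(p1, nrow(sp$val))
})

test_that("early stopping restores the best parameters and respects patience", {
  sp <- separable_fixture()
  # patience 0 with a vanishing learning rate: validation never improves
  # beyond the untrained baseline, so training stops after the first epoch
  cfg0 <- epi_model_config(conv_filters = c(2, 2), dense_units = 4,
                           dropout_rate = 0, learning_rate = 1e-15,
                           batch_size = 32, max_epochs = 10,
                           early_stop_patience = 0, seed = 3)
  m0 <- train_epi_model(build_epi_model(cfg0, 8, 8), sp$train[1:40, ],
                        sp$val[1:20, ])
  expect_equal(attr(m0$history, "stopped_epoch"), 1L)
  expect_lte(attr(m0$history, "stopped_epoch"), cfg0$max_epochs)

  # with real training the restored parameters score the best epoch's loss
  cfg <- train_config(seed = 31)
  m <- train_epi_model(build_epi_model(cfg, 8, 8), sp$train, sp$val,
                       epochs = 12)
  h <- tidy(m)
  best <- attr(m$history, "best_epoch")
  expect_equal(h$val_loss[best], min(h$val_loss))
  vm <- epifold:::tensor_matrices(epifold:::as_tensor_set(sp$val, m))
  expect_equal(epifold:::validation_loss(m$params, vm, m$specs),
               h$val_loss[best])
})

test_that("label-shuffled training generalises at chance level", {
  sim <- simulate_epi(sim_config(
    n_cell_lines = 1, n_positive = 150, n_negative = 3000,
    enhancer_len = 64, promoter_len = 64,
    enhancer_motif_copies = 3, promoter_motif_copies = 3,
    n_shared_motif_pairs = 1, n_specific_motif_pairs = 0, seed = 41))
  bal <- under_sample_negatives(sim$pairs, 150, seed = 42)
  shuf <- bal
  shuf$label <- withr::with_seed(43, sample(shuf$label))
  sp <- split_pairs(shuf, seed = 44)
  m <- train_epi_model(build_epi_model(train_config(seed = 45), 8, 8),
                       sp$train, epochs = 8, early_stopping = FALSE)
  # evaluate against the held-out truth: a noise-trained model is blind to it
  ev <- evaluate_scores(predict(m, bal), bal$label)
  expect_gt(ev$auc, 0.4)
  expect_lt(ev$auc, 0.6)
})

test_that("checkpoints round-trip through a single archive file", {
  sp <- separable_fixture()
  cfg <- tiny_config(seed = 2)
  m <- train_epi_model(build_epi_model(cfg, 8, 8), sp$train[1:30, ], epochs = 1,
                       early_stopping = FALSE)
  path <- tempfile(fileext = ".rds")
  save_epi_model(m, path)
  m2 <- load_epi_model(path)
  expect_identical(m2$params, m$params)
  expect_identical(m2$config, m$config)
  expect_identical(predict(m2, sp$val[1:10, ]), predict(m, sp$val[1:10, ]))
  expect_error(train_epi_model(m, sp$train[0, ]), "empty")
})

test_that("glance summarises a fitted model", {
  sp <- separable_fixture()
  m <- train_epi_model(build_epi_model(tiny_config(seed = 9), 8, 8),
                       sp$train[1:30, ], sp$val[1:10, ], epochs = 2)
  g <- glance(m)
  expect_equal(nrow(g), 1L)
  expect_gt(g$n_parameters, 0)
  expect_true(g$stopped_epoch <= 2)
})
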