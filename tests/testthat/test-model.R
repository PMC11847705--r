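test_that("the combiner mixes branch predictions without a bias term", {
  enc <- tiny_encoded()
  model <- comet_model(embed_dim = 6, hidden_dim = 4, n_layers = 2,
                       n_analytes = ncol(enc$omics), task = "continuous",
                       mode = "full", dropout = 0, seed = 2)
  expect_length(model$params$combiner, 3)
  batch <- comet:::batch_slice(enc, 1:5, model)
  # combiner = (1, 0, 0): output tracks the EHR branch only
  model$params$combiner <- c(1, 0, 0)
  f1 <- comet:::forward_model(model, batch)
  batch2 <- batch
  batch2$omics <- batch2$omics + 100
  f2 <- comet:::forward_model(model, batch2)
  expect_equal(f1$yhat, f2$yhat, tolerance = 1e-12)
  expect_equal(f1$yhat, unname(f1$branches[, "ehr"]), tolerance = 1e-12)
  # all-zero branch values give exactly zero output (no bias anywhere to add)
  expect_equal(drop(cbind(0, 0, 0) %*% model$params$combiner), 0)
})

test_that("a zero combined score maps to probability one half", {
  enc <- tiny_encoded()
  model <- comet_model(embed_dim = 6, hidden_dim = 4, n_layers = 2,
                       n_analytes = ncol(enc$omics), task = "binary",
                       mode = "full", dropout = 0, seed = 2)
  model$params$combiner <- c(0, 0, 0)
  batch <- comet:::batch_slice(enc, 1:4, model)
  f <- comet:::forward_model(model, batch)
  expect_equal(unname(f$yhat), rep(0.5, 4))
})

test_that("forward reports dimension mismatches by branch", {
  enc <- tiny_encoded()
  model <- comet_model(embed_dim = 9, hidden_dim = 4, n_layers = 1,
                       n_analytes = ncol(enc$omics), task = "continuous",
                       mode = "full", seed = 1)
  expect_error(comet:::forward_model(model, comet:::batch_slice(enc, 1:3, model)),
               "EHR branch")
  model2 <- comet_model(embed_dim = 6, hidden_dim = 4, n_layers = 1,
                        n_analytes = 99, task = "continuous",
                        mode = "full", seed = 1)
  expect_error(comet:::forward_model(model2, comet:::batch_slice(enc, 1:3, model2)),
               "omics branch")
})

test_that("single-branch baselines equal the full network with ablated combiner", {
  enc <- tiny_encoded()
  full <- comet_model(embed_dim = 6, hidden_dim = 4, n_layers = 2,
                      n_analytes = ncol(enc$omics), task = "continuous",
                      mode = "full", dropout = 0, seed = 11)
  batch_full <- comet:::batch_slice(enc, 1:6, full)
  fwd <- comet:::forward_model(full, batch_full)
  # EHR-only baseline: same rnn + head weights
  ehr <- comet_model(embed_dim = 6, hidden_dim = 4, n_layers = 2,
                     task = "continuous", mode = "ehr", dropout = 0, seed = 99)
  ehr$params$rnn <- full$params$rnn
  ehr$params$ehr_head <- full$params$ehr_head
  p_ehr <- comet:::forward_model(ehr, comet:::batch_slice(enc, 1:6, ehr))$yhat
  expect_equal(p_ehr, unname(fwd$branches[, "ehr"]), tolerance = 1e-12)
  # omics-only baseline
  omx <- comet_model(embed_dim = 6, hidden_dim = 4,
                     n_analytes = ncol(enc$omics), task = "continuous",
                     mode = "omics", seed = 98)
  omx$params$omics_head <- full$params$omics_head
  p_om <- comet:::forward_model(omx, comet:::batch_slice(enc, 1:6, omx))$yhat
  expect_equal(p_om, unname(fwd$branches[, "omics"]), tolerance = 1e-12)
})

test_that("transfer freezes the encoder exactly through multimodal training", {
  enc <- tiny_encoded()
  pre_enc <- comet:::encode_cohort(cohort_subset(tiny_gen()$cohort, "pretraining"),
                                   tiny_embeddings())
  ptr <- pretrain_ehr(pre_enc, embed_dim = 6, hidden_dim = 4, n_layers = 2,
                      dropout = 0,
                      config = train_config(batch_size = 16, max_epochs = 4,
                                            seed = 5))
  fresh <- comet_model(embed_dim = 6, hidden_dim = 4, n_layers = 2,
                       n_analytes = ncol(enc$omics), task = "continuous",
                       mode = "full", dropout = 0, seed = 6)
  tf <- transfer_and_freeze(ptr$model, fresh)
  expect_true("rnn" %in% tf$frozen)
  # identity before any multimodal training: EHR branch reproduces the
  # pretrained model's forward pass
  b <- comet:::batch_slice(enc, 1:6, tf)
  fwd <- comet:::forward_model(tf, b)
  pre_b <- comet:::batch_slice(enc, 1:6, ptr$model)
  expect_equal(unname(fwd$branches[, "ehr"]),
               comet:::forward_model(ptr$model, pre_b)$yhat,
               tolerance = 1e-12)
  # after training, serialized encoder weights are bitwise identical
  fit <- train_model(tf, comet:::encoded_subset(enc, 1:10),
                     comet:::encoded_subset(enc, 11:16),
                     train_config(batch_size = 8, max_epochs = 6, seed = 7))
  expect_identical(serialize(fit$model$params$rnn, NULL),
                   serialize(ptr$model$params$rnn, NULL))
  # but the trainable parts moved
  expect_false(identical(fit$model$params$joint_head, tf$params$joint_head))
  # incompatible hidden dimensions are refused
  small <- comet_model(embed_dim = 6, hidden_dim = 3, n_layers = 2,
                       n_analytes = ncol(enc$omics), task = "continuous",
                       mode = "full", seed = 1)
  expect_error(transfer_and_freeze(ptr$model, small), "shapes")
})

test_that("training restores the best epoch and stops after patience is exhausted", {
  enc <- tiny_encoded()
  model <- comet_model(embed_dim = 6, hidden_dim = 4, n_layers = 1,
                       n_analytes = ncol(enc$omics), task = "continuous",
                       mode = "omics", seed = 3)
  fit <- train_model(model, comet:::encoded_subset(enc, 1:10),
                     comet:::encoded_subset(enc, 11:16),
                     train_config(batch_size = 8, max_epochs = 50,
                                  patience = 5, seed = 4))
  tr <- fit$trace
  expect_lte(tr$best_epoch, tr$stop_epoch)
  expect_lte(tr$stop_epoch, 50)
  if (tr$stop_epoch < 50) {
    # stopping epoch is exactly patience epochs past the best one
    expect_equal(tr$stop_epoch, tr$best_epoch + 5)
  }
  # restored parameters reproduce the recorded best test loss
  pred <- predict(fit$model, comet:::encoded_subset(enc, 11:16))
  expect_equal(task_loss(enc$y[11:16], pred, "continuous"),
               min(tr$test_loss), tolerance = 1e-10)
})

test_that("training is reproducible under a fixed seed", {
  enc <- tiny_encoded()
  run <- function() {
    model <- comet_model(embed_dim = 6, hidden_dim = 4, n_layers = 2,
                         n_analytes = ncol(enc$omics), task = "continuous",
                         mode = "full", dropout = 0.2, seed = 21)
    train_model(model, comet:::encoded_subset(enc, 1:10),
                comet:::encoded_subset(enc, 11:16),
                train_config(batch_size = 8, max_epochs = 5, seed = 22))
  }
  expect_identical(serialize(run()$model$params, NULL),
                   serialize(run()$model$params, NULL))
})

test_that("a one-patient pretraining cohort still trains to finite weights", {
  gen1 <- generate_cohort(synthetic_config(n_pretrain = 1, n_omics = 1,
                                           vocab_size = 10, horizon = 5,
                                           seed = 3))
  tab <- train_embeddings(build_sentences(gen1$cohort, 1), d = 4, seed = 1)
  enc1 <- comet:::encode_cohort(cohort_subset(gen1$cohort, "pretraining"), tab)
  expect_warning(
    ptr <- pretrain_ehr(enc1, embed_dim = 4, hidden_dim = 3, n_layers = 1,
                        config = train_config(batch_size = 4, max_epochs = 3,
                                              seed = 1)),
    "identical")
  expect_true(all(vapply(comet:::tree_map(function(x) all(is.finite(x)),
                                          ptr$model$params) |> unlist(), isTRUE,
                         TRUE)))
})

test_that("grid search returns the single grid point and keeps folds patient-grouped", {
  enc <- tiny_encoded()
  grid <- data.frame(lr = 0.01, dropout = 0, n_layers = 1, hidden_dim = 3)
  gs <- grid_search(grid, enc, mode = "omics",
                    base_config = train_config(batch_size = 8, max_epochs = 3,
                                               seed = 2), seed = 3)
  expect_equal(gs$index, 1L)
  expect_equal(gs$best$lr, 0.01)
})

test_that("grid search prefers a clearly dominant setting on synthetic data", {
  # a near-zero learning rate cannot fit anything; the sane rate must win
  wins <- vapply(1:5, function(s) {
    gen <- generate_cohort(synthetic_config(n_pretrain = 1, n_omics = 25,
                                            vocab_size = 15, n_analytes = 6,
                                            horizon = 6, latent_dim = 2,
                                            samples_per_patient = 1,
                                            omics_noise = 0.3, seed = 100 + s))
    tab <- train_embeddings(build_sentences(gen$cohort, 1), d = 4, seed = 1)
    enc <- comet:::encode_cohort(cohort_subset(gen$cohort, "omics"), tab)
    grid <- data.frame(lr = c(1e-2, 1e-9), dropout = 0, n_layers = 1,
                       hidden_dim = 3)
    gs <- grid_search(grid, enc, mode = "omics",
                      base_config = train_config(batch_size = 8,
                                                 max_epochs = 25, seed = s),
                      seed = s)
    gs$index == 1L
  }, TRUE)
  expect_gte(sum(wins), 4)
})

test_that("checkpoints round-trip weights, frozen flags and config", {
  enc <- tiny_encoded()
  model <- comet_model(embed_dim = 6, hidden_dim = 4, n_layers = 1,
                       n_analytes = ncol(enc$omics), task = "continuous",
                       mode = "full", seed = 31)
  model$frozen <- "rnn"
  f <- withr::local_tempfile(fileext = ".rds")
  fit <- train_model(model, comet:::encoded_subset(enc, 1:10),
                     comet:::encoded_subset(enc, 11:16),
                     train_config(batch_size = 8, max_epochs = 2, seed = 32))
  save_checkpoint(fit$model, f, trace = fit$trace)
  back <- load_checkpoint(f)
  expect_identical(serialize(back$params, NULL),
                   serialize(fit$model$params, NULL))
  expect_equal(back$frozen, "rnn")
  side <- jsonlite::read_json(paste0(f, ".trace.json"), simplifyVector = TRUE)
  expect_equal(side$stop_epoch, fit$trace$stop_epoch)
})
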