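toy_full_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      enc <- tiny_encoded()
      model <- comet_model(embed_dim = 6, hidden_dim = 4, n_layers = 1,
                           n_analytes = ncol(enc$omics), task = "continuous",
                           mode = "full", dropout = 0, seed = 13)
      fit <- train_model(model, comet:::encoded_subset(enc, 1:10),
                         comet:::encoded_subset(enc, 11:16),
                         train_config(batch_size = 8, max_epochs = 8, seed = 14))
      cache <<- fit$model
    }
    cache
  }
})

test_that("integrated gradients are exact for linear maps and null at the baseline", {
  enc <- tiny_encoded()
  model <- toy_full_model()
  # the regression architecture is linear in the omics vector given the EHR
  # sequence, so even m = 1 is exact and completeness holds to round-off
  ig <- integrated_gradients(model, enc, idx = 1:5, m = 1)
  expect_lt(max(abs(ig$completeness)), 1e-10)
  # a pure linear function f(x) = 2 x1: attributions (2 x1, 0, ...)
  lin <- comet_model(embed_dim = 6, hidden_dim = 4, n_layers = 1,
                     n_analytes = ncol(enc$omics), task = "continuous",
                     mode = "omics", seed = 1)
  lin$params$omics_head$W[] <- c(2, rep(0, ncol(enc$omics) - 1))
  lin$params$omics_head$b <- 0
  ig2 <- integrated_gradients(lin, enc, idx = 3, m = 4)
  expect_equal(unname(ig2$attributions[1, 1]), 2 * enc$omics[3, 1])
  expect_equal(unname(ig2$attributions[1, -1]), rep(0, ncol(enc$omics) - 1))
  # x = baseline gives all-zero attributions
  encz <- enc
  encz$omics[2, ] <- 0
  ig3 <- integrated_gradients(model, encz, idx = 2, m = 8)
  expect_equal(max(abs(ig3$attributions)), 0)
})

test_that("integrated gradients satisfy completeness on a nonlinear model", {
  enc <- tiny_encoded()
  enc$y <- as.numeric(enc$y > median(enc$y))
  enc$task <- "binary"
  model <- comet_model(embed_dim = 6, hidden_dim = 4, n_layers = 1,
                       n_analytes = ncol(enc$omics), task = "binary",
                       mode = "full", dropout = 0, omics_hidden = 6, seed = 15)
  fit <- train_model(model, comet:::encoded_subset(enc, 1:10),
                     comet:::encoded_subset(enc, 11:16),
                     train_config(batch_size = 8, max_epochs = 5, seed = 16))
  ig <- integrated_gradients(fit$model, enc, idx = 1:8, m = 256)
  tol <- 1e-3 * abs(ig$f_x - ig$f_baseline) + 1e-6
  expect_true(all(abs(ig$completeness) <= tol))
  # the m = 256 Riemann sum is close to a near-exact m = 4096 reference
  ig_ref <- integrated_gradients(fit$model, enc, idx = 1:8, m = 4096)
  expect_equal(ig$attributions, ig_ref$attributions, tolerance = 1e-2)
})

test_that("latent alignment counts Bonferroni-significant correlations", {
  set.seed(21)
  n <- 171
  om <- matrix(rnorm(n * 6), n, 6)
  # one latent dimension duplicates an analyte: that pair must be significant
  lat <- cbind(om[, 3], matrix(rnorm(n * 3), n, 3))
  al <- latent_alignment(lat, om)
  expect_true(al$p[1, 3] < al$threshold)
  expect_gte(al$n_significant, 1)
  expect_equal(al$threshold, 0.05 / (4 * 6))
  # per-analyte fractions are consistent with the significance matrix
  expect_equal(al$per_analyte_fraction[3], mean(al$p[, 3] < al$threshold))
  # forcing p-values to 1 gives a zero count
  al0 <- latent_alignment(matrix(rnorm(n * 4), n, 4), om, alpha = 1e-12)
  expect_equal(al0$n_significant, 0)
  # constant columns are flagged, not significant
  lat2 <- cbind(lat, 1)
  al2 <- latent_alignment(lat2, om)
  expect_match(al2$note, "constant")
})

test_that("alignment counts are invariant to column permutations", {
  set.seed(22)
  lat <- matrix(rnorm(120 * 5), 120, 5)
  om <- lat[, c(1, 2, 3)] + matrix(rnorm(120 * 3, sd = 0.5), 120, 3)
  a1 <- latent_alignment(lat, om)
  a2 <- latent_alignment(lat[, sample(5)], om[, sample(3)])
  expect_equal(a1$n_significant, a2$n_significant)
})

test_that("correlation maps embed correlation profiles with seeded t-SNE", {
  set.seed(23)
  n <- 60
  ehr <- matrix(rbinom(n * 5, 1, 0.4), n, 5)
  om <- matrix(rnorm(n * 4), n, 4)
  om[, 1] <- ehr[, 1] * 2 + rnorm(n, sd = 0.3)   # one strong cross-modal pair
  feats <- cbind(ehr, om)
  mod <- c(rep("ehr", 5), rep("omics", 4))
  y <- rnorm(n)
  cm <- correlation_map(feats, mod, y, seed = 4)
  expect_equal(dim(cm$coords), c(9, 2))
  expect_gte(cm$per_analyte_sig[1], 1)
  expect_length(cm$ehr_max_abs_cor, 5)
  # determinism under the seed
  cm2 <- correlation_map(feats, mod, y, seed = 4)
  expect_identical(cm$coords, cm2$coords)
  # identical features have identical correlation profiles (distance 0)
  feats2 <- cbind(feats, feats[, 1])
  C <- suppressWarnings(cor(feats2)); C[is.na(C)] <- 0; diag(C) <- 1
  expect_equal(C[1, ], C[10, ], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("intermediate nodes are scored against the outcome per branch", {
  enc <- tiny_encoded()
  model <- toy_full_model()
  perf <- intermediate_node_performance(model, enc)
  expect_named(perf, c("ehr", "omics", "joint"))
  # a branch whose value equals the outcome scores r = 1: force it through
  # a probe model whose omics head copies the outcome via a single analyte
  enc2 <- enc
  enc2$omics <- cbind(enc$y, enc$omics[, -1])
  probe <- comet_model(embed_dim = 6, hidden_dim = 4, n_layers = 1,
                       n_analytes = ncol(enc2$omics), task = "continuous",
                       mode = "full", dropout = 0, seed = 2)
  probe$params$omics_head$W[] <- c(1, rep(0, ncol(enc2$omics) - 1))
  probe$params$omics_head$b <- 0
  perf2 <- intermediate_node_performance(probe, enc2)
  expect_equal(unname(perf2["omics"]), 1)
})

test_that("pure-noise branch values score near chance AUROC", {
  set.seed(31)
  n <- 500
  y <- rbinom(n, 1, 0.5)
  noise <- rnorm(n)
  expect_lt(abs(comet:::auroc(y, noise) - 0.5), 0.07)
})

test_that("function-space traces distinguish runs and preserve identical snapshots", {
  enc <- tiny_encoded()
  model <- comet_model(embed_dim = 6, hidden_dim = 4, n_layers = 1,
                       n_analytes = ncol(enc$omics), task = "continuous",
                       mode = "full", dropout = 0, seed = 41)
  fit <- train_model(model, comet:::encoded_subset(enc, 1:10),
                     comet:::encoded_subset(enc, 11:16),
                     train_config(batch_size = 8, max_epochs = 6, seed = 42,
                                  snapshots = TRUE))
  snaps <- fit$trace$snapshots
  runs <- list(a = list(model = model, snapshots = snaps),
               frozen_run = list(model = model,
                                 snapshots = list(snaps[[1]], snaps[[1]],
                                                  snaps[[1]])))
  trace <- function_space_trace(runs, enc, view = "overall", seed = 43)
  expect_equal(nrow(trace$coords), length(snaps) + 3)
  # a run that never updates yields identical output rows
  frozen_rows <- trace$outputs[trace$meta$run == "frozen_run", ]
  expect_equal(max(dist(frozen_rows)), 0)
  # branch views have the same shape
  tr2 <- function_space_trace(runs, enc, view = "omics", seed = 43)
  expect_equal(dim(tr2$outputs), dim(trace$outputs))
})
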