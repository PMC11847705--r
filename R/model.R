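#' Construct a COMET multimodal model
#'
#' The full architecture has three branches: an EHR branch (a gated
#' recurrent unit stack over daily summary embeddings, or a transformer
#' encoder, followed by a single linear prediction layer), an omics branch
#' (a single linear layer for regression, or a one-hidden-layer perceptron
#' with rectifier nonlinearity for classification), and a joint branch (a
#' single linear layer over the concatenated EHR latent state and omics
#' vector). A final bias-free linear layer combines the three branch
#' predictions. For classification the branches produce raw scores that
#' are combined on the logit scale; the logistic link is applied to the
#' combined score (and to the omics branch's own score when it stands
#' alone as the omics-only baseline).
#'
#' `mode` selects the sub-architecture: `"full"` (all branches),
#' `"ehr"` (the EHR branch alone, the EHR-only baseline and the
#' pretraining network) or `"omics"` (the omics branch alone).
#'
#' @param embed_dim Input embedding dimension per day (d).
#' @param hidden_dim Recurrent hidden dimension (400 at paper scale).
#' @param n_layers Recurrent layers (2 or 4).
#' @param n_analytes Omics input dimension P (0 for `"ehr"` mode).
#' @param task `"continuous"` or `"binary"`.
#' @param mode `"full"`, `"ehr"` or `"omics"`.
#' @param dropout Dropout between recurrent layers during training.
#' @param omics_hidden Hidden width of the classification omics perceptron
#'   (16, 32 or 64 in the grid).
#' @param encoder `"gru"` or `"transformer"`.
#' @param transformer A [transformer_config()] when `encoder` is
#'   `"transformer"`.
#' @param vocab_size Code vocabulary size (transformer encoder only).
#' @param seed Weight initialization seed.
#' @return A `comet_model`.
#' @export
comet_model <- function(embed_dim, hidden_dim, n_layers = 2, n_analytes = 0,
                        task = c("continuous", "binary"),
                        mode = c("full", "ehr", "omics"),
                        dropout = 0.1, omics_hidden = 32,
                        encoder = c("gru", "transformer"),
                        transformer = NULL, vocab_size = NULL, seed = 1) {
  task <- match.arg(task)
  mode <- match.arg(mode)
  encoder <- match.arg(encoder)
  stopifnot(hidden_dim >= 1)
  params <- with_seed(seed, {
    p <- list()
    if (mode != "omics") {
      if (encoder == "gru") {
        p$rnn <- gru_init(embed_dim, hidden_dim, n_layers)
      } else {
        if (is.null(transformer)) transformer <- transformer_config(d = hidden_dim)
        if (is.null(vocab_size)) {
          stopf("comet_model: transformer encoder needs vocab_size")
        }
        p$rnn <- transformer_init(transformer, vocab_size)
        hidden_dim <- transformer$d
      }
      p$ehr_head <- list(W = init_mat(hidden_dim, 1, hidden_dim),
                         b = init_vec(1, hidden_dim))
    }
    if (mode != "ehr") {
      stopifnot(n_analytes >= 1)
      if (task == "continuous") {
        p$omics_head <- list(W = init_mat(n_analytes, 1, n_analytes),
                             b = init_vec(1, n_analytes))
      } else {
        p$omics_head <- list(W1 = init_mat(n_analytes, omics_hidden, n_analytes),
                             b1 = init_vec(omics_hidden, n_analytes),
                             W2 = init_mat(omics_hidden, 1, omics_hidden),
                             b2 = init_vec(1, omics_hidden))
      }
    }
    if (mode == "full") {
      p$joint_head <- list(W = init_mat(hidden_dim + n_analytes, 1,
                                        hidden_dim + n_analytes),
                           b = init_vec(1, hidden_dim + n_analytes))
      p$combiner <- init_vec(3, 3)
    }
    p
  })
  structure(list(
    params = params, task = task, mode = mode, encoder = encoder,
    frozen = character(),
    config = list(embed_dim = embed_dim, hidden_dim = hidden_dim,
                  n_layers = n_layers, n_analytes = n_analytes,
                  dropout = dropout, omics_hidden = omics_hidden,
                  transformer = transformer, vocab_size = vocab_size,
                  seed = seed)
  ), class = "comet_model")
}

#' @export
print.comet_model <- function(x, ...) {
  cat(sprintf("comet_model (%s, %s mode, %s encoder)\n",
              x$task, x$mode, x$encoder))
  cat(sprintf("  hidden %d x %d layers; %d analytes%s\n",
              x$config$hidden_dim, x$config$n_layers, x$config$n_analytes,
              if (length(x$frozen)) paste0("; frozen: ",
                                           paste(x$frozen, collapse = ","))
              else ""))
  invisible(x)
}

# ---- forward / backward -----------------------------------------------------

# batch: list(X, lengths, omics, tokens (transformer)); returns yhat, raw
# combined score, branch values, latent h, and caches for backprop.
forward_model <- function(model, batch, training = FALSE, want_cache = FALSE) {
  p <- model$params
  mode <- model$mode
  B <- length(batch$lengths %||% batch$y %||% rep(0, nrow(batch$omics)))
  if (!is.null(batch$omics)) B <- max(B, nrow(batch$omics))
  h <- NULL; enc_cache <- NULL
  if (mode != "omics") {
    if (model$encoder == "gru") {
      if (dim(batch$X)[3] != nrow(p$rnn[[1]]$Wi)) {
        stopf("forward: EHR branch input dimension %d != expected %d",
              dim(batch$X)[3], nrow(p$rnn[[1]]$Wi))
      }
      enc <- gru_forward(p$rnn, batch$X, batch$lengths,
                         dropout = model$config$dropout, training = training,
                         want_cache = want_cache)
    } else {
      enc <- transformer_forward(p$rnn, batch$tokens, model$config$transformer,
                                 dropout = model$config$dropout,
                                 training = training, want_cache = want_cache)
    }
    h <- enc$h
    enc_cache <- enc$cache
    B <- nrow(h)
    p_ehr <- drop(h %*% p$ehr_head$W) + p$ehr_head$b
  }
  om_cache <- NULL
  if (mode != "ehr") {
    x_om <- batch$omics
    if (ncol(x_om) != model$config$n_analytes) {
      stopf("forward: omics branch input dimension %d != expected %d",
            ncol(x_om), model$config$n_analytes)
    }
    if (model$task == "continuous") {
      p_om <- drop(x_om %*% p$omics_head$W) + p$omics_head$b
    } else {
      a1 <- sweep(x_om %*% p$omics_head$W1, 2, p$omics_head$b1, "+")
      z1 <- pmax(a1, 0)
      p_om <- drop(z1 %*% p$omics_head$W2) + p$omics_head$b2
      om_cache <- list(a1 = a1, z1 = z1)
    }
  }
  if (mode == "full") {
    hx <- cbind(h, batch$omics)
    p_joint <- drop(hx %*% p$joint_head$W) + p$joint_head$b
    branches <- cbind(ehr = p_ehr, omics = p_om, joint = p_joint)
    raw <- drop(branches %*% p$combiner)
  } else if (mode == "ehr") {
    branches <- cbind(ehr = p_ehr)
    raw <- p_ehr
  } else {
    branches <- cbind(omics = p_om)
    raw <- p_om
  }
  raw <- unname(raw)
  yhat <- if (model$task == "binary") logistic(raw) else raw
  list(yhat = yhat, raw = raw, branches = branches, h = h,
       cache = list(enc = enc_cache, om = om_cache, batch = batch))
}

# gradient of the task loss w.r.t. every parameter; fwd must carry caches
backward_model <- function(model, fwd, y) {
  p <- model$params
  B <- length(y)
  # d loss / d raw: MSE with identity output, BCE with logistic output both
  # reduce to (prediction - target) / B (x2 for the squared error)
  draw <- if (model$task == "continuous") 2 * (fwd$yhat - y) / B
          else (fwd$yhat - y) / B
  g <- list()
  dh <- NULL
  mode <- model$mode
  batch <- fwd$cache$batch
  if (mode == "full") {
    g$combiner <- drop(crossprod(fwd$branches, draw))
    db <- outer(draw, p$combiner)        # B x 3: ehr, omics, joint
    d_ehr <- db[, 1]; d_om <- db[, 2]; d_joint <- db[, 3]
  } else if (mode == "ehr") {
    d_ehr <- draw
  } else {
    d_om <- draw
  }
  if (mode != "omics") {
    H <- nrow(p$ehr_head$W)
    g$ehr_head <- list(W = crossprod(fwd$h, matrix(d_ehr, ncol = 1)),
                       b = sum(d_ehr))
    dh <- matrix(d_ehr, ncol = 1) %*% t(p$ehr_head$W)
  }
  if (mode != "ehr") {
    x_om <- batch$omics
    if (model$task == "continuous") {
      g$omics_head <- list(W = crossprod(x_om, matrix(d_om, ncol = 1)),
                           b = sum(d_om))
    } else {
      z1 <- fwd$cache$om$z1
      dz1 <- matrix(d_om, ncol = 1) %*% t(p$omics_head$W2)
      da1 <- dz1 * (fwd$cache$om$a1 > 0)
      g$omics_head <- list(
        W1 = crossprod(x_om, da1), b1 = colSums(da1),
        W2 = crossprod(z1, matrix(d_om, ncol = 1)), b2 = sum(d_om))
    }
  }
  if (mode == "full") {
    hx <- cbind(fwd$h, x_om)
    g$joint_head <- list(W = crossprod(hx, matrix(d_joint, ncol = 1)),
                         b = sum(d_joint))
    H <- nrow(p$ehr_head$W)
    dh <- dh + matrix(d_joint, ncol = 1) %*% t(p$joint_head$W[seq_len(H), ,
                                                              drop = FALSE])
  }
  if (mode != "omics") {
    g$rnn <- if (model$encoder == "gru") {
      gru_backward(p$rnn, fwd$cache$enc, dh)
    } else {
      transformer_backward(p$rnn, fwd$cache$enc, dh,
                           model$config$transformer)
    }
  }
  g
}

# ---- batch plumbing ---------------------------------------------------------

batch_slice <- function(enc, idx, model) {
  b <- list(lengths = enc$lengths[idx], y = enc$y[idx])
  if (model$mode != "omics") {
    if (model$encoder == "gru") {
      b$X <- enc$X[idx, , , drop = FALSE]
    } else {
      b$tokens <- enc$tokens[idx]
    }
  }
  if (model$mode != "ehr") b$omics <- enc$omics[idx, , drop = FALSE]
  b
}

#' Predict from a COMET model
#'
#' @param object A `comet_model`.
#' @param data An `encoded_cohort` (see [encode_cohort()]).
#' @param ... Unused.
#' @return Numeric predictions (probabilities for binary tasks).
#' @export
predict.comet_model <- function(object, data, ...) {
  fwd <- forward_model(object, batch_slice(data, seq_along(data$y), object))
  unname(fwd$yhat)
}

# ---- training ---------------------------------------------------------------

#' Training configuration
#'
#' @param lr Initial Adam learning rate.
#' @param lr_decay Per-epoch multiplicative decay:
#'   `lr_epoch = lr * (1 - lr_decay)^epoch`.
#' @param batch_size Minibatch size (512 for pretraining cohorts, 16 for
#'   omics cohorts at paper scale).
#' @param max_epochs Epoch cap; early stopping normally ends training first.
#' @param patience Early stopping halts training when the held-out test
#'   loss has not improved for this many consecutive epochs (5).
#' @param seed Seed for batch shuffling and dropout.
#' @param snapshots Keep per-epoch parameter snapshots in the trace (for
#'   function-space analysis).
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-2, lr_decay = 1e-3, batch_size = 16,
                         max_epochs = 100, patience = 5, seed = 1,
                         snapshots = FALSE) {
  stopifnot(patience >= 1)
  structure(list(lr = lr, lr_decay = lr_decay, batch_size = batch_size,
                 max_epochs = max_epochs, patience = patience, seed = seed,
                 snapshots = snapshots), class = "train_config")
}

#' Train a COMET model with early stopping
#'
#' Minimises the task loss on the training set by Adam, evaluating the
#' loss on a held-out test set after every epoch. Training stops when the
#' test loss has not improved for `patience` consecutive epochs (or at
#' `max_epochs`), and the weights from the best-test-loss epoch are
#' restored. Parameters listed in `model$frozen` (the transferred encoder)
#' receive no updates.
#'
#' @param model A `comet_model`.
#' @param train,test `encoded_cohort` objects.
#' @param config A [train_config()].
#' @return List with `model` (trained) and `trace` (per-epoch train/test
#'   loss, `stop_epoch`, `best_epoch`, optional snapshots).
#' @export
train_model <- function(model, train, test, config = train_config()) {
  if (length(unique(train$y)) == 1L) {
    warnf("train_model: all training labels are identical; degenerate task")
  }
  with_seed(config$seed, train_model_impl(model, train, test, config))
}

train_model_impl <- function(model, train, test, config) {
  n <- length(train$y)
  state <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  since_improve <- 0L
  tr_loss <- te_loss <- numeric(0)
  snaps <- list()
  test_batch <- batch_slice(test, seq_along(test$y), model)
  stop_epoch <- config$max_epochs
  for (epoch in seq_len(config$max_epochs)) {
    lr <- config$lr * (1 - config$lr_decay)^(epoch - 1)
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      batch <- batch_slice(train, idx, model)
      fwd <- forward_model(model, batch, training = TRUE, want_cache = TRUE)
      grads <- backward_model(model, fwd, batch$y)
      upd <- adam_step(model$params, grads, state, lr, frozen = model$frozen)
      model$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + task_loss(batch$y, fwd$yhat, model$task) * length(idx)
    }
    tr_loss <- c(tr_loss, ep_loss / n)
    pred_te <- forward_model(model, test_batch)$yhat
    lte <- task_loss(test$y, pred_te, model$task)
    te_loss <- c(te_loss, lte)
    if (config$snapshots) snaps[[epoch]] <- model$params
    if (lte < best$loss - 1e-12) {
      best <- list(loss = lte, params = model$params, epoch = epoch)
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= config$patience) {
        stop_epoch <- epoch
        break
      }
    }
  }
  model$params <- best$params
  list(model = model,
       trace = structure(list(train_loss = tr_loss, test_loss = te_loss,
                              stop_epoch = stop_epoch,
                              best_epoch = best$epoch,
                              snapshots = if (config$snapshots) snaps),
                         class = "train_trace"))
}

#' Pretrain the EHR-only network on the pretraining cohort
#'
#' Trains the sequence encoder plus the EHR prediction head on the
#' EHR-only cohort with the task loss, holding out 20% of patients as a
#' test set for early stopping, and returns the best-epoch weights.
#'
#' @param enc An `encoded_cohort` for the pretraining cohort.
#' @param embed_dim,hidden_dim,n_layers,dropout Architecture settings.
#' @param task `"continuous"` or `"binary"`.
#' @param config A [train_config()] (batch size 512 at paper scale).
#' @param encoder,transformer,vocab_size Passed to [comet_model()].
#' @return List with `model` (mode `"ehr"`) and `trace`.
#' @export
pretrain_ehr <- function(enc, embed_dim, hidden_dim, n_layers = 2,
                         dropout = 0.1, task = enc$task,
                         config = train_config(batch_size = 512),
                         encoder = "gru", transformer = NULL,
                         vocab_size = NULL) {
  model <- comet_model(embed_dim, hidden_dim, n_layers = n_layers,
                       task = task, mode = "ehr", dropout = dropout,
                       encoder = encoder, transformer = transformer,
                       vocab_size = vocab_size, seed = config$seed)
  split <- with_seed(derive_seed(config$seed, 77), {
    pats <- unique(enc$patient_id)
    te <- sample(pats, max(1L, round(0.2 * length(pats))))
    list(test = which(enc$patient_id %in% te),
         train = which(!enc$patient_id %in% te))
  })
  if (length(split$train) == 0L) {  # single-patient degenerate cohort
    split$train <- split$test
  }
  train_model(model, encoded_subset(enc, split$train),
              encoded_subset(enc, split$test), config)
}

#' Transfer pretrained encoder weights and freeze them
#'
#' Copies the pretrained recurrent (or transformer) encoder weights into a
#' fresh multimodal model and marks them frozen: they receive no gradient
#' updates during multimodal training. The pretrained EHR prediction head
#' is copied as an initialization but remains trainable (only the encoder
#' weights are frozen).
#'
#' @param pretrained A pretrained `comet_model` (mode `"ehr"`).
#' @param fresh A freshly initialised `comet_model` (mode `"full"`), with
#'   matching encoder architecture.
#' @return `fresh` with transferred, frozen encoder weights.
#' @export
transfer_and_freeze <- function(pretrained, fresh) {
  shape <- function(tree) tree_map(function(x) paste(dim(x) %||% length(x),
                                                     collapse = "x"), tree)
  s1 <- shape(pretrained$params$rnn)
  s2 <- shape(fresh$params$rnn)
  if (!identical(s1, s2)) {
    stopf("transfer_and_freeze: encoder shapes differ (pretrained %s vs fresh %s)",
          paste(unlist(s1), collapse = ","), paste(unlist(s2), collapse = ","))
  }
  fresh$params$rnn <- pretrained$params$rnn
  fresh$params$ehr_head <- pretrained$params$ehr_head
  fresh$frozen <- union(fresh$frozen, "rnn")
  fresh
}

# ---- checkpoints ------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS container holding the weights, frozen
#' flags and architecture configuration; when a training trace is given,
#' a human-readable JSON sidecar (`<path>.trace.json`) records the
#' per-epoch losses and stopping epoch.
#'
#' @param model A `comet_model`.
#' @param path Checkpoint file path.
#' @param trace Optional `train_trace` from [train_model()].
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   the restored `comet_model`.
#' @export
save_checkpoint <- function(model, path, trace = NULL) {
  saveRDS(model, path)
  if (!is.null(trace)) {
    jsonlite::write_json(
      list(train_loss = trace$train_loss, test_loss = trace$test_loss,
           stop_epoch = trace$stop_epoch, best_epoch = trace$best_epoch),
      paste0(path, ".trace.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "comet_model"))
  model
}

# ---- grid search ------------------------------------------------------------

#' Grid search with patient-grouped threefold cross-validation
#'
#' For each grid point, runs threefold cross-validation grouped by patient
#' id; within the two training folds, 20% of patients are held out as a
#' test set for early stopping. The grid point with the minimum mean
#' validation loss is selected; ties are broken by grid order.
#'
#' @param grid A data.frame of hyperparameter combinations; recognised
#'   columns are `lr`, `lr_decay`, `dropout`, `n_layers`, `hidden_dim`,
#'   `omics_hidden`.
#' @param enc An `encoded_cohort`.
#' @param mode Model mode (`"full"`, `"ehr"`, `"omics"`).
#' @param base_config A [train_config()] supplying everything the grid
#'   does not vary.
#' @param pretrained Optional pretrained model for transfer (COMET runs).
#' @param seed Fold assignment seed.
#' @return List with `best` (the chosen row), `results` (grid with mean
#'   validation loss), `index` of the chosen row.
#' @export
grid_search <- function(grid, enc, mode = "full",
                        base_config = train_config(), pretrained = NULL,
                        seed = 1) {
  stopifnot(nrow(grid) >= 1)
  pats <- unique(enc$patient_id)
  folds <- with_seed(seed, {
    f <- rep_len(1:3, length(pats))
    stats::setNames(sample(f), pats)
  })
  mean_loss <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    gp <- grid[gi, , drop = FALSE]
    losses <- numeric(3)
    for (fold in 1:3) {
      val_idx <- which(folds[enc$patient_id] == fold)
      tr_pats <- pats[folds[pats] != fold]
      te_pats <- with_seed(derive_seed(seed, fold), {
        sample(tr_pats, max(1L, round(0.2 * length(tr_pats))))
      })
      te_idx <- which(enc$patient_id %in% te_pats)
      tr_idx <- which(enc$patient_id %in% setdiff(tr_pats, te_pats))
      cfg <- base_config
      for (nm in intersect(names(gp), c("lr", "lr_decay"))) cfg[[nm]] <- gp[[nm]]
      model <- comet_model(
        embed_dim = dim(enc$X)[3],
        hidden_dim = gp$hidden_dim %||% (if (!is.null(pretrained))
          pretrained$config$hidden_dim else 32),
        n_layers = gp$n_layers %||% (if (!is.null(pretrained))
          pretrained$config$n_layers else 2),
        n_analytes = if (mode == "ehr") 0 else ncol(enc$omics),
        task = enc$task, mode = mode,
        dropout = gp$dropout %||% 0.1,
        omics_hidden = gp$omics_hidden %||% 32,
        seed = cfg$seed)
      if (!is.null(pretrained)) model <- transfer_and_freeze(pretrained, model)
      fit <- train_model(model, encoded_subset(enc, tr_idx),
                         encoded_subset(enc, te_idx), cfg)
      pred <- predict(fit$model, encoded_subset(enc, val_idx))
      losses[fold] <- task_loss(enc$y[val_idx], pred, enc$task)
    }
    mean_loss[gi] <- mean(losses)
  }
  best_i <- which.min(mean_loss)  # which.min takes the first minimum: grid order
  list(best = grid[best_i, , drop = FALSE],
       results = cbind(grid, mean_val_loss = mean_loss),
       index = best_i)
}
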