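# Shared small fixtures, built once per test run.

# tiny cohort pair: 30 pretraining + 8 omics patients, 2 samples each
tiny_config <- function(seed = 404, ...) {
  synthetic_config(n_pretrain = 30, n_omics = 8, vocab_size = 40,
                   n_analytes = 10, latent_dim = 3, horizon = 12,
                   seed = seed, ...)
}

tiny_gen <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(tiny_config())
    cache
  }
})

tiny_embeddings <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- train_embeddings(build_sentences(tiny_gen()$cohort, seed = 2),
                                 d = 6, seed = 2)
    }
    cache
  }
})

tiny_encoded <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- comet:::encode_cohort(
        cohort_subset(tiny_gen()$cohort, "omics"), tiny_embeddings())
    }
    cache
  }
})

# ---- parameter-tree helpers for gradient checking ---------------------------

get_path <- function(tree, path) {
  for (k in path) tree <- tree[[k]]
  tree
}

assign_path <- function(tree, path, value) {
  if (length(path) == 0) return(value)
  key <- path[[1]]
  tree[[key]] <- assign_path(tree[[key]], path[-1], value)
  tree
}

leaf_paths <- function(tree, prefix = list()) {
  if (is.list(tree)) {
    out <- list()
    nms <- names(tree)
    for (i in seq_along(tree)) {
      key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
      out <- c(out, leaf_paths(tree[[i]], c(prefix, list(key))))
    }
    out
  } else {
    list(prefix)
  }
}

# compare analytic gradients of a comet_model against central differences on
# a few random entries of every parameter leaf; returns max relative error
max_grad_rel_err <- function(model, batch, n_entries = 2, eps = 1e-5) {
  fwd <- comet:::forward_model(model, batch, want_cache = TRUE)
  grads <- comet:::backward_model(model, fwd, batch$y)
  loss_at <- function(params) {
    m2 <- model
    m2$params <- params
    f <- comet:::forward_model(m2, batch)
    task_loss(batch$y, f$yhat, model$task)
  }
  worst <- 0
  for (p in leaf_paths(model$params)) {
    leaf <- get_path(model$params, p)
    gl <- get_path(grads, p)
    for (entry in sample(length(leaf), min(n_entries, length(leaf)))) {
      bump <- function(delta) {
        nl <- leaf
        nl[entry] <- nl[entry] + delta
        loss_at(assign_path(model$params, p, nl))
      }
      num <- (bump(eps) - bump(-eps)) / (2 * eps)
      rel <- abs(num - gl[entry]) / max(1e-6, abs(num) + abs(gl[entry]))
      worst <- max(worst, rel)
    }
  }
  worst
}
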