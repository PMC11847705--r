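#' Run the full COMET-versus-baselines experiment on one cohort pair
#'
#' Convenience driver wiring together the whole pipeline on a generated
#' (or supplied) cohort pair: day-sentence construction, skip-gram
#' embedding training (one model per cohort by default), daily summary
#' encoding, EHR-only pretraining, transfer with frozen encoder weights,
#' and the repeated-splits protocol for each requested mode, with the
#' final metrics computed on averaged validation predictions.
#'
#' @param config A [synthetic_config()] (used when `cohort` is NULL).
#' @param cohort Optionally a pre-built `comet_cohort` with both
#'   sub-cohorts.
#' @param modes Modes to evaluate (subset of `"comet"`, `"joint"`,
#'   `"ehr"`, `"omics"`, `"comet_transformer"`).
#' @param embed_dim Code embedding dimension.
#' @param hidden_dim,n_layers,dropout Encoder architecture.
#' @param n_repeats Protocol repeats (25 in the full protocol).
#' @param base_seed Seed governing embeddings, splits and training.
#' @param share_embeddings Use one embedding table for both cohorts
#'   instead of independently trained per-cohort tables.
#' @param pretrain_config,mm_config [train_config()]s for pretraining and
#'   multimodal training (batch sizes 512 and 16).
#' @param transformer A [transformer_config()] for the transformer mode.
#' @param tune_grid Optional data.frame of candidate training settings
#'   (columns among `lr`, `lr_decay`, `dropout`); when given, a grouped
#'   threefold grid search picks each mode's setting once, before the
#'   repeated splits, mirroring the per-experiment hyperparameter
#'   selection of the full protocol.
#' @param keep Per-repeat extras to retain (see [run_protocol()]).
#' @return A `comet_experiment` list: per-mode `results` (each with
#'   `predictions`, `metrics`, `protocol`), `pretrained`, the encoded
#'   cohorts, the embedding tables, `truth` (when generated) and the plan.
#' @export
comet_experiment <- function(config = synthetic_config(), cohort = NULL,
                             modes = c("comet", "joint", "ehr", "omics"),
                             embed_dim = 16, hidden_dim = 32, n_layers = 2,
                             dropout = 0.1, n_repeats = 25,
                             base_seed = config$seed,
                             share_embeddings = FALSE,
                             pretrain_config = NULL, mm_config = NULL,
                             transformer = NULL, tune_grid = NULL,
                             keep = character()) {
  truth <- NULL
  if (is.null(cohort)) {
    gen <- generate_cohort(config)
    cohort <- gen$cohort
    truth <- gen$truth
  }
  task <- cohort$task
  pre <- cohort_subset(cohort, "pretraining")
  om <- cohort_subset(cohort, "omics")

  emb_seed <- derive_seed(base_seed, 1)
  sent_pre <- build_sentences(pre, seed = emb_seed)
  table_pre <- train_embeddings(sent_pre, d = embed_dim, seed = emb_seed)
  table_om <- if (share_embeddings) table_pre else {
    # separate per-cohort models, reconciled into the pretraining space so
    # the transferred encoder can read omics-cohort summaries
    align_embeddings(train_embeddings(build_sentences(om, seed = emb_seed),
                                      d = embed_dim, seed = emb_seed),
                     table_pre)
  }

  pretrain_config <- pretrain_config %||%
    train_config(batch_size = 512, max_epochs = 100,
                 seed = derive_seed(base_seed, 2))
  mm_config <- mm_config %||%
    train_config(batch_size = 16, max_epochs = 100,
                 seed = derive_seed(base_seed, 3))

  enc_pre <- encode_cohort(pre, table_pre)
  enc_om <- encode_cohort(om, table_om)

  needs_rnn_pretrain <- any(modes %in% "comet")
  pretrained <- NULL
  if (needs_rnn_pretrain) {
    pretrained <- pretrain_ehr(enc_pre, embed_dim, hidden_dim,
                               n_layers = n_layers, dropout = dropout,
                               task = task, config = pretrain_config)$model
  }

  pretrained_tf <- NULL
  enc_om_tok <- NULL
  if ("comet_transformer" %in% modes) {
    transformer <- transformer %||% transformer_config(d = hidden_dim)
    vocab <- rownames(table_pre)
    tok_pre <- tokenize_cohort(pre, vocab, seed = emb_seed)
    enc_om_tok <- tokenize_cohort(om, vocab, seed = emb_seed)
    pretrained_tf <- pretrain_ehr(
      tok_pre, embed_dim = transformer$d, hidden_dim = transformer$d,
      dropout = dropout, task = task,
      config = pretrain_config, encoder = "transformer",
      transformer = transformer, vocab_size = length(vocab))$model
  }

  plan <- make_split_plan(om$records |> vapply(`[[`, "", "patient_id"),
                          base_seed = derive_seed(base_seed, 4),
                          n_repeats = n_repeats)

  chosen <- list()
  results <- list()
  for (mode in modes) {
    is_tf <- mode == "comet_transformer"
    cfg_mode <- mm_config
    if (!is.null(tune_grid) && !is_tf) {
      model_mode <- if (mode %in% c("comet", "joint")) "full" else mode
      tg <- tune_grid
      if (is.null(tg$hidden_dim)) tg$hidden_dim <- hidden_dim
      if (is.null(tg$n_layers)) tg$n_layers <- n_layers
      if (is.null(tg$dropout)) tg$dropout <- dropout
      gs <- grid_search(tg, enc_om, mode = model_mode,
                        base_config = mm_config,
                        pretrained = if (mode == "comet") pretrained,
                        seed = derive_seed(base_seed, 6))
      for (nm in intersect(names(gs$best), c("lr", "lr_decay"))) {
        cfg_mode[[nm]] <- gs$best[[nm]]
      }
      chosen[[mode]] <- gs$best
    }
    res <- run_protocol(
      if (is_tf) enc_om_tok else enc_om, mode, plan,
      config = cfg_mode,
      pretrained = if (mode == "comet") pretrained
                   else if (is_tf) pretrained_tf,
      model_args = list(hidden_dim = hidden_dim, n_layers = n_layers,
                        dropout = dropout),
      keep = keep)
    ok <- !is.na(res$predictions$y_pred)
    metrics <- compute_metrics(res$predictions$y_true[ok],
                               res$predictions$y_pred[ok], task = task,
                               n_boot = 200,
                               seed = derive_seed(base_seed, 5))
    results[[mode]] <- list(predictions = res$predictions,
                            metrics = metrics, protocol = res)
  }
  structure(list(results = results, pretrained = pretrained,
                 pretrained_transformer = pretrained_tf,
                 enc_pretrain = enc_pre, enc_omics = enc_om,
                 table_pretrain = table_pre, table_omics = table_om,
                 truth = truth, plan = plan, config = config,
                 chosen = chosen, task = task),
            class = "comet_experiment")
}

#' @export
print.comet_experiment <- function(x, ...) {
  cat(sprintf("comet_experiment (%s task, %d repeats)\n", x$task,
              length(x$plan$repeats)))
  key <- if (x$task == "continuous") "r" else "auroc"
  for (mode in names(x$results)) {
    cat(sprintf("  %-18s %s = %.3f\n", mode, key,
                x$results[[mode]]$metrics$estimates[key]))
  }
  invisible(x)
}
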