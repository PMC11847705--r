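#' Patient-grouped repeated 70/15/15 split plan
#'
#' Builds the repeated-splits experiment plan: each repeat partitions the
#' patients into train (70%), test (15%, used for early stopping) and
#' validation (15%) sets. Splitting is at the patient level, so all
#' records of a patient land in one set. Deterministic given `base_seed`.
#'
#' @param patient_ids Character vector (one entry per record is fine;
#'   duplicates are collapsed).
#' @param base_seed Plan seed.
#' @param n_repeats Number of repeats (25 in the full protocol).
#' @param fractions Train/test/validation fractions (sum to 1).
#' @return A `split_plan`: list of repeats, each with `train`, `test`,
#'   `validation` patient-id sets and the repeat seed.
#' @export
make_split_plan <- function(patient_ids, base_seed = 1, n_repeats = 25,
                            fractions = c(0.70, 0.15, 0.15)) {
  pats <- unique(as.character(patient_ids))
  n <- length(pats)
  if (n < 7) stopf("make_split_plan: need at least 7 patients, got %d", n)
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  n_te <- max(1L, round(fractions[2] * n))
  n_va <- max(1L, round(fractions[3] * n))
  n_tr <- n - n_te - n_va
  repeats <- with_seed(base_seed, {
    seeds <- sample.int(2^30, n_repeats)
    lapply(seq_len(n_repeats), function(r) {
      ord <- with_seed(seeds[r], sample(pats))
      list(train = ord[seq_len(n_tr)],
           test = ord[n_tr + seq_len(n_te)],
           validation = ord[n_tr + n_te + seq_len(n_va)],
           seed = seeds[r])
    })
  })
  structure(list(repeats = repeats, base_seed = base_seed,
                 patients = pats, fractions = fractions),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  r1 <- x$repeats[[1]]
  cat(sprintf("split_plan: %d repeats over %d patients (%d/%d/%d train/test/validation)\n",
              length(x$repeats), length(x$patients),
              length(r1$train), length(r1$test), length(r1$validation)))
  invisible(x)
}

#' Run the repeated-splits evaluation protocol for one model mode
#'
#' For every repeat of the plan: train on the training set (early stopping
#' on the test set), then predict the validation set. The final prediction
#' for each record is the mean of its predictions over the repeats in
#' which it fell in validation; records never in any validation set are
#' reported as missing with a warning. Hyperparameters are fixed before
#' the repeats (grid search, where used, runs once beforehand).
#'
#' Modes: `"comet"` (transfer + frozen encoder), `"joint"` (same
#' architecture, no pretraining), `"ehr"`, `"omics"`,
#' `"comet_transformer"` (transfer with the transformer encoder),
#' `"prior_ridge"` and `"prior_logistic"` (linear baselines; `gamma`/
#' regularization from `linear_choice`, fitted on train+test since they
#' need no early stopping).
#'
#' @param enc `encoded_cohort` for the omics cohort ([encode_cohort()] for
#'   recurrent modes, [tokenize_cohort()] for the transformer mode).
#' @param mode One of the modes above.
#' @param plan A [make_split_plan()].
#' @param config A [train_config()] for the neural modes.
#' @param pretrained Pretrained `comet_model` (comet modes).
#' @param model_args Extra arguments for [comet_model()] (e.g.
#'   `hidden_dim`, `n_layers`, `dropout`, `omics_hidden`).
#' @param design A `design_matrix` over the same records (linear modes).
#' @param beta0 Prior coefficients for the linear modes.
#' @param linear_choice List with `lambda` or `C` and `gamma`.
#' @param keep Per-repeat extras to retain: any of `"model"`, `"trace"`,
#'   `"latents"`.
#' @return A `protocol_result`: list with `predictions` (record_id,
#'   y_true, y_pred averaged, n_validation), `mode`, and `repeats` (kept
#'   extras).
#' @export
run_protocol <- function(enc, mode, plan, config = train_config(),
                         pretrained = NULL, model_args = list(),
                         design = NULL, beta0 = NULL, linear_choice = NULL,
                         keep = character()) {
  linear <- mode %in% c("prior_ridge", "prior_logistic")
  n <- length(enc$y)
  pred_sum <- numeric(n)
  pred_n <- integer(n)
  extras <- list()
  for (r in seq_along(plan$repeats)) {
    rep_def <- plan$repeats[[r]]
    va <- which(enc$patient_id %in% rep_def$validation)
    if (linear) {
      tr <- which(enc$patient_id %in% c(rep_def$train, rep_def$test))
      X <- design$X
      fit <- if (mode == "prior_ridge") {
        fit_prior_ridge(X[tr, , drop = FALSE], design$y[tr],
                        linear_choice$lambda, linear_choice$gamma %||% 0, beta0)
      } else {
        fit_prior_logistic(X[tr, , drop = FALSE], design$y[tr],
                           linear_choice$C, linear_choice$gamma %||% 0, beta0)
      }
      pv <- fit$predict(X[va, , drop = FALSE])
      if (any(c("model", "trace") %in% keep)) {
        extras[[r]] <- list(model = if ("model" %in% keep) fit)
      }
    } else {
      tr <- which(enc$patient_id %in% rep_def$train)
      te <- which(enc$patient_id %in% rep_def$test)
      cfg <- config
      cfg$seed <- derive_seed(config$seed, r)
      margs <- model_args
      margs$task <- enc$task
      margs$seed <- cfg$seed
      if (mode %in% c("comet", "joint", "comet_transformer")) {
        margs$mode <- "full"
      } else {
        margs$mode <- mode
      }
      if (mode == "comet_transformer") {
        margs$encoder <- "transformer"
        margs$embed_dim <- margs$embed_dim %||% pretrained$config$transformer$d
      } else {
        margs$embed_dim <- margs$embed_dim %||% dim(enc$X)[3]
      }
      if (margs$mode != "ehr") margs$n_analytes <- ncol(enc$omics)
      if (!is.null(pretrained)) {
        margs$hidden_dim <- pretrained$config$hidden_dim
        margs$n_layers <- pretrained$config$n_layers
        margs$transformer <- pretrained$config$transformer
        margs$vocab_size <- pretrained$config$vocab_size
      }
      model <- do.call(comet_model, margs)
      if (mode %in% c("comet", "comet_transformer")) {
        model <- transfer_and_freeze(pretrained, model)
      }
      fit <- train_model(model, encoded_subset(enc, tr),
                         encoded_subset(enc, te), cfg)
      pv <- predict(fit$model, encoded_subset(enc, va))
      if (length(keep)) {
        ex <- list()
        if ("model" %in% keep) ex$model <- fit$model
        if ("trace" %in% keep) ex$trace <- fit$trace
        if ("latents" %in% keep && margs$mode != "omics") {
          ex$latents <- forward_model(
            fit$model, batch_slice(enc, seq_len(n), fit$model))$h
        }
        extras[[r]] <- ex
      }
    }
    pred_sum[va] <- pred_sum[va] + pv
    pred_n[va] <- pred_n[va] + 1L
  }
  if (any(pred_n == 0L)) {
    warnf("run_protocol: %d record(s) never fell in a validation set; reported as NA",
          sum(pred_n == 0L))
  }
  predictions <- data.frame(
    record_id = enc$record_id, y_true = enc$y,
    y_pred = ifelse(pred_n > 0L, pred_sum / pmax(pred_n, 1L), NA_real_),
    n_validation = pred_n, stringsAsFactors = FALSE, row.names = NULL)
  structure(list(predictions = predictions, mode = mode, repeats = extras),
            class = "protocol_result")
}

# ---- metrics ----------------------------------------------------------------

# Mann-Whitney formulation; ties share rank mass
auroc <- function(y, score) {
  y <- as.numeric(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# precision-recall step integration over descending score thresholds
auprc <- function(y, score) {
  y <- as.numeric(y)
  if (sum(y == 1) == 0) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  y <- y[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  rec <- tp / sum(y)
  # keep the last index of each tied-score block
  s <- score[ord]
  block_end <- c(s[-1] != s[-length(s)], TRUE)
  prec <- prec[block_end]; rec <- rec[block_end]
  sum(diff(c(0, rec)) * prec)
}

# Lin's concordance correlation coefficient
lins_ccc <- function(y, yhat) {
  n <- length(y)
  vy <- var(y) * (n - 1) / n
  vp <- var(yhat) * (n - 1) / n
  cv <- stats::cov(y, yhat) * (n - 1) / n
  2 * cv / (vy + vp + (mean(y) - mean(yhat))^2)
}

cohen_kappa <- function(y, yhat_class) {
  po <- mean(y == yhat_class)
  pe <- mean(y == 1) * mean(yhat_class == 1) +
    mean(y == 0) * mean(yhat_class == 0)
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

#' Compute the evaluation metric set
#'
#' Regression: Pearson r (t-distribution p-value), r.m.s.e. (in outcome
#' units, e.g. days), and Lin's concordance correlation coefficient
#' \eqn{\rho_c = 2\,\mathrm{cov}(y,\hat y) / (\mathrm{var}\,y +
#' \mathrm{var}\,\hat y + (\bar y - \bar{\hat y})^2)}.
#' Classification: AUROC (rank statistic), AUPRC (precision-recall step
#' integration) and Cohen's kappa at the given threshold. 95% confidence
#' intervals come from a seeded nonparametric percentile bootstrap over
#' prediction pairs.
#'
#' @param y_true,y_pred Prediction pairs (rows with missing predictions
#'   are dropped with a note).
#' @param task `"continuous"` or `"binary"`.
#' @param threshold Score threshold for kappa (0.5).
#' @param n_boot Bootstrap resamples (1000); 0 skips CIs.
#' @param seed Bootstrap seed.
#' @return A `metric_report` list.
#' @export
compute_metrics <- function(y_true, y_pred, task = c("continuous", "binary"),
                            threshold = 0.5, n_boot = 1000, seed = 1) {
  task <- match.arg(task)
  keep <- is.finite(y_true) & is.finite(y_pred)
  if (any(!keep)) {
    message(sprintf("compute_metrics: dropped %d pair(s) with missing values",
                    sum(!keep)))
  }
  y <- y_true[keep]; p <- y_pred[keep]
  if (length(y) < 3) stopf("compute_metrics: need at least 3 prediction pairs")
  point <- function(yy, pp) {
    if (task == "continuous") {
      r <- if (sd(pp) == 0 || sd(yy) == 0) NA_real_ else cor(yy, pp)
      c(r = r, rmse = sqrt(mean((yy - pp)^2)), ccc = lins_ccc(yy, pp))
    } else {
      c(auroc = auroc(yy, pp), auprc = auprc(yy, pp),
        kappa = cohen_kappa(yy, as.numeric(pp >= threshold)))
    }
  }
  est <- point(y, p)
  ci <- NULL
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        i <- sample.int(length(y), replace = TRUE)
        point(y[i], p[i])
      }, est)
    })
    ci <- apply(boots, 1, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  }
  out <- list(task = task, n = length(y), estimates = est, ci = ci)
  if (task == "continuous") {
    out$p_value <- if (is.na(est["r"])) NA_real_ else
      cor.test(y, p)$p.value
    if (is.na(est["r"])) {
      out$note <- "constant predictions: r undefined"
    }
  }
  class(out) <- "metric_report"
  out
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report (%s task, n = %d)\n", x$task, x$n))
  for (m in names(x$estimates)) {
    ci_txt <- if (!is.null(x$ci)) {
      sprintf(" [%.3f, %.3f]", x$ci[1, m], x$ci[2, m])
    } else ""
    cat(sprintf("  %-6s %.4f%s\n", m, x$estimates[m], ci_txt))
  }
  if (!is.null(x$p_value)) cat(sprintf("  p(r)   %.3g\n", x$p_value))
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}
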