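#' @title Post-hoc interpretation of trained COMET models
#' @name interpret
#' @description Integrated-gradients feature attributions on the omics
#'   branch, latent-representation/analyte alignment counting,
#'   feature-feature correlation maps, intermediate-node performance and
#'   function-space trajectories.
NULL

# value and gradient of the model output w.r.t. the omics vector, with the
# EHR latent state held fixed; X is m x P (rows are evaluation points)
omics_value_grad <- function(model, h, X) {
  p <- model$params
  m <- nrow(X)
  P <- ncol(X)
  if (model$mode == "full") {
    H <- nrow(p$ehr_head$W)
    p_ehr <- sum(h * drop(p$ehr_head$W)) + p$ehr_head$b
    wj <- drop(p$joint_head$W)
    raw_j <- drop(X %*% wj[H + seq_len(P)]) + sum(h * wj[seq_len(H)]) +
      p$joint_head$b
    om <- omics_branch_value_grad(model, X)
    raw <- p$combiner[1] * p_ehr + p$combiner[2] * om$value +
      p$combiner[3] * raw_j
    G <- p$combiner[2] * om$grad +
      matrix(p$combiner[3] * wj[H + seq_len(P)], m, P, byrow = TRUE)
  } else if (model$mode == "omics") {
    om <- omics_branch_value_grad(model, X)
    raw <- om$value
    G <- om$grad
  } else {
    stopf("omics_value_grad: model has no omics input")
  }
  if (model$task == "binary") {
    s <- logistic(raw)
    list(value = s, grad = G * (s * (1 - s)))
  } else {
    list(value = raw, grad = G)
  }
}

omics_branch_value_grad <- function(model, X) {
  p <- model$params$omics_head
  if (model$task == "continuous") {
    list(value = drop(X %*% p$W) + p$b,
         grad = matrix(drop(p$W), nrow(X), ncol(X), byrow = TRUE))
  } else {
    a1 <- sweep(X %*% p$W1, 2, p$b1, "+")
    z1 <- pmax(a1, 0)
    value <- drop(z1 %*% p$W2) + p$b2
    act <- (a1 > 0) * matrix(drop(p$W2), nrow(X), ncol(a1), byrow = TRUE)
    list(value = value, grad = act %*% t(p$W1))
  }
}

#' Integrated-gradients attributions on the omics branch
#'
#' For each sample, attributes the model output across omics features by
#' the path integral \deqn{attr_i = (x_i - b_i)\,\frac{1}{m}
#' \sum_{s=1}^{m} \left.\frac{\partial f}{\partial x_i}\right|_{b +
#' \frac{s - 1/2}{m}(x-b)}} (a midpoint discretisation, whose
#' second-order error keeps the completeness identity tight at moderate
#' m) with the EHR input held fixed at the sample's own
#' sequence. The default baseline is the zero vector, i.e. the cohort
#' mean on standardized features. Attributions are exact for linear maps
#' and satisfy the completeness identity \eqn{\sum_i attr_i \approx f(x)
#' - f(b)} up to Riemann-sum error.
#'
#' @param model A trained `comet_model` with an omics branch.
#' @param enc `encoded_cohort` holding the samples to attribute.
#' @param idx Row indices to attribute (default: all).
#' @param baseline Baseline omics vector (default zero).
#' @param m Integration steps (128 by default).
#' @return An `attribution` list: `attributions` (samples x analytes),
#'   `completeness` (per-sample residual \eqn{\sum attr - (f(x)-f(b))}),
#'   `f_x`, `f_baseline`, and `importance` (per-analyte mean absolute
#'   attribution).
#' @export
integrated_gradients <- function(model, enc, idx = NULL, baseline = NULL,
                                 m = 128) {
  stopifnot(m >= 1)
  if (is.null(idx)) idx <- seq_along(enc$y)
  P <- ncol(enc$omics)
  if (is.null(baseline)) baseline <- rep(0, P)
  hs <- NULL
  if (model$mode != "omics") {
    hs <- forward_model(model, batch_slice(enc, idx, model))$h
  }
  A <- matrix(0, length(idx), P, dimnames = list(enc$record_id[idx],
                                                 colnames(enc$omics)))
  f_x <- f_b <- numeric(length(idx))
  for (j in seq_along(idx)) {
    x <- enc$omics[idx[j], ]
    h <- if (!is.null(hs)) hs[j, ] else NULL
    steps <- baseline + outer((seq_len(m) - 0.5) / m, x - baseline)
    vg <- omics_value_grad(model, h, steps)
    avg_grad <- colMeans(vg$grad)
    A[j, ] <- (x - baseline) * avg_grad
    f_x[j] <- omics_value_grad(model, h, matrix(x, 1))$value
    f_b[j] <- omics_value_grad(model, h, matrix(baseline, 1))$value
  }
  structure(list(attributions = A,
                 completeness = rowSums(A) - (f_x - f_b),
                 f_x = f_x, f_baseline = f_b,
                 importance = colMeans(abs(A))),
            class = "attribution")
}

#' Latent-representation / analyte alignment counting
#'
#' Computes all latent-dimension x analyte Pearson correlations with
#' t-distribution p-values and counts those significant after Bonferroni
#' correction over the full d x P family. Constant columns yield
#' undefined correlations and are reported as non-significant.
#'
#' @param latents n x d matrix of EHR latent representations.
#' @param omics n x P matrix of analyte values (matched rows).
#' @param alpha Family-wise significance level (0.05).
#' @return An `alignment_result`: `r` and `p` matrices (d x P),
#'   `n_significant`, `per_analyte_fraction` (fraction of latent
#'   dimensions each analyte correlates with), `threshold`.
#' @export
latent_alignment <- function(latents, omics, alpha = 0.05) {
  latents <- as.matrix(latents); omics <- as.matrix(omics)
  stopifnot(nrow(latents) == nrow(omics))
  n <- nrow(latents)
  r <- suppressWarnings(cor(latents, omics))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-15))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  const <- is.na(r)
  note <- NULL
  if (any(const)) {
    p[const] <- 1
    note <- sprintf("%d correlation(s) undefined (constant column); treated as non-significant",
                    sum(const))
  }
  thr <- alpha / (nrow(r) * ncol(r))
  sig <- p < thr
  structure(list(r = r, p = p, n_significant = sum(sig),
                 per_analyte_fraction = colMeans(sig),
                 threshold = thr, note = note),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("alignment_result: %d x %d tests, %d significant (Bonferroni threshold %.3g)\n",
              nrow(x$r), ncol(x$r), x$n_significant, x$threshold))
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

#' Correlation-structure map of mixed EHR/omics features
#'
#' Embeds each feature's correlation profile (its row of the feature
#' correlation matrix) in two dimensions with seeded t-SNE, so features
#' close together have similar correlations with all other variables.
#' Also reports each feature's univariate outcome correlation (used for
#' point sizes), the number of Bonferroni-significant EHR x analyte
#' correlations per analyte (family = n_EHR x n_analytes), and each EHR
#' feature's maximum absolute correlation over analytes.
#'
#' @param features n x q matrix (one-hot EHR indicators and analytes).
#' @param modality Length-q character vector, `"ehr"` or `"omics"`.
#' @param outcome Length-n outcome vector.
#' @param alpha Family-wise level for the cross-modality counts.
#' @param perplexity,seed t-SNE settings (perplexity is reduced
#'   automatically for small q).
#' @return A `correlation_map` list: `coords` (q x 2), `outcome_cor`,
#'   `per_analyte_sig`, `no_sig_fraction` (fraction of analytes with no
#'   significant EHR correlation), `ehr_max_abs_cor`, `modality`.
#' @export
correlation_map <- function(features, modality, outcome, alpha = 0.05,
                            perplexity = 30, seed = 1) {
  features <- as.matrix(features)
  q <- ncol(features)
  stopifnot(q >= 3, length(modality) == q)
  n <- nrow(features)
  C <- suppressWarnings(cor(features))
  C[is.na(C)] <- 0
  diag(C) <- 1
  coords <- tsne_embed(C, perplexity = perplexity, seed = seed)
  outcome_cor <- suppressWarnings(drop(cor(features, outcome)))
  is_ehr <- modality == "ehr"
  per_analyte_sig <- NULL
  no_sig_fraction <- NA_real_
  ehr_max <- NULL
  if (any(is_ehr) && any(!is_ehr)) {
    r <- C[is_ehr, !is_ehr, drop = FALSE]
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-15))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    thr <- alpha / length(p)
    per_analyte_sig <- colSums(p < thr)
    no_sig_fraction <- mean(per_analyte_sig == 0)
    ehr_max <- apply(abs(r), 1, max)
  }
  structure(list(coords = coords, outcome_cor = outcome_cor,
                 per_analyte_sig = per_analyte_sig,
                 no_sig_fraction = no_sig_fraction,
                 ehr_max_abs_cor = ehr_max, modality = modality),
            class = "correlation_map")
}

#' Intermediate-node (branch) performance
#'
#' Evaluates the value at each node just before the prediction head —
#' the EHR, omics and joint branch predictions — against the outcome:
#' Pearson r for regression, AUROC for classification.
#'
#' @param model A trained `comet_model` (mode `"full"`).
#' @param enc `encoded_cohort` with the records to evaluate.
#' @return Named numeric vector (`ehr`, `omics`, `joint`).
#' @export
intermediate_node_performance <- function(model, enc) {
  fwd <- forward_model(model, batch_slice(enc, seq_along(enc$y), model))
  apply(fwd$branches, 2, function(v) {
    if (model$task == "continuous") {
      if (sd(v) == 0) NA_real_ else cor(v, enc$y)
    } else {
      auroc(enc$y, v)
    }
  })
}

#' Function-space trajectories of training runs
#'
#' Compares models by the functions they represent rather than by raw
#' parameters: for every parameter snapshot (one per epoch), all records
#' are pushed through the network and the outputs are concatenated into
#' one vector per snapshot; the snapshot x record matrix is embedded in
#' two dimensions with seeded t-SNE. Views: `"overall"` (final output)
#' or one branch (`"ehr"`, `"omics"`, `"joint"`).
#'
#' @param runs Named list of runs; each run is a list with `model` (a
#'   `comet_model` skeleton) and `snapshots` (list of parameter trees,
#'   from [train_model()] with `snapshots = TRUE` in the config).
#' @param enc `encoded_cohort` of records to probe with.
#' @param view `"overall"`, `"ehr"`, `"omics"` or `"joint"`.
#' @param perplexity,seed t-SNE settings.
#' @return A `function_space_trace`: `coords` (2-D), `meta` (run label
#'   and epoch per row), `outputs` (the pre-embedding matrix).
#' @export
function_space_trace <- function(runs, enc, view = c("overall", "ehr",
                                                     "omics", "joint"),
                                 perplexity = 10, seed = 1) {
  view <- match.arg(view)
  rows <- list()
  meta <- list()
  for (label in names(runs)) {
    run <- runs[[label]]
    if (length(run$snapshots) < 2) {
      stopf("function_space_trace: run '%s' has fewer than 2 snapshots", label)
    }
    model <- run$model
    for (e in seq_along(run$snapshots)) {
      model$params <- run$snapshots[[e]]
      fwd <- forward_model(model, batch_slice(enc, seq_along(enc$y), model))
      out <- if (view == "overall") fwd$yhat else fwd$branches[, view]
      rows[[length(rows) + 1L]] <- out
      meta[[length(meta) + 1L]] <- data.frame(run = label, epoch = e,
                                              stringsAsFactors = FALSE)
    }
  }
  M <- do.call(rbind, rows)
  meta <- do.call(rbind, meta)
  coords <- tsne_embed(M, perplexity = perplexity, seed = seed)
  structure(list(coords = coords, meta = meta, outputs = M),
            class = "function_space_trace")
}
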