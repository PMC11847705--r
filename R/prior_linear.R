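#' Build a design matrix of one-hot EHR indicators and omics columns
#'
#' EHR features are one-hot occurrence indicators over the observation
#' window (1 if the code occurred, else 0); omics analytes enter as-is.
#' Low-variance features (raw variance below `min_var`, assessed before
#' standardization — afterwards it would be vacuous) are removed, and the
#' remaining columns are standardized to mean 0, sd 1. The
#' standardization recipe (centres/scales) is stored so that pretraining
#' and omics-cohort designs are on comparable scales.
#'
#' @param cohort A `comet_cohort`.
#' @param min_var Raw variance threshold (0.01).
#' @param include_omics Include omics columns (if present).
#' @param recipe Optional recipe from a previous design, to reuse its
#'   feature set, centres and scales (features absent here are filled
#'   with zeros pre-standardization).
#' @return A `design_matrix`: list with `X`, `y`, `feature_names`,
#'   `modality` (`"ehr"`/`"omics"` per column), `groups` (patient ids),
#'   and `recipe`.
#' @export
build_design <- function(cohort, min_var = 0.01, include_omics = TRUE,
                         recipe = NULL) {
  recs <- cohort$records
  n <- length(recs)
  codes <- sort(unique(unlist(lapply(recs, function(r) unique(r$events$code)))))
  X_ehr <- matrix(0, n, length(codes), dimnames = list(NULL, codes))
  for (i in seq_len(n)) {
    occ <- unique(recs[[i]]$events$code)
    X_ehr[i, occ] <- 1
  }
  modality <- rep("ehr", ncol(X_ehr))
  X <- X_ehr
  if (include_omics && !is.null(cohort$analytes) &&
      any(vapply(recs, function(r) !is.null(r$omics), TRUE))) {
    X_om <- do.call(rbind, lapply(recs, `[[`, "omics"))
    X <- cbind(X, X_om)
    modality <- c(modality, rep("omics", ncol(X_om)))
  }
  y <- vapply(recs, function(r) as.numeric(r$outcome), 0)
  if (is.null(recipe)) {
    v <- apply(X, 2, var)
    keep <- v > min_var
    X <- X[, keep, drop = FALSE]
    modality <- modality[keep]
    centers <- colMeans(X)
    scales <- apply(X, 2, sd)
    scales[scales == 0] <- 1
    recipe <- list(features = colnames(X), centers = centers, scales = scales,
                   modality = modality)
  } else {
    full <- matrix(0, n, length(recipe$features),
                   dimnames = list(NULL, recipe$features))
    shared <- intersect(colnames(X), recipe$features)
    full[, shared] <- X[, shared]
    X <- full
    modality <- recipe$modality
  }
  X <- sweep(sweep(X, 2, recipe$centers, "-"), 2, recipe$scales, "/")
  structure(list(X = X, y = y, feature_names = colnames(X),
                 modality = modality,
                 groups = vapply(recs, `[[`, "", "patient_id"),
                 recipe = recipe),
            class = "design_matrix")
}

#' Align pretrained coefficients to a design matrix
#'
#' Produces the prior vector beta0 for a multimodal design: features
#' present in the pretraining fit keep their coefficients, features absent
#' from the pretraining data (all omics analytes, and any code unseen
#' there) get exactly 0.
#'
#' @param beta0 Named coefficient vector from a pretraining-cohort fit.
#' @param feature_names Feature names of the target design.
#' @return A `prior_coefficients` numeric vector with a `from_pretraining`
#'   logical attribute.
#' @export
align_prior <- function(beta0, feature_names) {
  out <- stats::setNames(rep(0, length(feature_names)), feature_names)
  shared <- intersect(names(beta0), feature_names)
  out[shared] <- beta0[shared]
  structure(out, from_pretraining = feature_names %in% names(beta0),
            class = "prior_coefficients")
}

#' Prior-informed ridge regression
#'
#' Minimises \eqn{\|y - X\beta\|^2 + \lambda\|\beta - \gamma\beta_0\|^2}
#' (no 1/n factor; the \eqn{\lambda} grid is tied to this convention) via
#' the closed form \eqn{\beta = (X^\top X + \lambda I)^{-1}(X^\top y +
#' \lambda\gamma\beta_0)}, the unique minimiser. An unpenalised intercept
#' is fitted by centring `y` (the design columns are standardized to mean
#' zero, so the intercept decouples).
#'
#' @param X Design matrix.
#' @param y Response.
#' @param lambda Ridge strength.
#' @param gamma Prior strength in \[0, 1\]; 0 recovers standard ridge.
#' @param beta0 Prior coefficients (default all-zero).
#' @param intercept Fit an unpenalised intercept (default TRUE; the
#'   hand-checkable closed-form cases use FALSE).
#' @return List with `beta`, `intercept`, and a `predict(newX)` closure.
#' @export
fit_prior_ridge <- function(X, y, lambda, gamma = 0, beta0 = NULL,
                            intercept = TRUE) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stopf("fit_prior_ridge: non-finite values in the input")
  }
  p <- ncol(X)
  if (is.null(beta0)) beta0 <- rep(0, p)
  b0 <- mean(y) * intercept
  yc <- y - b0
  A <- crossprod(X) + diag(lambda, p)
  beta <- drop(solve(A, crossprod(X, yc) + lambda * gamma * beta0))
  names(beta) <- colnames(X)
  list(beta = beta, intercept = b0,
       predict = function(newX) drop(as.matrix(newX) %*% beta) + b0)
}

#' Prior-informed logistic regression by Newton-Raphson
#'
#' Minimises \eqn{-\log L + \frac{1}{2C}\|\beta - \gamma\beta_0\|^2} with
#' \eqn{p(x) = 1/(1+e^{-\beta^\top x})}, by damped Newton-Raphson updates
#' on the penalised negative log-likelihood. An unpenalised intercept is
#' included. Convergence is declared when the penalised-gradient norm
#' drops below `tol`; non-convergence is flagged, not raised.
#'
#' @param X Design matrix.
#' @param y Binary response in \{0, 1\}.
#' @param C Inverse regularization strength (small C = strong pull).
#' @param gamma Prior strength.
#' @param beta0 Prior coefficients.
#' @param max_iter Maximum Newton iterations (100).
#' @param tol Gradient-norm convergence tolerance (1e-6).
#' @return List with `beta`, `intercept`, `converged`, `n_iter`,
#'   `grad_norm`, and a `predict(newX)` closure returning probabilities.
#' @export
fit_prior_logistic <- function(X, y, C, gamma = 0, beta0 = NULL,
                               max_iter = 100, tol = 1e-6) {
  X <- as.matrix(X)
  stopifnot(all(y %in% c(0, 1)))
  p <- ncol(X)
  if (is.null(beta0)) beta0 <- rep(0, p)
  Xi <- cbind(`(Intercept)` = 1, X)
  # penalty applies to the slopes only, pulling them toward gamma * beta0
  target <- c(0, gamma * beta0)
  pen <- c(0, rep(1 / C, p))
  theta <- target
  obj <- function(th) {
    eta <- drop(Xi %*% th)
    # log(1 + e^eta) computed overflow-safely
    lse <- pmax(eta, 0) + log1p(exp(-abs(eta)))
    -sum(y * eta - lse) + sum(pen * (th - target)^2) / 2
  }
  grad <- function(th) {
    pr <- logistic(drop(Xi %*% th))
    drop(crossprod(Xi, pr - y)) + pen * (th - target)
  }
  converged <- FALSE
  g <- grad(theta)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    pr <- logistic(drop(Xi %*% theta))
    wt <- pmax(pr * (1 - pr), 1e-10)
    Hh <- crossprod(Xi, Xi * wt) + diag(pen, length(pen))
    step <- solve(Hh, g)
    f0 <- obj(theta)
    alpha <- 1
    repeat {  # halving guards the few steps where pure Newton overshoots
      thn <- theta - alpha * step
      if (obj(thn) <= f0 + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    theta <- thn
    g <- grad(theta)
    if (sqrt(sum(g^2)) < tol) {
      converged <- TRUE
      break
    }
  }
  beta <- stats::setNames(theta[-1], colnames(X))
  list(beta = beta, intercept = theta[1], converged = converged, n_iter = it,
       grad_norm = sqrt(sum(g^2)),
       predict = function(newX) {
         logistic(drop(as.matrix(newX) %*% beta) + theta[1])
       })
}

#' Cross-validated selection for the prior-informed linear baselines
#'
#' Threefold cross-validation over a (regularization, gamma) grid.
#' Splits are grouped by patient id by default, preventing leakage
#' between repeated samples of one patient (`grouped = FALSE` gives plain
#' random record-level splits). Regression selects the minimum mean
#' r.m.s.e. across validation folds; classification the maximum mean
#' AUROC. Final predictions are the concatenated held-out fold
#' predictions at the selected grid point. Ties keep the first grid row.
#'
#' @param design A `design_matrix` (or list with `X`, `y`, `groups`).
#' @param beta0 Prior coefficient vector aligned to `design$X` columns.
#' @param grid Data.frame with columns `lambda` (regression) or `C`
#'   (classification) and `gamma`. Defaults to the standard grids:
#'   lambda in \{0.1, 1, 5, 10, 25, 50, 75, 100, 250, 500, 1000\}, C in
#'   \{1e-8 ... 1e-2\}, gamma in \{0, 0.25, 0.5, 0.75, 1\}.
#' @param task `"continuous"` or `"binary"`.
#' @param grouped Group folds by patient id.
#' @param n_folds Number of folds (3).
#' @param seed Fold assignment seed.
#' @return List with `best` (chosen row), `results` (per-point scores),
#'   `predictions` (data.frame of held-out predictions), `index`.
#' @export
cv_select <- function(design, beta0 = NULL, grid = NULL,
                      task = c("continuous", "binary"), grouped = TRUE,
                      n_folds = 3, seed = 1) {
  task <- match.arg(task)
  X <- design$X; y <- design$y
  groups <- design$groups %||% as.character(seq_along(y))
  if (is.null(beta0)) beta0 <- rep(0, ncol(X))
  if (is.null(grid)) {
    grid <- if (task == "continuous") {
      expand.grid(lambda = c(0.1, 1, 5, 10, 25, 50, 75, 100, 250, 500, 1000),
                  gamma = c(0, 0.25, 0.5, 0.75, 1))
    } else {
      expand.grid(C = 10^(-8:-2), gamma = c(0, 0.25, 0.5, 0.75, 1))
    }
  }
  units <- if (grouped) unique(groups) else as.character(seq_along(y))
  if (length(units) < n_folds) {
    stopf("cv_select: need at least %d groups", n_folds)
  }
  fold_of <- with_seed(seed, {
    stats::setNames(sample(rep_len(seq_len(n_folds), length(units))), units)
  })
  fold_idx <- if (grouped) fold_of[groups] else fold_of[as.character(seq_along(y))]

  score <- numeric(nrow(grid))
  pred_store <- vector("list", nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    fold_scores <- rep(NA_real_, n_folds)
    preds <- rep(NA_real_, length(y))
    for (fold in seq_len(n_folds)) {
      hold <- which(fold_idx == fold)
      tr <- which(fold_idx != fold)
      if (task == "binary" && length(unique(y[tr])) < 2) {
        warnf("cv_select: fold %d has a single class in training; skipped", fold)
        next
      }
      fit <- if (task == "continuous") {
        fit_prior_ridge(X[tr, , drop = FALSE], y[tr], grid$lambda[gi],
                        grid$gamma[gi], beta0)
      } else {
        fit_prior_logistic(X[tr, , drop = FALSE], y[tr], grid$C[gi],
                           grid$gamma[gi], beta0)
      }
      ph <- fit$predict(X[hold, , drop = FALSE])
      preds[hold] <- ph
      fold_scores[fold] <- if (task == "continuous") {
        sqrt(mean((y[hold] - ph)^2))
      } else {
        if (length(unique(y[hold])) < 2) NA_real_ else auroc(y[hold], ph)
      }
    }
    score[gi] <- mean(fold_scores, na.rm = TRUE)
    pred_store[[gi]] <- preds
  }
  best_i <- if (task == "continuous") which.min(score) else which.max(score)
  list(best = grid[best_i, , drop = FALSE],
       results = cbind(grid, score = score),
       predictions = data.frame(y_true = y, y_pred = pred_store[[best_i]],
                                fold = as.integer(fold_idx)),
       index = best_i)
}

#' Fit pretraining-cohort prior coefficients
#'
#' Fits the EHR-only linear model (ridge or logistic, gamma = 0) on the
#' pretraining cohort, selecting the regularization strength by grouped
#' cross-validation, and returns coefficients named by feature for use as
#' beta0 in the omics-cohort model via [align_prior()].
#'
#' @param design A pretraining-cohort `design_matrix` (EHR features only).
#' @param task `"continuous"` or `"binary"`.
#' @param seed Fold seed.
#' @return Named coefficient vector.
#' @export
prior_from_pretraining <- function(design, task = c("continuous", "binary"),
                                   seed = 1) {
  task <- match.arg(task)
  grid <- if (task == "continuous") {
    data.frame(lambda = c(0.1, 1, 5, 10, 25, 50, 75, 100, 250, 500, 1000),
               gamma = 0)
  } else {
    data.frame(C = 10^(-8:-2), gamma = 0)
  }
  sel <- cv_select(design, grid = grid, task = task, seed = seed)
  fit <- if (task == "continuous") {
    fit_prior_ridge(design$X, design$y, sel$best$lambda, 0)
  } else {
    fit_prior_logistic(design$X, design$y, sel$best$C, 0)
  }
  fit$beta
}
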