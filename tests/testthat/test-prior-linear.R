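test_that("prior ridge reproduces the hand-derivable one-feature fits", {
  X <- matrix(c(1, 2), 2, 1)
  y <- c(1, 2)
  # (X'X + lambda)^-1 X'y = 5/6 with lambda = 1, beta0 = 0
  f0 <- fit_prior_ridge(X, y, lambda = 1, gamma = 1, beta0 = 0,
                        intercept = FALSE)
  expect_equal(unname(f0$beta), 5 / 6)
  # beta0 = 1 pulls the solution to (5+1)/(5+1) = 1 exactly
  f1 <- fit_prior_ridge(X, y, lambda = 1, gamma = 1, beta0 = 1,
                        intercept = FALSE)
  expect_equal(unname(f1$beta), 1)
  # gamma = 0 is standard ridge no matter what beta0 says
  f2 <- fit_prior_ridge(X, y, lambda = 1, gamma = 0, beta0 = 100,
                        intercept = FALSE)
  expect_equal(unname(f2$beta), 5 / 6)
  expect_error(fit_prior_ridge(matrix(NA_real_, 1, 1), 1, 1), "non-finite")
})

test_that("the ridge closed form minimises the printed objective", {
  # random small instances, checked against a numerical minimizer
  objective <- function(beta, X, y, lambda, gamma, beta0) {
    sum((y - X %*% beta)^2) + lambda * sum((beta - gamma * beta0)^2)
  }
  set.seed(14)
  for (trial in 1:10) {
    n <- sample(3:20, 1)
    p <- sample(1:6, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    b0 <- rnorm(p)
    lambda <- sample(c(0.1, 1, 10, 100), 1)
    gamma <- sample(c(0, 0.5, 1), 1)
    fit <- fit_prior_ridge(X, y, lambda, gamma, b0, intercept = FALSE)
    num <- optim(rep(0, p), objective, X = X, y = y, lambda = lambda,
                 gamma = gamma, beta0 = b0, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14))
    expect_lt(sqrt(sum((fit$beta - num$par)^2)) /
                max(1e-8, sqrt(sum(num$par^2))), 1e-5)
  }
})

test_that("converged logistic fits zero the penalised gradient", {
  set.seed(5)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rbinom(n, 1, plogis(X %*% c(1, -1, 0.5)))
  b0 <- c(0.5, -0.5, 0)
  for (C in c(1e-4, 1e-2)) {
    fit <- fit_prior_logistic(X, y, C, gamma = 0.5, beta0 = b0)
    expect_true(fit$converged)
    expect_lt(fit$grad_norm, 1e-6)
    # numerical-gradient oracle at the solution
    obj <- function(th) {
      eta <- drop(cbind(1, X) %*% th)
      -sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))) +
        sum((th[-1] - 0.5 * b0)^2) / (2 * C)
    }
    th <- c(fit$intercept, fit$beta)
    for (j in seq_along(th)) {
      e <- rep(0, length(th)); e[j] <- 1e-6
      expect_lt(abs((obj(th + e) - obj(th - e)) / 2e-6), 1e-3)
    }
  }
})

test_that("shrinking C pulls logistic coefficients monotonically toward the prior", {
  set.seed(6)
  n <- 80
  X <- matrix(rnorm(n * 2), n, 2)
  y <- rbinom(n, 1, plogis(X %*% c(2, -1)))
  b0 <- c(0.3, 0.3)
  gamma <- 1
  dist <- vapply(10^(-8:-2), function(C) {
    fit <- fit_prior_logistic(X, y, C, gamma, b0)
    sqrt(sum((fit$beta - gamma * b0)^2))
  }, 0)
  # distances along the grid from strongest (C = 1e-8) to weakest penalty
  expect_true(all(diff(dist) >= -1e-8))
  # symmetric 1-feature data: the sign of beta follows the association
  X1 <- matrix(c(-2, -1, 1, 2), 4, 1)
  y1 <- c(0, 0, 1, 1)
  fit1 <- fit_prior_logistic(X1, y1, C = 1e-2, gamma = 0)
  expect_gt(unname(fit1$beta), 0)
})

test_that("design matrices one-hot the codes, filter variance and standardize", {
  gen <- tiny_gen()
  om <- cohort_subset(gen$cohort, "omics")
  D <- build_design(om)
  expect_equal(nrow(D$X), length(om$records))
  # standardized columns
  expect_lt(max(abs(colMeans(D$X))), 1e-10)
  expect_lt(max(abs(apply(D$X, 2, sd) - 1)), 1e-10)
  expect_setequal(unique(D$modality), c("ehr", "omics"))
  # EHR indicators are binary pre-standardization: raw variance filter kept
  # only codes that actually vary
  expect_true(all(D$recipe$centers[D$modality == "ehr"] > 0 &
                    D$recipe$centers[D$modality == "ehr"] < 1))
  # reusing a recipe aligns a new cohort onto the same feature space
  D2 <- build_design(om, recipe = D$recipe)
  expect_equal(colnames(D2$X), colnames(D$X))
})

test_that("prior alignment zero-fills features absent from pretraining", {
  b0 <- c(f1 = 0.5, f2 = -0.2)
  pr <- align_prior(b0, c("f2", "omA", "f1", "omB"))
  expect_equal(unname(pr), c(-0.2, 0, 0.5, 0), ignore_attr = TRUE)
  expect_equal(attr(pr, "from_pretraining"), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("cv_select keeps patients within folds and honours a one-point grid", {
  gen <- tiny_gen()
  om <- cohort_subset(gen$cohort, "omics")
  D <- build_design(om)
  sel <- cv_select(D, grid = data.frame(lambda = 10, gamma = 0),
                   task = "continuous", seed = 2)
  expect_equal(sel$index, 1L)
  expect_equal(unname(sel$best$lambda), 10)
  # grouped folds: all records of a patient share a fold
  by_pat <- tapply(sel$predictions$fold, D$groups, function(f) length(unique(f)))
  expect_true(all(by_pat == 1))
  # held-out predictions exist for every record
  expect_true(all(is.finite(sel$predictions$y_pred)))
})

test_that("an informative prior helps when the omics cohort is small", {
  # beta0 set to the true coefficients: gamma > 0 should win the CV and cut
  # the held-out error relative to gamma = 0, on most seeds
  better <- vapply(1:5, function(s) {
    set.seed(200 + s)
    p <- 12; n <- 24
    beta_true <- rnorm(p)
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X %*% beta_true) + rnorm(n, sd = 2)
    D <- list(X = X, y = y, groups = as.character(seq_len(n)))
    grid <- expand.grid(lambda = c(1, 10, 100), gamma = c(0, 0.5, 1))
    sel <- cv_select(D, beta0 = beta_true, grid = grid, task = "continuous",
                     seed = s)
    rmse_prior <- sqrt(mean((sel$predictions$y_pred - y)^2))
    sel0 <- cv_select(D, beta0 = beta_true,
                      grid = expand.grid(lambda = c(1, 10, 100), gamma = 0),
                      task = "continuous", seed = s)
    rmse0 <- sqrt(mean((sel0$predictions$y_pred - y)^2))
    c(sel$best$gamma > 0, rmse_prior <= rmse0)
  }, logical(2))
  expect_gte(sum(better[1, ]), 4)  # gamma > 0 selected
  expect_gte(sum(better[2, ]), 4)  # and it does not hurt held-out error
})
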