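#' Configuration for the synthetic EHR + omics cohort generator
#'
#' Describes a pair of cohorts — a large EHR-only pretraining cohort and a
#' small omics cohort — driven by a shared low-dimensional latent state
#' \eqn{z \in R^k} per patient. On each day \eqn{t} within the simulated
#' history, concept code \eqn{c} is recorded with probability
#' \eqn{\mathrm{logit}^{-1}(b_c + u_c^\top z + \delta_t)}, where \eqn{b_c}
#' sets the base daily rate, \eqn{u_c} are code loadings and \eqn{\delta_t}
#' is a linear drift toward the anchor day (e.g. rising code intensity in
#' late pregnancy). Analyte abundances are \eqn{x = A z + \varepsilon},
#' \eqn{\varepsilon \sim N(0, \sigma_x^2 I)}; the continuous outcome is
#' \eqn{y = w^\top z + \eta} and the binary outcome is
#' \eqn{\mathrm{Bernoulli}(\mathrm{logit}^{-1}(w^\top z + w_0))} with
#' \eqn{w_0} solved to hit `prevalence`.
#'
#' Defaults are the desk-scale study conditions used throughout the test
#' suite: 2000 pretraining patients, 80 omics patients with 2 samples each,
#' 200 codes, 50 analytes, 4 latent dimensions, 20 days of history.
#' The outcome weights are fixed at \eqn{w_j = \pm 1} so the population
#' variance-explained ceiling \eqn{\|w\|^2/(\|w\|^2+\sigma_\eta^2)} is the
#' same for every seed; with the default `outcome_noise` 1.15 that ceiling
#' corresponds to a best-achievable Pearson r of about 0.87.
#'
#' @param n_pretrain Number of pretraining-cohort patients (EHR + label only).
#' @param n_omics Number of omics-cohort patients (EHR + omics + label).
#' @param vocab_size Number of distinct concept codes V.
#' @param n_analytes Number of omics analytes P.
#' @param latent_dim Latent state dimension k.
#' @param horizon Days of simulated EHR history per patient (before anchor).
#' @param code_base_rate Baseline per-day emission probability of one code.
#' @param loading_scale Standard deviation of code/analyte loading entries.
#' @param omics_noise Analyte noise s.d. \eqn{\sigma_x} (signal s.d. per
#'   analyte is about `loading_scale * sqrt(latent_dim)`).
#' @param outcome_noise Continuous-outcome noise s.d. \eqn{\sigma_\eta}.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param prevalence Target positive-class prevalence for binary outcomes.
#' @param samples_per_patient Omics samples drawn per omics-cohort patient.
#' @param drift_slope Magnitude of the linear temporal drift \eqn{\delta_t}
#'   (0 at the anchor day, `-drift_slope` at the start of the horizon).
#' @param outcome_scale Multiplier on the outcome weights w (0 gives a null
#'   outcome unrelated to the latent state).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_pretrain = 2000, n_omics = 80,
                             vocab_size = 200, n_analytes = 50,
                             latent_dim = 4, horizon = 20,
                             code_base_rate = 0.02, loading_scale = 1,
                             omics_noise = 2, outcome_noise = 1.15,
                             outcome_type = c("continuous", "binary"),
                             prevalence = 0.2, samples_per_patient = 2,
                             drift_slope = 1, outcome_scale = 1, seed = 1) {
  outcome_type <- match.arg(outcome_type)
  cfg <- list(n_pretrain = n_pretrain, n_omics = n_omics,
              vocab_size = vocab_size, n_analytes = n_analytes,
              latent_dim = latent_dim, horizon = horizon,
              code_base_rate = code_base_rate, loading_scale = loading_scale,
              omics_noise = omics_noise, outcome_noise = outcome_noise,
              outcome_type = outcome_type, prevalence = prevalence,
              samples_per_patient = samples_per_patient,
              drift_slope = drift_slope, outcome_scale = outcome_scale,
              seed = seed)
  counts <- c("n_pretrain", "n_omics", "vocab_size", "n_analytes",
              "latent_dim", "horizon", "samples_per_patient")
  for (f in counts) {
    if (length(cfg[[f]]) != 1 || cfg[[f]] < 1) {
      stopf("synthetic_config: '%s' must be a count >= 1", f)
    }
  }
  if (code_base_rate <= 0 || code_base_rate >= 1) {
    stopf("synthetic_config: 'code_base_rate' must lie in (0, 1)")
  }
  if (omics_noise < 0 || outcome_noise < 0) {
    stopf("synthetic_config: noise levels must be >= 0")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic pretraining + omics cohort pair
#'
#' Simulates patients under the latent-state model described in
#' [synthetic_config()], applies the pregnancy-style observation windows
#' (pretraining patients: a random cut-off within the last
#' `min(100, horizon)` days before the anchor; omics patients: one window
#' per sampling day), and returns the windowed records together with the
#' generating ground truth for parameter-recovery and ceiling analyses.
#'
#' @param config A [synthetic_config()].
#' @return A list with components `cohort` (a `comet_cohort`) and `truth`
#'   (a `ground_truth` list with `Z`, `U`, `A`, `w`, `b`, `anchor_day`,
#'   `intercept` for binary outcomes, and per-record latent row indices).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_pretrain + cfg$n_omics
  k <- cfg$latent_dim
  V <- cfg$vocab_size
  P <- cfg$n_analytes
  Tn <- cfg$horizon

  patient_id <- sprintf("P%05d", seq_len(n))
  is_omics <- c(rep(FALSE, cfg$n_pretrain), rep(TRUE, cfg$n_omics))
  codes <- sprintf("C%04d", seq_len(V))
  analytes <- sprintf("A%03d", seq_len(P))

  Z <- matrix(rnorm(n * k), n, k, dimnames = list(patient_id, NULL))
  U <- matrix(rnorm(V * k, sd = cfg$loading_scale), V, k,
              dimnames = list(codes, NULL))
  A <- matrix(rnorm(P * k, sd = cfg$loading_scale), P, k,
              dimnames = list(analytes, NULL))
  w <- cfg$outcome_scale * sample(c(-1, 1), k, replace = TRUE)
  b <- rep(qlogis(cfg$code_base_rate), V)
  anchor_day <- rep(280L, n)  # arbitrary epoch; windows are relative anyway

  # per-day drift: 0 on the anchor day, -drift_slope at the horizon start
  days <- seq_len(Tn)                      # day index t = anchor - horizon + t
  delta <- -cfg$drift_slope * (Tn - days) / Tn

  # latent linear predictor per patient x code
  eta_code <- Z %*% t(U)                   # n x V

  # signal for binary outcomes: intercept solved to hit target prevalence
  score <- drop(Z %*% w)
  intercept <- NA_real_
  y_patient <- NULL
  if (cfg$outcome_type == "binary") {
    f <- function(b0) mean(plogis(score + b0)) - cfg$prevalence
    intercept <- uniroot(f, c(-50, 50))$root
    y_patient <- rbinom(n, 1, plogis(score + intercept))
    if (all(y_patient == 0) || all(y_patient == 1)) {
      stopf(paste("generate_cohort: all labels identical at prevalence %.3f;",
                  "increase the cohort size"), cfg$prevalence)
    }
  }

  max_back <- min(100L, Tn - 1L)           # window cut-off offsets before anchor

  records <- vector("list", 0L)
  latent_row <- integer(0)

  for (i in seq_len(n)) {
    # emit codes: V x T Bernoulli with per-code, per-day probability
    lp <- outer(eta_code[i, ], delta, "+") + b   # V x T
    occ <- matrix(runif(V * Tn) < plogis(lp), V, Tn)
    hit <- which(occ, arr.ind = TRUE)
    ev <- data.frame(
      day = anchor_day[i] - Tn + hit[, 2],
      code = codes[hit[, 1]],
      stringsAsFactors = FALSE
    )
    ev <- ev[order(ev$day, ev$code), , drop = FALSE]

    if (!is_omics[i]) {
      offset <- sample.int(max_back + 1L, 1L) - 1L
      wend <- anchor_day[i] - offset
      y <- if (cfg$outcome_type == "binary") y_patient[i] else
        sum(w * Z[i, ]) + rnorm(1, sd = cfg$outcome_noise)
      records[[length(records) + 1L]] <- list(
        record_id = patient_id[i], patient_id = patient_id[i],
        cohort = "pretraining", window = c(anchor_day[i] - 280, wend),
        events = ev[ev$day <= wend, , drop = FALSE],
        omics = NULL, outcome = y)
      latent_row <- c(latent_row, i)
    } else {
      offs <- sample.int(max_back + 1L, min(cfg$samples_per_patient, max_back + 1L)) - 1L
      for (s in seq_along(offs)) {
        wend <- anchor_day[i] - offs[s]
        x <- drop(A %*% Z[i, ]) + rnorm(P, sd = cfg$omics_noise)
        names(x) <- analytes
        y <- if (cfg$outcome_type == "binary") y_patient[i] else
          sum(w * Z[i, ]) + rnorm(1, sd = cfg$outcome_noise)
        records[[length(records) + 1L]] <- list(
          record_id = sprintf("%s_S%d", patient_id[i], s),
          patient_id = patient_id[i],
          cohort = "omics", window = c(anchor_day[i] - 280, wend),
          events = ev[ev$day <= wend, , drop = FALSE],
          omics = x, outcome = y)
        latent_row <- c(latent_row, i)
      }
    }
  }

  cohort <- new_comet_cohort(
    records, task = cfg$outcome_type, analytes = analytes,
    manifest = list(generator = "synthetic", seed = cfg$seed,
                    n_pretrain = cfg$n_pretrain, n_omics = cfg$n_omics,
                    vocab_size = cfg$vocab_size))
  truth <- structure(
    list(Z = Z, U = U, A = A, w = w, b = b, anchor_day = anchor_day,
         intercept = intercept, latent_row = latent_row,
         patient_id = patient_id, is_omics = is_omics),
    class = "ground_truth")
  list(cohort = cohort, truth = truth)
}

#' Population ceiling on outcome variance explained by the latent state
#'
#' For continuous outcomes \eqn{y = w^\top z + \eta} with
#' \eqn{z \sim N(0, I)}, the fraction of outcome variance any model can
#' explain is \eqn{\|w\|^2 / (\|w\|^2 + \sigma_\eta^2)}.
#'
#' @param truth A `ground_truth` object from [generate_cohort()].
#' @param config The matching [synthetic_config()].
#' @return The population R-squared ceiling in \[0, 1\].
#' @export
oracle_r2 <- function(truth, config) {
  if (config$outcome_type != "continuous") {
    stopf("oracle_r2 is defined for continuous outcomes")
  }
  ss <- sum(truth$w^2)
  if (ss == 0) return(0)
  ss / (ss + config$outcome_noise^2)
}
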