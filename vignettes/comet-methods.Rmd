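---
title: "Methods: multimodal EHR-omics fusion with a pretrained, frozen encoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal EHR-omics fusion with a pretrained, frozen encoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Omics studies measure thousands of analytes on small cohorts; models fit on
such data overfit, and their "important features" replicate poorly.
Electronic health records (EHR), by contrast, exist for very large
populations. This package implements COMET (clinical and omics multimodal
analysis enhanced with transfer learning): pretrain a sequence encoder on a
large EHR-only cohort with outcome labels, freeze it, and transfer it into a
three-branch multimodal network trained on the small cohort that has both
EHR and omics data. Pretraining acts as a regularizer by initialization: the
frozen encoder pins the EHR representation, and through backpropagation also
constrains what the omics and joint branches must learn.

## Data model and embedding pipeline

EHR events are (patient, concept code, day) triples from the five OMOP
event tables (measurement, observation, drug_exposure, condition_occurrence,
procedure_occurrence); rows with `concept_id == 0` are dropped. Dates are
integer day offsets from an arbitrary epoch — all the windowing rules below
operate on whole days, because codes are grouped by day anyway.

Two observation-window rules are implemented:

* **Pregnancy-style**: the window opens 280 days before childbirth. For
  omics-cohort records it closes at the omics sampling day; pretraining
  patients have no sampling day, so the close is drawn uniformly on whole
  days from the last 100 days before delivery (both endpoints included —
  the minimal reading of "a random date between childbirth and up to 100
  days prior"). The regression outcome is days from window close to
  delivery.
* **Diagnosis/sampling-anchored**: all history is kept; the window closes
  at the sampling day (omics cohort) or the day of first cancer diagnosis
  (pretraining cohort). The outcome is a supplied binary label such as
  3-year mortality.

All codes recorded for one patient on one day form a "sentence"; the
within-day order is randomly shuffled (intra-day time stamps are not
reliable), and skip-gram word2vec with negative sampling learns a vector per
code. Each day is then summarized by the mean embedding of its codes, and
the chronological sequence of the 32 most recent summary days feeds the
sequence encoder. Three choices here deserve a note:

* Out-of-vocabulary codes at summarization time are skipped rather than
  zero-imputed; zero vectors would drag day means toward the origin.
* Days with no embeddable codes are dropped and do not count toward the
  32-day cap, which is defined on days *of data*.
* Sequences shorter than the batch maximum are front-padded with zero rows;
  the encoders carry per-record lengths and padded steps leave the hidden
  state untouched (verified by an invariance test).

Embedding hyperparameters (window 5, 5 negative samples, 5 epochs,
`min_count` 1) follow common word2vec practice; training is single-threaded
so a seed fully determines the table. The embedding dimension is 400 at full
scale; the desk-scale experiments in this package use 16.

### Reconciling separately trained embedding spaces

A separate word2vec model is trained for the pretraining and omics cohorts,
yet the recurrent encoder trained on one cohort's embeddings must read the
other's. Independently trained skip-gram spaces agree only up to an
orthogonal transformation, and at desk scale (d = 16) this matters: raw
separately-trained tables are substantially rotated relative to each
other, and an encoder frozen in one space cannot read summaries built in
the other. `align_embeddings()` therefore rotates the omics-cohort table
onto the pretraining table by orthogonal Procrustes over the shared
vocabulary — the standard alignment for separately trained word
embeddings — after which the frozen encoder transfers cleanly (a test
verifies that the rotation recovers an orthogonally transformed table
exactly). The
vocabulary is kept in deterministic name order so that shared codes receive
identical seeded initializations, which keeps the two training runs in the
same solution basin. Setting `share_embeddings = TRUE` in
`comet_experiment()` uses a single table for both cohorts instead (an
ablation, not the default).

## Architecture

The full network has three branches:

* **EHR branch**: a gated-recurrent-unit stack (2 or 4 layers; hidden
  dimension 400 at paper scale, 32 at desk scale) over the daily summary
  sequence, followed by one linear layer producing a scalar EHR prediction.
* **Omics branch**: one linear layer for regression; for classification a
  one-hidden-layer perceptron (hidden 16/32/64, rectifier) producing a raw
  score.
* **Joint branch**: one linear layer over the concatenation of the final
  EHR hidden state and the omics vector.

A final linear layer **with no bias** mixes the three branch predictions.
For classification the branches are combined on the logit scale and the
logistic link is applied to the combined score; the omics-only baseline
applies the link to its own score. Losses are mean squared error and binary
cross-entropy (predictions clamped to `[1e-7, 1 - 1e-7]`).

An alternative transformer encoder replaces word2vec + GRU: codes become
tokens (with sequence-start and day-boundary specials), capped at 1024
tokens by dropping the oldest; learned embeddings scaled by sqrt(d) are
added to sinusoidal positional encodings and passed through 2 post-norm
encoder layers (4 heads, 512-dim feed-forward at paper scale). Padding keys
receive large negative attention scores. The latent representation is the
hidden state at the last non-padding position — reading a padding position
would take a masked token. Because no deep-learning framework ships with
this package's environment-agnostic core, both encoders, the fusion heads
and Adam are implemented directly in R with hand-derived backpropagation;
every gradient path is validated against central differences in the test
suite.

## Training protocol

* **Pretraining**: encoder + EHR head on the pretraining cohort, batch 512,
  holding out 20% of patients for early stopping.
* **Transfer**: encoder weights are copied and frozen (the optimizer skips
  them; a test asserts bitwise identity after training). The pretrained EHR
  head is copied as an initialization but stays trainable — only the
  recurrent weights are described as frozen; re-initializing the head
  would discard calibration, freezing it would over-constrain the combiner.
* **Multimodal training**: batch 16, Adam (the standard choice for this
  architecture family; the grid covers the learning rate), per-epoch
  learning-rate decay `lr * (1 - lr_decay)^epoch`, early stopping when the
  held-out test loss fails to improve for 5 consecutive epochs, best-epoch
  weights restored. `max_epochs` defaults to 100; early stopping governs in
  practice.
* **Hyperparameters** are chosen once by grouped threefold cross-validation
  with a 20% early-stopping holdout inside the training folds, then reused
  for every subsequent split (ties keep grid order). Each experiment mode
  is tuned separately, as in the full protocol — a transfer run and a
  from-scratch run need not share an optimal learning rate.
* **Evaluation**: 25 repeats of patient-grouped 70/15/15
  train/test/validation splits; per record, the final prediction is the
  mean over the repeats where it fell in validation. Metrics: Pearson r,
  r.m.s.e., Lin's concordance (regression); AUROC, AUPRC, Cohen's kappa at
  threshold 0.5 (classification; the operating point is configurable since
  none is prescribed). Confidence intervals use a seeded percentile
  bootstrap over prediction pairs (1000 resamples) — metric-agnostic and
  assumption-light; no analytic form is assumed anywhere.

The prior-informed linear baselines minimize
`||y - X b||^2 + lambda ||b - gamma b0||^2` (ridge, closed form; the
objective is exactly as printed, with no 1/n factor — the lambda grid is
tied to that convention) and `-log L + 1/(2C) ||b - gamma b0||^2`
(logistic, damped Newton-Raphson, convergence at gradient norm below 1e-6).
`b0` comes from an EHR-only fit on the pretraining cohort; features absent
there — all omics analytes — get `b0 = 0`. Features are one-hot code
indicators plus analytes, variance-filtered at 0.01 *before*
standardization (afterwards the filter would be vacuous), then standardized;
the same recipe is applied to the pretraining design so coefficients are on
comparable scales. Intercepts are fitted unpenalized — shrinking an
intercept toward 0 or a prior is rarely intended. Cross-validation is
grouped by patient for both baselines (a `grouped = FALSE` flag reproduces
plain random splits where wanted).

## The synthetic cohort generator

Real cohorts of this design (hospital OMOP extracts, biobank proteomics)
are access-restricted, so the package ships a generator whose cohorts make
every downstream stage testable. Each patient carries a latent state
`z ~ N(0, I_k)` that drives everything:

* codes: on each day, code c occurs with probability
  `plogis(b_c + u_c' z + delta_t)`, Bernoulli per code per day (the
  embedding pipeline only consumes within-day presence), with `delta_t`
  rising linearly toward the anchor day — the analogue of intensifying
  late-pregnancy care;
* analytes: `x = A z + noise(sd = omics_noise)`;
* outcome: `y = w' z + noise(sd = outcome_noise)` or
  `Bernoulli(plogis(w' z + w0))` with `w0` solved for a target prevalence.

Defaults (the study conditions for all tests): 2000 pretraining patients,
80 omics patients with 2 samples each (sampling days in the last
`min(100, horizon)` days before the anchor), 200 codes, 50 analytes, k = 4,
20 days of history, `code_base_rate = 0.02` (a few codes per day),
`loading_scale = 1`, `omics_noise = 2` (per-analyte signal-to-noise about
one — typical of plasma proteomics, and low enough that 50 analytes
jointly determine z in population while a 112-sample fit cannot),
`outcome_noise = 1.15`. Outcome weights are fixed at ±1, so the population
ceiling `||w||^2 / (||w||^2 + outcome_noise^2) = 0.75` — a best-achievable
Pearson r of about 0.87, matching the scale of accuracy seen in real
pregnancy cohorts — is identical for every seed (`oracle_r2()` returns it).
The binary default prevalence is 0.2 rather than the 5.5% of a real cancer
cohort: at 80 patients, 5.5% leaves about 4 positive patients and
single-class folds. What the generator does **not** emulate: realistic OMOP
vocabularies and visit structure, code burstiness, informative missingness,
heavy-tailed analyte distributions, or nonlinear latent-outcome links.
Passing tests show the machinery recovers a linear-Gaussian shared factor;
they do not certify performance on real EHR.

## Problem sizes used in the shipped experiments

The acceptance-style experiments run the full pipeline at the default
generator scale with embedding dimension 16 and hidden dimension 32, 10
protocol repeats per mode and 5 base seeds — sizes chosen so the complete
comparison runs on one desktop core in minutes while leaving the protocol
machinery (grouped repeated splits, averaged validation predictions)
identical to the full 25-repeat design. The repeat count is a scale
parameter of the experiment, not of the method; `n_repeats = 25` reproduces
the full design unchanged.

## Numerical and degenerate-input choices

* Ridge uses one Cholesky-backed solve of `(X'X + lambda I)`; the
  penalized system is always positive definite.
* Newton-Raphson halves its step while the penalized objective fails to
  decrease; non-convergence within 100 iterations is flagged on the result
  rather than raised.
* BCE clamps predictions at 1e-7; logistic log-likelihoods use the
  overflow-safe `log(1 + exp(x))` form.
* Patients whose window contains no events are retained with an empty
  sequence (the encoder sees all padding and returns the zero state);
  dropping them would silently change cohort composition.
* Empty days, out-of-vocabulary codes and constant columns in correlation
  tests are all handled explicitly (skipped, skipped, reported
  non-significant with a note, respectively).
* Grid-search and cross-validation ties keep the first grid row.

## Interpretation suite

* **Integrated gradients** on the omics branch, EHR input held fixed at
  the sample's own sequence: baseline = zero vector (the cohort mean on
  standardized features), m = 128 steps by default; completeness
  `sum(attr) = f(x) - f(baseline)` is asserted on every attributed sample.
  Per-analyte importance is the mean absolute attribution over validation
  samples.
* **Latent-analyte alignment**: all d x P Pearson correlations between the
  EHR latent dimensions and analytes, Bonferroni-corrected over the full
  d x P family (the conservative reading when no family is stated);
  reported as a significant-pair count and per-analyte fractions.
* **Correlation maps**: each feature's row of the full signed correlation
  matrix embedded in 2-D, plus per-analyte significant-correlation counts
  against EHR features and per-EHR-feature maximum absolute correlations.
* **Function-space trajectories**: per-epoch snapshots are compared by
  their concatenated outputs on a fixed record set (networks with
  different weights can be functionally identical), embedded in 2-D.

No t-SNE implementation is available to this package's dependency set, so
the two embedding-based views use a small exact (dense) t-SNE written here:
perplexity-calibrated Gaussian affinities by per-point bisection, early
exaggeration, momentum gradient descent, fixed seed. Perplexity is reduced
automatically when fewer points than `3 * perplexity + 1` are embedded.
Inputs in this package are at most a few hundred points, where the exact
method is fast and has no approximation noise.

## Known limitations

* The generator is linear-Gaussian; none of the shipped experiments probe
  nonlinear latent-outcome structure.
* At desk scale the latent state is low-dimensional and recoverable from
  either modality alone, so the *predictive* margin of the pretrained
  model over the joint baseline is small — the acceptance script reports
  both. The transfer effect is clearer in the latent-analyte alignment
  counts, where the frozen pretrained encoder's representation correlates
  with the analytes more broadly than the from-scratch encoders' in most
  seeds. Large pretraining margins of the kind seen on real cohorts need
  the information asymmetry of real EHR: high-dimensional messy inputs
  that a small cohort cannot learn to encode from scratch.
* Survival losses and censoring are out of scope; the binary task treats
  3-year mortality as fully observed.
* The transformer path shares the fusion machinery but has only desk-scale
  defaults; no pretrained-language-model initialization is attempted.
* Bootstrap confidence intervals at n below ~50 are known to under-cover
  slightly; the coverage test asserts the 90-99% band, not exact 95%.
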