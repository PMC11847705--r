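#' @title Concept-code embeddings and daily summary sequences
#' @name code_embedding
#' @description All codes recorded for a patient within one day form a
#'   "sentence"; sentences are randomly shuffled (time stamps within a day
#'   are unreliable), embedded with skip-gram word2vec, and each day is
#'   summarised by the arithmetic mean of its code embeddings. The
#'   chronological sequence of daily means — capped at the 32 most recent
#'   days with data — is the input consumed by the sequence encoders.
NULL

#' Build shuffled day sentences from a cohort
#'
#' One sentence per (patient, day) with at least one code; the within-day
#' order is a seeded random permutation of the day's codes. Days with no
#' codes produce no sentence. Records sharing a patient (multiple omics
#' samples) contribute each patient-day once.
#'
#' @param cohort A `comet_cohort` (or a list of its records).
#' @param seed Shuffle seed.
#' @return A list of character vectors (the sentences), with a
#'   `patient_day` attribute identifying each sentence.
#' @export
build_sentences <- function(cohort, seed = 1) {
  records <- if (inherits(cohort, "comet_cohort")) cohort$records else cohort
  ev <- do.call(rbind, lapply(records, function(r) {
    if (nrow(r$events) == 0L) return(NULL)
    data.frame(patient_id = r$patient_id, day = r$events$day,
               code = r$events$code, stringsAsFactors = FALSE)
  }))
  if (is.null(ev) || nrow(ev) == 0L) {
    return(structure(list(), patient_day = character(0)))
  }
  ev <- unique(ev)
  key <- paste(ev$patient_id, ev$day, sep = "@")
  groups <- split(ev$code, key)
  # deterministic sentence order regardless of record order
  groups <- groups[order(names(groups))]
  sentences <- with_seed(seed, lapply(groups, function(cs) {
    if (length(cs) == 1L) cs else cs[sample.int(length(cs))]
  }))
  structure(unname(sentences), patient_day = names(groups))
}

#' Train skip-gram code embeddings
#'
#' Skip-gram with negative sampling over the day sentences (the word2vec
#' objective), run single-threaded so that a seed fully determines the
#' result. Hyperparameter defaults follow common word2vec practice:
#' window 5, 5 negative samples, 5 epochs, `min_count` 1 (clinical codes
#' are sparse; rare codes are still informative at desk scale).
#'
#' @param sentences Output of [build_sentences()].
#' @param d Embedding dimension (400 at full scale; 16-32 at desk scale).
#' @param window Maximum skip-gram context window.
#' @param negative Negative samples per positive pair.
#' @param min_count Minimum corpus frequency for a code to be embedded.
#' @param epochs Training epochs.
#' @param lr Initial learning rate (linearly decayed to `lr/1e4`).
#' @param seed Seed for initialization, window shrinkage and sampling.
#' @return An `embedding_table`: a codes-by-d numeric matrix with the code
#'   vocabulary as row names.
#' @export
train_embeddings <- function(sentences, d = 16, window = 5, negative = 5,
                             min_count = 1, epochs = 5, lr = 0.025, seed = 1) {
  if (length(sentences) == 0L) stopf("train_embeddings: empty corpus")
  counts <- table(unlist(sentences))
  vocab <- sort(names(counts)[counts >= min_count])
  # vocabulary in deterministic name order (not frequency order): codes
  # shared between separately trained cohort models then receive identical
  # seeded initializations, keeping the two embedding spaces comparable
  if (length(vocab) == 0L) stopf("train_embeddings: no code meets min_count")
  idx <- stats::setNames(seq_along(vocab), vocab)
  sent_idx <- lapply(sentences, function(s) unname(idx[s[s %in% vocab]]))
  sent_idx <- sent_idx[vapply(sent_idx, length, 0L) > 0L]
  mat <- sgns_train_cpp(sent_idx, length(vocab), as.integer(d),
                        as.integer(counts[vocab]), as.integer(window),
                        as.integer(negative), as.integer(epochs),
                        lr, lr * 1e-4, as.double(seed))
  rownames(mat) <- vocab
  structure(mat, class = c("embedding_table", "matrix"),
            d = as.integer(d))
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("embedding_table: %d codes x %d dimensions\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Align one embedding table to another by orthogonal Procrustes
#'
#' Independently trained skip-gram models place codes in spaces that agree
#' only up to rotation/reflection; an encoder trained on one space cannot
#' read the other directly. This rotates `table` onto `reference` by the
#' orthogonal Procrustes solution over their shared vocabulary (the SVD of
#' the cross-covariance), the standard reconciliation for separately
#' trained word-embedding spaces. Geometry within `table` (norms, angles)
#' is unchanged.
#'
#' @param table The `embedding_table` to rotate (e.g. the omics cohort's).
#' @param reference The target space (e.g. the pretraining cohort's).
#' @return `table` rotated into the reference space.
#' @export
align_embeddings <- function(table, reference) {
  shared <- intersect(rownames(table), rownames(reference))
  if (length(shared) < 2) {
    stopf("align_embeddings: fewer than 2 shared codes")
  }
  s <- svd(crossprod(table[shared, , drop = FALSE],
                     reference[shared, , drop = FALSE]))
  out <- unclass(table) %*% (s$u %*% t(s$v))
  rownames(out) <- rownames(table)
  structure(out, class = c("embedding_table", "matrix"), d = ncol(out))
}

#' Write / read an embedding table as tab-separated text
#' @param table An `embedding_table`.
#' @param path Destination file.
#' @export
write_embeddings <- function(table, path) {
  df <- data.frame(code = rownames(table), unclass(table),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- as.character(df$code)
  dimnames(mat)[[2]] <- NULL
  structure(mat, class = c("embedding_table", "matrix"), d = ncol(mat))
}

#' Summarise one record into a daily mean-embedding sequence
#'
#' For each day with at least one embeddable code, the summary row is the
#' mean of that day's code vectors. Codes absent from the vocabulary are
#' skipped (zero-imputing them would bias day means toward the origin);
#' days left with no embeddable codes are dropped and do not count toward
#' the cap. Only the `max_days` most recent summary days are kept, ordered
#' oldest first.
#'
#' @param record A cohort record.
#' @param table An `embedding_table`.
#' @param max_days Day cap (32, matching the encoders' input length).
#' @return A list with `matrix` (L x d, possibly L = 0), `days` (the day
#'   indices retained) and `length` (L).
#' @export
summarize_record <- function(record, table, max_days = 32) {
  d <- ncol(table)
  ev <- record$events
  ev <- ev[ev$code %in% rownames(table), , drop = FALSE]
  if (nrow(ev) == 0L) {
    return(list(matrix = matrix(0, 0, d), days = integer(0), length = 0L))
  }
  days <- sort(unique(ev$day))
  if (length(days) > max_days) days <- tail(days, max_days)
  rows <- vapply(days, function(dy) {
    vecs <- table[ev$code[ev$day == dy], , drop = FALSE]
    colMeans(vecs)
  }, numeric(d))
  list(matrix = t(matrix(rows, nrow = d)), days = as.integer(days),
       length = length(days))
}

#' Encode a cohort for the sequence encoders
#'
#' Applies [summarize_record()] to every record and packs the results into
#' a front-padded array for batched training: sequences shorter than the
#' longest are padded with zero rows at the front, and per-record lengths
#' let the encoders ignore the padding.
#'
#' @param cohort A `comet_cohort`.
#' @param table An `embedding_table`.
#' @param max_days Day cap per record.
#' @return An `encoded_cohort`: list with `X` (N x T x d array), `lengths`,
#'   `omics` (N x P matrix or NULL), `y`, `record_id`, `patient_id`.
#' @export
encode_cohort <- function(cohort, table, max_days = 32) {
  recs <- cohort$records
  seqs <- lapply(recs, summarize_record, table = table, max_days = max_days)
  lens <- vapply(seqs, `[[`, 0L, "length")
  Tmax <- max(1L, max(lens))
  d <- ncol(table)
  N <- length(recs)
  X <- array(0, dim = c(N, Tmax, d))
  for (i in seq_len(N)) {
    L <- lens[i]
    if (L > 0L) X[i, (Tmax - L + 1L):Tmax, ] <- seqs[[i]]$matrix
  }
  omics <- NULL
  has_om <- vapply(recs, function(r) !is.null(r$omics), TRUE)
  if (any(has_om)) {
    omics <- do.call(rbind, lapply(recs, function(r) {
      r$omics %||% rep(NA_real_, length(cohort$analytes))
    }))
    rownames(omics) <- names(recs)
  }
  structure(list(
    X = X, lengths = lens, omics = omics,
    y = vapply(recs, function(r) as.numeric(r$outcome), 0),
    record_id = vapply(recs, `[[`, "", "record_id"),
    patient_id = vapply(recs, `[[`, "", "patient_id"),
    task = cohort$task
  ), class = "encoded_cohort")
}

# take a row subset of an encoded cohort
encoded_subset <- function(enc, idx) {
  structure(list(
    X = if (!is.null(enc$X)) enc$X[idx, , , drop = FALSE],
    tokens = if (!is.null(enc$tokens)) enc$tokens[idx],
    lengths = enc$lengths[idx],
    omics = if (!is.null(enc$omics)) enc$omics[idx, , drop = FALSE],
    y = enc$y[idx], record_id = enc$record_id[idx],
    patient_id = enc$patient_id[idx], task = enc$task
  ), class = "encoded_cohort")
}
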