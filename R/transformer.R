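#' Transformer encoder configuration
#'
#' Settings for the alternative EHR encoder: clinical codes are tokenized
#' (with special tokens for sequence start and day boundaries), mapped to
#' learned embeddings scaled by \eqn{\sqrt d}, combined with sinusoidal
#' positional encodings, and passed through masked self-attention encoder
#' layers (post-norm, rectifier feed-forward). Paper-scale values are
#' d = 128, 4 heads, 2 layers, 512 feed-forward, maximum length 1024.
#'
#' @param d Token embedding / model dimension (even, divisible by `heads`).
#' @param heads Attention heads.
#' @param layers Encoder layers.
#' @param ff_dim Feed-forward inner dimension.
#' @param max_len Maximum token-sequence length; longer histories drop
#'   their oldest tokens.
#' @return A `transformer_config` list.
#' @export
transformer_config <- function(d = 32, heads = 4, layers = 2, ff_dim = 128,
                               max_len = 1024) {
  if (d %% 2 != 0) stopf("transformer_config: d must be even")
  if (d %% heads != 0) stopf("transformer_config: heads must divide d")
  structure(list(d = d, heads = heads, layers = layers, ff_dim = ff_dim,
                 max_len = max_len), class = "transformer_config")
}

# special-token ids appended after the code vocabulary
tok_special <- function(vocab_size) {
  c(START = vocab_size + 1L, DAYSTART = vocab_size + 2L,
    DAYEND = vocab_size + 3L, PAD = vocab_size + 4L)
}

#' Tokenize a patient record for the transformer encoder
#'
#' Days in chronological order, each wrapped in day-start/day-end tokens,
#' with the within-day code order shuffled (time stamps within a day are
#' unreliable) and a sequence-start token first. Histories longer than
#' `max_len` drop their oldest tokens (those right after the start token)
#' to fit exactly.
#'
#' @param record A cohort record.
#' @param vocab Character vector of codes defining token ids 1..V; codes
#'   outside it are skipped.
#' @param seed Within-day shuffle seed.
#' @param max_len Maximum sequence length.
#' @return Integer token vector (length >= 1; starts with the START token
#'   unless truncation dropped it).
#' @export
tokenize_record <- function(record, vocab, seed = 1, max_len = 1024) {
  sp <- tok_special(length(vocab))
  idx <- stats::setNames(seq_along(vocab), vocab)
  ev <- record$events
  ev <- ev[ev$code %in% vocab, , drop = FALSE]
  toks <- sp[["START"]]
  if (nrow(ev) > 0L) {
    days <- sort(unique(ev$day))
    body <- with_seed(seed, {
      unlist(lapply(days, function(dy) {
        cs <- unname(idx[ev$code[ev$day == dy]])
        if (length(cs) > 1L) cs <- cs[sample.int(length(cs))]
        c(sp[["DAYSTART"]], cs, sp[["DAYEND"]])
      }))
    })
    toks <- c(toks, body)
  }
  if (length(toks) > max_len) {
    toks <- c(toks[1L], tail(toks[-1L], max_len - 1L))
  }
  as.integer(toks)
}

#' Sinusoidal positional encoding
#'
#' Evaluates \eqn{PE(pos, 2i) = \sin(pos / 10000^{2i/d})} and
#' \eqn{PE(pos, 2i+1) = \cos(pos / 10000^{2i/d})} for 0-based position
#' `pos` and dimension-pair index `i`.
#'
#' @param pos 0-based position (scalar or vector).
#' @param d Model dimension.
#' @return A `length(pos)` x `d` matrix (a vector for scalar `pos`).
#' @export
positional_encoding <- function(pos, d) {
  i <- seq_len(d / 2) - 1
  freq <- 1 / 10000^(2 * i / d)
  out <- matrix(0, length(pos), d)
  ang <- outer(pos, freq)
  out[, 2 * i + 1] <- sin(ang)
  out[, 2 * i + 2] <- cos(ang)
  if (length(pos) == 1L) drop(out) else out
}

transformer_init <- function(cfg, vocab_size) {
  d <- cfg$d; ff <- cfg$ff_dim
  layers <- lapply(seq_len(cfg$layers), function(l) {
    list(Wq = init_mat(d, d, d), bq = init_vec(d, d),
         Wk = init_mat(d, d, d), bk = init_vec(d, d),
         Wv = init_mat(d, d, d), bv = init_vec(d, d),
         Wo = init_mat(d, d, d), bo = init_vec(d, d),
         g1 = rep(1, d), be1 = rep(0, d),
         W1 = init_mat(d, ff, d), b1 = init_vec(ff, d),
         W2 = init_mat(ff, d, ff), b2 = init_vec(d, ff),
         g2 = rep(1, d), be2 = rep(0, d))
  })
  list(emb = init_mat(vocab_size + 4L, d, d), layers = layers)
}

ln_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  Y <- sweep(sweep(xhat, 2, g, "*"), 2, b, "+")
  list(Y = Y, xhat = xhat, inv = inv)
}

ln_backward <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2, g, "*")
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dY * xhat), db = colSums(dY))
}

# encoder forward for a list of token sequences; padding tokens are kept in
# place and excluded from attention via large negative scores, and the
# latent is read at the last non-padding position.
transformer_forward <- function(params, tokens, cfg, dropout = 0,
                                training = FALSE, want_cache = FALSE) {
  B <- length(tokens)
  d <- cfg$d
  nh <- cfg$heads
  dk <- d / nh
  pad_id <- nrow(params$emb)
  h <- matrix(0, B, d)
  caches <- if (want_cache) vector("list", B)
  for (s in seq_len(B)) {
    tk <- tokens[[s]]
    L <- length(tk)
    is_pad <- tk == pad_id
    X <- params$emb[tk, , drop = FALSE] * sqrt(d) +
      positional_encoding(seq_len(L) - 1, d)
    if (L == 1L) X <- matrix(X, 1L, d)
    lcaches <- if (want_cache) vector("list", length(params$layers))
    for (l in seq_along(params$layers)) {
      p <- params$layers[[l]]
      Q <- sweep(X %*% p$Wq, 2, p$bq, "+")
      K <- sweep(X %*% p$Wk, 2, p$bk, "+")
      Vv <- sweep(X %*% p$Wv, 2, p$bv, "+")
      Ah <- vector("list", nh)
      Ocat <- matrix(0, L, d)
      for (hh in seq_len(nh)) {
        cols <- ((hh - 1) * dk + 1):(hh * dk)
        S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dk)
        if (any(is_pad)) S[, is_pad] <- S[, is_pad] - 1e9
        S <- S - apply(S, 1, max)
        A <- exp(S)
        A <- A / rowSums(A)
        Ah[[hh]] <- A
        Ocat[, cols] <- A %*% Vv[, cols, drop = FALSE]
      }
      O <- sweep(Ocat %*% p$Wo, 2, p$bo, "+")
      dm1 <- NULL
      if (training && dropout > 0) {
        dm1 <- matrix(rbinom(L * d, 1, 1 - dropout) / (1 - dropout), L, d)
        O <- O * dm1
      }
      ln1 <- ln_forward(X + O, p$g1, p$be1)
      X1 <- ln1$Y
      a1 <- sweep(X1 %*% p$W1, 2, p$b1, "+")
      z1 <- pmax(a1, 0)
      dmf <- NULL
      if (training && dropout > 0) {
        dmf <- matrix(rbinom(L * cfg$ff_dim, 1, 1 - dropout) / (1 - dropout),
                      L, cfg$ff_dim)
        z1 <- z1 * dmf
      }
      FF <- sweep(z1 %*% p$W2, 2, p$b2, "+")
      ln2 <- ln_forward(X1 + FF, p$g2, p$be2)
      if (want_cache) {
        lcaches[[l]] <- list(X = X, Q = Q, K = K, V = Vv, Ah = Ah,
                             Ocat = Ocat, ln1 = ln1, X1 = X1, a1 = a1,
                             z1 = z1, ln2 = ln2, dm1 = dm1, dmf = dmf)
      }
      X <- ln2$Y
    }
    last <- max(which(!is_pad))
    h[s, ] <- X[last, ]
    if (want_cache) {
      caches[[s]] <- list(tokens = tk, is_pad = is_pad, last = last,
                          layers = lcaches)
    }
  }
  list(h = h, cache = caches)
}

transformer_backward <- function(params, caches, dh, cfg) {
  d <- cfg$d
  nh <- cfg$heads
  dk <- d / nh
  grads <- tree_zeros(params)
  for (s in seq_along(caches)) {
    cc <- caches[[s]]
    L <- length(cc$tokens)
    dX <- matrix(0, L, d)
    dX[cc$last, ] <- dh[s, ]
    for (l in rev(seq_along(params$layers))) {
      p <- params$layers[[l]]
      lc <- cc$layers[[l]]
      g <- grads$layers[[l]]
      bn2 <- ln_backward(dX, lc$ln2, p$g2)
      g$g2 <- g$g2 + bn2$dg; g$be2 <- g$be2 + bn2$db
      dres2 <- bn2$dx               # grad at X1 + FF
      dz1 <- dres2 %*% t(p$W2)
      g$W2 <- g$W2 + crossprod(lc$z1, dres2)
      g$b2 <- g$b2 + colSums(dres2)
      if (!is.null(lc$dmf)) dz1 <- dz1 * lc$dmf
      da1 <- dz1 * (lc$a1 > 0)
      g$W1 <- g$W1 + crossprod(lc$X1, da1)
      g$b1 <- g$b1 + colSums(da1)
      dX1 <- dres2 + da1 %*% t(p$W1)
      bn1 <- ln_backward(dX1, lc$ln1, p$g1)
      g$g1 <- g$g1 + bn1$dg; g$be1 <- g$be1 + bn1$db
      dres1 <- bn1$dx               # grad at X + O
      dO <- dres1
      if (!is.null(lc$dm1)) dO <- dO * lc$dm1
      dOcat <- dO %*% t(p$Wo)
      g$Wo <- g$Wo + crossprod(lc$Ocat, dO)
      g$bo <- g$bo + colSums(dO)
      dQ <- matrix(0, L, d); dK <- matrix(0, L, d); dV <- matrix(0, L, d)
      for (hh in seq_len(nh)) {
        cols <- ((hh - 1) * dk + 1):(hh * dk)
        A <- lc$Ah[[hh]]
        dhead <- dOcat[, cols, drop = FALSE]
        dA <- tcrossprod(dhead, lc$V[, cols, drop = FALSE])
        dV[, cols] <- crossprod(A, dhead)
        dS <- A * (dA - rowSums(dA * A))
        dQ[, cols] <- dS %*% lc$K[, cols, drop = FALSE] / sqrt(dk)
        dK[, cols] <- crossprod(dS, lc$Q[, cols, drop = FALSE]) / sqrt(dk)
      }
      Xin <- lc$X
      g$Wq <- g$Wq + crossprod(Xin, dQ); g$bq <- g$bq + colSums(dQ)
      g$Wk <- g$Wk + crossprod(Xin, dK); g$bk <- g$bk + colSums(dK)
      g$Wv <- g$Wv + crossprod(Xin, dV); g$bv <- g$bv + colSums(dV)
      dX <- dres1 + dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
      grads$layers[[l]] <- g
    }
    # embedding rows (scaled by sqrt(d) in the forward pass)
    demb <- dX * sqrt(d)
    for (i in seq_len(L)) {
      grads$emb[cc$tokens[i], ] <- grads$emb[cc$tokens[i], ] + demb[i, ]
    }
  }
  grads
}

#' Tokenize a whole cohort for the transformer encoder
#'
#' @param cohort A `comet_cohort`.
#' @param vocab Code vocabulary (token ids 1..V in this order).
#' @param seed Within-day shuffle seed.
#' @param max_len Maximum sequence length.
#' @return An `encoded_cohort` carrying `tokens` instead of `X`.
#' @export
tokenize_cohort <- function(cohort, vocab, seed = 1, max_len = 1024) {
  recs <- cohort$records
  tokens <- lapply(seq_along(recs), function(i) {
    tokenize_record(recs[[i]], vocab, seed = derive_seed(seed, i),
                    max_len = max_len)
  })
  omics <- NULL
  if (any(vapply(recs, function(r) !is.null(r$omics), TRUE))) {
    omics <- do.call(rbind, lapply(recs, `[[`, "omics"))
    rownames(omics) <- names(recs)
  }
  structure(list(
    tokens = tokens, lengths = vapply(tokens, length, 0L), omics = omics,
    y = vapply(recs, function(r) as.numeric(r$outcome), 0),
    record_id = vapply(recs, `[[`, "", "record_id"),
    patient_id = vapply(recs, `[[`, "", "patient_id"),
    task = cohort$task
  ), class = "encoded_cohort")
}
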