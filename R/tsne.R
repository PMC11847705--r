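# Exact (dense) t-distributed stochastic neighbour embedding, used for the
# correlation-map and function-space views. Inputs there are at most a few
# hundred points, where the O(n^2) exact method is both fast and free of
# approximation noise; the embedding is fully determined by the seed.

tsne_embed <- function(X, perplexity = 30, seed = 1, n_iter = 400,
                       dims = 2) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stopf("tsne_embed: need at least 4 points")
  perplexity <- min(perplexity, floor((n - 1) / 3))
  perplexity <- max(perplexity, 2)
  D <- as.matrix(stats::dist(X))^2

  # per-point precision chosen by bisection to match the target entropy
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    Di <- D[i, -i]
    for (iter in 1:50) {
      p <- exp(-Di * beta)
      sp <- sum(p)
      if (sp == 0) { p <- rep(1 / length(Di), length(Di)); break }
      H <- log(sp) + beta * sum(Di * p) / sp
      p <- p / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  with_seed(seed, {
    Y <- matrix(rnorm(n * dims, sd = 1e-4), n, dims)
    gains <- matrix(1, n, dims)
    dY <- matrix(0, n, dims)
    momentum <- 0.5
    eta <- 100
    Pex <- P * 4  # early exaggeration
    for (it in seq_len(n_iter)) {
      if (it == 101) Pex <- P
      if (it == 21) momentum <- 0.8
      num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pex - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      dY <- momentum * dY - eta * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}
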