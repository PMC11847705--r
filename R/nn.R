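# Minimal neural-network kernel: GRU stack with backpropagation through
# time, parameter trees, Adam, and the two task losses. Everything is plain
# matrix algebra; batches are (B x T x D) arrays front-padded with zero rows,
# with per-sample lengths so padded steps leave the hidden state untouched.

# ---- parameter-tree helpers -------------------------------------------------

tree_map <- function(f, a) {
  if (is.list(a)) return(lapply(a, function(x) tree_map(f, x)))
  f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    return(mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE))
  }
  f(a, b)
}

tree_zeros <- function(a) tree_map(function(x) x * 0, a)

# uniform fan-in initialization, the standard scheme for recurrent stacks
init_mat <- function(nr, nc, fan_in) {
  matrix(runif(nr * nc, -1, 1) / sqrt(fan_in), nr, nc)
}
init_vec <- function(n, fan_in) runif(n, -1, 1) / sqrt(fan_in)

# ---- GRU --------------------------------------------------------------------

gru_init <- function(input_dim, hidden_dim, n_layers) {
  lapply(seq_len(n_layers), function(l) {
    d_in <- if (l == 1) input_dim else hidden_dim
    list(Wi = init_mat(d_in, 3 * hidden_dim, hidden_dim),
         Wh = init_mat(hidden_dim, 3 * hidden_dim, hidden_dim),
         bi = init_vec(3 * hidden_dim, hidden_dim),
         bh = init_vec(3 * hidden_dim, hidden_dim))
  })
}

# returns list(h = final hidden state of the top layer (B x H), cache)
gru_forward <- function(layers, X, lengths, dropout = 0, training = FALSE,
                        want_cache = FALSE) {
  B <- dim(X)[1]; Tn <- dim(X)[2]
  H <- ncol(layers[[1]]$Wh)
  H <- H / 3
  n_layers <- length(layers)
  # front padding: step t is real for sample i iff t > Tn - lengths[i]
  mask <- outer(lengths, seq_len(Tn), function(L, t) as.numeric(t > Tn - L))
  cache <- if (want_cache) {
    list(mask = mask, layers = vector("list", n_layers), drop_masks = NULL)
  }
  drop_masks <- vector("list", n_layers)
  input <- X  # B x T x D
  h_final <- NULL
  for (l in seq_len(n_layers)) {
    par <- layers[[l]]
    rs <- seq_len(H); zs <- H + rs; ns <- 2 * H + rs
    h <- matrix(0, B, H)
    out <- array(0, dim = c(B, Tn, H))
    steps <- if (want_cache) vector("list", Tn)
    for (t in seq_len(Tn)) {
      x <- matrix(input[, t, ], nrow = B)
      gi <- x %*% par$Wi
      gi <- sweep(gi, 2, par$bi, "+")
      gh <- h %*% par$Wh
      gh <- sweep(gh, 2, par$bh, "+")
      r <- logistic(gi[, rs, drop = FALSE] + gh[, rs, drop = FALSE])
      z <- logistic(gi[, zs, drop = FALSE] + gh[, zs, drop = FALSE])
      ghn <- gh[, ns, drop = FALSE]
      nn <- tanh(gi[, ns, drop = FALSE] + r * ghn)
      h_new <- (1 - z) * nn + z * h
      m <- mask[, t]
      h_next <- m * h_new + (1 - m) * h
      if (want_cache) {
        steps[[t]] <- list(x = x, h_prev = h, r = r, z = z, nn = nn, ghn = ghn)
      }
      h <- h_next
      out[, t, ] <- h
    }
    if (l < n_layers && dropout > 0 && training) {
      dm <- array(rbinom(B * Tn * H, 1, 1 - dropout) / (1 - dropout),
                  dim = c(B, Tn, H))
      out <- out * dm
      drop_masks[[l]] <- dm
    }
    if (want_cache) cache$layers[[l]] <- list(steps = steps, input = input)
    input <- out
    h_final <- h
  }
  if (want_cache) cache$drop_masks <- drop_masks
  list(h = h_final, cache = cache)
}

# dh_final: B x H gradient at the top layer's final hidden state
gru_backward <- function(layers, cache, dh_final) {
  n_layers <- length(layers)
  H <- ncol(layers[[1]]$Wh) / 3
  mask <- cache$mask
  B <- nrow(mask); Tn <- ncol(mask)
  rs <- seq_len(H); zs <- H + rs; ns <- 2 * H + rs
  grads <- vector("list", n_layers)
  # dOut[l]: gradient w.r.t. layer l's output at every step
  dOut <- NULL
  for (l in rev(seq_len(n_layers))) {
    par <- layers[[l]]
    lc <- cache$layers[[l]]
    dWi <- par$Wi * 0; dWh <- par$Wh * 0
    dbi <- par$bi * 0; dbh <- par$bh * 0
    d_in <- nrow(par$Wi)
    dX <- array(0, dim = c(B, Tn, d_in))
    dh <- if (l == n_layers) dh_final else matrix(0, B, H)
    for (t in rev(seq_len(Tn))) {
      if (!is.null(dOut)) dh <- dh + matrix(dOut[, t, ], nrow = B)
      st <- lc$steps[[t]]
      m <- mask[, t]
      dh_new <- dh * m
      dh_carry <- dh * (1 - m)
      dnn <- dh_new * (1 - st$z)
      dz <- dh_new * (st$h_prev - st$nn)
      da_n <- dnn * (1 - st$nn^2)
      dghn <- da_n * st$r
      dr <- da_n * st$ghn
      da_r <- dr * st$r * (1 - st$r)
      da_z <- dz * st$z * (1 - st$z)
      dgi <- cbind(da_r, da_z, da_n)
      dgh <- cbind(da_r, da_z, dghn)
      dWi <- dWi + crossprod(st$x, dgi)
      dWh <- dWh + crossprod(st$h_prev, dgh)
      dbi <- dbi + colSums(dgi)
      dbh <- dbh + colSums(dgh)
      dX[, t, ] <- dgi %*% t(par$Wi)
      dh <- dh_carry + dh_new * st$z + dgh %*% t(par$Wh)
    }
    grads[[l]] <- list(Wi = dWi, Wh = dWh, bi = dbi, bh = dbh)
    if (l > 1) {
      dOut <- dX
      dm <- cache$drop_masks[[l - 1]]
      if (!is.null(dm)) dOut <- dOut * dm
    }
  }
  grads
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_zeros(params), v = tree_zeros(params), t = 0)
}

adam_step <- function(params, grads, state, lr, frozen = character(),
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  tt <- state$t
  for (name in names(params)) {
    if (name %in% frozen) next
    g <- grads[[name]]
    if (is.null(g)) next
    state$m[[name]] <- tree_map2(function(m, gg) beta1 * m + (1 - beta1) * gg,
                                 state$m[[name]], g)
    state$v[[name]] <- tree_map2(function(v, gg) beta2 * v + (1 - beta2) * gg^2,
                                 state$v[[name]], g)
    mhat <- tree_map(function(m) m / (1 - beta1^tt), state$m[[name]])
    vhat <- tree_map(function(v) v / (1 - beta2^tt), state$v[[name]])
    params[[name]] <- tree_map2(function(p, upd) p - upd,
                                params[[name]],
                                tree_map2(function(m, v) lr * m / (sqrt(v) + eps),
                                          mhat, vhat))
  }
  list(params = params, state = state)
}

# ---- losses -----------------------------------------------------------------

#' Task losses
#'
#' Mean squared error for regression and binary cross-entropy for
#' classification: \deqn{MSE = \frac{1}{N}\sum (y - \hat y)^2,\quad
#' BCE = -\frac{1}{N}\sum \left(y \log \hat y + (1-y)\log(1-\hat y)\right).}
#' BCE predictions are clamped to \[1e-7, 1-1e-7\] to avoid `log(0)`.
#'
#' @param y_true,y_pred Equal-length numeric vectors; classification
#'   predictions must lie in \[0, 1\].
#' @param task `"continuous"` (MSE) or `"binary"` (BCE).
#' @return A non-negative scalar.
#' @export
task_loss <- function(y_true, y_pred, task = c("continuous", "binary")) {
  task <- match.arg(task)
  stopifnot(length(y_true) == length(y_pred))
  if (task == "continuous") {
    mean((y_true - y_pred)^2)
  } else {
    p <- clamp(y_pred, 1e-7, 1 - 1e-7)
    -mean(y_true * log(p) + (1 - y_true) * log(1 - p))
  }
}
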