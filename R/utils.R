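#' @useDynLib comet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom plogis qlogis sd var cor cor.test
#'   pt quantile uniroot optim
#' @importFrom utils read.csv read.delim write.csv head tail
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic package code funnels through this,
# so a user-level seed never perturbs (or is perturbed by) the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Derive a child seed from a base seed and a stream index; stays below 2^31.
derive_seed <- function(base_seed, index) {
  (as.double(base_seed) * 48271 + index * 16807) %% 2147483587 + 1
}

logistic <- function(x) 1 / (1 + exp(-x))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
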