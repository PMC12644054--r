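#' @importFrom stats fft rnorm runif rpois setNames sd predict
#' @importFrom rlang .data
#' @importFrom utils head tail
#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Numerically stable softmax
#'
#' @param x numeric vector of logits (may contain `-Inf` for masked entries).
#' @return vector of the same length summing to 1; if every entry is `-Inf`
#'   the result is all zeros (callers decide the fallback).
#' @keywords internal
softmax <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(rep(0, length(x)))
  e <- exp(x - m)
  e / sum(e)
}

#' Row-wise softmax of a matrix
#' @keywords internal
row_softmax <- function(x) {
  t(apply(x, 1L, softmax))
}

#' Layer normalization of a vector or matrix rows
#'
#' Standardizes each row to zero mean and unit variance (epsilon-stabilized),
#' then applies an affine gain/bias.
#' @keywords internal
layer_norm <- function(x, gain = 1, bias = 0, eps = 1e-6) {
  if (is.matrix(x)) {
    mu <- rowMeans(x)
    v <- rowMeans((x - mu)^2)
    sweep((x - mu) / sqrt(v + eps), 2L, rep_len(gain, ncol(x)), `*`) +
      matrix(rep_len(bias, ncol(x)), nrow(x), ncol(x), byrow = TRUE)
  } else {
    mu <- mean(x)
    v <- mean((x - mu)^2)
    gain * (x - mu) / sqrt(v + eps) + bias
  }
}

leaky_relu <- function(x, slope = 0.2) ifelse(x >= 0, x, slope * x)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Cosine similarity with a zero-vector convention
#'
#' Returns 0 when either argument has zero norm (degenerate fused states must
#' not poison downstream exponentials).
#' @keywords internal
cosine_sim <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

#' Seeded Gaussian matrix initializer (scaled by fan-in)
#' @keywords internal
init_mat <- function(nrow, ncol, scale = NULL) {
  if (is.null(scale)) scale <- 1 / sqrt(max(1, ncol))
  matrix(rnorm(nrow * ncol, sd = scale), nrow, ncol)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers never disturb the
#' caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Derive a child seed from a master seed and a stream label
#'
#' Keeps every source of randomness attached to one top-level seed while
#' giving independent streams to data generation, initialization and
#' shuffling. Result stays below 2^31.
#' @keywords internal
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sg <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_sg <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
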