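# Multi-level discrete wavelet transform (periodic), used both for the
# per-frame acoustic wavelet features and to seed the hierarchical temporal
# decomposition filters. Orthonormal filters, so the inverse is the adjoint.

wavelet_filters <- function(wavelet = c("db4", "haar")) {
  wavelet <- match.arg(wavelet)
  h <- switch(wavelet,
    haar = c(1, 1) / sqrt(2),
    # Daubechies filter with 4 vanishing moments (8 taps), orthonormal.
    db4 = c(0.23037781330885523, 0.71484657055254153, 0.63088076792959036,
            -0.02798376941698385, -0.18703481171888114, 0.03084138183598697,
            0.03288301166698295, -0.01059740178499728)
  )
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)   # quadrature mirror filter
  list(h = h, g = g, length = L, name = wavelet)
}

dwt_step <- function(x, filt) {
  n <- length(x)
  if (n %% 2L != 0L) stop_sg("dwt_step: length %d is not even", n)
  k <- seq.int(0L, n / 2L - 1L)
  a <- numeric(n / 2L); d <- numeric(n / 2L)
  for (j in seq_len(filt$length)) {
    idx <- (2L * k + (j - 1L)) %% n + 1L
    a <- a + filt$h[j] * x[idx]
    d <- d + filt$g[j] * x[idx]
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d, filt) {
  n <- 2L * length(a)
  x <- numeric(n)
  k <- seq.int(0L, length(a) - 1L)
  for (j in seq_len(filt$length)) {
    idx <- (2L * k + (j - 1L)) %% n + 1L
    x[idx] <- x[idx] + filt$h[j] * a + filt$g[j] * d
  }
  x
}

#' Multi-level periodic discrete wavelet transform
#'
#' Mallat pyramid with circular boundary handling. The signal length must be a
#' multiple of `2^levels` (frames are zero-padded upstream when needed).
#'
#' @param x numeric vector.
#' @param wavelet `"db4"` (default) or `"haar"`.
#' @param levels number of decomposition levels `J`.
#' @return list with `details` (list of length `levels`, finest first),
#'   `approx` (coarsest approximation), `wavelet`, `levels`.
#' @export
dwt <- function(x, wavelet = c("db4", "haar"), levels = 1L) {
  filt <- wavelet_filters(match.arg(wavelet))
  n <- length(x)
  if (n < 2^levels) {
    stop_sg("dwt: signal length %d too short for %d levels (need >= %d)",
            n, levels, 2^levels)
  }
  if (n %% 2^levels != 0L) {
    stop_sg("dwt: signal length %d must be a multiple of 2^levels = %d",
            n, 2^levels)
  }
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    st <- dwt_step(a, filt)
    details[[l]] <- st$d
    a <- st$a
  }
  structure(list(details = details, approx = a,
                 wavelet = filt$name, levels = levels),
            class = "sleepgraph_dwt")
}

#' Inverse multi-level periodic discrete wavelet transform
#'
#' Exact inverse of [dwt()] for orthonormal filters (perfect reconstruction).
#'
#' @param w a `sleepgraph_dwt` object.
#' @return the reconstructed numeric vector.
#' @export
idwt <- function(w) {
  filt <- wavelet_filters(w$wavelet)
  a <- w$approx
  for (l in rev(seq_len(w$levels))) {
    a <- idwt_step(a, w$details[[l]], filt)
  }
  a
}
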