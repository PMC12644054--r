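# Message passing over graph snapshots: multi-scale graph convolution on
# |dt|-banded adjacencies, temporal-aware graph attention with sinusoidal
# time encodings, and bidirectional cross-modal attention fusion.

#' Symmetric degree normalization of an adjacency matrix
#'
#' `A_hat = D^{-1/2} A D^{-1/2}`. Self-loops (`A + I`) are added by default so
#' isolated nodes keep unit degree; with `self_loops = FALSE` zero-degree
#' rows/columns are left at zero.
#'
#' @param A square nonnegative adjacency matrix.
#' @param self_loops add the identity before normalizing (default `TRUE`).
#' @return the normalized adjacency.
#' @export
normalize_adjacency <- function(A, self_loops = TRUE) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop_sg("A must be square")
  if (any(!is.finite(A)) || any(A < 0)) stop_sg("A must be finite and nonnegative")
  if (self_loops) A <- A + diag(nrow(A))
  d <- rowSums(A)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  A * outer(inv_sqrt, inv_sqrt)
}

#' Multi-scale graph convolution
#'
#' `H' = sigma(sum_s A_hat_s H W_s)` over `S` scale-specific normalized
#' adjacencies; with `S = 1` this is a standard graph convolution.
#'
#' @param H `n x d_in` node feature matrix.
#' @param A_hat_list list of `S` normalized adjacencies.
#' @param W_list list of `S` weight matrices `d_in x d_out`.
#' @param act activation (default LeakyReLU, slope 0.2).
#' @return `n x d_out` matrix.
#' @export
multiscale_graph_conv <- function(H, A_hat_list, W_list,
                                  act = function(x) leaky_relu(x, 0.2)) {
  if (length(A_hat_list) != length(W_list)) {
    stop_sg("scale count mismatch: %d adjacencies vs %d weight matrices",
            length(A_hat_list), length(W_list))
  }
  acc <- 0
  for (s in seq_along(A_hat_list)) {
    acc <- acc + A_hat_list[[s]] %*% H %*% W_list[[s]]
  }
  act(acc)
}

#' Sinusoidal temporal relationship encoding
#'
#' Interleaved `[sin(omega_m dt), cos(omega_m dt)]` over the frequency vector,
#' so the encoding has length `2 * length(omega)`.
#'
#' @param t_i,t_j timestamps in seconds.
#' @param omega strictly positive frequency vector.
#' @return numeric vector of length `2 * length(omega)`.
#' @export
temporal_encoding <- function(t_i, t_j, omega) {
  if (any(omega <= 0)) stop_sg("omega frequencies must be strictly positive")
  dt <- t_i - t_j
  as.numeric(rbind(sin(omega * dt), cos(omega * dt)))
}

#' Temporal-aware graph attention layer parameters
#'
#' @param d_in,d_out input and output feature dims.
#' @param n_heads attention heads (outputs concatenated, linearly mixed).
#' @param d_omega number of temporal-encoding frequencies (geometric ladder).
#' @param seed initializer seed.
#' @return parameter container of class `sleepgraph_gat`.
#' @export
temporal_gat <- function(d_in, d_out, n_heads = 2L, d_omega = 4L, seed = 1) {
  with_seed(seed, {
    heads <- lapply(seq_len(n_heads), function(m) {
      list(W = init_mat(d_in, d_out),
           a = rnorm(2L * d_out + 2L * d_omega, sd = 1 / sqrt(2 * d_out)))
    })
    structure(list(d_in = d_in, d_out = d_out, n_heads = n_heads,
                   omega = 1 / 10^(seq(0, 2, length.out = d_omega)),
                   heads = heads,
                   W_mix = init_mat(n_heads * d_out, d_out)),
              class = "sleepgraph_gat")
  })
}

#' Temporal-aware graph attention layer
#'
#' Per edge, the logit is
#' `LeakyReLU(a' [W h_i || W h_j || phi(t_i, t_j)])`; coefficients are a
#' softmax over `N_i` plus the mandatory self-loop, and the node update is
#' `sigma(sum_j alpha_ij W h_j)` per head, heads concatenated and mixed.
#'
#' @param H `n x d_in` node features.
#' @param edges directed edge tibble with node-index columns `i`, `j`
#'   (1-based row indices into `H`; self-loops are added internally).
#' @param timestamps per-node timestamps (seconds).
#' @param gat a [temporal_gat()].
#' @param act output activation (default LeakyReLU).
#' @return list with `H_out` (`n x d_out`) and `alpha` (tibble of directed
#'   coefficients including self-loops).
#' @export
temporal_gat_layer <- function(H, edges, timestamps, gat,
                               act = function(x) leaky_relu(x, 0.2)) {
  n <- nrow(H)
  src <- c(edges$i, seq_len(n))
  dst <- c(edges$j, seq_len(n))      # self-loops appended
  phi <- t(vapply(seq_along(src), function(e) {
    temporal_encoding(timestamps[src[e]], timestamps[dst[e]], gat$omega)
  }, numeric(2L * length(gat$omega))))
  head_outs <- list(); alpha_all <- NULL
  for (m in seq_len(gat$n_heads)) {
    hm <- gat$heads[[m]]
    Wh <- H %*% hm$W
    logits <- leaky_relu(
      cbind(Wh[src, , drop = FALSE], Wh[dst, , drop = FALSE], phi) %*% hm$a,
      0.2)
    if (any(!is.finite(logits))) stop_sg("nonfinite attention logits")
    alpha <- numeric(length(logits))
    for (i0 in unique(src)) {
      sel <- which(src == i0)
      alpha[sel] <- softmax(logits[sel])
    }
    msg <- matrix(0, n, gat$d_out)
    for (e in seq_along(src)) {
      msg[src[e], ] <- msg[src[e], ] + alpha[e] * Wh[dst[e], ]
    }
    head_outs[[m]] <- act(msg)
    if (m == 1L) alpha_all <- tibble::tibble(i = src, j = dst, alpha = alpha)
  }
  list(H_out = do.call(cbind, head_outs) %*% gat$W_mix, alpha = alpha_all)
}

#' Cross-modal fusion parameters
#'
#' @param dim shared hidden dimension of the pooled modality summaries.
#' @param d_k attention key dimension.
#' @param seed initializer seed.
#' @return parameter container of class `sleepgraph_fusion`.
#' @export
fusion_layer <- function(dim, d_k = max(4L, dim %/% 2L), seed = 1) {
  with_seed(seed, {
    structure(list(dim = dim, d_k = d_k,
                   W_Qf = init_mat(dim, d_k), W_Ka = init_mat(dim, d_k),
                   W_Va = init_mat(dim, dim),
                   W_Qa = init_mat(dim, d_k), W_Kf = init_mat(dim, d_k),
                   W_Vf = init_mat(dim, dim),
                   ln1 = list(gain = 1, bias = 0),
                   ln2 = list(gain = 1, bias = 0)),
              class = "sleepgraph_fusion")
  })
}

#' Bidirectional cross-modal attention fusion
#'
#' `Attn_{f->a} = softmax(Q_f K_a' / sqrt(d_k)) V_a` and symmetrically
#' `Attn_{a->f}`; the fused state is
#' `LayerNorm(h_f + Attn_{a->f}) + LayerNorm(h_a + Attn_{f->a})`. Inputs are
#' the per-window pooled modality summaries (equal row counts).
#'
#' @param h_f,h_a `n x dim` matrices (or length-`dim` vectors).
#' @param fus a [fusion_layer()].
#' @return list with `h_fused` (`n x dim`), and the two attention weight
#'   matrices `attn_fa`, `attn_af` (rows summing to 1).
#' @export
crossmodal_fuse <- function(h_f, h_a, fus) {
  if (!is.matrix(h_f)) h_f <- matrix(h_f, nrow = 1L)
  if (!is.matrix(h_a)) h_a <- matrix(h_a, nrow = 1L)
  if (ncol(h_f) != fus$dim || ncol(h_a) != fus$dim) {
    stop_sg("fusion dim mismatch: got %d/%d, expected %d",
            ncol(h_f), ncol(h_a), fus$dim)
  }
  if (nrow(h_f) != nrow(h_a)) {
    stop_sg("fusion expects equal row counts (pooled per window); got %d vs %d",
            nrow(h_f), nrow(h_a))
  }
  Qf <- h_f %*% fus$W_Qf; Ka <- h_a %*% fus$W_Ka; Va <- h_a %*% fus$W_Va
  Qa <- h_a %*% fus$W_Qa; Kf <- h_f %*% fus$W_Kf; Vf <- h_f %*% fus$W_Vf
  A_fa <- row_softmax(Qf %*% t(Ka) / sqrt(fus$d_k))
  A_af <- row_softmax(Qa %*% t(Kf) / sqrt(fus$d_k))
  attn_fa <- A_fa %*% Va   # facial queries attending to audio
  attn_af <- A_af %*% Vf
  h_fused <- layer_norm(h_f + attn_af, fus$ln1$gain, fus$ln1$bias) +
    layer_norm(h_a + attn_fa, fus$ln2$gain, fus$ln2$bias)
  list(h_fused = h_fused, attn_fa = A_fa, attn_af = A_af)
}
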