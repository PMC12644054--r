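# Sequence modeling over fused window representations. Every operator here is
# strictly causal: the output at window t never depends on inputs after t.

#' Graph-embedded GRU parameters
#'
#' @param d_in input (fused state) dimension.
#' @param dim hidden state dimension.
#' @param seed initializer seed.
#' @return parameter container of class `sleepgraph_gru`.
#' @export
graph_gru <- function(d_in, dim, seed = 1) {
  with_seed(seed, {
    structure(list(
      d_in = d_in, dim = dim,
      W_r = init_mat(dim, d_in), U_r = init_mat(dim, dim), b_r = numeric(dim),
      W_z = init_mat(dim, d_in), U_z = init_mat(dim, dim), b_z = numeric(dim),
      W_s = init_mat(dim, d_in), U_s = init_mat(dim, dim), b_s = numeric(dim)
    ), class = "sleepgraph_gru")
  })
}

#' One step of the graph-embedded GRU
#'
#' Reset gate `r = sigmoid(W_r h + U_r s + b_r)`, update gate
#' `z = sigmoid(W_z h + U_z s + b_z)`, candidate
#' `s~ = tanh(W_s h + U_s (r * s) + b_s)`, new state
#' `s' = (1 - z) * s + z * s~`.
#'
#' @param h_fused_t fused input vector (length `d_in`).
#' @param s_prev previous state (length `dim`; zeros at t = 1).
#' @param gru a [graph_gru()].
#' @return list with `s` (new state), `r`, `z`, `s_tilde`.
#' @export
graph_gru_step <- function(h_fused_t, s_prev, gru) {
  r <- sigmoid(as.numeric(gru$W_r %*% h_fused_t) +
               as.numeric(gru$U_r %*% s_prev) + gru$b_r)
  z <- sigmoid(as.numeric(gru$W_z %*% h_fused_t) +
               as.numeric(gru$U_z %*% s_prev) + gru$b_z)
  s_tilde <- tanh(as.numeric(gru$W_s %*% h_fused_t) +
                  as.numeric(gru$U_s %*% (r * s_prev)) + gru$b_s)
  s <- (1 - z) * s_prev + z * s_tilde
  if (any(!is.finite(s))) stop_sg("graph_gru_step: nonfinite state")
  list(s = s, r = r, z = z, s_tilde = s_tilde)
}

#' Run the graph GRU over a sequence
#'
#' @param H `T x d_in` matrix of fused states.
#' @param gru a [graph_gru()].
#' @param s0 initial state (default zeros).
#' @return `T x dim` matrix of states.
#' @export
graph_gru_sequence <- function(H, gru, s0 = numeric(gru$dim)) {
  out <- matrix(0, nrow(H), gru$dim)
  s <- s0
  for (t in seq_len(nrow(H))) {
    s <- graph_gru_step(H[t, ], s, gru)$s
    out[t, ] <- s
  }
  out
}

#' Hierarchical temporal decomposer
#'
#' Per level `l = 1..levels`, a bank of `K_l = 2` filters over the lookback
#' window `Delta_l = 2^l * base_lookback` states, initialized from the chosen
#' discrete wavelet's low-pass and high-pass taps dilated by `2^(l-1)`
#' (the high-pass bank therefore annihilates constant histories), combined by
#' the coefficients `alpha` and projected back to `dim`.
#'
#' @param dim state dimension.
#' @param levels number of decomposition levels `L` (default 3).
#' @param base_lookback lookback of level 1 in windows (default 2).
#' @param wavelet filter family for the taps (`"haar"` or `"db4"`).
#' @param seed projection initializer seed.
#' @return parameter container of class `sleepgraph_decomposer`.
#' @export
hierarchical_decomposer <- function(dim, levels = 3L, base_lookback = 2L,
                                    wavelet = "haar", seed = 1) {
  filt <- wavelet_filters(wavelet)
  lvls <- lapply(seq_len(levels), function(l) {
    delta <- 2^l * base_lookback
    taps <- delta + 1L                     # history s_{t-Delta_l : t}
    dil <- 2^(l - 1L)
    bank <- lapply(list(filt$h, filt$g), function(f) {
      w <- numeric(taps)
      pos <- 1L + (seq_along(f) - 1L) * dil
      pos <- pos[pos <= taps]
      w[pos] <- f[seq_along(pos)]
      rev(w)                               # most recent state gets the first tap
    })
    list(delta = delta, filters = bank, alpha = c(1, 1))
  })
  with_seed(seed, {
    structure(list(dim = dim, levels = levels, base_lookback = base_lookback,
                   wavelet = wavelet, level_cfg = lvls,
                   W_proj = init_mat(levels * dim, dim)),
              class = "sleepgraph_decomposer")
  })
}

#' Multi-scale decomposition of the state history at one time point
#'
#' Each level filters the trailing `Delta_l + 1` states with its wavelet-seeded
#' bank (history shorter than the lookback is left-padded with zeros and
#' flagged); level outputs are concatenated and projected to `dim`.
#'
#' @param history `t x dim` matrix of states up to and including the current
#'   window (the last row is the current state).
#' @param dec a [hierarchical_decomposer()].
#' @return list with `s_multi` (length `dim`), `per_level` (pre-projection
#'   level outputs), and `padded` (logical flag).
#' @export
hierarchical_decompose <- function(history, dec) {
  if (!is.matrix(history)) history <- matrix(history, ncol = dec$dim)
  t_now <- nrow(history)
  padded <- FALSE
  per_level <- vector("list", dec$levels)
  for (l in seq_len(dec$levels)) {
    cfg <- dec$level_cfg[[l]]
    taps <- cfg$delta + 1L
    if (t_now < taps) {
      padded <- TRUE
      slab <- rbind(matrix(0, taps - t_now, dec$dim), history)
    } else {
      slab <- history[(t_now - taps + 1L):t_now, , drop = FALSE]
    }
    bank <- lapply(cfg$filters, function(f) as.numeric(f %*% slab))
    lvl <- 0
    for (k in seq_along(bank)) lvl <- lvl + cfg$alpha[k] * bank[[k]]
    per_level[[l]] <- lvl
    attr(per_level[[l]], "bank") <- bank
  }
  s_multi <- as.numeric(matrix(unlist(lapply(per_level, as.numeric)),
                               nrow = 1L) %*% dec$W_proj)
  list(s_multi = s_multi, per_level = per_level, padded = padded)
}

#' Causal dilated convolution over a sequence
#'
#' `h_t = sum_{i=0}^{k-1} W_i s_{t - i d} + b`, with implicit left
#' zero-padding so the output has the input length; strictly causal.
#'
#' @param X `T x d_in` matrix (a vector is treated as `T x 1`).
#' @param weights list of `k` matrices `d_in x d_out` (scalars allowed for
#'   `d_in = d_out = 1`), `weights[[i + 1]]` multiplying `s_{t - i d}`.
#' @param dilation dilation factor `d >= 1`.
#' @param bias output bias (default 0).
#' @return `T x d_out` matrix.
#' @export
causal_conv <- function(X, weights, dilation = 1L, bias = 0) {
  if (dilation < 1L) stop_sg("dilation must be >= 1")
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  weights <- lapply(weights, function(w) if (is.matrix(w)) w else matrix(w, 1L, 1L))
  Tn <- nrow(X)
  d_out <- ncol(weights[[1]])
  out <- matrix(rep_len(bias, d_out), Tn, d_out, byrow = TRUE)
  for (i in seq_along(weights) - 1L) {
    shift <- i * dilation
    if (shift >= Tn) next
    rows <- (shift + 1L):Tn
    out[rows, ] <- out[rows, ] + X[rows - shift, , drop = FALSE] %*% weights[[i + 1L]]
  }
  out
}

#' Causal attention mask with bounded radius
#'
#' Additive mask: positions with `0 <= i - j <= R` receive the positional
#' offset `W_pos[i - j + 1]`; future keys (`j > i`) and keys beyond the radius
#' are masked to `-Inf`, which is what real-time monitoring requires: no
#' output may depend on information after its own time step.
#'
#' @param n sequence length.
#' @param R attention radius (`>= 1`).
#' @param W_pos positional offset table, length `>= R + 1`.
#' @return `n x n` mask matrix (query rows, key columns).
#' @export
causal_mask <- function(n, R, W_pos = numeric(R + 1)) {
  if (R < 1L) stop_sg("attention radius must be >= 1")
  if (length(W_pos) < R + 1L) stop_sg("W_pos must have length >= R + 1")
  lag <- outer(seq_len(n), seq_len(n), `-`)    # i - j
  M <- matrix(-Inf, n, n)
  ok <- lag >= 0 & lag <= R
  M[ok] <- W_pos[lag[ok] + 1L]
  M
}

#' Dilated causal self-attention
#'
#' Queries attend only to keys at `t' <= t` within radius `R`; in-radius
#' logits get the additive positional offset, masked logits are `-Inf` before
#' the softmax (a query always retains its self key).
#'
#' @param H `T x d` input sequence.
#' @param R attention radius.
#' @param W_pos positional offset table (length `>= R + 1`).
#' @param proj list with projection matrices `Q`, `K` (`d x d_k`) and `V`
#'   (`d x d_v`).
#' @return list with `out` (`T x d_v`) and `alpha` (`T x T` attention rows
#'   summing to 1).
#' @export
dilated_causal_attention <- function(H, R, W_pos, proj) {
  Q <- H %*% proj$Q; K <- H %*% proj$K; V <- H %*% proj$V
  logits <- Q %*% t(K) / sqrt(ncol(Q)) + causal_mask(nrow(H), R, W_pos)
  alpha <- row_softmax(logits)
  list(out = alpha %*% V, alpha = alpha)
}

#' Build the composed temporal stack
#'
#' Graph GRU -> hierarchical decomposition (residual) -> stack of dilated
#' causal convolutions (residual) -> dilated causal self-attention (residual).
#'
#' @param d_in fused-state input dimension.
#' @param dim hidden dimension used throughout the stack.
#' @param kernel causal convolution kernel size (default 3).
#' @param dilations dilation schedule (default `c(1, 2, 4, 8)`).
#' @param radius attention radius `R` (default 16).
#' @param pos_table positional table size (default 128).
#' @param levels hierarchical decomposition levels (default 3).
#' @param base_lookback level-1 lookback (default 2).
#' @param seed initializer seed.
#' @return parameter container of class `sleepgraph_temporal`.
#' @export
temporal_stack <- function(d_in, dim, kernel = 3L, dilations = c(1L, 2L, 4L, 8L),
                           radius = 16L, pos_table = 128L, levels = 3L,
                           base_lookback = 2L, seed = 1) {
  gru <- graph_gru(d_in, dim, derive_seed(seed, "gru"))
  dec <- hierarchical_decomposer(dim, levels, base_lookback,
                                 seed = derive_seed(seed, "decomp"))
  with_seed(derive_seed(seed, "temporal"), {
    convs <- lapply(seq_along(dilations), function(i) {
      list(weights = lapply(seq_len(kernel), function(k) init_mat(dim, dim)),
           bias = numeric(dim), dilation = dilations[i])
    })
    structure(list(d_in = d_in, dim = dim, gru = gru, dec = dec,
                   convs = convs, radius = radius,
                   W_pos = rnorm(pos_table, sd = 0.1),
                   attn_proj = list(Q = init_mat(dim, dim), K = init_mat(dim, dim),
                                    V = init_mat(dim, dim))),
              class = "sleepgraph_temporal")
  })
}

#' Run the composed temporal stack over a fused-state sequence
#'
#' @param H `T x d_in` matrix of fused window states.
#' @param stack a [temporal_stack()].
#' @return `T x dim` matrix of temporal outputs (strictly causal in `H`).
#' @export
temporal_forward <- function(H, stack) {
  S <- graph_gru_sequence(H, stack$gru)
  multi <- t(vapply(seq_len(nrow(S)), function(t) {
    hierarchical_decompose(S[seq_len(t), , drop = FALSE], stack$dec)$s_multi
  }, numeric(stack$dim)))
  X <- S + multi
  for (cv in stack$convs) {
    X <- X + leaky_relu(causal_conv(X, cv$weights, cv$dilation, cv$bias), 0.2)
  }
  att <- dilated_causal_attention(X, stack$radius,
                                  stack$W_pos[seq_len(stack$radius + 1L)],
                                  stack$attn_proj)
  X + att$out
}
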