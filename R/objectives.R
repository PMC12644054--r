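# The four-term training objective: weighted focal classification loss,
# similarity-gated temporal consistency, cross-modal InfoNCE contrastive
# alignment, and autoencoder-style reconstruction.

#' Inverse-frequency class weights
#'
#' `alpha_k` proportional to `1 / count_k`, normalized to mean 1 over the
#' classes present, so balanced data recovers uniform weights. Classes absent
#' from `labels` get the mean weight 1.
#'
#' @param labels integer labels in `0..K-1`.
#' @param K number of classes.
#' @return numeric vector of length `K`.
#' @export
inverse_freq_weights <- function(labels, K) {
  counts <- tabulate(labels + 1L, nbins = K)
  present <- counts > 0
  alpha <- rep(1, K)
  raw <- 1 / counts[present]
  alpha[present] <- raw / mean(raw)
  alpha
}

#' Weighted focal classification loss
#'
#' `-(1/T) sum_t alpha_y (1 - p_y)^gamma log p_y` over the predicted
#' probability of the true class; `gamma = 0` with uniform weights reduces to
#' mean cross-entropy. Probabilities are clamped at `1e-12` before the log.
#'
#' @param prob `T x K` matrix of predicted distributions (rows sum to 1).
#' @param labels integer true labels in `0..K-1`.
#' @param alpha class weights (length `K`, default uniform).
#' @param gamma focusing exponent (default 2).
#' @return nonnegative scalar.
#' @export
focal_loss <- function(prob, labels, alpha = rep(1, ncol(prob)), gamma = 2) {
  if (gamma < 0) stop_sg("gamma must be >= 0")
  p <- prob[cbind(seq_len(nrow(prob)), labels + 1L)]
  if (any(p < 1e-12)) {
    warn_sg("focal_loss: true-class probability clamped at 1e-12")
    p <- pmax(p, 1e-12)
  }
  a <- alpha[labels + 1L]
  mean(-a * (1 - p)^gamma * log(p))
}

# gradient of the focal loss w.r.t. the softmax logits (T x K)
focal_grad_logits <- function(prob, labels, alpha, gamma) {
  Tn <- nrow(prob); K <- ncol(prob)
  iy <- cbind(seq_len(Tn), labels + 1L)
  p <- pmax(prob[iy], 1e-12)
  a <- alpha[labels + 1L]
  # dL/dp_y for each row
  dLdp <- a * (gamma * (1 - p)^pmax(gamma - 1, 0) * log(p) - (1 - p)^gamma / p)
  if (gamma == 0) dLdp <- -a / p
  G <- matrix(0, Tn, K)
  onehot <- matrix(0, Tn, K); onehot[iy] <- 1
  G <- (dLdp * p / Tn) * (onehot - prob)
  G
}

#' Temporal consistency loss
#'
#' `(1/(T-1)) sum_t omega_t ||p_{t+1} - p_t||^2` with
#' `omega_t = exp(-beta * cos_sim(h_{t+1}, h_t))`: transitions are penalized
#' unless the fused representations themselves changed. A zero-norm fused
#' vector contributes similarity 0.
#'
#' @param prob `T x K` predicted distributions (`T >= 2`).
#' @param h_fused `T x d` fused states aligned with `prob`.
#' @param beta similarity sharpness (default 0.5).
#' @return nonnegative scalar.
#' @export
temporal_consistency_loss <- function(prob, h_fused, beta = 0.5) {
  Tn <- nrow(prob)
  if (Tn < 2L) stop_sg("temporal_consistency_loss: need T >= 2")
  w <- consistency_weights(h_fused, beta)
  dp <- prob[-1L, , drop = FALSE] - prob[-Tn, , drop = FALSE]
  mean(w * rowSums(dp^2))
}

consistency_weights <- function(h_fused, beta) {
  Tn <- nrow(h_fused)
  sims <- vapply(seq_len(Tn - 1L), function(t) {
    cosine_sim(h_fused[t + 1L, ], h_fused[t, ])
  }, numeric(1))
  exp(-beta * sims)
}

# gradient of the temporal consistency loss w.r.t. the logits
temporal_grad_logits <- function(prob, h_fused, beta) {
  Tn <- nrow(prob)
  w <- consistency_weights(h_fused, beta)
  Gp <- matrix(0, Tn, ncol(prob))
  for (t in seq_len(Tn)) {
    g <- 0
    if (t > 1L) g <- g + 2 * w[t - 1L] * (prob[t, ] - prob[t - 1L, ])
    if (t < Tn) g <- g + 2 * w[t] * (prob[t, ] - prob[t + 1L, ])
    Gp[t, ] <- g / (Tn - 1L)
  }
  # through softmax: dL/dl = p * (g - sum(g * p))
  prob * (Gp - rowSums(Gp * prob))
}

#' Cross-modal contrastive loss (InfoNCE over same-label pairs)
#'
#' For every facial/audio pair with matching labels,
#' `-log( exp(sim_ij / tau) / sum_k exp(sim_ik / tau) )` with cosine
#' similarity; the denominator runs over every audio embedding in the batch
#' (the positive included, self-pairs counted as positives when labels match).
#'
#' @param h_f `n x d` facial embeddings.
#' @param h_a `n x d` audio embeddings.
#' @param labels integer labels (length `n`).
#' @param tau temperature (> 0, default 0.1).
#' @param reduce `"sum"` (the unreduced pair sum, default) or `"mean"` over
#'   positive pairs (used by the training objective for batch-size
#'   stability).
#' @return nonnegative scalar; 0 with a warning when no positive pair exists.
#' @export
contrastive_loss <- function(h_f, h_a, labels, tau = 0.1,
                             reduce = c("sum", "mean")) {
  reduce <- match.arg(reduce)
  if (tau <= 0) stop_sg("tau must be > 0")
  S <- cosine_sim_matrix(h_f, h_a)
  pos <- outer(labels, labels, `==`)
  if (!any(pos)) {
    warn_sg("contrastive_loss: no positive pair in batch; returning 0")
    return(0)
  }
  logZ <- apply(S / tau, 1L, function(r) {
    m <- max(r); m + log(sum(exp(r - m)))
  })
  per_pair <- -(S / tau - logZ)          # n x n matrix of pair losses
  tot <- sum(per_pair[pos])
  if (reduce == "mean") tot / sum(pos) else tot
}

cosine_sim_matrix <- function(U, V) {
  nu <- sqrt(rowSums(U^2)); nv <- sqrt(rowSums(V^2))
  nu[nu == 0] <- Inf; nv[nv == 0] <- Inf   # zero vectors -> similarity 0
  (U %*% t(V)) / outer(nu, nv)
}

#' Reconstruction loss
#'
#' `sum_t ||f_t - Dec_f(h_fused_t)||^2 + ||a_t - Dec_a(h_fused_t)||^2` for
#' lightweight decoder networks mapping the fused state back to each
#' modality's features.
#'
#' @param f `T x d_f` facial features.
#' @param a `T x d_a` audio features.
#' @param h_fused `T x d` fused states.
#' @param decoders list with elements `f` and `a`, each a [mlp_decoder()].
#' @param reduce `"sum"` (default) or `"mean"` over windows.
#' @return nonnegative scalar.
#' @export
reconstruction_loss <- function(f, a, h_fused, decoders,
                                reduce = c("sum", "mean")) {
  reduce <- match.arg(reduce)
  rf <- mlp_forward(decoders$f, h_fused)$out
  ra <- mlp_forward(decoders$a, h_fused)$out
  if (ncol(rf) != ncol(f) || ncol(ra) != ncol(a)) {
    stop_sg("decoder output dims (%d, %d) do not match feature dims (%d, %d)",
            ncol(rf), ncol(ra), ncol(f), ncol(a))
  }
  per_t <- rowSums((f - rf)^2) + rowSums((a - ra)^2)
  if (reduce == "mean") mean(per_t) else sum(per_t)
}

#' Weighted total loss
#'
#' `w_cls L_cls + w_temp L_temp + w_cont L_cont + w_rec L_rec` with the
#' default weights `1.0, 0.3, 0.2, 0.1`.
#'
#' @param components named list/vector with `cls`, `temp`, `cont`, `rec`.
#' @param weights named list/vector with `cls`, `temp`, `cont`, `rec`.
#' @return scalar total.
#' @export
total_loss <- function(components,
                       weights = c(cls = 1.0, temp = 0.3, cont = 0.2, rec = 0.1)) {
  components <- unlist(components)[c("cls", "temp", "cont", "rec")]
  weights <- unlist(weights)[c("cls", "temp", "cont", "rec")]
  if (any(weights < 0)) stop_sg("loss term weights must be nonnegative")
  if (any(!is.finite(components))) stop_sg("loss components must be finite")
  sum(weights * components)
}

# ---- single-hidden-layer perceptrons (heads and decoders) ----

#' Single-hidden-layer perceptron
#'
#' tanh hidden layer, linear output; used for the classification head and the
#' modality decoders.
#'
#' @param d_in,d_hidden,d_out layer sizes.
#' @param seed initializer seed.
#' @return parameter container of class `sleepgraph_mlp`.
#' @export
mlp_decoder <- function(d_in, d_hidden, d_out, seed = 1) {
  with_seed(seed, {
    structure(list(W1 = init_mat(d_hidden, d_in), b1 = numeric(d_hidden),
                   W2 = init_mat(d_out, d_hidden), b2 = numeric(d_out),
                   d_in = d_in, d_hidden = d_hidden, d_out = d_out),
              class = "sleepgraph_mlp")
  })
}

mlp_forward <- function(mlp, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  Z1 <- sweep(X %*% t(mlp$W1), 2L, mlp$b1, `+`)
  A1 <- tanh(Z1)
  out <- sweep(A1 %*% t(mlp$W2), 2L, mlp$b2, `+`)
  list(out = out, A1 = A1, X = X)
}

# backprop through the MLP given dL/dout; returns gradients and dL/dX
mlp_backward <- function(mlp, fwd, G_out) {
  gW2 <- t(G_out) %*% fwd$A1
  gb2 <- colSums(G_out)
  G_A1 <- G_out %*% mlp$W2
  G_Z1 <- G_A1 * (1 - fwd$A1^2)
  gW1 <- t(G_Z1) %*% fwd$X
  gb1 <- colSums(G_Z1)
  G_X <- G_Z1 %*% mlp$W1
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, G_X = G_X)
}
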