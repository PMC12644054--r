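# Brute-force oracles kept deliberately independent of the package internals:
# direct summations and loops only.

dft_direct <- function(x) {
  n <- length(x)
  vapply(seq_len(n) - 1L, function(k) {
    sum(x * exp(-2i * pi * k * (seq_len(n) - 1L) / n))
  }, complex(1))
}

graph_conv_loop <- function(A_hat_list, H, W_list, act = function(x) ifelse(x >= 0, x, 0.2 * x)) {
  n <- nrow(H)
  d_out <- ncol(W_list[[1]])
  out <- matrix(0, n, d_out)
  for (s in seq_along(A_hat_list)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (A_hat_list[[s]][i, j] != 0) {
          out[i, ] <- out[i, ] + A_hat_list[[s]][i, j] * as.numeric(H[j, ] %*% W_list[[s]])
        }
      }
    }
  }
  act(out)
}

softmax_loop <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

cross_entropy_oracle <- function(prob, labels) {
  # mean negative log-likelihood, labels 1-based
  -mean(log(prob[cbind(seq_len(nrow(prob)), labels)]))
}

auc_pair_count <- function(scores, truth) {
  # Mann-Whitney: P(score_pos > score_neg) + 0.5 P(equal)
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

confusion_oracle <- function(y, yhat, classes) {
  res <- list()
  for (k in classes) {
    tp <- sum(y == k & yhat == k)
    fp <- sum(y != k & yhat == k)
    fn <- sum(y == k & yhat != k)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    res[[as.character(k)]] <- c(precision = prec, recall = rec, f1 = f1)
  }
  present <- classes[vapply(classes, function(k) any(y == k) || any(yhat == k), logical(1))]
  list(accuracy = mean(y == yhat),
       per_class = res,
       macro_f1 = mean(vapply(as.character(present), function(k) res[[k]]["f1"], numeric(1))))
}

num_grad <- function(f, x, eps = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
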