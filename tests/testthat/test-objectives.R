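test_that("focal loss matches hand values and reduces to cross-entropy at gamma 0", {
  perfect <- matrix(c(1, 0, 0, 1), 2, 2, byrow = FALSE)
  expect_equal(focal_loss(rbind(c(1, 0), c(0, 1)), c(0, 1)), 0)
  expect_equal(focal_loss(matrix(c(0.5, 0.5), 1), labels = 0, gamma = 2),
               0.25 * log(2), tolerance = 1e-10)
  set.seed(51)
  for (trial in 1:100) {
    K <- sample(2:5, 1); Tn <- sample(3:10, 1)
    prob <- matrix(rexp(Tn * K), Tn, K); prob <- prob / rowSums(prob)
    y <- sample(0:(K - 1), Tn, replace = TRUE)
    expect_equal(focal_loss(prob, y, gamma = 0),
                 cross_entropy_oracle(prob, y + 1L), tolerance = 1e-10)
  }
  expect_warning(focal_loss(rbind(c(0, 1)), 0), "clamped")
})

test_that("inverse-frequency weights normalize to mean 1 and recover uniform on balance", {
  expect_equal(inverse_freq_weights(c(0, 0, 1, 1, 2, 2), 3), rep(1, 3))
  w <- inverse_freq_weights(c(rep(0, 8), 1, 2), 3)
  expect_equal(mean(w), 1)
  expect_gt(w[2], w[1])
  expect_equal(w[2], w[3])
})

test_that("temporal consistency loss gates transitions by fused-state similarity", {
  prob_const <- matrix(0.25, 5, 4)
  h <- matrix(rnorm(20), 5, 4)
  expect_equal(temporal_consistency_loss(prob_const, h), 0)
  # T = 2 hand value: identical fused states, beta 0.5 -> exp(-0.5) * 2
  p <- rbind(c(1, 0), c(0, 1))
  hf <- rbind(c(1, 2), c(1, 2))
  expect_equal(temporal_consistency_loss(p, hf, beta = 0.5),
               exp(-0.5) * 2, tolerance = 1e-10)
  # invariant to a fixed class relabeling
  perm <- c(2, 1)
  expect_equal(temporal_consistency_loss(p[, perm], hf, 0.5),
               temporal_consistency_loss(p, hf, 0.5))
  # monotone nonincreasing in similarity for fixed predictions (beta > 0)
  aligned <- rbind(c(1, 0), c(1, 0) * 0.9 + 0.05)
  sim_hi <- rbind(c(1, 1), c(1, 1))
  sim_lo <- rbind(c(1, 1), c(-1, -1))
  expect_lt(temporal_consistency_loss(p, sim_hi, 0.5),
            temporal_consistency_loss(p, sim_lo, 0.5))
  # zero-norm fused vectors use similarity 0
  h0 <- rbind(c(0, 0), c(1, 1))
  expect_equal(temporal_consistency_loss(p, h0, 0.5), exp(0) * 2)
  expect_error(temporal_consistency_loss(p[1, , drop = FALSE], hf), "T >= 2")
})

test_that("contrastive loss matches hand-evaluated InfoNCE sums", {
  h_f <- rbind(c(1, 0), c(0, 1))
  h_a <- rbind(c(1, 0), c(-1, 0))
  # positives (1,1) sim 1 vs negative sim -1, and (2,2) sims (0, 0)
  expected <- -log(exp(1) / (exp(1) + exp(-1))) - log(0.5)
  expect_equal(contrastive_loss(h_f, h_a, c(0, 1), tau = 1), expected,
               tolerance = 1e-10)
  # all-identical embeddings: log(n) per pair
  n <- 4
  hs <- matrix(rep(c(1, 2), each = n), n, 2)
  expect_equal(contrastive_loss(hs, hs, rep(0, n), tau = 0.5, reduce = "mean"),
               log(n), tolerance = 1e-10)
  # sharpening: smaller tau strictly decreases the loss when every positive
  # holds the top similarity in its row
  la <- contrastive_loss(h_f, h_a, c(0, 1), tau = 1)
  lb <- contrastive_loss(h_f, h_a, c(0, 1), tau = 0.2)
  expect_lt(lb, la)
  expect_error(contrastive_loss(h_f, h_a, c(0, 1), tau = 0), "tau")
  # self-pairs always count as positives, so only an empty batch lacks one
  expect_warning(out <- contrastive_loss(h_f[0, , drop = FALSE],
                                         h_a[0, , drop = FALSE],
                                         labels = integer(0), tau = 1),
                 "no positive")
  expect_equal(out, 0)
})

test_that("reconstruction loss is zero for perfect decoders and plug-in for zero ones", {
  d <- 4
  h <- matrix(rnorm(3 * d), 3, d)
  f <- matrix(rep(c(1, -1, 2), each = 3), 3, 3)[, c(1, 1, 1)] * 0 + 0.7
  a <- matrix(-0.3, 3, 2)
  dec_f <- mlp_decoder(d, 5, 3, seed = 1)
  dec_a <- mlp_decoder(d, 5, 2, seed = 2)
  # perfect: zero hidden path, bias equal to the constant targets
  dec_f$W1[] <- 0; dec_f$W2[] <- 0; dec_f$b2 <- rep(0.7, 3)
  dec_a$W1[] <- 0; dec_a$W2[] <- 0; dec_a$b2 <- rep(-0.3, 2)
  expect_equal(reconstruction_loss(f, a, h, list(f = dec_f, a = dec_a)), 0)
  # zero decoders: sum of squared feature norms
  dec_f$b2[] <- 0; dec_a$b2[] <- 0
  expect_equal(reconstruction_loss(f, a, h, list(f = dec_f, a = dec_a)),
               sum(f^2) + sum(a^2), tolerance = 1e-10)
  set.seed(52)
  fr <- matrix(rnorm(9), 3, 3); ar <- matrix(rnorm(6), 3, 2)
  expect_gte(reconstruction_loss(fr, ar, h, list(f = dec_f, a = dec_a)), 0)
  dec_bad <- mlp_decoder(d, 5, 4, seed = 3)
  expect_error(reconstruction_loss(fr, ar, h, list(f = dec_bad, a = dec_a)),
               "decoder output dims")
})

test_that("the weighted total combines terms with the configured defaults", {
  expect_equal(total_loss(list(cls = 1, temp = 1, cont = 1, rec = 1)), 1.6)
  expect_equal(total_loss(list(cls = 0, temp = 0, cont = 0, rec = 0)), 0)
  expect_error(total_loss(list(cls = 1, temp = 1, cont = 1, rec = 1),
                          c(cls = -1, temp = 0.3, cont = 0.2, rec = 0.1)),
               "nonnegative")
})

test_that("analytic loss gradients match numerical differentiation", {
  set.seed(53)
  Tn <- 6; K <- 3
  logits <- matrix(rnorm(Tn * K), Tn, K)
  y <- sample(0:(K - 1), Tn, replace = TRUE)
  alpha <- inverse_freq_weights(y, K)
  h <- matrix(rnorm(Tn * 4), Tn, 4)

  soft_rows <- function(L) t(apply(L, 1, softmax_loop))
  f_focal <- function(v) {
    focal_loss(soft_rows(matrix(v, Tn, K)), y, alpha, gamma = 2)
  }
  g_num <- num_grad(f_focal, as.numeric(logits))
  g_ana <- sleepgraph:::focal_grad_logits(soft_rows(logits), y, alpha, 2)
  expect_equal(as.numeric(g_ana), g_num, tolerance = 1e-6)

  f_temp <- function(v) {
    temporal_consistency_loss(soft_rows(matrix(v, Tn, K)), h, beta = 0.5)
  }
  g_num2 <- num_grad(f_temp, as.numeric(logits))
  g_ana2 <- sleepgraph:::temporal_grad_logits(soft_rows(logits), h, 0.5)
  expect_equal(as.numeric(g_ana2), g_num2, tolerance = 1e-6)

  # MLP backward pass against numerical gradients
  mlp <- mlp_decoder(4, 5, 3, seed = 6)
  X <- matrix(rnorm(8), 2, 4)
  Yt <- matrix(rnorm(6), 2, 3)
  loss_mlp <- function(theta) {
    m <- mlp
    m$W1 <- matrix(theta[1:20], 5, 4)
    m$b1 <- theta[21:25]
    m$W2 <- matrix(theta[26:40], 3, 5)
    m$b2 <- theta[41:43]
    sum((sleepgraph:::mlp_forward(m, X)$out - Yt)^2)
  }
  theta0 <- c(as.numeric(mlp$W1), mlp$b1, as.numeric(mlp$W2), mlp$b2)
  fwd <- sleepgraph:::mlp_forward(mlp, X)
  bk <- sleepgraph:::mlp_backward(mlp, fwd, 2 * (fwd$out - Yt))
  g_ana3 <- c(as.numeric(bk$W1), bk$b1, as.numeric(bk$W2), bk$b2)
  expect_equal(g_ana3, num_grad(loss_mlp, theta0), tolerance = 1e-6)
})
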