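test_that("adjacency normalization matches hand computations", {
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(normalize_adjacency(A, self_loops = FALSE), A)
  A2 <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_equal(normalize_adjacency(A2, self_loops = FALSE),
               matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(normalize_adjacency(diag(3) * 0, self_loops = TRUE), diag(3))
  # symmetric input stays symmetric; spectral radius <= 1 with self-loops
  set.seed(31)
  S <- abs(matrix(rnorm(25), 5, 5)); S <- S + t(S)
  An <- normalize_adjacency(S)
  expect_equal(An, t(An))
  expect_lte(max(abs(eigen(An, only.values = TRUE)$values)), 1 + 1e-10)
  expect_error(normalize_adjacency(matrix(-1, 2, 2)), "nonnegative")
})

test_that("multi-scale graph convolution matches a brute-force loop oracle", {
  set.seed(32)
  n <- 5; d_in <- 3; d_out <- 4; S <- 3
  A_list <- lapply(1:S, function(s) {
    A <- matrix(runif(n * n) < 0.5, n, n) * abs(matrix(rnorm(n * n), n, n))
    normalize_adjacency(A + t(A))
  })
  W_list <- lapply(1:S, function(s) matrix(rnorm(d_in * d_out), d_in, d_out))
  H <- matrix(rnorm(n * d_in), n, d_in)
  got <- multiscale_graph_conv(H, A_list, W_list)
  expect_equal(got, graph_conv_loop(A_list, H, W_list), tolerance = 1e-10)
  # degenerate cases
  W0 <- lapply(W_list, function(w) w * 0)
  expect_equal(multiscale_graph_conv(H, A_list, W0), matrix(0, n, d_out))
  expect_equal(multiscale_graph_conv(H, list(diag(n)), list(diag(d_in)),
                                     act = identity), H)
  expect_error(multiscale_graph_conv(H, A_list, W_list[1:2]), "scale count")
})

test_that("temporal encoding interleaves sines and cosines with correct parity", {
  omega <- c(1, 0.5, 0.1)
  expect_equal(temporal_encoding(3, 3, omega), rep(c(0, 1), 3))
  expect_equal(temporal_encoding(pi / 2, 0, 1), c(1, 0), tolerance = 1e-12)
  enc_p <- temporal_encoding(2.3, 0, omega)
  enc_m <- temporal_encoding(0, 2.3, omega)
  idx_sin <- seq(1, 6, 2); idx_cos <- seq(2, 6, 2)
  expect_equal(enc_p[idx_sin], -enc_m[idx_sin])
  expect_equal(enc_p[idx_cos], enc_m[idx_cos])
  expect_error(temporal_encoding(1, 0, c(1, -1)), "strictly positive")
})

test_that("temporal GAT coefficients match a brute-force softmax oracle", {
  set.seed(33)
  n <- 4; d <- 3
  H <- matrix(rnorm(n * d), n, d)
  ts <- c(0, 15, 30, 45)
  edges <- tibble::tibble(i = c(1, 2, 2, 3, 4), j = c(2, 1, 3, 2, 3))
  gat <- temporal_gat(d, d, n_heads = 1, d_omega = 2, seed = 8)
  res <- temporal_gat_layer(H, edges, ts, gat)

  # loop oracle for head 1
  hm <- gat$heads[[1]]
  Wh <- H %*% hm$W
  lrelu <- function(x) ifelse(x >= 0, x, 0.2 * x)
  for (i in 1:n) {
    nb <- c(edges$j[edges$i == i], i)
    logits <- vapply(nb, function(j) {
      phi <- as.numeric(rbind(sin(gat$omega * (ts[i] - ts[j])),
                              cos(gat$omega * (ts[i] - ts[j]))))
      lrelu(sum(hm$a * c(Wh[i, ], Wh[j, ], phi)))
    }, numeric(1))
    a_or <- exp(logits - max(logits)); a_or <- a_or / sum(a_or)
    got <- res$alpha$alpha[res$alpha$i == i]
    expect_equal(sort(got), sort(a_or), tolerance = 1e-10)
    expect_equal(sum(got), 1, tolerance = 1e-6)
  }
})

test_that("an isolated node attends only to itself and symmetry yields equal weights", {
  d <- 3
  H <- matrix(rnorm(3 * d), 3, d)
  ts <- c(0, 0, 0)
  gat <- temporal_gat(d, d, n_heads = 1, seed = 9)
  gat$W_mix <- diag(d)
  # node 3 isolated
  edges <- tibble::tibble(i = c(1, 2), j = c(2, 1))
  res <- temporal_gat_layer(H, edges, ts, gat)
  a3 <- res$alpha[res$alpha$i == 3, ]
  expect_equal(a3$alpha, 1)
  expect_equal(res$H_out[3, ],
               as.numeric(leaky_relu(H[3, ] %*% gat$heads[[1]]$W, 0.2)),
               tolerance = 1e-12)
  # identical neighbors at identical timestamps get equal attention
  H2 <- rbind(H[1, ], H[2, ], H[2, ])
  edges2 <- tibble::tibble(i = c(1, 1), j = c(2, 3))
  res2 <- temporal_gat_layer(H2, edges2, ts, gat)
  a1 <- res2$alpha$alpha[res2$alpha$i == 1 & res2$alpha$j != 1]
  expect_equal(a1[1], a1[2], tolerance = 1e-12)
})

test_that("graph layers are permutation equivariant", {
  set.seed(34)
  n <- 6; d <- 4
  H <- matrix(rnorm(n * d), n, d)
  ts <- seq(0, 75, 15)
  A <- abs(matrix(rnorm(n * n), n, n)); A <- A + t(A)
  An <- normalize_adjacency(A)
  W <- list(matrix(rnorm(d * d), d, d))
  perm <- sample(n)
  P <- diag(n)[perm, ]
  out1 <- multiscale_graph_conv(H, list(An), W)
  out2 <- multiscale_graph_conv(H[perm, ], list(normalize_adjacency(A[perm, perm])), W)
  expect_equal(out2, out1[perm, ], tolerance = 1e-10)

  gat <- temporal_gat(d, d, n_heads = 2, seed = 10)
  edges <- tibble::tibble(i = c(1, 2, 3, 5), j = c(2, 3, 4, 6))
  inv <- order(perm)
  edges_p <- tibble::tibble(i = inv[edges$i], j = inv[edges$j])
  g1 <- temporal_gat_layer(H, edges, ts, gat)$H_out
  g2 <- temporal_gat_layer(H[perm, ], edges_p, ts[perm], gat)$H_out
  expect_equal(g2, g1[perm, ], tolerance = 1e-10)
})

test_that("cross-modal fusion reduces to summed layer norms when values vanish", {
  set.seed(35)
  d <- 6
  fus <- fusion_layer(d, seed = 11)
  h_f <- matrix(rnorm(2 * d), 2, d)
  h_a <- matrix(rnorm(2 * d), 2, d)
  fus0 <- fus; fus0$W_Va[] <- 0; fus0$W_Vf[] <- 0
  got <- crossmodal_fuse(h_f, h_a, fus0)
  expect_equal(got$h_fused,
               layer_norm(h_f) + layer_norm(h_a), tolerance = 1e-10)
  res <- crossmodal_fuse(h_f, h_a, fus)
  expect_equal(rowSums(res$attn_fa), c(1, 1), tolerance = 1e-6)
  expect_equal(rowSums(res$attn_af), c(1, 1), tolerance = 1e-6)
  expect_equal(dim(res$h_fused), c(2, d))
  expect_error(crossmodal_fuse(h_f, matrix(0, 2, 3), fus), "dim mismatch")
})

test_that("a four-layer scaled stack composes without shape errors", {
  dims <- c(32, 24, 16, 8)
  set.seed(36)
  n <- 10
  H <- matrix(rnorm(n * dims[1]), n, dims[1])
  ts <- seq(0, by = 15, length.out = n)
  A <- normalize_adjacency(abs(matrix(rnorm(n * n), n, n)))
  edges <- tibble::tibble(i = rep(1:(n - 1)), j = 2:n)
  X <- H
  for (l in seq_len(3)) {
    if (l %% 2 == 1) {
      W <- list(matrix(rnorm(ncol(X) * dims[l + 1]), ncol(X), dims[l + 1]))
      X <- multiscale_graph_conv(X, list(A), W)
    } else {
      gat <- temporal_gat(ncol(X), dims[l + 1], n_heads = 2, seed = l)
      X <- temporal_gat_layer(X, edges, ts, gat)$H_out
    }
  }
  expect_equal(ncol(X), 8)
  expect_true(all(is.finite(X)))
})
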