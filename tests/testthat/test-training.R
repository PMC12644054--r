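test_that("the cosine warm-restart schedule hits its endpoints exactly", {
  expect_identical(lr_schedule(0, 20), 1e-3)
  expect_identical(lr_schedule(20, 20), 1e-6)
  expect_equal(lr_schedule(10, 20), (1e-6 + 1e-3) / 2)
  # continuity on a fine grid and monotone decay within a cycle
  g <- vapply(seq(0, 20, 0.25), lr_schedule, numeric(1), T_i = 20)
  expect_true(all(diff(g) < 0))
  expect_true(all(g >= 1e-6 & g <= 1e-3))
  expect_error(lr_schedule(1, 0), "T_i")
  expect_error(lr_schedule(-1, 10), "T_cur")
  # restarts reset the cycle and double its length
  expect_equal(sleepgraph:::restart_position(0, 20, 2), list(T_cur = 0, T_i = 20))
  expect_equal(sleepgraph:::restart_position(19, 20, 2), list(T_cur = 19, T_i = 20))
  expect_equal(sleepgraph:::restart_position(20, 20, 2), list(T_cur = 0, T_i = 40))
  expect_equal(sleepgraph:::restart_position(65, 20, 2), list(T_cur = 5, T_i = 80))
})

test_that("EMA-adaptive clipping rescales only above threshold and tracks norms", {
  g <- list(a = c(0.3, 0.4))           # norm 0.5 < 1
  r <- clip_gradients_ema(g, list(ema = NULL, decay = 0.99), 1)
  expect_identical(r$grads, g)
  expect_false(r$scaled)
  g2 <- list(a = c(0, 2))              # norm 2 = 2 * threshold
  r2 <- clip_gradients_ema(g2, list(ema = NULL, decay = 0.99), 1)
  expect_true(r2$scaled)
  expect_equal(sqrt(sum(unlist(r2$grads)^2)), 1, tolerance = 1e-10)
  # EMA converges geometrically to a constant observed norm
  st <- list(ema = NULL, decay = 0.9)
  for (i in 1:200) st <- clip_gradients_ema(list(a = c(3, 4)), st, 1)$state
  expect_equal(st$ema, 5, tolerance = 1e-6)
  # a larger EMA raises the effective threshold above the base norm
  r3 <- clip_gradients_ema(list(a = c(0, 4)), list(ema = 6, decay = 0.9), 1)
  expect_false(r3$scaled)
  expect_warning(r4 <- clip_gradients_ema(list(a = c(NaN, 1)),
                                          list(ema = 1, decay = 0.9), 1),
                 "nonfinite")
  expect_null(r4$grads)
  expect_error(clip_gradients_ema(g, base_max_norm = 0), "> 0")
})

test_that("AdamW minimizes a simple quadratic", {
  params <- list(w = c(5, -3))
  opt <- sleepgraph:::adamw_init(params)
  for (i in 1:500) {
    g <- list(w = 2 * params$w)
    st <- sleepgraph:::adamw_step(params, g, opt, lr = 0.05, weight_decay = 0)
    params <- st$params; opt <- st$opt
  }
  expect_lt(sqrt(sum(params$w^2)), 1e-2)
})

test_that("contrastive projection gradients match numerical differentiation", {
  set.seed(71)
  n <- 5; d <- 3
  h_f <- matrix(rnorm(n * d), n, d)
  h_a <- matrix(rnorm(n * d), n, d)
  y <- c(0, 0, 1, 1, 2)
  P_f <- matrix(rnorm(d * d), d, d)
  P_a <- matrix(rnorm(d * d), d, d)
  loss_of <- function(theta) {
    Pf <- matrix(theta[1:9], d, d); Pa <- matrix(theta[10:18], d, d)
    contrastive_loss(h_f %*% t(Pf), h_a %*% t(Pa), y, tau = 0.5, reduce = "mean")
  }
  g <- sleepgraph:::contrastive_grads(h_f, h_a, y, P_f, P_a, tau = 0.5)
  g_num <- num_grad(loss_of, c(as.numeric(P_f), as.numeric(P_a)))
  expect_equal(c(as.numeric(g$P_f), as.numeric(g$P_a)), g_num, tolerance = 1e-6)
  expect_equal(g$loss, loss_of(c(as.numeric(P_f), as.numeric(P_a))),
               tolerance = 1e-10)
})

small_dataset <- function(n = 10, seed = 3, ...) {
  cfg <- sim_config(n_sessions = n, n_windows = 16L, sample_rate = 50,
                    facial_rate = 1, facial_dim = 8L, K = 3L, event_rate = 12,
                    event_duration = c(30, 60), crossmodal_xor = TRUE, ...)
  make_dataset(cfg, seed)
}

tiny_config <- function() {
  cfg <- default_config("desk")
  cfg$facial$d_in <- 8L; cfg$facial$d_f <- 8L; cfg$facial$d_k <- 4L
  cfg$audio$frame_length <- 32L; cfg$audio$hop_length <- 16L
  cfg$audio$n_fft <- 32L; cfg$audio$n_cepstra <- 6L; cfg$audio$wavelet_levels <- 3L
  cfg$graph$d <- 16L
  cfg$network$hidden_dims <- c(16L, 16L)
  cfg$temporal$gru_dim <- 16L
  cfg$training$head_hidden <- 16L
  cfg
}

test_that("fit produces a finite history and is reproducible under a fixed seed", {
  ds <- small_dataset()
  cfg <- tiny_config()
  f1 <- sleepgraph_fit(ds, cfg, seed = 5, epochs = 2)
  expect_equal(nrow(f1$history), 2)
  expect_true(all(is.finite(as.matrix(f1$history))))
  f2 <- sleepgraph_fit(ds, cfg, seed = 5, epochs = 2)
  expect_identical(f1$history$loss_total, f2$history$loss_total)
  expect_identical(f1$history$val_macro_f1, f2$history$val_macro_f1)
  # prediction contract: one row per window with score columns summing to 1
  preds <- predict(f1)
  expect_true(all(c("truth", "estimate", "score_0", "score_1", "score_2") %in%
                    names(preds)))
  probs <- as.matrix(preds[, paste0("score_", 0:2)])
  expect_equal(rowSums(probs), rep(1, nrow(preds)), tolerance = 1e-6)
  g <- glance(f1)
  expect_equal(g$epochs, 2)
  td <- tidy(f1)
  expect_true(all(c("epoch", "metric", "value") %in% names(td)))
})

test_that("the optimizer memorizes a small noiseless training set", {
  # classification term of the objective drops below 10% of its initial value
  # (the contrastive and reconstruction terms have positive floors set by the
  # data and architecture, see the methods vignette)
  cfg_sim <- sim_config(n_sessions = 10, n_windows = 16L, sample_rate = 50,
                        facial_rate = 1, facial_dim = 8L, K = 3L,
                        event_rate = 12, event_duration = c(30, 60),
                        crossmodal_xor = TRUE, audio_noise_sd = 1e-3,
                        facial_noise_sd = 1e-3)
  ds <- make_dataset(cfg_sim, 4)
  # memorization target: 4 training sessions
  ds$manifest$split <- c(rep("train", 4), rep("val", 3), rep("test", 3))
  cfg <- tiny_config()
  cfg$training$patience <- 200L
  cfg$training$dropout <- 0
  fit <- sleepgraph_fit(ds, cfg, seed = 2, epochs = 60)
  expect_lt(min(fit$history$loss_cls), 0.1 * fit$history$loss_cls[1])
})

test_that("training losses stay nonnegative and the total matches its parts", {
  ds <- small_dataset()
  cfg <- tiny_config()
  fit <- sleepgraph_fit(ds, cfg, seed = 9, epochs = 2)
  h <- fit$history
  expect_true(all(h$loss_cls >= 0 & h$loss_temp >= 0 &
                    h$loss_cont >= 0 & h$loss_rec >= 0))
  w <- unlist(cfg$loss$weights)
  expect_equal(h$loss_total,
               w["cls"] * h$loss_cls + w["temp"] * h$loss_temp +
                 w["cont"] * h$loss_cont + w["rec"] * h$loss_rec,
               tolerance = 1e-10, ignore_attr = TRUE)
})
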