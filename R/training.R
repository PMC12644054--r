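# Optimization. The encoder is fixed at its seeded initialization (reservoir
# regime, see the methods vignette); AdamW with cosine warm restarts and
# EMA-adaptive gradient clipping trains the readout stack: classification
# head (focal + temporal-consistency terms), contrastive projection heads
# (cross-modal InfoNCE), and modality decoders (reconstruction).

#' Cosine annealing learning rate with warm restarts
#'
#' `eta = eta_min + (eta_max - eta_min)/2 * (1 + cos(pi * T_cur / T_i))`.
#'
#' @param T_cur epochs since the last restart, in `[0, T_i]`.
#' @param T_i epochs in the current restart cycle (> 0).
#' @param eta_min,eta_max learning rate bounds (defaults 1e-6 / 1e-3).
#' @return the learning rate.
#' @export
lr_schedule <- function(T_cur, T_i, eta_min = 1e-6, eta_max = 1e-3) {
  if (T_i <= 0) stop_sg("lr_schedule: T_i must be > 0")
  if (T_cur < 0 || T_cur > T_i) stop_sg("lr_schedule: T_cur must lie in [0, T_i]")
  eta_min + 0.5 * (eta_max - eta_min) * (1 + cos(pi * T_cur / T_i))
}

# epoch (0-based) -> (T_cur, T_i) under a doubling warm-restart schedule
restart_position <- function(epoch, restart_len = 20L, mult = 2) {
  T_i <- restart_len
  e <- epoch
  while (e >= T_i) {
    e <- e - T_i
    T_i <- T_i * mult
  }
  list(T_cur = e, T_i = T_i)
}

#' EMA-adaptive gradient clipping
#'
#' The effective threshold is `base_max_norm * max(1, ema / base_max_norm)`
#' (i.e. the larger of the base norm and the running EMA of observed norms);
#' gradients above it are rescaled to the threshold, and the EMA is updated
#' afterwards with the configured decay.
#'
#' @param grads list (or vector) of numeric gradients.
#' @param state list with `ema` (running norm EMA, `NULL` initially) and
#'   `decay` (default 0.99).
#' @param base_max_norm base clipping norm (> 0, default 1).
#' @return list with `grads` (rescaled), `state` (updated), `norm`, `scaled`.
#' @export
clip_gradients_ema <- function(grads, state = list(ema = NULL, decay = 0.99),
                               base_max_norm = 1) {
  if (base_max_norm <= 0) stop_sg("base_max_norm must be > 0")
  flat <- unlist(grads, use.names = FALSE)
  if (any(!is.finite(flat))) {
    warn_sg("nonfinite gradient; skipping step")
    return(list(grads = NULL, state = state, norm = NA_real_, scaled = FALSE))
  }
  nrm <- sqrt(sum(flat^2))
  ema <- state$ema %||% base_max_norm
  threshold <- base_max_norm * max(1, ema / base_max_norm)
  scaled <- FALSE
  if (nrm > threshold && nrm > 0) {
    scale <- threshold / nrm
    grads <- rapply(grads, function(g) g * scale, how = "replace")
    scaled <- TRUE
  }
  decay <- state$decay %||% 0.99
  state$ema <- decay * ema + (1 - decay) * nrm
  list(grads = grads, state = state, norm = nrm, scaled = scaled)
}

# ---- AdamW over a named list of parameter arrays ----

adamw_init <- function(params) {
  list(m = rapply(params, function(p) p * 0, how = "replace"),
       v = rapply(params, function(p) p * 0, how = "replace"),
       t = 0L)
}

adamw_step <- function(params, grads, opt, lr, weight_decay = 1e-4,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       decay_exempt = character(0)) {
  opt$t <- opt$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    wd <- if (nm %in% decay_exempt) 0 else weight_decay
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) + wd * params[[nm]])
  }
  list(params = params, opt = opt)
}

# ---- readout parameters and gradients ----

init_readout <- function(model, K, seed) {
  cfg <- model$config
  n_mod <- if (model$modality == "both") 2L else 1L
  d_z <- model$hdim * (1L + n_mod) + cfg$temporal$gru_dim
  hh <- cfg$training$head_hidden
  list(
    head = mlp_decoder(d_z, hh, K, derive_seed(seed, "head")),
    dec_f = mlp_decoder(model$hdim, model$hdim, cfg$facial$d_f,
                        derive_seed(seed, "dec_f")),
    dec_a = mlp_decoder(model$hdim, model$hdim, model$d_a,
                        derive_seed(seed, "dec_a")),
    P_f = with_seed(derive_seed(seed, "proj_f"), init_mat(model$hdim, model$hdim)),
    P_a = with_seed(derive_seed(seed, "proj_a"), init_mat(model$hdim, model$hdim))
  )
}

head_probabilities <- function(head, Z, drop_mask = NULL) {
  fwd <- mlp_forward(head, Z)
  if (!is.null(drop_mask)) {
    fwd$A1 <- fwd$A1 * drop_mask
    fwd$out <- sweep(fwd$A1 %*% t(head$W2), 2L, head$b2, `+`)
  }
  prob <- row_softmax(fwd$out)
  list(prob = prob, fwd = fwd)
}

# InfoNCE gradient w.r.t. the two projection matrices (mean over positives)
contrastive_grads <- function(h_f, h_a, labels, P_f, P_a, tau) {
  Zf <- h_f %*% t(P_f); Za <- h_a %*% t(P_a)
  n <- nrow(Zf)
  S <- cosine_sim_matrix(Zf, Za)
  pos <- outer(labels, labels, `==`)
  n_pos <- sum(pos)
  if (n_pos == 0) {
    return(list(P_f = P_f * 0, P_a = P_a * 0, loss = 0))
  }
  P <- t(apply(S / tau, 1L, softmax))
  npos_i <- rowSums(pos)
  dS <- (npos_i * P - pos) / (n_pos * tau)
  logZ <- apply(S / tau, 1L, function(r) { m <- max(r); m + log(sum(exp(r - m))) })
  loss <- sum((-(S / tau - logZ))[pos]) / n_pos
  nf <- sqrt(rowSums(Zf^2)); na_ <- sqrt(rowSums(Za^2))
  nf[nf == 0] <- Inf; na_[na_ == 0] <- Inf
  # dS_ij/dZf_i = Za_j/(|Zf_i||Za_j|) - S_ij Zf_i/|Zf_i|^2
  Gf <- (dS / outer(nf, na_)) %*% Za - (rowSums(dS * S) / nf^2) * Zf
  Ga <- t(dS / outer(nf, na_)) %*% Zf - (colSums(dS * S) / na_^2) * Za
  list(P_f = t(Gf) %*% h_f, P_a = t(Ga) %*% h_a, loss = loss)
}

flatten_params <- function(p) {
  out <- list()
  for (nm in names(p)) {
    if (inherits(p[[nm]], "sleepgraph_mlp")) {
      for (f in c("W1", "b1", "W2", "b2")) out[[paste0(nm, ".", f)]] <- p[[nm]][[f]]
    } else out[[nm]] <- p[[nm]]
  }
  out
}

unflatten_params <- function(flat, template) {
  for (nm in names(template)) {
    if (inherits(template[[nm]], "sleepgraph_mlp")) {
      for (f in c("W1", "b1", "W2", "b2")) template[[nm]][[f]] <- flat[[paste0(nm, ".", f)]]
    } else template[[nm]] <- flat[[nm]]
  }
  template
}

chunk_indices <- function(Tn, size) {
  starts <- seq(1L, Tn, by = size)
  lapply(starts, function(s) s:min(s + size - 1L, Tn))
}

readout_chunk_grads <- function(readout, enc, idx, alpha, cfg, model, drop_rate,
                                weights) {
  Z <- enc$z[idx, , drop = FALSE]
  y <- enc$labels[idx]
  n <- length(idx)
  drop_mask <- if (drop_rate > 0) {
    matrix(stats::rbinom(n * readout$head$d_hidden, 1L, 1 - drop_rate) /
             (1 - drop_rate), n, readout$head$d_hidden)
  } else NULL
  hp <- head_probabilities(readout$head, Z, drop_mask)
  G_logits <- weights[["cls"]] *
    focal_grad_logits(hp$prob, y, alpha, cfg$loss$gamma_focal)
  l_temp <- 0
  if (n >= 2L) {
    hseg <- enc$h_fused[idx, , drop = FALSE]
    G_logits <- G_logits + weights[["temp"]] *
      temporal_grad_logits(hp$prob, hseg, cfg$loss$beta)
    l_temp <- temporal_consistency_loss(hp$prob, hseg, cfg$loss$beta)
  }
  hb <- mlp_backward(readout$head, hp$fwd, G_logits)
  grads <- list(head.W1 = hb$W1, head.b1 = hb$b1, head.W2 = hb$W2, head.b2 = hb$b2)
  losses <- c(cls = focal_loss(hp$prob, y, alpha, cfg$loss$gamma_focal),
              temp = l_temp)
  # reconstruction (mean over windows in the chunk)
  use_f <- model$modality %in% c("both", "facial")
  use_a <- model$modality %in% c("both", "audio")
  H <- enc$h_fused[idx, , drop = FALSE]
  l_rec <- 0
  if (use_f) {
    fw <- mlp_forward(readout$dec_f, H)
    G <- 2 * (fw$out - enc$F[idx, , drop = FALSE]) / n * weights[["rec"]]
    bb <- mlp_backward(readout$dec_f, fw, G)
    grads$dec_f.W1 <- bb$W1; grads$dec_f.b1 <- bb$b1
    grads$dec_f.W2 <- bb$W2; grads$dec_f.b2 <- bb$b2
    l_rec <- l_rec + mean(rowSums((fw$out - enc$F[idx, , drop = FALSE])^2))
  }
  if (use_a) {
    fw <- mlp_forward(readout$dec_a, H)
    G <- 2 * (fw$out - enc$A[idx, , drop = FALSE]) / n * weights[["rec"]]
    bb <- mlp_backward(readout$dec_a, fw, G)
    grads$dec_a.W1 <- bb$W1; grads$dec_a.b1 <- bb$b1
    grads$dec_a.W2 <- bb$W2; grads$dec_a.b2 <- bb$b2
    l_rec <- l_rec + mean(rowSums((fw$out - enc$A[idx, , drop = FALSE])^2))
  }
  losses["rec"] <- l_rec
  # contrastive alignment (multimodal only)
  if (use_f && use_a) {
    cg <- contrastive_grads(enc$h_f[idx, , drop = FALSE],
                            enc$h_a[idx, , drop = FALSE],
                            y, readout$P_f, readout$P_a, cfg$loss$tau)
    grads$P_f <- weights[["cont"]] * cg$P_f
    grads$P_a <- weights[["cont"]] * cg$P_a
    losses["cont"] <- cg$loss
  } else losses["cont"] <- 0
  list(grads = grads, losses = losses)
}

#' Fit the model on a simulated (or compatible) dataset
#'
#' Encodes every session once through the seeded deep encoder, then optimizes
#' the readout stack with AdamW under a cosine warm-restart schedule,
#' EMA-adaptive gradient clipping, early stopping on validation macro-F1 and
#' checkpoint averaging over the best validation checkpoints. All randomness
#' (initialization, shuffling, dropout) derives from `seed`.
#'
#' @param dataset a [make_dataset()] result (sessions + manifest).
#' @param config a [default_config()]; `config$training` controls the loop.
#' @param seed master seed.
#' @param modality `"both"`, `"facial"` or `"audio"` (ablations).
#' @param epochs override for `config$training$epochs`.
#' @param verbose print per-epoch progress.
#' @return object of class `sleepgraph_fit` with elements `model`, `readout`,
#'   `history` (tibble), `scaler`, `alpha`, `best_epoch`, `config`, `seed`.
#' @export
sleepgraph_fit <- function(dataset, config = default_config("desk"),
                           seed = 1L, modality = "both", epochs = NULL,
                           verbose = FALSE) {
  tr <- config$training
  epochs <- epochs %||% tr$epochs
  man <- dataset$manifest
  if (!any(man$split == "train") || !any(man$split == "val")) {
    stop_sg("sleepgraph_fit: dataset must contain train and val splits")
  }
  K <- dataset$sessions[[1]]$K
  model <- sleepgraph_model(config, derive_seed(seed, "model"), modality)

  # feature standardization from the training split
  feats <- lapply(dataset$sessions, function(s) session_features(model, s))
  tr_idx <- which(man$split == "train")
  model$scaler <- list(
    facial = fit_scaler(do.call(rbind, lapply(feats[tr_idx], `[[`, "F"))),
    audio = fit_scaler(do.call(rbind, lapply(feats[tr_idx], `[[`, "A")))
  )
  enc_all <- lapply(dataset$sessions, function(s) encode_session(model, s))
  # standardize the head input so the tanh hidden layer starts in range
  z_scaler <- fit_scaler(do.call(rbind, lapply(enc_all[tr_idx], `[[`, "z")))
  enc_all <- lapply(enc_all, function(e) { e$z <- apply_scaler(e$z, z_scaler); e })
  labels_train <- unlist(lapply(enc_all[tr_idx], `[[`, "labels"))
  alpha <- inverse_freq_weights(labels_train, K)
  weights <- unlist(config$loss$weights)

  readout <- init_readout(model, K, seed)
  params <- flatten_params(readout)
  opt <- adamw_init(params)
  clip_state <- list(ema = NULL, decay = tr$ema_decay)
  history <- list()
  ckpts <- list()
  best_f1 <- -Inf; best_epoch <- 0L; stall <- 0L

  val_idx <- which(man$split == "val")
  eval_split <- function(readout, idx) {
    preds <- dplyr::bind_rows(lapply(idx, function(i) {
      prob <- head_probabilities(readout$head, enc_all[[i]]$z)$prob
      tibble::tibble(truth = enc_all[[i]]$labels,
                     estimate = max.col(prob) - 1L)
    }))
    list(macro_f1 = confusion_metrics(preds, K = K)$macro_f1,
         accuracy = mean(preds$truth == preds$estimate))
  }

  for (epoch in seq_len(epochs)) {
    pos <- restart_position(epoch - 1L, tr$restart_len, tr$restart_mult)
    lr <- lr_schedule(pos$T_cur, pos$T_i, tr$eta_min, tr$eta_max)
    ep_losses <- c(cls = 0, temp = 0, cont = 0, rec = 0); n_chunks <- 0L
    order_tr <- with_seed(derive_seed(seed, paste0("shuffle", epoch)),
                          sample(tr_idx))
    for (i in order_tr) {
      enc <- enc_all[[i]]
      for (idx in chunk_indices(length(enc$labels), tr$batch_size)) {
        step <- with_seed(derive_seed(seed, paste0("drop", epoch, "_", i, "_", idx[1])), {
          readout_chunk_grads(readout, enc, idx, alpha, config, model,
                              tr$dropout, weights)
        })
        cl <- clip_gradients_ema(step$grads, clip_state, tr$clip_norm)
        clip_state <- cl$state
        if (is.null(cl$grads)) next
        upd <- adamw_step(params, cl$grads, opt, lr, tr$weight_decay,
                          decay_exempt = grep("\\.b[12]$", names(params), value = TRUE))
        params <- upd$params; opt <- upd$opt
        readout <- unflatten_params(params, readout)
        ep_losses <- ep_losses + step$losses[names(ep_losses)]
        n_chunks <- n_chunks + 1L
      }
    }
    ep_losses <- ep_losses / max(1L, n_chunks)
    total <- total_loss(as.list(ep_losses), weights)
    vm <- eval_split(readout, val_idx)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr, loss_cls = ep_losses["cls"],
      loss_temp = ep_losses["temp"], loss_cont = ep_losses["cont"],
      loss_rec = ep_losses["rec"], loss_total = total,
      val_macro_f1 = vm$macro_f1, val_accuracy = vm$accuracy)
    if (verbose) {
      message(sprintf("epoch %3d lr %.2e loss %.4f val-F1 %.4f",
                      epoch, lr, total, vm$macro_f1))
    }
    ckpts[[epoch]] <- list(params = params, val_f1 = vm$macro_f1)
    if (vm$macro_f1 > best_f1 + 1e-9) {
      best_f1 <- vm$macro_f1; best_epoch <- epoch; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= tr$patience) break
    }
  }
  # checkpoint averaging over the top validation checkpoints
  f1s <- vapply(ckpts, `[[`, numeric(1), "val_f1")
  top <- order(f1s, decreasing = TRUE)[seq_len(min(tr$ckpt_avg, length(ckpts)))]
  avg <- ckpts[[top[1]]]$params
  if (length(top) > 1L) {
    for (nm in names(avg)) {
      avg[[nm]] <- Reduce(`+`, lapply(top, function(e) ckpts[[e]]$params[[nm]])) /
        length(top)
    }
  }
  readout_avg <- unflatten_params(avg, readout)
  # keep the better of the averaged and the single best checkpoint
  if (eval_split(readout_avg, val_idx)$macro_f1 >=
      eval_split(unflatten_params(ckpts[[which.max(f1s)]]$params, readout),
                 val_idx)$macro_f1) {
    readout <- readout_avg
  } else {
    readout <- unflatten_params(ckpts[[which.max(f1s)]]$params, readout)
  }
  structure(list(model = model, readout = readout,
                 history = dplyr::bind_rows(history), alpha = alpha,
                 best_epoch = best_epoch, K = K, config = config, seed = seed,
                 manifest = man, enc_cache = enc_all, z_scaler = z_scaler),
            class = "sleepgraph_fit")
}

#' @export
print.sleepgraph_fit <- function(x, ...) {
  cat(sprintf("<sleepgraph fit> %s | %d epochs (best %d) | val macro-F1 %.4f\n",
              x$model$modality, nrow(x$history), x$best_epoch,
              max(x$history$val_macro_f1)))
  invisible(x)
}

#' Per-window predictions for sessions
#'
#' @param object a [sleepgraph_fit()].
#' @param sessions list of sessions (default: the cached test split).
#' @param split with cached sessions, which manifest split to score
#'   (`"test"`, `"val"`, `"train"`).
#' @param ... unused.
#' @return tibble with `session`, `window`, `time`, `start`, `end`, `truth`,
#'   `estimate` and per-class `score_k` columns.
#' @export
predict.sleepgraph_fit <- function(object, sessions = NULL, split = "test", ...) {
  encs <- if (is.null(sessions)) {
    idx <- which(object$manifest$split == split)
    stats::setNames(object$enc_cache[idx], idx)
  } else {
    stats::setNames(lapply(sessions, function(s) {
      e <- encode_session(object$model, s)
      e$z <- apply_scaler(e$z, object$z_scaler)
      e
    }), seq_along(sessions))
  }
  dplyr::bind_rows(lapply(names(encs), function(sid) {
    enc <- encs[[sid]]
    prob <- head_probabilities(object$readout$head, enc$z)$prob
    out <- tibble::tibble(session = as.integer(sid),
                          window = enc$windows$window,
                          time = (enc$windows$start + enc$windows$end) / 2,
                          start = enc$windows$start, end = enc$windows$end,
                          truth = enc$labels,
                          estimate = max.col(prob) - 1L)
    for (k in seq_len(ncol(prob))) out[[paste0("score_", k - 1L)]] <- prob[, k]
    out
  }))
}

#' Evaluate a fit on a split or explicit sessions
#'
#' @param fit a [sleepgraph_fit()].
#' @param sessions optional list of sessions (default: cached test split).
#' @param split manifest split to use when `sessions` is `NULL`.
#' @param tau_iou event IoU threshold.
#' @return a [evaluate_windows()] report.
#' @export
evaluate_fit <- function(fit, sessions = NULL, split = "test", tau_iou = 0.5) {
  preds <- predict(fit, sessions = sessions, split = split)
  evaluate_windows(preds, K = fit$K, tau_iou = tau_iou)
}

#' Tidy the training history
#' @param x a `sleepgraph_fit`.
#' @param ... unused.
#' @return long tibble with `epoch`, `metric`, `value`.
#' @export
tidy.sleepgraph_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch", names_to = "metric",
                      values_to = "value")
}

#' One-row fit summary
#' @param x a `sleepgraph_fit`.
#' @param ... unused.
#' @return tibble with the final losses and best validation scores.
#' @export
glance.sleepgraph_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
                 loss_total = last$loss_total,
                 val_macro_f1 = max(x$history$val_macro_f1),
                 val_accuracy = max(x$history$val_accuracy),
                 modality = x$model$modality)
}
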