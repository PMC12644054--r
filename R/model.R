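# Full pipeline assembly. A sleepgraph_model bundles the facial encoder, the
# audio feature configuration, the edge-weight model, the graph-network
# layers, the cross-modal fusion and the temporal stack, all initialized from
# one seed. The deep encoder stays at its seeded initialization (a reservoir
# regime); training (R/training.R) optimizes the readout stack on top of the
# cached encodings.

#' Build the full multimodal dynamic-graph model
#'
#' @param config a [default_config()] list.
#' @param seed master initializer seed.
#' @param modality `"both"` (default), or `"facial"` / `"audio"` for the
#'   unimodal ablations (the graph then carries only that modality's nodes
#'   and fusion degenerates to a layer-normalized single stream).
#' @return object of class `sleepgraph_model`.
#' @export
sleepgraph_model <- function(config, seed = config$seed %||% 1L,
                             modality = c("both", "facial", "audio")) {
  modality <- match.arg(modality)
  d_a <- config$audio$n_cepstra + 4L +
    length(config$audio$wavelet_stats %||% c("log_energy", "std")) *
      (config$audio$wavelet_levels + 1L)
  enc <- facial_encoder(config$facial, derive_seed(seed, "facial"))
  edge <- edge_weight_model(config$facial$d_f, d_a, config$graph$d,
                            lambda = config$graph$lambda,
                            gamma_decay = config$graph$gamma_decay,
                            seed = derive_seed(seed, "edges"))
  dims <- c(config$graph$d, config$network$hidden_dims)
  layers <- lapply(seq_along(config$network$hidden_dims), function(l) {
    if (l %% 2L == 1L) {
      with_seed(derive_seed(seed, paste0("conv", l)), {
        list(kind = "conv",
             W = lapply(seq_len(config$network$scales), function(s) {
               init_mat(dims[l], dims[l + 1L])
             }))
      })
    } else {
      list(kind = "gat",
           gat = temporal_gat(dims[l], dims[l + 1L],
                              n_heads = config$network$gat_heads,
                              d_omega = config$network$d_omega %||% 4L,
                              seed = derive_seed(seed, paste0("gat", l))))
    }
  })
  hdim <- utils::tail(dims, 1L)
  fus <- fusion_layer(hdim, config$network$d_k, derive_seed(seed, "fusion"))
  stack <- temporal_stack(hdim, config$temporal$gru_dim,
                          kernel = config$temporal$kernel,
                          dilations = config$temporal$dilations,
                          radius = config$temporal$radius,
                          pos_table = config$temporal$pos_table,
                          levels = config$temporal$levels,
                          base_lookback = config$temporal$base_lookback,
                          seed = derive_seed(seed, "temporal"))
  structure(list(config = config, seed = seed, modality = modality,
                 d_a = d_a, encoder = enc, edge = edge, layers = layers,
                 hdim = hdim, fusion = fus, stack = stack, scaler = NULL),
            class = "sleepgraph_model")
}

#' @export
print.sleepgraph_model <- function(x, ...) {
  cat(sprintf("<sleepgraph model> modality %s | d_f %d, d_a %d, node d %d -> %s -> GRU %d\n",
              x$modality, x$config$facial$d_f, x$d_a, x$config$graph$d,
              paste(x$config$network$hidden_dims, collapse = "/"),
              x$config$temporal$gru_dim))
  invisible(x)
}

fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2L, stats::sd)
  sd_[sd_ < 1e-8] <- 1
  list(mu = mu, sd = sd_)
}

apply_scaler <- function(X, sc) {
  sweep(sweep(X, 2L, sc$mu, `-`), 2L, sc$sd, `/`)
}

window_facial_matrix <- function(model, session) {
  wins <- session$windows
  if (session$facial_mode == "vector") {
    frames <- lapply(seq_len(nrow(wins)), function(i) {
      sel <- session$facial_times >= wins$start[i] & session$facial_times < wins$end[i]
      if (!any(sel)) sel <- which.min(abs(session$facial_times -
                                            (wins$start[i] + wins$end[i]) / 2))
      session$facial[sel, , drop = FALSE]
    })
  } else {
    frames <- lapply(seq_len(nrow(wins)), function(i) {
      sel <- which(session$facial_times >= wins$start[i] &
                     session$facial_times < wins$end[i])
      if (!length(sel)) sel <- which.min(abs(session$facial_times -
                                               (wins$start[i] + wins$end[i]) / 2))
      session$facial[sel]
    })
  }
  frames
}

#' Extract the per-window feature streams of a session
#'
#' Facial windows go through the attention encoder; audio windows through the
#' acoustic feature pipeline. Returns raw (unstandardized) `T x d` matrices.
#'
#' @param model a [sleepgraph_model()].
#' @param session a [simulate_session()] result (or compatible list).
#' @return list with `F` (`T x d_f`), `A` (`T x d_a`), `windows`.
#' @export
session_features <- function(model, session) {
  wins <- session$windows
  Fm <- encode_sequence(model$encoder, window_facial_matrix(model, session),
                        timestamps = wins$start)
  Am <- as.matrix(window_audio_features(session$audio, session$sample_rate,
                                        wins, model$config$audio)[, -1])
  list(F = Fm, A = unname(Am), windows = wins)
}

run_graph_layers <- function(model, nodes, X) {
  ts <- nodes$timestamp
  stride <- model$config$data$window_s * (1 - model$config$data$overlap)
  topo <- build_topology(nodes, model$config$graph$temporal_radius,
                         model$config$graph$connectivity_cap)
  snap <- compute_edge_weights(graph_snapshot(nodes, X, topo), model$edge)
  ed <- snap$edges
  n <- nrow(nodes)
  idx <- setNames(seq_len(n), nodes$id)
  H <- X
  # scale-s adjacency: symmetrized weighted graph restricted to |dt| <= s*stride
  A_full <- matrix(0, n, n)
  if (nrow(ed) > 0) {
    A_full[cbind(idx[as.character(ed$i)], idx[as.character(ed$j)])] <- ed$weight
    A_full <- (A_full + t(A_full)) / 2
  }
  A_scales <- lapply(seq_len(model$config$network$scales), function(s) {
    A_s <- A_full
    gap <- abs(outer(ts, ts, `-`))
    A_s[gap > s * stride + 1e-9] <- 0
    normalize_adjacency(A_s)
  })
  dir_edges <- if (nrow(ed) > 0) {
    tibble::tibble(i = as.integer(idx[as.character(ed$i)]),
                   j = as.integer(idx[as.character(ed$j)]))
  } else tibble::tibble(i = integer(0), j = integer(0))
  for (layer in model$layers) {
    H_new <- if (layer$kind == "conv") {
      S <- length(layer$W)
      multiscale_graph_conv(H, A_scales[seq_len(S)], layer$W)
    } else {
      temporal_gat_layer(H, dir_edges, ts, layer$gat)$H_out
    }
    # identity skip whenever the layer preserves width (standard GNN practice;
    # counters over-smoothing of the planted per-window signal)
    H <- if (ncol(H_new) == ncol(H)) H + H_new else H_new
  }
  H
}

#' Encode a session through the full pipeline
#'
#' Features, node projection, per-window context graphs (trailing context of
#' `temporal_radius` windows, so the representation is causal), message
#' passing, cross-modal fusion and the temporal stack.
#'
#' @param model a [sleepgraph_model()] (with `scaler` set when standardized
#'   features are wanted, as during training).
#' @param session a session object.
#' @return list with `F`, `A` (standardized when a scaler is set), `h_f`,
#'   `h_a`, `h_fused` (`T x hdim`), `temporal` (`T x gru_dim`),
#'   `z` (`T x (hdim + gru_dim)` head input), `labels`, `windows`.
#' @export
encode_session <- function(model, session) {
  feats <- session_features(model, session)
  Fm <- feats$F; Am <- feats$A
  if (!is.null(model$scaler)) {
    Fm <- apply_scaler(Fm, model$scaler$facial)
    Am <- apply_scaler(Am, model$scaler$audio)
  }
  wins <- feats$windows
  Tn <- nrow(wins)
  proj <- project_nodes(Fm, Am, model$edge)
  radius <- model$config$graph$temporal_radius
  use_f <- model$modality %in% c("both", "facial")
  use_a <- model$modality %in% c("both", "audio")
  h_f <- matrix(0, Tn, model$hdim); h_a <- matrix(0, Tn, model$hdim)
  centers <- (wins$start + wins$end) / 2
  for (t in seq_len(Tn)) {
    ctx <- max(1L, t - radius):t
    nodes <- list(); Xr <- list()
    for (w in ctx) {
      if (use_f) {
        nodes[[length(nodes) + 1L]] <- tibble::tibble(
          id = 2L * w - 1L, modality = "facial", window = wins$window[w],
          timestamp = centers[w])
        Xr[[length(Xr) + 1L]] <- proj$x_f[w, ]
      }
      if (use_a) {
        nodes[[length(nodes) + 1L]] <- tibble::tibble(
          id = 2L * w, modality = "audio", window = wins$window[w],
          timestamp = centers[w])
        Xr[[length(Xr) + 1L]] <- proj$x_a[w, ]
      }
    }
    nodes <- dplyr::bind_rows(nodes)
    H <- run_graph_layers(model, nodes, do.call(rbind, Xr))
    if (use_f) h_f[t, ] <- H[which(nodes$modality == "facial" & nodes$window == wins$window[t]), ]
    if (use_a) h_a[t, ] <- H[which(nodes$modality == "audio" & nodes$window == wins$window[t]), ]
  }
  h_fused <- if (model$modality == "both") {
    # fusion operates on the per-window pooled summaries: window by window,
    # so no cross-window (in particular no future) attention enters here
    t(vapply(seq_len(Tn), function(t) {
      crossmodal_fuse(h_f[t, , drop = FALSE], h_a[t, , drop = FALSE],
                      model$fusion)$h_fused[1, ]
    }, numeric(model$hdim)))
  } else if (model$modality == "facial") {
    layer_norm(h_f)
  } else {
    layer_norm(h_a)
  }
  temporal <- temporal_forward(h_fused, model$stack)
  # classifier input: fused + temporal states plus skip connections from the
  # per-window modality summaries (only the modalities in use)
  z <- cbind(h_fused, temporal,
             if (use_f) h_f, if (use_a) h_a)
  list(F = Fm, A = Am, h_f = h_f, h_a = h_a, h_fused = h_fused,
       temporal = temporal, z = z,
       labels = wins$label, windows = wins)
}
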