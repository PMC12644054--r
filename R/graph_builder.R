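# Dynamic heterogeneous graph construction: facial and audio nodes over a
# sliding temporal context, typed edges (ff / aa / fa), and adaptive edge
# weights mixing a neighborhood-softmax temporal attention, a sigmoid
# cross-modal gate on concatenated/elementwise-product embeddings, and an
# exponential decay in the timestamp gap.

#' Edge-weight model parameters
#'
#' @param d_f,d_a facial and audio feature dims entering the node projection.
#' @param d shared node embedding dimension.
#' @param d_h hidden width of the temporal-attention scorer.
#' @param lambda mixing weights `c(lambda1, lambda2, lambda3)` for the
#'   temporal-attention, cross-modal and decay components (defaults
#'   `0.4, 0.4, 0.2`).
#' @param gamma_decay temporal decay rate (default `0.1` / s).
#' @param seed initializer seed.
#' @return parameter container of class `sleepgraph_edge_model`.
#' @export
edge_weight_model <- function(d_f, d_a, d, d_h = d, lambda = c(0.4, 0.4, 0.2),
                              gamma_decay = 0.1, seed = 1) {
  if (any(lambda < 0)) stop_sg("lambda weights must be nonnegative")
  if (gamma_decay < 0) stop_sg("gamma_decay must be nonnegative")
  with_seed(seed, {
    structure(list(
      d_f = d_f, d_a = d_a, d = d,
      W_f = init_mat(d, d_f), b_f = numeric(d),
      W_a = init_mat(d, d_a), b_a = numeric(d),
      W_1 = init_mat(d_h, d), W_2 = init_mat(d_h, d),
      W_temp = rnorm(d_h, sd = 1 / sqrt(d_h)),
      W_cross = rnorm(3 * d, sd = 1 / sqrt(3 * d)),
      lambda = lambda, gamma_decay = gamma_decay, seed = seed
    ), class = "sleepgraph_edge_model")
  })
}

#' Project modality features into the shared node space
#'
#' `x^f = W_f f + b_f`, `x^a = W_a a + b_a`; both outputs have length `d`.
#'
#' @param f_t facial feature vector (length `d_f`) or `T x d_f` matrix.
#' @param a_t audio feature vector (length `d_a`) or `T x d_a` matrix.
#' @param model an [edge_weight_model()].
#' @return list with `x_f` and `x_a` (vectors or `T x d` matrices).
#' @export
project_nodes <- function(f_t, a_t, model) {
  proj <- function(x, W, b, d_in, what) {
    if (is.matrix(x)) {
      if (ncol(x) != d_in) stop_sg("%s dim %d != expected %d", what, ncol(x), d_in)
      sweep(x %*% t(W), 2L, b, `+`)
    } else {
      if (length(x) != d_in) stop_sg("%s dim %d != expected %d", what, length(x), d_in)
      as.numeric(W %*% x) + b
    }
  }
  list(x_f = proj(f_t, model$W_f, model$b_f, model$d_f, "facial"),
       x_a = proj(a_t, model$W_a, model$b_a, model$d_a, "audio"))
}

#' Build the unweighted graph topology
#'
#' Connects intra-modal node pairs whose windows are within
#' `temporal_radius`, and cross-modal pairs that are co-windowed or within the
#' radius. Edges are unordered pairs (`i < j`); directed consumers expand each
#' pair in both directions. When the realized edge count would exceed
#' `connectivity_cap` times the complete-graph pair count, the longest-|dt|
#' pairs are dropped first (ties broken by node ids), deterministically.
#'
#' @param nodes tibble with columns `id`, `modality` (`"facial"`/`"audio"`),
#'   `window`, `timestamp` (seconds), sorted by timestamp.
#' @param temporal_radius intra-modal reach in windows (`>= 0`).
#' @param connectivity_cap fraction of the complete graph allowed (default
#'   `0.85`).
#' @return tibble of edges: `i`, `j` (node ids), `type` (`ff`/`aa`/`fa`),
#'   `dt` (|timestamp gap|).
#' @export
build_topology <- function(nodes, temporal_radius, connectivity_cap = 0.85) {
  if (temporal_radius < 0) stop_sg("temporal_radius must be >= 0")
  if (is.unsorted(nodes$timestamp)) stop_sg("nodes must be timestamp-sorted")
  n <- nrow(nodes)
  if (n < 2L) {
    return(tibble::tibble(i = integer(0), j = integer(0),
                          type = character(0), dt = numeric(0)))
  }
  pairs <- utils::combn(n, 2L)
  ia <- pairs[1L, ]; ja <- pairs[2L, ]
  dw <- abs(nodes$window[ia] - nodes$window[ja])
  same_mod <- nodes$modality[ia] == nodes$modality[ja]
  keep <- (same_mod & dw <= temporal_radius & dw > 0L) |
          (!same_mod & dw <= temporal_radius)
  ia <- ia[keep]; ja <- ja[keep]
  type <- ifelse(nodes$modality[ia] == nodes$modality[ja],
                 ifelse(nodes$modality[ia] == "facial", "ff", "aa"), "fa")
  dt <- abs(nodes$timestamp[ia] - nodes$timestamp[ja])
  max_edges <- ceiling(connectivity_cap * n * (n - 1) / 2)
  if (length(ia) > max_edges) {
    ord <- order(dt, nodes$id[ia], nodes$id[ja])   # keep shortest gaps
    sel <- sort(ord[seq_len(max_edges)])
    ia <- ia[sel]; ja <- ja[sel]; type <- type[sel]; dt <- dt[sel]
  }
  tibble::tibble(i = nodes$id[ia], j = nodes$id[ja], type = type, dt = dt)
}

#' Assemble a graph snapshot
#'
#' @param nodes node tibble (`id`, `modality`, `window`, `timestamp`).
#' @param X node feature matrix, one row per node (rows follow `nodes`).
#' @param edges unordered edge tibble from [build_topology()].
#' @return validated object of class `sleepgraph_graph`.
#' @export
graph_snapshot <- function(nodes, X, edges) {
  if (anyDuplicated(nodes$id)) stop_sg("node ids must be unique")
  if (nrow(X) != nrow(nodes)) stop_sg("X rows (%d) != node count (%d)",
                                      nrow(X), nrow(nodes))
  if (nrow(edges) > 0) {
    if (!all(edges$i %in% nodes$id) || !all(edges$j %in% nodes$id)) {
      stop_sg("edge endpoints must exist in the node set")
    }
    mod <- setNames(nodes$modality, nodes$id)
    expected <- ifelse(mod[as.character(edges$i)] == mod[as.character(edges$j)],
                       ifelse(mod[as.character(edges$i)] == "facial", "ff", "aa"),
                       "fa")
    if (!all(edges$type == expected)) {
      stop_sg("edge types inconsistent with endpoint modalities")
    }
  }
  structure(list(nodes = nodes, X = X, edges = edges),
            class = "sleepgraph_graph")
}

#' Compute adaptive edge weights for a snapshot
#'
#' Expands each unordered pair into two directed edges and assigns
#' `w_ij = lambda1 * alpha_temp + lambda2 * alpha_cross +
#' lambda3 * exp(-gamma |t_i - t_j|)`. The temporal attention is a softmax of
#' `W_temp' tanh(W_1 x_i + W_2 x_j)` over node `i`'s full topological
#' neighborhood (all edge types); the cross-modal gate is
#' `sigmoid(W_cross' [x_i || x_j || x_i * x_j])`, strictly inside `(0, 1)`.
#' A node with an empty neighborhood gets `alpha_temp = 0` on (nonexistent)
#' outgoing edges.
#'
#' @param snapshot a [graph_snapshot()].
#' @param model an [edge_weight_model()] (its projections are *not* re-applied;
#'   `snapshot$X` is already in node space).
#' @return the snapshot with a directed, weighted edge tibble
#'   (`i`, `j`, `type`, `dt`, `alpha_temp`, `alpha_cross`, `decay`, `weight`).
#' @export
compute_edge_weights <- function(snapshot, model) {
  ed <- snapshot$edges
  nodes <- snapshot$nodes
  X <- snapshot$X
  if (nrow(ed) == 0L) {
    snapshot$edges <- tibble::tibble(i = integer(0), j = integer(0),
                                     type = character(0), dt = numeric(0),
                                     alpha_temp = numeric(0),
                                     alpha_cross = numeric(0),
                                     decay = numeric(0), weight = numeric(0))
    return(snapshot)
  }
  idx <- setNames(seq_len(nrow(nodes)), nodes$id)
  dir_i <- c(ed$i, ed$j); dir_j <- c(ed$j, ed$i)
  type <- c(ed$type, ed$type); dt <- c(ed$dt, ed$dt)
  ii <- idx[as.character(dir_i)]; jj <- idx[as.character(dir_j)]
  # temporal attention logits, then softmax over each source neighborhood
  Z1 <- X %*% t(model$W_1); Z2 <- X %*% t(model$W_2)
  logits <- as.numeric(tanh(Z1[ii, , drop = FALSE] + Z2[jj, , drop = FALSE]) %*%
                         model$W_temp)
  alpha_temp <- numeric(length(logits))
  for (src in unique(ii)) {
    sel <- which(ii == src)
    alpha_temp[sel] <- softmax(logits[sel])
  }
  cross_in <- cbind(X[ii, , drop = FALSE], X[jj, , drop = FALSE],
                    X[ii, , drop = FALSE] * X[jj, , drop = FALSE])
  alpha_cross <- sigmoid(as.numeric(cross_in %*% model$W_cross))
  decay <- exp(-model$gamma_decay * dt)
  w <- model$lambda[1] * alpha_temp + model$lambda[2] * alpha_cross +
    model$lambda[3] * decay
  if (any(!is.finite(w))) stop_sg("nonfinite edge weights")
  snapshot$edges <- tibble::tibble(i = dir_i, j = dir_j, type = type, dt = dt,
                                   alpha_temp = alpha_temp,
                                   alpha_cross = alpha_cross,
                                   decay = decay, weight = w)
  snapshot
}

#' Serialize a graph snapshot to JSON
#'
#' @param snapshot a [graph_snapshot()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(snapshot, path) {
  jsonlite::write_json(list(nodes = snapshot$nodes,
                            edges = snapshot$edges,
                            features = snapshot$X),
                       path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
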