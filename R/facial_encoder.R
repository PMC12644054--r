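# Facial stream encoder. Image mode runs a small residual backbone with
# cardinality-grouped convolutions and global average pooling; vector mode
# (the default, used with precomputed per-frame features) embeds the frames
# linearly. Either way a window of frames becomes one vector f_t through
# spatial self-attention over frame/position tokens gated by a temporal
# attention vector that carries state across windows.

conv2d <- function(x, w, b = NULL, groups = 1L) {
  # x: H x W x Cin array; w: kh x kw x (Cin/groups) x Cout; "same" padding.
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Cg <- dim(w)[3]; Cout <- dim(w)[4]
  if (Cin %% groups != 0L || Cout %% groups != 0L || Cg != Cin / groups) {
    stop_sg("conv2d: channel/group mismatch (Cin=%d, Cout=%d, groups=%d, w ch=%d)",
            Cin, Cout, groups, Cg)
  }
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  xp <- array(0, c(H + 2 * ph, W + 2 * pw, Cin))
  xp[ph + seq_len(H), pw + seq_len(W), ] <- x
  out <- matrix(0, H * W, Cout)
  og <- Cout / groups
  for (g in seq_len(groups)) {
    ci <- (g - 1L) * Cg + seq_len(Cg)
    co <- (g - 1L) * og + seq_len(og)
    for (dh in seq_len(kh)) {
      for (dw in seq_len(kw)) {
        slab <- xp[dh + seq_len(H) - 1L, dw + seq_len(W) - 1L, ci, drop = FALSE]
        out[, co] <- out[, co] +
          matrix(slab, H * W, Cg) %*% matrix(w[dh, dw, , co], Cg, og)
      }
    }
  }
  if (!is.null(b)) out <- sweep(out, 2L, b, `+`)
  array(out, c(H, W, Cout))
}

avg_pool2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  h2 <- H %/% 2L; w2 <- W %/% 2L
  x <- x[seq_len(2L * h2), seq_len(2L * w2), , drop = FALSE]
  0.25 * (x[seq(1, 2 * h2, 2), seq(1, 2 * w2, 2), , drop = FALSE] +
          x[seq(2, 2 * h2, 2), seq(1, 2 * w2, 2), , drop = FALSE] +
          x[seq(1, 2 * h2, 2), seq(2, 2 * w2, 2), , drop = FALSE] +
          x[seq(2, 2 * h2, 2), seq(2, 2 * w2, 2), , drop = FALSE])
}

#' Build the small grouped-convolution facial backbone
#'
#' A residual network in the ResNeXt family at configurable scale: a 3x3 stem,
#' then `n_stages` residual blocks (1x1 reduce, 3x3 grouped convolution with
#' the configured cardinality, 1x1 expand, identity skip), each followed by
#' 2x2 average pooling; global average pooling yields the raw feature vector.
#'
#' @param input_shape `c(H, W, C)` of the frames.
#' @param width channel width (must be divisible by `cardinality`).
#' @param n_stages number of residual stages.
#' @param cardinality number of convolution groups (32 at full scale).
#' @param seed initializer seed.
#' @return parameter container of class `sleepgraph_backbone`.
#' @export
facial_backbone <- function(input_shape = c(32, 32, 1), width = 16,
                            n_stages = 3, cardinality = 4, seed = 1) {
  if (width %% cardinality != 0L) {
    stop_sg("backbone width %d not divisible by cardinality %d", width, cardinality)
  }
  with_seed(seed, {
    stem <- list(w = array(rnorm(3 * 3 * input_shape[3] * width,
                                 sd = 1 / sqrt(9 * input_shape[3])),
                           c(3, 3, input_shape[3], width)),
                 b = numeric(width))
    stages <- lapply(seq_len(n_stages), function(s) {
      list(
        reduce = list(w = array(rnorm(width * width, sd = 1 / sqrt(width)),
                                c(1, 1, width, width)), b = numeric(width)),
        grouped = list(w = array(rnorm(3 * 3 * (width / cardinality) * width,
                                       sd = 1 / sqrt(9 * width / cardinality)),
                                 c(3, 3, width / cardinality, width)),
                       b = numeric(width)),
        expand = list(w = array(rnorm(width * width, sd = 1 / sqrt(width)),
                                c(1, 1, width, width)), b = numeric(width))
      )
    })
    structure(list(input_shape = input_shape, width = width,
                   n_stages = n_stages, cardinality = cardinality,
                   stem = stem, stages = stages, seed = seed),
              class = "sleepgraph_backbone")
  })
}

#' Encode one facial frame through the backbone
#'
#' @param frame `H x W x C` array (or `H x W` matrix for `C = 1`) with values
#'   in `[0, 1]`.
#' @param backbone a [facial_backbone()].
#' @return list with `f_raw` (global-average-pooled feature vector, length
#'   `width`) and `tokens` (final feature map cells as an
#'   `n_positions x width` matrix, the spatial-attention tokens).
#' @export
encode_frame <- function(frame, backbone) {
  if (is.matrix(frame)) frame <- array(frame, c(dim(frame), 1L))
  if (!all(dim(frame) == backbone$input_shape)) {
    stop_sg("frame shape (%s) does not match configured (%s)",
            paste(dim(frame), collapse = "x"),
            paste(backbone$input_shape, collapse = "x"))
  }
  if (any(!is.finite(frame))) stop_sg("encode_frame: nonfinite frame values")
  x <- leaky_relu(conv2d(frame, backbone$stem$w, backbone$stem$b))
  for (st in backbone$stages) {
    y <- leaky_relu(conv2d(x, st$reduce$w, st$reduce$b))
    y <- leaky_relu(conv2d(y, st$grouped$w, st$grouped$b,
                           groups = backbone$cardinality))
    y <- conv2d(y, st$expand$w, st$expand$b)
    x <- leaky_relu(x + y)
    x <- avg_pool2(x)
  }
  tokens <- matrix(x, prod(dim(x)[1:2]), dim(x)[3])
  list(f_raw = colMeans(tokens), tokens = tokens)
}

#' Build the facial encoder
#'
#' @param cfg facial configuration list: `mode` (`"vector"` or `"image"`),
#'   `d_in` (vector mode input dim) or `input_shape`/`width`/`n_stages`/
#'   `cardinality` (image mode), `d_f` (output dim), `d_k` (attention key
#'   dim), `n_heads` (spatial attention heads), `context_length` (max frames
#'   attended per window).
#' @param seed initializer seed.
#' @return parameter container of class `sleepgraph_facial_encoder`.
#' @export
facial_encoder <- function(cfg, seed = 1) {
  mode <- cfg$mode %||% "vector"
  d_f <- cfg$d_f
  d_k <- cfg$d_k %||% max(4L, d_f %/% 2L)
  n_heads <- cfg$n_heads %||% 2L
  backbone <- NULL
  d_tok <- if (mode == "image") {
    backbone <- facial_backbone(cfg$input_shape %||% c(32, 32, 1),
                                cfg$width %||% 16, cfg$n_stages %||% 3,
                                cfg$cardinality %||% 4,
                                derive_seed(seed, "backbone"))
    backbone$width
  } else cfg$d_in
  if (d_f %% n_heads != 0L) stop_sg("d_f (%d) must be divisible by n_heads (%d)", d_f, n_heads)
  dv <- d_f %/% n_heads
  with_seed(derive_seed(seed, "facial_attn"), {
    params <- list(
      heads = lapply(seq_len(n_heads), function(m) {
        list(WQ = init_mat(d_tok, d_k), WK = init_mat(d_tok, d_k),
             WV = init_mat(d_tok, dv))
      }),
      W_o = init_mat(d_f, d_f),
      W_f = init_mat(d_f, d_tok),
      W_h = init_mat(d_f, d_f),
      W_t = init_mat(d_f, d_f)
    )
    structure(list(mode = mode, backbone = backbone, d_tok = d_tok, d_f = d_f,
                   d_k = d_k, n_heads = n_heads,
                   context_length = cfg$context_length %||% 16L,
                   params = params, seed = seed),
              class = "sleepgraph_facial_encoder")
  })
}

#' Temporal-spatial attention over a window's tokens
#'
#' Spatial self-attention `A_spatial = row-softmax(Q K' / sqrt(d_k))` applied
#' to `V` per head (heads concatenated then linearly mixed), average-pooled
#' over positions to a `d_f` vector, then gated elementwise by the temporal
#' attention `A_temporal = softmax(W_t tanh(W_f f_raw + W_h h_prev))`.
#'
#' @param tokens `n_positions x d_tok` matrix.
#' @param f_raw raw feature vector for the window (length `d_tok`).
#' @param h_prev hidden state from the previous window (length `d_f`; zeros
#'   for the first window).
#' @param enc a [facial_encoder()].
#' @return list with `f_t` (length `d_f`), `a_temporal`, and `a_spatial`
#'   (list of per-head attention matrices, rows summing to 1).
#' @export
spatiotemporal_attention <- function(tokens, f_raw, h_prev, enc) {
  p <- enc$params
  if (ncol(tokens) != enc$d_tok) stop_sg("token dim %d != configured %d",
                                         ncol(tokens), enc$d_tok)
  heads_out <- list(); a_sp <- list()
  for (m in seq_len(enc$n_heads)) {
    hm <- p$heads[[m]]
    Q <- tokens %*% hm$WQ; K <- tokens %*% hm$WK; V <- tokens %*% hm$WV
    logits <- Q %*% t(K) / sqrt(enc$d_k)
    if (any(!is.finite(logits))) stop_sg("nonfinite spatial attention logits")
    A <- row_softmax(logits)
    a_sp[[m]] <- A
    heads_out[[m]] <- A %*% V
  }
  mixed <- do.call(cbind, heads_out) %*% p$W_o        # n_pos x d_f
  pooled <- colMeans(mixed)
  z <- as.numeric(p$W_t %*% tanh(as.numeric(p$W_f %*% f_raw) +
                                 as.numeric(p$W_h %*% h_prev)))
  if (any(!is.finite(z))) stop_sg("nonfinite temporal attention logits")
  a_temp <- softmax(z)
  list(f_t = a_temp * pooled, a_temporal = a_temp, a_spatial = a_sp)
}

window_tokens <- function(enc, frames) {
  # frames: vector mode = n_frames x d_in matrix; image mode = list of arrays
  if (enc$mode == "vector") {
    if (!is.matrix(frames)) frames <- matrix(frames, nrow = 1L)
    n <- nrow(frames)
    keep <- if (n > enc$context_length) {
      unique(round(seq(1L, n, length.out = enc$context_length)))
    } else seq_len(n)
    tokens <- frames[keep, , drop = FALSE]
    list(tokens = tokens, f_raw = colMeans(tokens))
  } else {
    n <- length(frames)
    keep <- if (n > enc$context_length) {
      unique(round(seq(1L, n, length.out = enc$context_length)))
    } else seq_len(n)
    encs <- lapply(frames[keep], encode_frame, backbone = enc$backbone)
    tokens <- do.call(rbind, lapply(encs, function(e) e$f_raw))
    list(tokens = tokens,
         f_raw = colMeans(do.call(rbind, lapply(encs, function(e) e$f_raw))))
  }
}

#' Encode a sequence of facial windows
#'
#' Applies the temporal-spatial attention window by window, carrying the
#' hidden state forward as `h_t := f_t` (identity recurrence); `h_0` is the
#' zero vector. Windows must be ordered by timestamp.
#'
#' @param enc a [facial_encoder()].
#' @param windows list with one element per window: in vector mode an
#'   `n_frames x d_in` matrix of per-frame features, in image mode a list of
#'   frame arrays.
#' @param timestamps window timestamps in seconds (strictly increasing).
#' @return `T x d_f` matrix of per-window facial features `f_t`.
#' @export
encode_sequence <- function(enc, windows, timestamps = seq_along(windows)) {
  if (is.unsorted(timestamps, strictly = TRUE)) {
    stop_sg("encode_sequence: window timestamps must be strictly increasing")
  }
  h <- numeric(enc$d_f)
  out <- matrix(0, length(windows), enc$d_f)
  for (t in seq_along(windows)) {
    wt <- window_tokens(enc, windows[[t]])
    # vector mode embeds raw tokens: project through W_f-compatible shape
    res <- spatiotemporal_attention(wt$tokens, wt$f_raw, h, enc)
    out[t, ] <- res$f_t
    h <- res$f_t
  }
  out
}
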