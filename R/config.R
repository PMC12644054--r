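# Run configuration: nested defaults mirroring the published architecture
# table, YAML loading with strict schema validation, and a scaled-down "desk"
# preset whose dimensions suit CPU-scale studies (the methods vignette
# documents the choice of sizes).

#' Default run configuration
#'
#' Nested configuration covering data geometry, the facial and audio feature
#' modules, graph construction, the graph network, temporal modeling, losses
#' and training. `preset = "full"` carries the published full-scale values
#' (30 s windows at 50% overlap, 44.1 kHz audio with 2048/512 STFT framing,
#' 13 cepstra, J = 8 wavelet levels, d_f = 2048, node dim 512, S = 4 scales,
#' GNN dims 512/384/256/128, GRU 256, focal gamma 2, tau 0.1, beta 0.5, loss
#' weights 1/0.3/0.2/0.1, AdamW at 1e-3 with cosine warm restarts between
#' 1e-6 and 1e-3, batch 16, clip norm 1). `preset = "desk"` keeps every
#' mechanism but scales dimensions to run on one CPU.
#'
#' @param preset `"desk"` (default) or `"full"`.
#' @return nested configuration list of class `sleepgraph_config`.
#' @export
default_config <- function(preset = c("desk", "full")) {
  preset <- match.arg(preset)
  full <- list(
    data = list(window_s = 30, overlap = 0.5, sample_rate = 44100,
                facial_rate = 10, K = 5L),
    facial = list(mode = "vector", d_in = 64L, d_f = 2048L, d_k = 64L,
                  n_heads = 8L, context_length = 16L,
                  backbone = list(input_shape = c(224L, 224L, 1L), width = 64L,
                                  n_stages = 3L, cardinality = 32L)),
    audio = list(frame_length = 2048L, hop_length = 512L, n_fft = 2048L,
                 window_fn = "hann", n_cepstra = 13L, mel_banks = NULL,
                 wavelet = "db4", wavelet_levels = 8L,
                 wavelet_stats = c("log_energy", "std"), log_floor = 1e-10),
    graph = list(d = 512L, temporal_radius = 3L, connectivity_cap = 0.85,
                 lambda = c(0.4, 0.4, 0.2), gamma_decay = 0.1),
    network = list(hidden_dims = c(512L, 384L, 256L, 128L), scales = 4L,
                   gat_heads = 4L, d_k = 64L, d_omega = 4L),
    temporal = list(gru_dim = 256L, levels = 3L, base_lookback = 2L,
                    kernel = 3L, dilations = c(1L, 2L, 4L, 8L), radius = 16L,
                    pos_table = 128L),
    loss = list(gamma_focal = 2.0, tau = 0.1, beta = 0.5,
                weights = list(cls = 1.0, temp = 0.3, cont = 0.2, rec = 0.1)),
    training = list(optimizer = "adamw", lr = 1e-3, eta_min = 1e-6,
                    eta_max = 1e-3, weight_decay = 1e-4, batch_size = 16L,
                    epochs = 30L, restart_len = 20L, restart_mult = 2,
                    clip_norm = 1.0, ema_decay = 0.99, patience = 10L,
                    ckpt_avg = 3L, dropout = 0.3, head_hidden = 64L),
    seed = 1L,
    schema_version = "1"
  )
  cfg <- full
  if (preset == "desk") {
    cfg$data$sample_rate <- 100
    cfg$data$facial_rate <- 2
    cfg$facial$d_in <- 16L; cfg$facial$d_f <- 16L; cfg$facial$d_k <- 8L
    cfg$facial$n_heads <- 2L
    cfg$facial$backbone <- list(input_shape = c(32L, 32L, 1L), width = 16L,
                                n_stages = 2L, cardinality = 4L)
    cfg$audio$frame_length <- 64L; cfg$audio$hop_length <- 32L
    cfg$audio$n_fft <- 64L; cfg$audio$n_cepstra <- 8L
    cfg$audio$wavelet_levels <- 4L
    cfg$graph$d <- 32L
    cfg$network$hidden_dims <- c(32L, 32L)
    cfg$network$gat_heads <- 2L; cfg$network$d_k <- 8L
    cfg$temporal$gru_dim <- 32L
    cfg$training$head_hidden <- 32L
  }
  structure(c(cfg, list(preset = preset)), class = "sleepgraph_config")
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base)) {
      stop_sg("unknown configuration key: %s", here)
    }
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(user[[nm]])) stop_sg("key %s must be a section", here)
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], here)
    } else {
      base[nm] <- list(user[[nm]])   # keeps explicit NULLs
    }
  }
  base
}

validate_config <- function(cfg) {
  stopifnot(cfg$data$window_s > 0, cfg$data$overlap >= 0, cfg$data$overlap < 1)
  if (cfg$audio$n_fft < cfg$audio$frame_length) {
    stop_sg("config: audio.n_fft must be >= audio.frame_length")
  }
  if (any(unlist(cfg$loss$weights) < 0)) stop_sg("config: loss weights must be >= 0")
  if (cfg$loss$tau <= 0) stop_sg("config: loss.tau must be > 0")
  if (cfg$training$eta_min > cfg$training$eta_max) {
    stop_sg("config: eta_min must be <= eta_max")
  }
  invisible(cfg)
}

#' Load and validate a YAML run configuration
#'
#' Unset keys fall back to the preset defaults; unknown keys are rejected
#' with their full path. Loading the dump of a config reproduces it
#' (idempotent defaulting).
#'
#' @param path YAML file (an empty file yields the full default set).
#' @param preset base preset the file overrides (default `"desk"`).
#' @return validated `sleepgraph_config`.
#' @export
load_config <- function(path, preset = "desk") {
  if (!file.exists(path)) stop_sg("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  base <- default_config(preset)
  if (is.null(user)) return(base)
  if (!is.null(user$preset)) {
    base <- default_config(user$preset)
    user$preset <- NULL
  }
  cfg <- merge_config(unclass(base), user)
  validate_config(structure(cfg, class = "sleepgraph_config"))
}

#' Write a configuration to YAML
#'
#' @param cfg a `sleepgraph_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Stable hash of a configuration (provenance stamping)
#' @param cfg a `sleepgraph_config`.
#' @return character hash.
#' @export
config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(unclass(cfg), give.attr = FALSE)),
             collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251 + 1)) %% 4294967291)
}
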