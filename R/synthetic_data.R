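# Synthetic sleep-session simulator. Generates paired breathing audio and
# facial feature streams with planted, labeled pathology episodes so the
# whole pipeline (features -> graph -> network -> training -> metrics) is
# testable without any recording. Pathology signatures:
#   class 1 (apnea-like)      audio breathing-envelope suppression
#   class 2 (restless)        facial micro-movement bursts
#   class 3 (cardiovascular)  breathing-envelope periodicity perturbation
#   class 4 (emergency)       suppression + bursts combined
# With `crossmodal_xor` on, the highest class is instead identifiable only
# from the joint sign pattern of a facial latent u and an audio latent v
# (u * v = -1 inside the episode, +1 everywhere else; both marginals are
# symmetric, so neither modality alone carries the class).

#' Simulator configuration
#'
#' @param n_sessions number of sessions in a dataset.
#' @param n_windows windows per session.
#' @param window_s window length in seconds (30, with 50% overlap).
#' @param overlap window overlap fraction (0.5).
#' @param sample_rate audio sampling rate in Hz (desk scale 100).
#' @param facial_mode `"vector"` (per-frame feature vectors) or `"image"`
#'   (rendered grayscale blob frames exercising the conv backbone).
#' @param facial_rate facial frame rate in Hz.
#' @param facial_dim facial feature dimension (vector mode).
#' @param image_size side length of rendered frames (image mode).
#' @param K number of classes including normal (default 5).
#' @param event_rate events per hour for each pathological class (scalar or
#'   length `K - 1`).
#' @param event_duration `c(min, max)` episode duration in seconds; episodes
#'   are snapped to the window stride grid and kept non-overlapping.
#' @param suppression breathing-envelope multiplier inside apnea-like
#'   episodes (in (0, 1)).
#' @param burst_magnitude facial burst offset magnitude.
#' @param audio_noise_sd,facial_noise_sd additive Gaussian noise levels.
#' @param tone_amp amplitude of the audio latent carrier tone.
#' @param envelope_freq breathing envelope frequency in Hz (~0.25).
#' @param latent_scale facial latent loading magnitude.
#' @param crossmodal_xor make the highest class cross-modal-only.
#' @return list of class `sleepgraph_sim_config`.
#' @export
sim_config <- function(n_sessions = 10L, n_windows = 60L, window_s = 30,
                       overlap = 0.5, sample_rate = 100, facial_mode = "vector",
                       facial_rate = 10, facial_dim = 16L, image_size = 32L,
                       K = 5L, event_rate = 6, event_duration = c(60, 150),
                       suppression = 0.25, burst_magnitude = 1.5,
                       audio_noise_sd = 0.05, facial_noise_sd = 0.3,
                       tone_amp = 0.4, envelope_freq = 0.25, latent_scale = 1,
                       crossmodal_xor = FALSE) {
  if (any(event_rate < 0)) stop_sg("event rates must be >= 0")
  if (any(event_duration <= 0) || event_duration[1] > event_duration[2]) {
    stop_sg("event durations must be positive with min <= max")
  }
  if (suppression <= 0 || suppression >= 1) stop_sg("suppression must be in (0, 1)")
  if (K < 2L) stop_sg("need at least 2 classes")
  event_rate <- rep_len(event_rate, K - 1L)
  structure(as.list(environment()), class = "sleepgraph_sim_config")
}

#' Desk-scale study configuration for the planted-signal experiment
#'
#' Three classes (normal / apnea-like / cross-modal), 60 windows per session,
#' 100 Hz audio, 2 Hz facial features; the sizes used throughout the package's
#' own studies.
#'
#' @param n_sessions number of sessions (default 40).
#' @return a [sim_config()].
#' @export
desk_study_config <- function(n_sessions = 40L) {
  sim_config(n_sessions = n_sessions, n_windows = 60L, sample_rate = 100,
             facial_rate = 2, facial_dim = 16L, K = 3L, event_rate = 8,
             event_duration = c(60, 150), crossmodal_xor = TRUE,
             audio_noise_sd = 0.05, facial_noise_sd = 0.3)
}

session_windows <- function(cfg) {
  stride <- cfg$window_s * (1 - cfg$overlap)
  tibble::tibble(window = seq_len(cfg$n_windows) - 1L,
                 start = (seq_len(cfg$n_windows) - 1L) * stride,
                 end = (seq_len(cfg$n_windows) - 1L) * stride + cfg$window_s)
}

plant_events <- function(cfg) {
  stride <- cfg$window_s * (1 - cfg$overlap)
  session_s <- cfg$window_s + (cfg$n_windows - 1L) * stride
  hours <- session_s / 3600
  ev <- list()
  for (k in seq_len(cfg$K - 1L)) {
    n_ev <- rpois(1L, cfg$event_rate[k] * hours)
    for (e in seq_len(n_ev)) {
      dur <- stride * max(1L, round(runif(1, cfg$event_duration[1],
                                          cfg$event_duration[2]) / stride))
      for (try in 1:40) {
        start <- stride * floor(runif(1, 0, max(0, (session_s - dur)) / stride))
        end <- start + dur
        clash <- FALSE
        for (x in ev) {
          if (start < x$end + stride && end > x$start - stride) { clash <- TRUE; break }
        }
        if (!clash) { ev[[length(ev) + 1L]] <- list(label = k, start = start, end = end); break }
      }
    }
  }
  if (length(ev) == 0L) {
    return(tibble::tibble(label = integer(0), start = numeric(0), end = numeric(0)))
  }
  out <- dplyr::bind_rows(lapply(ev, tibble::as_tibble))
  dplyr::arrange(out, .data$start)
}

label_windows <- function(windows, events, window_s) {
  lab <- integer(nrow(windows))
  if (nrow(events) > 0) {
    for (i in seq_len(nrow(windows))) {
      ov <- pmin(windows$end[i], events$end) - pmax(windows$start[i], events$start)
      hit <- which(ov >= window_s / 2)
      if (length(hit)) lab[i] <- events$label[hit[which.max(ov[hit])]]
    }
  }
  lab
}

# segment-level latent signs: constant within events and inter-event gaps
segment_latents <- function(cfg, events) {
  stride <- cfg$window_s * (1 - cfg$overlap)
  session_s <- cfg$window_s + (cfg$n_windows - 1L) * stride
  n_seg <- ceiling(session_s / stride)
  seg_start <- (seq_len(n_seg) - 1L) * stride
  xor_label <- if (cfg$crossmodal_xor) cfg$K - 1L else -1L
  ev_id <- vapply(seg_start, function(s0) {
    hit <- which(events$start <= s0 & events$end > s0)
    if (length(hit)) hit[1] else 0L
  }, integer(1))
  r <- rle(ev_id)
  run_id <- rep(seq_along(r$values), r$lengths)
  in_xor <- ev_id > 0 & events$label[pmax(ev_id, 1L)] == xor_label
  u_run <- sample(c(-1, 1), max(run_id), replace = TRUE)
  u <- u_run[run_id]
  v <- ifelse(in_xor, -u, u)
  tibble::tibble(segment = seq_len(n_seg) - 1L, start = seg_start,
                 u = u, v = v, in_xor = in_xor)
}

render_blob_frame <- function(size, u, burst) {
  # grayscale blob whose horizontal offset encodes the latent sign and whose
  # spread encodes bursts
  cx <- size / 2 + u * size / 6
  cy <- size / 2
  sd <- size / 10 * (1 + 0.6 * burst)
  g <- outer(seq_len(size), seq_len(size), function(y, x) {
    exp(-((x - cx)^2 + (y - cy)^2) / (2 * sd^2))
  })
  g / max(g)
}

#' Simulate one sleep session
#'
#' Baseline audio is breathing-band noise under a ~0.25 Hz periodic envelope
#' plus a latent carrier tone and Gaussian noise; facial frames carry a
#' latent loading on their first half dimensions plus burst offsets on the
#' second half. Episodes are planted per class (see the class table above),
#' labels follow the >= 50% window-overlap rule, and identical
#' (config, seed) pairs reproduce the session bit for bit.
#'
#' @param cfg a [sim_config()].
#' @param seed session seed.
#' @return object of class `sleepgraph_session`: `audio`, `sample_rate`,
#'   `facial` (matrix or list of frames), `facial_times`, `windows` (with
#'   per-window `label`), `events`, `latents`, `seed`.
#' @export
simulate_session <- function(cfg, seed = 1L) {
  if (!inherits(cfg, "sleepgraph_sim_config")) stop_sg("cfg must be a sim_config()")
  with_seed(seed, {
    stride <- cfg$window_s * (1 - cfg$overlap)
    session_s <- cfg$window_s + (cfg$n_windows - 1L) * stride
    windows <- session_windows(cfg)
    events <- plant_events(cfg)
    windows$label <- label_windows(windows, events, cfg$window_s)
    lat <- segment_latents(cfg, events)

    # ---- audio ----
    n <- round(session_s * cfg$sample_rate)
    t <- (seq_len(n) - 1L) / cfg$sample_rate
    seg_of <- pmin(floor(t / stride), nrow(lat) - 1L) + 1L
    env_freq <- rep(cfg$envelope_freq, n)
    suppress <- rep(1, n)
    burst_on <- rep(0, n)
    if (nrow(events) > 0) {
      for (e in seq_len(nrow(events))) {
        idx <- t >= events$start[e] & t < events$end[e]
        lb <- events$label[e]
        xor_class <- cfg$crossmodal_xor && lb == cfg$K - 1L
        if (!xor_class) {
          if (lb == 1L || lb == 4L) suppress[idx] <- cfg$suppression
          if (lb == 3L) env_freq[idx] <- cfg$envelope_freq * 2
          if (lb == 2L || lb == 4L) burst_on[idx] <- 1
        }
      }
    }
    phase <- 2 * pi * cumsum(env_freq) / cfg$sample_rate
    envelope <- (0.7 + 0.3 * sin(phase)) * suppress
    breath <- as.numeric(stats::filter(rnorm(n), rep(1 / 4, 4), sides = 1))
    breath[is.na(breath)] <- 0
    tone_freq <- ifelse(lat$v[seg_of] > 0, 0.2, 0.4) * cfg$sample_rate
    tone <- cfg$tone_amp * sin(pi * tone_freq * t)   # tone_freq is 2f here
    audio <- envelope * breath + tone + rnorm(n, sd = cfg$audio_noise_sd)

    # ---- facial ----
    n_fr <- max(1L, round(session_s * cfg$facial_rate))
    f_times <- (seq_len(n_fr) - 1L) / cfg$facial_rate
    f_seg <- pmin(floor(f_times / stride), nrow(lat) - 1L) + 1L
    u_fr <- lat$u[f_seg]
    burst_fr <- burst_on[pmin(n, floor(f_times * cfg$sample_rate) + 1L)]
    if (cfg$facial_mode == "vector") {
      d <- cfg$facial_dim
      half <- d %/% 2L
      load <- c(rep(1, half), rep(0, d - half)) / sqrt(half)
      burst_dir <- c(rep(0, half), rep(1, d - half)) / sqrt(d - half)
      facial <- outer(u_fr * cfg$latent_scale, load) +
        outer(burst_fr * cfg$burst_magnitude * abs(rnorm(n_fr)), burst_dir) +
        matrix(rnorm(n_fr * d, sd = cfg$facial_noise_sd), n_fr, d)
    } else {
      facial <- lapply(seq_len(n_fr), function(i) {
        fr <- render_blob_frame(cfg$image_size, u_fr[i], burst_fr[i]) +
          matrix(rnorm(cfg$image_size^2, sd = cfg$facial_noise_sd / 4),
                 cfg$image_size)
        fr[fr < 0] <- 0
        fr[fr > 1] <- 1
        fr
      })
    }
    structure(list(audio = audio, sample_rate = cfg$sample_rate,
                   facial = facial, facial_times = f_times,
                   windows = windows, events = events, latents = lat,
                   stride = stride, session_s = session_s,
                   facial_mode = cfg$facial_mode, seed = seed,
                   K = cfg$K, config = cfg),
              class = "sleepgraph_session")
  })
}

#' @export
print.sleepgraph_session <- function(x, ...) {
  cat(sprintf("<sleepgraph session> %.0f s, %d windows, %d events, seed %d\n",
              x$session_s, nrow(x$windows), nrow(x$events), x$seed))
  cat("  window labels:", paste(table(factor(x$windows$label, 0:(x$K - 1))),
                                collapse = "/"), "\n")
  invisible(x)
}

#' Simulate a stratified dataset of sessions
#'
#' Generates `cfg$n_sessions` sessions from per-session seeds derived from the
#' master seed, then splits them 70/15/15 (floor rule, remainder to train)
#' stratified by each session's dominant pathological class.
#'
#' @param cfg a [sim_config()] with `n_sessions >= 10`.
#' @param seed master seed; every session seed derives from it.
#' @return list with `sessions` (list of [simulate_session()] results) and
#'   `manifest` (tibble: `session`, `seed`, `split`, `dominant_class`,
#'   `n_events`).
#' @export
make_dataset <- function(cfg, seed = 1L) {
  if (cfg$n_sessions < 10L) stop_sg("make_dataset: need n_sessions >= 10")
  if (cfg$n_sessions < cfg$K) stop_sg("fewer sessions than classes")
  seeds <- vapply(seq_len(cfg$n_sessions), function(i) {
    derive_seed(seed, paste0("session", i))
  }, integer(1))
  sessions <- lapply(seeds, function(s) simulate_session(cfg, s))
  dom <- vapply(sessions, function(s) {
    tab <- table(factor(s$windows$label, levels = 0:(cfg$K - 1L)))[-1]
    if (sum(tab) == 0) 0L else as.integer(names(tab)[which.max(tab)])
  }, integer(1))
  n <- cfg$n_sessions
  n_val <- floor(0.15 * n); n_test <- floor(0.15 * n)
  split_lab <- rep("train", n)
  # shuffle within strata, then take evenly spaced positions across the
  # stratum-ordered list so val/test sample every stratum
  ord <- with_seed(derive_seed(seed, "split"), {
    unlist(lapply(base::split(seq_len(n), dom), sample), use.names = FALSE)
  })
  pick <- ord[round(seq(1L, n, length.out = n_val + n_test))]
  split_lab[pick] <- rep(c("val", "test"), length.out = n_val + n_test)
  manifest <- tibble::tibble(session = seq_len(n), seed = seeds, split = split_lab,
                             dominant_class = dom,
                             n_events = vapply(sessions, function(s) nrow(s$events),
                                               integer(1)))
  list(sessions = sessions, manifest = manifest)
}

#' Write a dataset manifest to JSON
#' @param dataset result of [make_dataset()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(dataset, path) {
  jsonlite::write_json(dataset$manifest, path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
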