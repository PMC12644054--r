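# Acoustic feature extraction. Each frame of breathing audio is summarized by
# cepstral coefficients of the log power spectrum, zero-crossing rate, RMS
# energy, the spectral centroid and spread (second central moment over bin
# index), and per-scale wavelet summaries; the per-frame vector a_t is their
# fixed-order concatenation.

window_taper <- function(n, window_fn = c("hann", "rect", "hamming")) {
  window_fn <- match.arg(window_fn)
  k <- seq_len(n) - 1L
  switch(window_fn,
    rect = rep(1, n),
    hann = 0.5 - 0.5 * cos(2 * pi * k / n),
    hamming = 0.54 - 0.46 * cos(2 * pi * k / n)
  )
}

#' Slice a signal into equal-length frames
#'
#' Frames of `frame_length` samples every `hop_length` samples; the tail frame
#' is zero-padded so all frames have equal length.
#'
#' @param samples numeric waveform.
#' @param frame_length,hop_length frame and hop sizes in samples (both > 0).
#' @return a `frame_length` x `n_frames` matrix (columns are frames).
#' @export
frame_signal <- function(samples, frame_length, hop_length) {
  if (frame_length <= 0 || hop_length <= 0) {
    stop_sg("frame_length and hop_length must be positive")
  }
  n <- length(samples)
  if (n == 0L) return(matrix(numeric(0), frame_length, 0L))
  n_frames <- max(1L, ceiling((n - frame_length) / hop_length) + 1L)
  padded <- c(samples, numeric(max(0L, (n_frames - 1L) * hop_length +
                                     frame_length - n)))
  idx <- outer(seq_len(frame_length),
               (seq_len(n_frames) - 1L) * hop_length, `+`)
  matrix(padded[idx], frame_length, n_frames)
}

#' Short-time Fourier transform
#'
#' Frames the signal, applies a taper, zero-pads each frame to `n_fft` and
#' returns the one-sided complex spectrogram.
#'
#' @param samples numeric waveform.
#' @param frame_length,hop_length framing parameters in samples.
#' @param n_fft FFT size, `>= frame_length`.
#' @param window_fn taper name (default `"hann"`).
#' @param sample_rate optional; attaches frequency/time axes when given.
#' @param on_empty `"error"` (default) or `"empty"` for a zero-length signal.
#' @return list with `spec` (n_frames x bins complex matrix,
#'   `bins = n_fft/2 + 1`), `freq`, `time`, and the framing parameters.
#' @export
stft <- function(samples, frame_length, hop_length, n_fft = frame_length,
                 window_fn = "hann", sample_rate = NULL,
                 on_empty = c("error", "empty")) {
  on_empty <- match.arg(on_empty)
  if (n_fft < frame_length) stop_sg("n_fft (%d) must be >= frame_length (%d)",
                                    n_fft, frame_length)
  if (length(samples) == 0L) {
    if (on_empty == "error") stop_sg("stft: empty signal")
    return(list(spec = matrix(complex(0), 0L, n_fft %/% 2L + 1L),
                freq = NULL, time = numeric(0),
                frame_length = frame_length, hop_length = hop_length,
                n_fft = n_fft))
  }
  if (any(!is.finite(samples))) stop_sg("stft: nonfinite samples")
  frames <- frame_signal(samples, frame_length, hop_length)
  w <- window_taper(frame_length, window_fn)
  tapered <- frames * w
  if (n_fft > frame_length) {
    tapered <- rbind(tapered, matrix(0, n_fft - frame_length, ncol(tapered)))
  }
  full <- stats::mvfft(tapered)
  bins <- n_fft %/% 2L + 1L
  spec <- t(full[seq_len(bins), , drop = FALSE])
  freq <- if (!is.null(sample_rate)) (seq_len(bins) - 1L) * sample_rate / n_fft
  time <- if (!is.null(sample_rate)) {
    ((seq_len(ncol(frames)) - 1L) * hop_length + frame_length / 2) / sample_rate
  } else seq_len(ncol(frames)) - 1
  list(spec = spec, freq = freq, time = time, frame_length = frame_length,
       hop_length = hop_length, n_fft = n_fft, window_fn = window_fn)
}

#' Zero-crossing rate of a frame
#'
#' `(1/2N) * sum |sgn(a[n]) - sgn(a[n-1])|` over adjacent samples, with the
#' convention `sgn(0) = 0` so a sample touching zero contributes two
#' half-crossings. Bounded in `[0, (N-1)/N]`.
#'
#' @param frame numeric vector with at least two samples.
#' @return the rate.
#' @export
zero_crossing_rate <- function(frame) {
  n <- length(frame)
  if (n < 2L) stop_sg("zero_crossing_rate: need at least 2 samples")
  s <- sign(frame)
  sum(abs(diff(s))) / (2 * n)
}

#' Root-mean-square energy of a frame
#'
#' @param frame numeric vector with at least one sample.
#' @return `sqrt(mean(frame^2))`, nonnegative.
#' @export
rms_energy <- function(frame) {
  if (length(frame) < 1L) stop_sg("rms_energy: empty frame")
  sqrt(mean(frame^2))
}

#' Spectral centroid and spread of a magnitude spectrum
#'
#' First moment (centroid, `SC`) and second central moment (`SRO`) of the
#' magnitude spectrum over bin index. Both are invariant under positive
#' scaling of the spectrum. `SRO` is the second central moment itself (no
#' square root); `spectral_spread` is an alias for the same quantity.
#'
#' @param mag_spectrum nonnegative magnitude spectrum.
#' @param bins bin coordinates; defaults to 0-based indices.
#' @return named list with `sc` and `sro`. An all-zero spectrum returns the
#'   sentinel `sc = 0, sro = 0` with a warning.
#' @export
spectral_shape <- function(mag_spectrum, bins = seq_along(mag_spectrum) - 1) {
  if (any(mag_spectrum < 0)) stop_sg("spectral_shape: negative magnitudes")
  total <- sum(mag_spectrum)
  if (total == 0) {
    warn_sg("spectral_shape: all-zero spectrum; returning sc = 0, sro = 0")
    return(list(sc = 0, sro = 0))
  }
  sc <- sum(bins * mag_spectrum) / total
  sro <- sum((bins - sc)^2 * mag_spectrum) / total
  list(sc = sc, sro = sro)
}

#' @rdname spectral_shape
#' @export
spectral_spread <- function(mag_spectrum, bins = seq_along(mag_spectrum) - 1) {
  spectral_shape(mag_spectrum, bins)$sro
}

dct_ii <- function(x) {
  # orthonormal DCT-II
  n <- length(x)
  k <- seq_len(n) - 1L
  m <- cos(pi / n * outer(k, (seq_len(n) - 0.5)))
  coef <- as.numeric(m %*% x)
  coef * c(sqrt(1 / n), rep(sqrt(2 / n), n - 1L))
}

#' Triangular mel filterbank matrix
#'
#' @param n_banks number of triangular filters.
#' @param n_bins number of (one-sided) spectrum bins.
#' @param sample_rate sampling rate in Hz.
#' @param n_fft FFT size the bins came from.
#' @return `n_banks` x `n_bins` matrix of filter weights.
#' @export
mel_filterbank <- function(n_banks, n_bins, sample_rate, n_fft = 2L * (n_bins - 1L)) {
  hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
  mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
  fmax <- sample_rate / 2
  mel_pts <- seq(0, hz_to_mel(fmax), length.out = n_banks + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  bin_f <- (seq_len(n_bins) - 1L) * sample_rate / n_fft
  fb <- matrix(0, n_banks, n_bins)
  for (b in seq_len(n_banks)) {
    lo <- hz_pts[b]; mid <- hz_pts[b + 1L]; hi <- hz_pts[b + 2L]
    up <- (bin_f - lo) / max(mid - lo, 1e-12)
    down <- (hi - bin_f) / max(hi - mid, 1e-12)
    fb[b, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Cepstral coefficients of a power spectrum
#'
#' DCT-II of the floored log power spectrum, truncated to the first
#' `n_cepstra` coefficients. With `mel_banks` set, the power spectrum is first
#' pooled through a triangular mel filterbank (MFCC-style).
#'
#' @param power_spectrum nonnegative power spectral density over bins.
#' @param n_cepstra number of coefficients to keep.
#' @param floor lower clamp applied before the log (default `1e-10`).
#' @param mel_banks optional number of mel filters (requires `sample_rate`).
#' @param sample_rate,n_fft needed only in the mel mode.
#' @return numeric vector of length `n_cepstra`.
#' @export
cepstral_coefficients <- function(power_spectrum, n_cepstra, floor = 1e-10,
                                  mel_banks = NULL, sample_rate = NULL,
                                  n_fft = NULL) {
  if (any(!is.finite(power_spectrum))) {
    stop_sg("cepstral_coefficients: nonfinite power spectrum")
  }
  if (any(power_spectrum < 0)) {
    stop_sg("cepstral_coefficients: negative power spectrum")
  }
  x <- power_spectrum
  if (!is.null(mel_banks)) {
    if (is.null(sample_rate)) stop_sg("mel mode requires sample_rate")
    fb <- mel_filterbank(mel_banks, length(x), sample_rate,
                         n_fft %||% (2L * (length(x) - 1L)))
    x <- as.numeric(fb %*% x)
  }
  if (n_cepstra > length(x)) {
    stop_sg("n_cepstra (%d) exceeds available bands (%d)", n_cepstra, length(x))
  }
  dct_ii(log(pmax(x, floor)))[seq_len(n_cepstra)]
}

#' Per-scale wavelet summaries of a frame
#'
#' Multi-level DWT of the frame ([dwt()]); each of the `J` detail bands and
#' the final approximation band is summarized by the configured statistics
#' (default log-energy and population standard deviation), giving
#' `length(stats) * (J + 1)` values. Frames whose length is not a multiple of
#' `2^J` are zero-padded to the next multiple.
#'
#' @param frame numeric vector, `length(frame) >= 2^levels`.
#' @param wavelet `"db4"` or `"haar"`.
#' @param levels decomposition depth `J`.
#' @param stats summary statistics per band, subset of
#'   `c("log_energy", "std")`.
#' @return named numeric vector, band-major order (detail 1..J, then approx).
#' @export
wavelet_features <- function(frame, wavelet = "db4", levels = 8L,
                             stats = c("log_energy", "std")) {
  need <- 2^levels
  if (length(frame) < need) {
    stop_sg("wavelet_features: frame length %d < required %d (= 2^%d)",
            length(frame), need, levels)
  }
  stats <- match.arg(stats, c("log_energy", "std"), several.ok = TRUE)
  n <- length(frame)
  if (n %% need != 0L) frame <- c(frame, numeric(need * ceiling(n / need) - n))
  w <- dwt(frame, wavelet, levels)
  bands <- c(w$details, list(w$approx))
  names(bands) <- c(paste0("d", seq_len(levels)), "a")
  out <- unlist(lapply(names(bands), function(bn) {
    x <- bands[[bn]]
    vals <- c(
      log_energy = log(sum(x^2) + 1e-12),
      std = sqrt(mean((x - mean(x))^2))
    )[stats]
    setNames(vals, paste0("wav_", bn, "_", stats))
  }))
  out
}

#' Assemble the per-frame audio feature vector
#'
#' Fixed concatenation `a_t = [C_t; ZCR_t; RMS_t; SC_t; SRO_t; W_{1:J,t}]`.
#' The parts must arrive as a named list in exactly this order; a reordered or
#' misnamed list is rejected by the schema check.
#'
#' @param parts named list with elements `cepstra`, `zcr`, `rms`, `sc`, `sro`,
#'   `wavelet` (in that order).
#' @param d_a optional declared total length; a mismatch is an error.
#' @return named numeric vector `a_t`.
#' @export
assemble_audio_features <- function(parts, d_a = NULL) {
  schema <- c("cepstra", "zcr", "rms", "sc", "sro", "wavelet")
  if (!identical(names(parts), schema)) {
    stop_sg("assemble_audio_features: parts must be named exactly %s in order; got %s",
            paste(schema, collapse = ", "),
            paste(names(parts) %||% "<unnamed>", collapse = ", "))
  }
  for (nm in c("zcr", "rms", "sc", "sro")) {
    if (length(parts[[nm]]) != 1L) stop_sg("part '%s' must be scalar", nm)
  }
  a <- c(setNames(as.numeric(parts$cepstra),
                  paste0("cep", seq_along(parts$cepstra) - 1L)),
         zcr = parts$zcr, rms = parts$rms, sc = parts$sc, sro = parts$sro,
         if (is.null(names(parts$wavelet))) {
           setNames(as.numeric(parts$wavelet),
                    paste0("wav", seq_along(parts$wavelet)))
         } else parts$wavelet)
  if (!is.null(d_a) && length(a) != d_a) {
    stop_sg("assembled feature length %d != declared d_a = %d", length(a), d_a)
  }
  a
}

#' Per-frame audio features for a waveform
#'
#' Runs the full acoustic pipeline: STFT, per-frame ZCR/RMS, spectral
#' centroid/spread, cepstra of the (optionally mel-pooled) power spectrum,
#' and wavelet band summaries, returning one row per STFT frame.
#'
#' @param samples numeric waveform.
#' @param sample_rate sampling rate in Hz.
#' @param cfg audio configuration list (see [default_config()] `$audio`):
#'   `frame_length`, `hop_length`, `n_fft`, `window_fn`, `n_cepstra`,
#'   `log_floor`, `wavelet`, `wavelet_levels`, `wavelet_stats`, `mel_banks`
#'   (`NULL` for raw-PSD cepstra).
#' @return a tibble with columns `frame`, `time` and one column per feature;
#'   attribute `d_a` records the feature dimension.
#' @export
audio_frame_features <- function(samples, sample_rate, cfg) {
  sp <- stft(samples, cfg$frame_length, cfg$hop_length, cfg$n_fft,
             cfg$window_fn %||% "hann", sample_rate)
  frames <- frame_signal(samples, cfg$frame_length, cfg$hop_length)
  n_frames <- ncol(frames)
  mag <- abs(sp$spec)                      # n_frames x bins
  psd <- mag^2
  zcr <- apply(frames, 2L, zero_crossing_rate)
  rms <- sqrt(colMeans(frames^2))
  tot <- rowSums(mag)
  bins <- seq_len(ncol(mag)) - 1
  sc <- ifelse(tot > 0, as.numeric(mag %*% bins) / tot, 0)
  sro <- vapply(seq_len(n_frames), function(i) {
    if (tot[i] == 0) return(0)
    sum((bins - sc[i])^2 * mag[i, ]) / tot[i]
  }, numeric(1))
  cep <- t(vapply(seq_len(n_frames), function(i) {
    cepstral_coefficients(psd[i, ], cfg$n_cepstra, cfg$log_floor %||% 1e-10,
                          mel_banks = cfg$mel_banks, sample_rate = sample_rate,
                          n_fft = cfg$n_fft)
  }, numeric(cfg$n_cepstra)))
  wav <- t(vapply(seq_len(n_frames), function(i) {
    wavelet_features(frames[, i], cfg$wavelet %||% "db4",
                     cfg$wavelet_levels, cfg$wavelet_stats %||% c("log_energy", "std"))
  }, wavelet_features(frames[, 1], cfg$wavelet %||% "db4",
                      cfg$wavelet_levels,
                      cfg$wavelet_stats %||% c("log_energy", "std"))))
  feats <- cbind(cep, zcr = zcr, rms = rms, sc = sc, sro = sro, wav)
  colnames(feats)[seq_len(cfg$n_cepstra)] <- paste0("cep", seq_len(cfg$n_cepstra) - 1L)
  out <- tibble::as_tibble(as.data.frame(feats))
  out <- dplyr::bind_cols(tibble::tibble(frame = seq_len(n_frames) - 1L,
                                         time = sp$time), out)
  attr(out, "d_a") <- ncol(feats)
  attr(out, "sample_rate") <- sample_rate
  out
}

#' Window-level audio features
#'
#' Aggregates per-frame features ([audio_frame_features()]) to the session's
#' analysis windows by averaging the frames whose centers fall inside each
#' half-open window `[start, end)`.
#'
#' @param samples numeric waveform.
#' @param sample_rate sampling rate in Hz.
#' @param windows tibble with `window`, `start`, `end` (seconds).
#' @param cfg audio configuration list.
#' @return tibble with `window` and one column per feature (the window-level
#'   `a_t`); attribute `d_a` as in [audio_frame_features()].
#' @export
window_audio_features <- function(samples, sample_rate, windows, cfg) {
  ff <- audio_frame_features(samples, sample_rate, cfg)
  feat_cols <- setdiff(names(ff), c("frame", "time"))
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    sel <- ff$time >= windows$start[i] & ff$time < windows$end[i]
    if (!any(sel)) sel <- which.min(abs(ff$time - (windows$start[i] + windows$end[i]) / 2))
    colMeans(ff[sel, feat_cols, drop = FALSE])
  })
  out <- dplyr::bind_cols(tibble::tibble(window = windows$window),
                          tibble::as_tibble(do.call(rbind, rows)))
  attr(out, "d_a") <- length(feat_cols)
  out
}
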