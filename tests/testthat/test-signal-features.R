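test_that("zero-crossing rate matches the hand-evaluated definition and its bounds", {
  expect_equal(zero_crossing_rate(c(2, 2, 2, 2)), 0)
  expect_equal(zero_crossing_rate(c(1, -1, 1, -1)), 0.75)
  expect_equal(zero_crossing_rate(c(1, 1, -1, -1)), 0.25)
  # sgn(0) = 0: touching zero contributes two half-crossings
  expect_equal(zero_crossing_rate(c(1, 0, -1)), (1 + 1) / (2 * 3))
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(4:64, 1))
    z <- zero_crossing_rate(x)
    expect_gte(z, 0)
    expect_lte(z, (length(x) - 1) / length(x))
    expect_equal(zero_crossing_rate(rev(x)), z)
  }
  expect_error(zero_crossing_rate(1), "at least 2")
})

test_that("RMS energy matches closed forms and is reversal invariant", {
  expect_equal(rms_energy(rep(-3, 10)), 3)
  expect_equal(rms_energy(c(3, 4)), sqrt(12.5))
  t <- seq(0, 1, length.out = 1001)[-1001]   # exactly 2 periods at 2 Hz
  expect_equal(rms_energy(sin(2 * pi * 2 * t)), 1 / sqrt(2), tolerance = 1e-6)
  set.seed(12)
  x <- rnorm(50)
  expect_equal(rms_energy(rev(x)), rms_energy(x))
})

test_that("spectral centroid and spread match point-mass and two-bin hand values", {
  one_hot <- c(0, 0, 0, 1, 0)
  sh <- spectral_shape(one_hot)
  expect_equal(sh$sc, 3)
  expect_equal(sh$sro, 0)
  two <- c(0, 1, 1, 0)
  sh2 <- spectral_shape(two)
  expect_equal(sh2$sc, 1.5)
  expect_equal(sh2$sro, 0.25)
  # positive scale invariance
  set.seed(13)
  m <- abs(rnorm(16))
  a <- spectral_shape(m); b <- spectral_shape(7.3 * m)
  expect_equal(a$sc, b$sc)
  expect_equal(a$sro, b$sro)
  expect_equal(spectral_spread(two), 0.25)
  expect_warning(z <- spectral_shape(numeric(8)), "all-zero")
  expect_equal(z, list(sc = 0, sro = 0))
})

test_that("cepstral coefficients are the DCT-II of the floored log spectrum", {
  flat <- cepstral_coefficients(rep(2.5, 16), 16)
  expect_equal(flat[-1], rep(0, 15), tolerance = 1e-12)
  expect_gt(abs(flat[1]), 0)
  # Table-default 13 coefficients from a 1025-bin spectrum
  set.seed(14)
  ps <- abs(rnorm(1025))^2
  expect_length(cepstral_coefficients(ps, 13), 13)
  # log-linearity: doubling the spectrum shifts only coefficient 0
  c1 <- cepstral_coefficients(ps, 13)
  c2 <- cepstral_coefficients(2 * ps, 13)
  expect_equal(c2[-1], c1[-1], tolerance = 1e-10)
  expect_equal(c2[1] - c1[1], sqrt(1 / 1025) * 1025 * log(2), tolerance = 1e-8)
  expect_error(cepstral_coefficients(c(1, NA, 2), 2), "nonfinite")
  expect_error(cepstral_coefficients(rep(1, 4), 5), "exceeds")
})

test_that("mel-pooled cepstra have the configured length and differ from raw-PSD cepstra", {
  set.seed(15)
  ps <- abs(rnorm(257))^2
  mel <- cepstral_coefficients(ps, 13, mel_banks = 40, sample_rate = 8000, n_fft = 512)
  expect_length(mel, 13)
  raw <- cepstral_coefficients(ps, 13)
  expect_false(isTRUE(all.equal(mel, raw)))
})

test_that("multi-level DWT reconstructs exactly and Haar annihilates constants", {
  set.seed(16)
  for (wavelet in c("haar", "db4")) {
    x <- rnorm(64)
    w <- dwt(x, wavelet, 4)
    expect_equal(idwt(w), x, tolerance = 1e-10)
  }
  wc <- dwt(rep(3.2, 32), "haar", 3)
  for (d in wc$details) expect_equal(d, rep(0, length(d)), tolerance = 1e-12)
  expect_error(dwt(rnorm(8), "haar", 4), "too short")
})

test_that("wavelet band summaries have the configured layout", {
  # J = 8 with log-energy + std -> 2 * 9 = 18 values
  set.seed(17)
  f <- wavelet_features(rnorm(256), "db4", 8)
  expect_length(f, 18)
  cf <- wavelet_features(rep(1, 64), "haar", 4)
  detail_energy <- cf[grepl("^wav_d\\d+_log_energy$", names(cf))]
  expect_true(all(detail_energy <= log(1e-11)))  # zero energy up to the eps floor
  expect_error(wavelet_features(rnorm(8), "haar", 4), "length 8 < required 16")
})

test_that("STFT agrees with a direct DFT oracle and satisfies Parseval", {
  # all-zero signal -> all-zero spectrum
  z <- stft(numeric(64), 32, 16, window_fn = "rect")
  expect_true(all(abs(z$spec) == 0))
  expect_equal(ncol(z$spec), 17)

  # pure cosine at exact bin k0 under a rectangular window concentrates there
  n <- 64; k0 <- 5
  x <- cos(2 * pi * k0 * (0:(n - 1)) / n)
  sp <- stft(x, n, n, window_fn = "rect")
  mag <- abs(sp$spec[1, ])
  expect_equal(which.max(mag) - 1L, k0)
  expect_equal(mag[k0 + 1], n / 2, tolerance = 1e-8)
  expect_lt(max(mag[-(k0 + 1)]), 1e-8)
  # one-sided spectrum matches the direct DFT oracle bin by bin
  expect_equal(sp$spec[1, ], dft_direct(x)[1:33], tolerance = 1e-8)

  # Parseval on random rectangular frames (one-sided accounting)
  set.seed(18)
  for (i in 1:5) {
    fr <- rnorm(64)
    X <- stft(fr, 64, 64, window_fn = "rect")$spec[1, ]
    lhs <- sum(fr^2)
    rhs <- (Mod(X[1])^2 + 2 * sum(Mod(X[2:32])^2) + Mod(X[33])^2) / 64
    expect_equal(rhs, lhs, tolerance = 1e-8)
  }
  expect_error(stft(numeric(0), 32, 16), "empty")
  e <- stft(numeric(0), 32, 16, on_empty = "empty")
  expect_equal(nrow(e$spec), 0)
})

test_that("feature assembly enforces the fixed concatenation schema", {
  parts <- list(cepstra = rnorm(13), zcr = 0.1, rms = 0.5, sc = 3.2, sro = 1.1,
                wavelet = rnorm(18))
  a <- assemble_audio_features(parts, d_a = 35)
  expect_length(a, 35)
  expect_equal(names(a)[1], "cep0")
  expect_equal(names(a)[14:17], c("zcr", "rms", "sc", "sro"))
  expect_error(assemble_audio_features(rev(parts)), "in order")
  expect_error(assemble_audio_features(parts, d_a = 40), "declared d_a")
})

test_that("feature extraction is a pure function of its input", {
  set.seed(19)
  x <- rnorm(4000)
  cfg <- list(frame_length = 64, hop_length = 32, n_fft = 64, n_cepstra = 8,
              wavelet = "db4", wavelet_levels = 4, mel_banks = NULL,
              log_floor = 1e-10)
  f1 <- audio_frame_features(x, 100, cfg)
  f2 <- audio_frame_features(x, 100, cfg)
  expect_identical(f1, f2)
  expect_equal(attr(f1, "d_a"), 8 + 4 + 10)
  expect_true(all(is.finite(as.matrix(f1))))
})
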