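test_that("silence removal keeps speech, drops pauses, and is idempotent", {
  silent <- remove_silence(audio_clip(numeric(24000), 48000))
  expect_length(silent$samples, 0)
  expect_true(attr(silent, "silent"))

  tone <- make_sine_clip(200, duration_s = 0.5)
  kept <- remove_silence(tone)
  expect_equal(length(kept), length(tone))

  gap <- audio_clip(c(make_sine_clip(200, 1)$samples, numeric(48000),
                      make_sine_clip(200, 1)$samples), 48000)
  out <- remove_silence(gap)
  # boundary frames straddling the tone edge are kept, so the recovered
  # length can exceed 2 s by up to a frame plus a hop per edge
  edge <- round(0.030 * 48000) + round(0.010 * 48000)
  expect_lt(abs(length(out) - 96000), 2 * edge)
  # idempotent and never longer
  again <- remove_silence(out)
  expect_lte(length(again), length(out))
  expect_lt(length(out) - length(again), 2 * edge)
  expect_error(remove_silence(audio_clip(numeric(0))), class = "cogscreen_domain_error")
})

test_that("pitch estimators recover pure and harmonic fundamentals", {
  tone <- make_sine_clip(220, duration_s = 0.6)
  p_ncf <- pitch(tone, "ncf")
  expect_lt(abs(median(p_ncf$f0_hz[p_ncf$voiced]) - 220), 1)
  expect_gt(mean(p_ncf$voiced), 0.9)

  t <- seq_len(28800) / 48000
  harm <- audio_clip(0.5 * sin(2 * pi * 150 * t) + 0.3 * sin(2 * pi * 300 * t) +
                       0.2 * sin(2 * pi * 450 * t), 48000)
  p_cep <- pitch(harm, "cep")
  expect_lt(abs(median(p_cep$f0_hz[p_cep$voiced]) - 150), 2)
  for (m in c("pef", "lhs", "srh")) {
    pm <- pitch(harm, m)
    expect_lt(abs(median(pm$f0_hz[pm$voiced]) - 150), 3)
  }

  set.seed(3)
  noise <- audio_clip(rnorm(24000, 0, 0.3), 48000)
  p_noise <- pitch(noise, "ncf")
  expect_lt(mean(p_noise$voiced), 0.5)
  expect_error(pitch(audio_clip(numeric(0))), class = "cogscreen_domain_error")
})

test_that("amplitude scaling is a level shift confined to cepstral coefficient 0", {
  t <- seq_len(14400) / 48000
  vowel <- audio_clip(0.4 * sin(2 * pi * 140 * t) + 0.25 * sin(2 * pi * 280 * t) +
                        0.15 * sin(2 * pi * 560 * t) + 0.08 * sin(2 * pi * 1120 * t),
                      48000)
  for (fn in list(mfcc, gtcc)) {
    base <- fn(vowel)
    scaled <- fn(audio_clip(vowel$samples * 2, vowel$rate_hz))
    diff0 <- scaled[1, ] - base[1, ]
    expect_lt(diff(range(diff0)), 1e-6)            # coefficient 0: constant shift
    expect_gt(mean(diff0), 0.1)
    expect_lt(max(abs(scaled[-1, ] - base[-1, ])), 1e-6)
  }
})

test_that("cepstral coefficients have the documented shape and match the direct oracle", {
  t <- seq_len(9600) / 48000
  vowel <- audio_clip(0.5 * sin(2 * pi * 150 * t) + 0.2 * sin(2 * pi * 450 * t), 48000)
  spec <- frame_spec()
  m <- mfcc(vowel, 13, spec)
  flen <- round(0.030 * 48000); hop <- round(0.010 * 48000)
  expect_identical(dim(m), c(13L, as.integer(floor((9600 - flen) / hop) + 1)))

  # independent direct computation of frame 3: window -> FFT -> mel bank ->
  # log -> orthonormal DCT
  k <- 3
  fr <- vowel$samples[((k - 1) * hop + 1):((k - 1) * hop + flen)]
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(flen) - 1) / (flen - 1))
  nfft <- 2^ceiling(log2(flen))
  mag <- Mod(fft(c(fr * w, numeric(nfft - flen))))[1:(nfft / 2 + 1)]
  fb <- cogscreen:::mel_filterbank(26, nfft, 48000)
  fbe <- log(as.numeric(fb %*% mag) + 1e-12)
  dct <- sapply(0:25, function(n) cos(pi * (0:12) * (2 * n + 1) / 52)) * sqrt(2 / 26)
  dct[1, ] <- dct[1, ] / sqrt(2)
  expect_equal(as.numeric(m[, k]), as.numeric(dct %*% fbe), tolerance = 1e-4)
})

test_that("spectral descriptors satisfy the point-spectrum and flat-spectrum identities", {
  tone <- make_sine_clip(1000, duration_s = 0.3)
  sd_tone <- spectral_descriptors(tone)
  bin_hz <- 48000 / 2048
  expect_lt(abs(median(sd_tone$centroid) - 1000), 3 * bin_hz)
  expect_lt(median(sd_tone$spread), 100)
  interior <- sd_tone$flux[-(1:2)]
  expect_lt(max(interior) / max(sd_tone$centroid), 0.05)  # stationary: tiny flux

  set.seed(9)
  noise <- audio_clip(rnorm(48000, 0, 0.5), 48000)
  sd_noise <- spectral_descriptors(noise)
  # per-frame magnitude-spectrum flatness of white noise has the Rayleigh
  # theoretical value exp((log 2 - gamma)/2) / sqrt(pi/2) ~ 0.846
  expect_gt(median(sd_noise$flatness), 0.8)
  expect_lt(median(sd_noise$flatness), 0.9)
  expect_gt(median(sd_noise$entropy), 0.9)
  expect_gt(median(sd_noise$rolloff), 0.75 * 24000)

  # amplitude invariance of centroid, flatness, rolloff
  loud <- spectral_descriptors(audio_clip(tone$samples * 2, 48000))
  expect_equal(median(loud$centroid), median(sd_tone$centroid))
  expect_equal(median(loud$rolloff), median(sd_tone$rolloff))

  z <- audio_clip(numeric(4800), 48000)
  expect_true(all(is.na(spectral_descriptors(z)$centroid)))
})

test_that("wavelet scattering yields 8 log-transformed windows with shift stability", {
  cfg <- wst_config()
  t <- seq_len(96000) / 48000
  sig <- audio_clip((1 + 0.4 * sin(2 * pi * 3 * t)) * sin(2 * pi * 800 * t), 48000)
  S <- wst_features(sig, cfg)
  expect_identical(ncol(S), 8L)
  expect_gt(nrow(S), 20)

  zeroed <- wst_features(audio_clip(numeric(48000), 48000), cfg)
  expect_true(all(abs(zeroed - log(1e-10)) < 1e-9))

  shift <- round(0.050 * 48000)
  shifted <- audio_clip(c(utils::tail(sig$samples, shift),
                          utils::head(sig$samples, -shift)), 48000)
  S2 <- wst_features(shifted, cfg)
  rel <- sqrt(sum((S2 - S)^2)) / sqrt(sum(S^2))
  expect_lt(rel, 0.05)

  expect_error(wst_features(audio_clip(numeric(1000), 48000), cfg),
               class = "cogscreen_domain_error")
})

test_that("the speech sequence preset assembles 28 z-scored columns deterministically", {
  clip <- make_sine_clip(180, duration_s = 0.5)
  seq1 <- assemble_speech_sequence(clip)
  expect_identical(ncol(seq1), 28L)
  expect_identical(colnames(seq1)[1], "pitch")
  mu <- colMeans(seq1)
  expect_lt(max(abs(mu)), 1e-9)
  expect_identical(seq1, assemble_speech_sequence(clip))
})
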