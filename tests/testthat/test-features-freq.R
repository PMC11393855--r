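test_that("spectral descriptors agree with a naive DFT double-loop oracle", {
  set.seed(9)
  for (i in 1:5) {
    fr <- rnorm(64)
    clip <- audio_clip(rep(fr, 4), 1600)
    fs <- frame_signal(clip, frame_ms = 40, hop_ms = 40, window = "rect")
    sp <- snoreforge:::frame_power_spectra(fs)
    P_naive <- naive_power_spectrum(fs$frames[1, ], sp$nfft)
    expect_equal(sp$P[1, ], P_naive, tolerance = 1e-8)
    d <- snoreforge:::spectral_descriptors(sp$P[1, ], sp$freqs)
    expect_equal(unname(d["centroid"]), naive_centroid(sp$P[1, ], sp$freqs),
                 tolerance = 1e-9)
    expect_equal(unname(d["flatness"]), naive_flatness(sp$P[1, ]),
                 tolerance = 1e-6)
  }
})

test_that("tonal and noisy clips separate on centroid, flatness and flux", {
  tone <- tone_clip(1000, dur = 0.3)
  ft <- spectral_shape_features(frame_signal(tone))
  nfft_bin <- 16000 / 512
  expect_equal(unname(ft["freq.centroid.mean"]), 1000, tolerance = 2 * nfft_bin)
  expect_lt(unname(ft["freq.flatness.mean"]), 0.1)

  flat_vals <- vapply(1:10, function(s) {
    nz <- noise_clip(dur = 0.3, seed = s)
    unname(spectral_shape_features(frame_signal(nz))["freq.flatness.mean"])
  }, numeric(1))
  expect_true(all(flat_vals > 0.5))

  # identical consecutive frames: zero flux
  fs <- frame_signal(tone, frame_ms = 25, hop_ms = 25, window = "rect")
  fs$frames <- fs$frames[rep(1, 4), ]
  ft2 <- spectral_shape_features(fs)
  expect_equal(unname(ft2["freq.flux.mean"]), 0, tolerance = 1e-9)
})

test_that("long-term average spectrum statistics track amplitude modulation", {
  rate <- 16000
  t <- seq(0, 1 - 1 / rate, by = 1 / rate)
  steady <- audio_clip(0.5 * sin(2 * pi * 300 * t), rate)
  am <- audio_clip(0.5 * (0.3 + 0.7 * (1 + sin(2 * pi * 3 * t)) / 2) *
                     sin(2 * pi * 300 * t), rate)
  f_st <- ltas_features(frame_signal(steady, window = "rect"))
  f_am <- ltas_features(frame_signal(am, window = "rect"))
  expect_lt(unname(f_st["freq.ltas.range"]), 0.02)
  expect_gt(unname(f_am["freq.ltas.range"]), unname(f_st["freq.ltas.range"]))

  # hand-computed stats on a known RMS series
  fs <- frame_signal(audio_clip(rep(1, 400), 100), frame_ms = 1000, hop_ms = 1000,
                     window = "rect")
  fs$frames <- matrix(c(1, 2, 3, 4), ncol = 1)
  f <- ltas_features(fs)
  expect_equal(unname(f["freq.ltas.range"]), 3)
  expect_equal(unname(f["freq.ltas.pvi"]), 1)
})

test_that("pitch, jitter, HNR and peak frequency behave on controlled tones", {
  tone <- tone_clip(200, dur = 0.5)
  tf <- tonality_features(tone)
  expect_equal(unname(tf["freq.f0.mean"]), 200, tolerance = 5)
  expect_lt(unname(tf["freq.jitter"]), 0.01)

  t <- seq(0, 0.5 - 1 / 16000, by = 1 / 16000)
  set.seed(4)
  clean <- audio_clip(0.5 * sin(2 * pi * 300 * t), 16000)
  noisy <- audio_clip(0.5 * sin(2 * pi * 300 * t) + 0.4 * rnorm(length(t)), 16000)
  expect_gt(unname(tonality_features(clean)["freq.hnr"]),
            unname(tonality_features(noisy)["freq.hnr"]))

  tf440 <- tonality_features(tone_clip(440, dur = 0.5))
  expect_equal(unname(tf440["freq.peak_frequency"]), 440, tolerance = 16000 / 8192)

  unvoiced <- tonality_features(noise_clip(dur = 0.3, seed = 8))
  expect_equal(unname(unvoiced["freq.f0.mean"]), 0)
})

test_that("LPC recovers an AR(2) process and LSFs interlace in (0, pi)", {
  set.seed(10)
  n <- 4000
  x <- numeric(n)
  e <- rnorm(n)
  for (i in 3:n) x[i] <- 1.0 * x[i - 1] - 0.5 * x[i - 2] + e[i]
  a <- snoreforge:::lpc_coefs(x, 2)
  # model convention: x_n = -a1 x_{n-1} - a2 x_{n-2} + e_n
  expect_equal(a[1], -1.0, tolerance = 0.1)
  expect_equal(a[2], 0.5, tolerance = 0.1)

  wn <- rnorm(4000)
  expect_lt(max(abs(snoreforge:::lpc_coefs(wn, 8))), 0.1)

  lsf <- snoreforge:::lsf_from_lpc(a <- snoreforge:::lpc_coefs(x, 8))
  expect_true(all(diff(lsf) > 0))
  expect_true(all(lsf > 0 & lsf < pi))
})
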