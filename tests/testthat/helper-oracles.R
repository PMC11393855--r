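# Independent naive-loop oracles used to cross-check the vectorized
# feature extractors, plus small fixture builders.

naive_zcr <- function(p) {
  N <- length(p)
  s <- ifelse(p >= 0, 1, 0)
  acc <- 0
  for (n in 2:N) acc <- acc + abs(s[n] - s[n - 1])
  acc / (2 * N)
}

naive_ste <- function(p) {
  acc <- 0
  for (n in seq_along(p)) acc <- acc + p[n]^2
  acc / length(p)
}

# explicit DFT power spectrum (one-sided), double loop
naive_power_spectrum <- function(x, nfft) {
  x <- c(x, rep(0, nfft - length(x)))
  nb <- nfft %/% 2 + 1
  P <- numeric(nb)
  for (k in seq_len(nb) - 1) {
    re <- 0; im <- 0
    for (n in seq_len(nfft) - 1) {
      re <- re + x[n + 1] * cos(2 * pi * k * n / nfft)
      im <- im - x[n + 1] * sin(2 * pi * k * n / nfft)
    }
    P[k + 1] <- re^2 + im^2
  }
  P
}

naive_centroid <- function(P, freqs) sum(freqs * P / sum(P))

naive_flatness <- function(P) exp(mean(log(P + 1e-10))) / mean(P)

# pure tone clip helper
tone_clip <- function(freq, dur = 0.5, rate = 16000, amp = 0.8,
                      label = NA, id = "tone") {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  audio_clip(amp * sin(2 * pi * freq * t), rate, label = label, clip_id = id)
}

noise_clip <- function(dur = 0.5, rate = 16000, seed = 1, label = NA,
                       id = "noise") {
  set.seed(seed)
  audio_clip(0.5 * stats::rnorm(dur * rate) / 3, rate, label = label,
             clip_id = id)
}

# small separable 2-class blob data
blob_data <- function(n_per = 20, sep = 4, d = 2, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * d), n_per, d),
             matrix(rnorm(n_per * d, mean = sep), n_per, d))
  list(X = X, y = rep(c("a", "b"), each = n_per))
}
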