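# power spectra of windowed frames: num_frames x (nfft/2 + 1), plus
# the matching frequency axis
frame_power_spectra <- function(frames) {
  N <- frames$frame_length
  nfft <- 2^ceiling(log2(N))
  nb <- nfft %/% 2L + 1L
  X <- t(apply(frames$frames, 1, function(fr) {
    sp <- stats::fft(c(fr, rep(0, nfft - N)))
    Mod(sp[seq_len(nb)])^2
  }))
  if (nrow(frames$frames) == 1L) X <- matrix(X, nrow = 1L)
  freqs <- (seq_len(nb) - 1) * frames$rate / nfft
  list(P = X, freqs = freqs, nfft = nfft)
}

# per-frame spectral shape descriptors on one power spectrum
spectral_descriptors <- function(p, freqs) {
  tot <- sum(p)
  if (tot < EPS) p <- p + EPS; tot <- sum(p)
  q <- p / tot
  centroid <- sum(freqs * q)
  spread <- sqrt(sum((freqs - centroid)^2 * q))
  skew <- if (spread < EPS) 0 else sum(((freqs - centroid) / spread)^3 * q)
  kurt <- if (spread < EPS) 0 else sum(((freqs - centroid) / spread)^4 * q) - 3
  gm <- exp(mean(log(p + EPS)))
  am <- mean(p)
  flatness <- gm / am
  crest <- max(p) / sum(p)
  cum <- cumsum(q)
  rolloff <- freqs[which(cum >= 0.85)[1]]
  # slope of a linear regression of amplitude on frequency
  a <- sqrt(p)
  fr_c <- freqs - mean(freqs)
  slope <- sum(fr_c * (a - mean(a))) / sum(fr_c^2)
  # decrease: low-frequency-weighted average difference from the first bin
  k <- seq_along(p)[-1] - 1
  decrease <- if (sum(a[-1]) < EPS) 0 else sum((a[-1] - a[1]) / k) / sum(a[-1])
  bandwidth <- sum(abs(freqs - centroid) * q)        # first absolute moment
  entropy <- -sum(q * log(q + EPS)) / log(length(q))
  center <- freqs[which(cum >= 0.5)[1]]              # median frequency
  c(centroid = centroid, spread = spread, skewness = skew, kurtosis = kurt,
    flatness = flatness, crest = crest, rolloff = rolloff, slope = slope,
    decrease = decrease, bandwidth = bandwidth, entropy = entropy,
    center = center)
}

# octave-based spectral contrast: log(peak) - log(valley) per octave
# band, peaks/valleys as 0.2-quantile neighbourhood means
obsc_bands <- function(p, freqs, edges = c(125, 250, 500, 1000, 2000, 4000, 8000)) {
  nb <- length(edges) - 1L
  out <- numeric(nb)
  for (b in seq_len(nb)) {
    sel <- which(freqs >= edges[b] & freqs < edges[b + 1])
    if (length(sel) < 2L) { out[b] <- 0; next }
    v <- sort(p[sel])
    k <- max(1L, round(0.2 * length(v)))
    valley <- mean(v[seq_len(k)])
    peak <- mean(v[(length(v) - k + 1L):length(v)])
    out[b] <- log(peak + EPS) - log(valley + EPS)
  }
  names(out) <- paste0("obsc", seq_len(nb))
  out
}

#' Spectral shape features for a clip
#'
#' Clip-level mean and standard deviation of per-frame spectral
#' descriptors (centroid, spread, skewness, kurtosis, flatness, crest,
#' 85% roll-off, slope, decrease, bandwidth, normalized Shannon entropy,
#' median frequency), spectral flux between consecutive frames, and
#' octave-based spectral contrast in six bands from 125 Hz.
#'
#' @param frames a `frame_set` from [frame_signal] (windowed).
#' @return named numeric vector (names prefixed `freq.`).
#' @export
spectral_shape_features <- function(frames) {
  sp <- frame_power_spectra(frames)
  D <- t(apply(sp$P, 1, spectral_descriptors, freqs = sp$freqs))
  if (nrow(sp$P) == 1L) D <- matrix(D, nrow = 1L,
                                    dimnames = list(NULL, names(spectral_descriptors(sp$P[1, ], sp$freqs))))
  mu <- colMeans(D)
  sdv <- apply(D, 2, stats::sd)
  sdv[!is.finite(sdv)] <- 0
  A <- sqrt(sp$P)
  flux <- if (nrow(A) < 2L) 0 else
    vapply(2:nrow(A), function(i) sqrt(sum((A[i, ] - A[i - 1, ])^2)), numeric(1))
  ob <- t(apply(sp$P, 1, obsc_bands, freqs = sp$freqs))
  if (nrow(sp$P) == 1L) ob <- matrix(ob, nrow = 1L, dimnames = list(NULL, paste0("obsc", 1:6)))
  ob_mu <- colMeans(ob)
  out <- c(stats::setNames(mu, paste0("freq.", names(mu), ".mean")),
           stats::setNames(sdv, paste0("freq.", names(mu), ".sd")),
           freq.flux.mean = mean(flux), freq.flux.sd = if (length(flux) > 1) stats::sd(flux) else 0,
           stats::setNames(ob_mu, paste0("freq.", names(ob_mu), ".mean")))
  out[!is.finite(out)] <- 0
  out
}

#' Long-term average spectrum statistics
#'
#' Statistics over the series of per-frame RMS values: range, skewness,
#' kurtosis, mean, coefficient of variation, and mean absolute
#' frame-to-frame difference (pairwise variability).
#'
#' @param frames a `frame_set`.
#' @return named numeric vector (names prefixed `freq.ltas.`).
#' @export
ltas_features <- function(frames) {
  r <- sqrt(rowMeans(frames$frames^2))
  out <- c(
    freq.ltas.range = max(r) - min(r),
    freq.ltas.skewness = safe_skewness(r),
    freq.ltas.kurtosis = safe_kurtosis(r),
    freq.ltas.mean = mean(r),
    freq.ltas.cv = if (mean(r) < EPS) 0 else stats::sd(r) / mean(r),
    freq.ltas.pvi = if (length(r) < 2L) 0 else mean(abs(diff(r))))
  out[!is.finite(out)] <- 0
  out
}

#' Tonality features: pitch, jitter, harmonic-to-noise ratio, peak frequency
#'
#' Per-frame fundamental frequency by the autocorrelation method
#' restricted to 50-500 Hz with a voicing threshold of 0.3 on the
#' normalized autocorrelation; clip mean F0, jitter (mean absolute
#' period-to-period difference over mean period), HNR in dB computed as
#' 10*log10(r/(1-r)) from the autocorrelation value r at the pitch lag,
#' and the peak frequency of the clip power spectrum. Unvoiced clips
#' receive sentinel 0 for F0, jitter and HNR.
#'
#' @param clip an [audio_clip].
#' @param frames a `frame_set` (rectangular window recommended).
#' @param f0_range numeric length-2 pitch search range in Hz.
#' @param voicing_threshold minimum normalized autocorrelation value.
#' @return named numeric vector (names prefixed `freq.`).
#' @export
tonality_features <- function(clip, frames = NULL,
                              f0_range = c(50, 500), voicing_threshold = 0.3) {
  if (is.null(frames)) frames <- frame_raw(clip, frame_ms = 40, hop_ms = 10)
  rate <- frames$rate
  min_lag <- max(2L, floor(rate / f0_range[2]))
  max_lag <- min(frames$frame_length - 1L, ceiling(rate / f0_range[1]))
  periods <- c(); rvals <- c()
  for (i in seq_len(nrow(frames$frames))) {
    pk <- acf_peak(frames$frames[i, ], max_lag = max_lag, min_lag = min_lag)
    if (pk[1] >= min_lag && pk[2] >= voicing_threshold) {
      periods <- c(periods, pk[1] / rate)
      rvals <- c(rvals, pk[2])
    }
  }
  if (length(periods) == 0L) {
    f0 <- 0; jitter <- 0; hnr <- 0
  } else {
    f0 <- 1 / mean(periods)
    jitter <- if (length(periods) < 2L) 0 else
      mean(abs(diff(periods))) / mean(periods)
    r <- min(mean(rvals), 1 - EPS)
    hnr <- 10 * log10(r / (1 - r))
  }
  # peak frequency from the whole-clip power spectrum
  n <- length(clip$samples)
  nfft <- 2^ceiling(log2(n))
  sp <- Mod(stats::fft(c(clip$samples, rep(0, nfft - n)))[1:(nfft %/% 2 + 1)])^2
  fax <- (seq_along(sp) - 1) * clip$rate / nfft
  peak_freq <- fax[which.max(sp)]
  c(freq.f0.mean = f0, freq.jitter = jitter, freq.hnr = hnr,
    freq.peak_frequency = peak_freq)
}

# Levinson-Durbin LPC on the frame autocorrelation; returns a1..a_order
# for the model x_n = -sum_k a_k x_{n-k} + e_n (so A(z) = 1 + sum a_k z^-k)
lpc_coefs <- function(x, order = 12L) {
  n <- length(x)
  if (n <= order) stop("signal shorter than LPC order", call. = FALSE)
  r <- vapply(0:order, function(k) sum(x[1:(n - k)] * x[(1 + k):n]), numeric(1))
  if (r[1] < EPS) return(rep(0, order))
  a <- numeric(order); e <- r[1]
  for (i in seq_len(order)) {
    acc <- r[i + 1]
    if (i > 1) acc <- acc + sum(a[1:(i - 1)] * r[i:2])
    k <- -acc / e
    new_a <- a
    new_a[i] <- k
    if (i > 1) new_a[1:(i - 1)] <- a[1:(i - 1)] + k * a[(i - 1):1]
    a <- new_a
    e <- e * (1 - k^2)
    if (e < EPS) break
  }
  a
}

# line spectral frequencies of an LPC set: roots of the symmetric /
# antisymmetric split polynomials, angles in (0, pi), sorted
lsf_from_lpc <- function(a) {
  p <- length(a)
  A <- c(1, a)
  P <- c(A, 0) + c(0, rev(A))    # palindromic
  Q <- c(A, 0) - c(0, rev(A))    # anti-palindromic
  ang <- function(poly) {
    r <- polyroot(rev(poly))
    th <- Arg(r)
    th <- th[th > 1e-9 & th < pi - 1e-9]
    sort(th)
  }
  lsf <- sort(c(ang(P), ang(Q)))
  if (length(lsf) >= p) lsf[seq_len(p)] else c(lsf, rep(pi - EPS, p - length(lsf)))
}

#' Autoregressive (LPC / LSF) features
#'
#' Per-clip mean of order-`order` linear-prediction coefficients
#' (Levinson-Durbin on the frame autocorrelation) and the line spectral
#' frequencies of the mean LPC polynomial, in radians, strictly
#' increasing in (0, pi).
#'
#' @param frames a `frame_set`.
#' @param order LPC order (default 12).
#' @return named numeric vector (names prefixed `freq.`).
#' @export
autoregressive_features <- function(frames, order = 12L) {
  if (order >= frames$frame_length) stop("order must be < frame length", call. = FALSE)
  A <- t(apply(frames$frames, 1, lpc_coefs, order = order))
  if (nrow(frames$frames) == 1L) A <- matrix(A, nrow = 1L)
  a_mean <- colMeans(A)
  lsf <- lsf_from_lpc(a_mean)
  c(stats::setNames(a_mean, paste0("freq.lpc", seq_len(order))),
    stats::setNames(lsf, paste0("freq.lsf", seq_len(order))))
}
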