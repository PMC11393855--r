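hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# triangular mel filterbank: n_filters x n_bins weights
mel_filterbank <- function(n_filters, n_bins, rate, nfft,
                           fmin = 0, fmax = rate / 2) {
  mel_pts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_filters + 2)
  hz_pts <- mel_to_hz(mel_pts)
  freqs <- (seq_len(n_bins) - 1) * rate / nfft
  FB <- matrix(0, n_filters, n_bins)
  for (m in seq_len(n_filters)) {
    lo <- hz_pts[m]; ce <- hz_pts[m + 1]; hi <- hz_pts[m + 2]
    up <- (freqs - lo) / max(ce - lo, EPS)
    dn <- (hi - freqs) / max(hi - ce, EPS)
    FB[m, ] <- pmax(0, pmin(up, dn))
  }
  FB
}

# ERB-spaced gammatone magnitude-response filterbank (4th order),
# sampled on the FFT bin grid
gammatone_filterbank <- function(n_filters, n_bins, rate, nfft,
                                 fmin = 50, fmax = rate / 2) {
  hz_to_erb <- function(f) 21.4 * log10(1 + 0.00437 * f)
  erb_to_hz <- function(e) (10^(e / 21.4) - 1) / 0.00437
  cfs <- erb_to_hz(seq(hz_to_erb(fmin), hz_to_erb(fmax), length.out = n_filters))
  freqs <- (seq_len(n_bins) - 1) * rate / nfft
  FB <- matrix(0, n_filters, n_bins)
  for (m in seq_len(n_filters)) {
    erb <- 24.7 * (0.00437 * cfs[m] + 1)
    b <- 1.019 * erb
    resp <- (1 + ((freqs - cfs[m]) / b)^2)^(-2)   # |H|^2 of 4th-order gammatone
    FB[m, ] <- resp / max(sum(resp), EPS)
  }
  FB
}

# orthonormal DCT-II matrix rows 1..n_out applied to log filterbank energies
dct2_matrix <- function(n_out, n_in) {
  M <- matrix(0, n_out, n_in)
  for (k in seq_len(n_out) - 1L) {
    M[k + 1L, ] <- cos(pi * k * (2 * (seq_len(n_in) - 1L) + 1) / (2 * n_in)) *
      sqrt((if (k == 0) 1 else 2) / n_in)
  }
  M
}

# cepstral coefficients through an arbitrary filterbank
fb_cepstra <- function(P, FB, n_coef) {
  E <- P %*% t(FB)                 # frames x filters
  logE <- log(pmax(E, EPS))
  C <- logE %*% t(dct2_matrix(n_coef, ncol(logE)))
  C
}

#' Linear-prediction cepstral coefficients from one LPC set
#'
#' Standard recursion converting LPC coefficients (predictor
#' A(z) = 1 + sum a_k z^-k) to cepstral coefficients c_1..c_n.
#'
#' @param a LPC coefficients a1..ap.
#' @param n_coef number of cepstral coefficients.
#' @return numeric vector c1..c_n.
#' @export
lpcc_from_lpc <- function(a, n_coef = 13L) {
  p <- length(a)
  cc <- numeric(n_coef)
  for (m in seq_len(n_coef)) {
    acc <- if (m <= p) -a[m] else 0
    if (m > 1) {
      kk <- 1:(m - 1)
      valid <- kk[(m - kk) <= p]
      if (length(valid) > 0)
        acc <- acc - sum((valid / m) * cc[valid] * a[m - valid])
    }
    cc[m] <- acc
  }
  cc
}

#' Cepstral-domain features: MFCC, LPCC and gammatone cepstra
#'
#' Clip mean and standard deviation of 13 MFCCs (26 triangular mel
#' filters, DCT-II of the log energies), 13 LPCCs (recursion from
#' order-12 LPC per frame), 13 gammatone cepstral coefficients (26
#' ERB-spaced gammatone filters through the same DCT path), plus the
#' means of the delta-MFCCs (first temporal difference).
#'
#' @param frames a `frame_set` (windowed).
#' @param n_coef number of cepstral coefficients (default 13).
#' @param n_filters number of filters per bank (default 26).
#' @return named numeric vector (names prefixed `ceps.`).
#' @export
cepstral_features <- function(frames, n_coef = 13L, n_filters = 26L) {
  sp <- frame_power_spectra(frames)
  nb <- ncol(sp$P)
  melFB <- mel_filterbank(n_filters, nb, frames$rate, sp$nfft)
  gtFB <- gammatone_filterbank(n_filters, nb, frames$rate, sp$nfft)
  mfcc <- fb_cepstra(sp$P, melFB, n_coef)
  gtcc <- fb_cepstra(sp$P, gtFB, n_coef)
  lpcc <- t(apply(frames$frames, 1, function(fr)
    lpcc_from_lpc(lpc_coefs(fr, 12L), n_coef)))
  if (nrow(frames$frames) == 1L) lpcc <- matrix(lpcc, nrow = 1L)
  dmfcc <- if (nrow(mfcc) > 1) diff(mfcc) else matrix(0, 1, n_coef)

  stat <- function(M, tag) {
    mu <- colMeans(M)
    sdv <- apply(M, 2, stats::sd)
    sdv[!is.finite(sdv)] <- 0
    c(stats::setNames(mu, paste0("ceps.", tag, seq_len(ncol(M)), ".mean")),
      stats::setNames(sdv, paste0("ceps.", tag, seq_len(ncol(M)), ".sd")))
  }
  out <- c(stat(mfcc, "mfcc"), stat(lpcc, "lpcc"), stat(gtcc, "gtcc"),
           stats::setNames(colMeans(dmfcc), paste0("ceps.dmfcc", seq_len(n_coef), ".mean")))
  out[!is.finite(out)] <- 0
  out
}
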