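#' Zero-crossing rate of one frame
#'
#' Z = (1/2N) * sum_{n=2}^{N} |sgn(p_n) - sgn(p_{n-1})| with
#' sgn(p) = 1 for p >= 0 and 0 otherwise, so Z lies in
#' \[0, (N-1)/(2N)\].
#'
#' @param frame numeric vector, length >= 2.
#' @return scalar rate.
#' @export
zero_crossing_rate <- function(frame) {
  N <- length(frame)
  if (N < 2L) stop("frame must have at least 2 samples", call. = FALSE)
  s <- as.numeric(frame >= 0)
  sum(abs(diff(s))) / (2 * N)
}

#' Mean-removed (detrended) zero-crossing rate
#'
#' The plain [zero_crossing_rate] applied after subtracting the frame
#' mean, which makes the count insensitive to DC offset.
#'
#' @inheritParams zero_crossing_rate
#' @return scalar rate.
#' @export
modified_zcr <- function(frame) {
  zero_crossing_rate(frame - mean(frame))
}

#' Short-time energy of one frame
#'
#' Mean energy per frame: (1/N) * sum p_n^2.
#'
#' @param frame numeric vector.
#' @return non-negative scalar.
#' @export
short_time_energy <- function(frame) {
  if (length(frame) == 0L) stop("empty frame", call. = FALSE)
  mean(frame^2)
}

# highest non-zero-lag normalized autocorrelation peak of a vector;
# returns c(lag_samples, value); (0, 0) when no local peak exists
acf_peak <- function(x, max_lag = length(x) - 1L, min_lag = 1L) {
  x <- x - mean(x)
  denom <- sum(x^2)
  if (denom < EPS) return(c(0, 0))
  n <- length(x)
  max_lag <- min(max_lag, n - 1L)
  r <- vapply(seq_len(max_lag), function(k) {
    sum(x[1:(n - k)] * x[(1 + k):n]) / denom
  }, numeric(1))
  lo <- max(min_lag, 2L)
  if (max_lag < lo) return(c(0, 0))
  # local maxima strictly above neighbours within the search band
  cand <- which(diff(sign(diff(r))) < 0) + 1L
  cand <- cand[cand >= min_lag]
  if (length(cand) == 0L) {
    k <- which.max(r[min_lag:max_lag]) + min_lag - 1L
    return(c(k, r[k]))
  }
  k <- cand[which.max(r[cand])]
  c(k, r[k])
}

# LPC residual of a signal through an order-p whitening filter
lpc_residual <- function(x, order = 12L) {
  a <- lpc_coefs(x, order)            # a1..ap with predictor x_n ~ -sum a_k x_{n-k}
  as.numeric(stats::filter(x, c(1, a), method = "convolution", sides = 1))[-seq_len(order)]
}

#' Time-domain feature vector for one clip
#'
#' Aggregates frame-level energy and zero-crossing descriptors and adds
#' clip-level envelope statistics:
#' mean/sd of short-time energy, ZCR and detrended ZCR; temporal
#' centroid (energy-weighted mean time in seconds); RMS volume; shimmer
#' (mean cycle-to-cycle change of per-frame peak amplitude divided by
#' mean amplitude); log attack time (log10 of the time the energy
#' envelope takes from 10% to 90% of its maximum); highest non-zero-lag
#' autocorrelation peak (lag in seconds and value); and LP-ZCR, the
#' ratio of signal ZCR to the ZCR of its linear-prediction residual.
#' Silent clips receive the sentinel 0 for log attack time and LP-ZCR.
#'
#' @param clip an [audio_clip].
#' @param frames optional precomputed rectangular [frame_signal] output.
#' @return named numeric vector (names prefixed `time.`).
#' @export
time_domain_features <- function(clip, frames = NULL) {
  if (is.null(frames)) frames <- frame_raw(clip)
  F <- frames$frames
  nf <- nrow(F)
  ste <- rowMeans(F^2)
  zcr <- apply(F, 1, zero_crossing_rate)
  zcrm <- apply(F, 1, modified_zcr)

  # temporal centroid over the frame-energy envelope, in seconds
  t_frames <- ((seq_len(nf) - 1) * frames$hop + frames$frame_length / 2) / frames$rate
  tot_e <- sum(ste)
  centroid <- if (tot_e < EPS) 0 else sum(t_frames * ste) / tot_e

  volume <- sqrt(mean(clip$samples^2))

  amp <- apply(abs(F), 1, max)
  shimmer <- if (mean(amp) < EPS || nf < 2L) 0 else
    mean(abs(diff(amp))) / mean(amp)

  # log attack time from the 10% -> 90% rise of the envelope
  pk <- max(ste)
  if (pk < EPS) {
    lat <- 0
  } else {
    i10 <- which(ste >= 0.1 * pk)[1]
    i90 <- which(ste >= 0.9 * pk)[1]
    dt <- max(i90 - i10, 0) * frames$hop / frames$rate
    lat <- if (dt <= 0) 0 else log10(dt)
  }

  pk_acf <- acf_peak(clip$samples, max_lag = min(length(clip$samples) - 1L,
                                                 as.integer(clip$rate / 25)))
  acf_lag_s <- pk_acf[1] / clip$rate

  z_sig <- zero_crossing_rate(clip$samples)
  lp_zcr <- if (sqrt(mean(clip$samples^2)) < EPS) 0 else {
    res <- lpc_residual(clip$samples, 12L)
    zr <- zero_crossing_rate(res)
    if (zr < EPS) 0 else z_sig / zr
  }

  out <- c(
    time.ste.mean = mean(ste), time.ste.sd = stats::sd(ste),
    time.zcr.mean = mean(zcr), time.zcr.sd = stats::sd(zcr),
    time.zcrmod.mean = mean(zcrm), time.zcrmod.sd = stats::sd(zcrm),
    time.temporal_centroid = centroid,
    time.volume = volume,
    time.shimmer = shimmer,
    time.log_attack_time = lat,
    time.acf_peak_lag = acf_lag_s,
    time.acf_peak_val = pk_acf[2],
    time.lp_zcr = lp_zcr)
  out[!is.finite(out)] <- 0
  out
}
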