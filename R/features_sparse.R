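#' Overcomplete DCT dictionary
#'
#' Unit-norm DCT-type atoms: column j is cos(pi*(j-1)*(2n+1)/(2*dict_size))
#' sampled at n = 0..signal_len-1, normalized. With
#' `dict_size > signal_len` the dictionary is overcomplete.
#'
#' @param signal_len atom length.
#' @param dict_size number of atoms (default 2x overcomplete).
#' @return signal_len x dict_size matrix with unit-norm columns.
#' @export
dct_dictionary <- function(signal_len, dict_size = 2L * signal_len) {
  n <- 0:(signal_len - 1)
  D <- vapply(seq_len(dict_size) - 1L, function(k) {
    a <- cos(pi * k * (2 * n + 1) / (2 * dict_size))
    a / sqrt(sum(a^2))
  }, numeric(signal_len))
  D
}

#' Orthogonal matching pursuit
#'
#' Greedy sparse approximation: at each step pick the atom with maximum
#' absolute correlation to the residual, re-fit all active coefficients
#' by least squares, and update the residual.
#'
#' @param x signal vector.
#' @param D dictionary matrix (columns unit-norm atoms).
#' @param k number of atoms to select.
#' @return list with `support` (atom indices in selection order),
#'   `coefs` (final least-squares coefficients), `residual_norms`
#'   (residual L2 norm after each step) and `residual` (final residual).
#' @export
omp <- function(x, D, k) {
  if (k > ncol(D)) stop("k exceeds dictionary size", call. = FALSE)
  r <- x
  support <- integer(0)
  res_norms <- numeric(k)
  coefs <- numeric(0)
  for (step in seq_len(k)) {
    corr <- abs(crossprod(D, r))
    corr[support] <- -Inf
    j <- which.max(corr)
    support <- c(support, j)
    A <- D[, support, drop = FALSE]
    coefs <- qr.coef(qr(A), x)
    coefs[is.na(coefs)] <- 0
    r <- x - A %*% coefs
    res_norms[step] <- sqrt(sum(r^2))
    if (res_norms[step] < 1e-12) { res_norms[step:k] <- res_norms[step]; break }
  }
  list(support = support, coefs = as.numeric(coefs),
       residual_norms = res_norms, residual = as.numeric(r))
}

#' Sparse-domain features via orthogonal matching pursuit
#'
#' The clip's central window is mean-magnitude normalized and decomposed
#' over an overcomplete DCT dictionary. Features: quartiles of the
#' residual energy fraction across the k pursuit steps, mean and
#' standard deviation of the absolute selected coefficients, and the
#' index spread (sd of selected atom indices normalized by dictionary
#' size).
#'
#' @param clip an [audio_clip].
#' @param window_len analysis window length in samples (default 256).
#' @param dict_size number of atoms (default 2 * window_len).
#' @param k number of OMP steps (default 20).
#' @return named numeric vector (names prefixed `sparse.`).
#' @export
sparse_features <- function(clip, window_len = 256L, dict_size = 2L * window_len,
                            k = 20L) {
  n <- length(clip$samples)
  if (n < window_len) {
    x <- c(clip$samples, rep(0, window_len - n))
  } else {
    start <- (n - window_len) %/% 2L + 1L
    x <- clip$samples[start:(start + window_len - 1L)]
  }
  mm <- mean(abs(x))
  if (mm > EPS) x <- x / mm
  D <- dct_dictionary(window_len, dict_size)
  fit <- omp(x, D, k)
  e0 <- sqrt(sum(x^2))
  frac <- if (e0 < EPS) rep(0, k) else fit$residual_norms^2 / e0^2
  qs <- stats::quantile(frac, c(0.25, 0.5, 0.75, 1), names = FALSE)
  ac <- abs(fit$coefs)
  out <- c(
    sparse.resfrac.q25 = qs[1], sparse.resfrac.q50 = qs[2],
    sparse.resfrac.q75 = qs[3], sparse.resfrac.final = qs[4],
    sparse.coef.mean_abs = mean(ac),
    sparse.coef.sd_abs = if (length(ac) > 1) stats::sd(ac) else 0,
    sparse.index_spread = if (length(fit$support) > 1)
      stats::sd(fit$support) / dict_size else 0)
  out[!is.finite(out)] <- 0
  out
}

#' Eigen-domain features from the frame matrix
#'
#' Singular values of the mean-centered frame matrix, normalized to sum
#' one, plus the cumulative energy of the top three and the Shannon
#' entropy of the normalized singular spectrum. Dominant-direction
#' concentration distinguishes tonal (low-rank) from noisy frames.
#'
#' @param frames a `frame_set` with at least `top_k` frames.
#' @param top_k number of leading singular values reported (default 10).
#' @return named numeric vector (names prefixed `eigen.`).
#' @export
eigen_features <- function(frames, top_k = 10L) {
  X <- frames$frames
  if (nrow(X) < top_k) stop("need at least top_k frames", call. = FALSE)
  X <- sweep(X, 2, colMeans(X))
  sv <- svd(X, nu = 0, nv = 0)$d
  tot <- sum(sv)
  s <- if (tot < EPS) rep(0, length(sv)) else sv / tot
  lead <- s[seq_len(top_k)]
  p <- s[s > EPS]
  ent <- if (length(p) == 0L) 0 else -sum(p * log(p))
  c(stats::setNames(lead, paste0("eigen.sv", seq_len(top_k))),
    eigen.cum3 = sum(s[1:3]), eigen.entropy = ent)
}
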