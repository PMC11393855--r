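# Daubechies-4 (4-tap) orthonormal analysis filters
db4_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))  # lowpass
  g <- rev(h) * c(1, -1, 1, -1)                            # highpass
  list(h = h, g = g)
}

# one analysis step with periodic extension; returns approximation and
# detail coefficients at half length
dwt_step <- function(x, h, g) {
  n <- length(x)
  L <- length(h)
  xe <- c(x, x[seq_len(L - 1)])  # periodic wrap
  starts <- seq.int(1L, n - 1L, by = 2L)
  conv_down <- function(f) {
    out <- numeric(length(starts))
    for (j in seq_len(L)) out <- out + f[j] * xe[starts + j - 1L]
    out
  }
  list(a = conv_down(h), d = conv_down(g))
}

#' Multilevel discrete wavelet decomposition
#'
#' Mallat pyramid with the 4-tap Daubechies orthonormal wavelet and
#' periodic boundary handling. Orthonormality means total coefficient
#' energy equals signal energy (for even dyadic lengths).
#'
#' @param x numeric signal; truncated to an even length divisible by
#'   2^levels.
#' @param levels decomposition depth.
#' @return list with `details` (list D1..Dlevels) and `approx` (A_levels).
#' @export
dwt_decompose <- function(x, levels = 5L) {
  if (length(x) < 2^levels) {
    levels <- max(1L, floor(log2(length(x))) - 1L)
    warning(sprintf("clip too short; wavelet depth reduced to %d", levels))
  }
  m <- 2^levels
  n <- (length(x) %/% m) * m
  x <- x[seq_len(n)]
  f <- db4_filters()
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    st <- dwt_step(a, f$h, f$g)
    details[[l]] <- st$d
    a <- st$a
  }
  names(details) <- paste0("D", seq_len(levels))
  list(details = details, approx = a, levels = levels)
}

#' Wavelet sub-band features
#'
#' For each sub-band (approximation A_L then details D_L..D1): relative
#' energy (band energy over total, summing to 1), log total band energy,
#' mean absolute coefficient, standard deviation, and Shannon entropy of
#' the normalized squared coefficients.
#'
#' @param clip an [audio_clip].
#' @param levels decomposition depth (default 5).
#' @return named numeric vector, 5 features x (levels + 1) bands, names
#'   prefixed `dwt.`.
#' @export
dwt_features <- function(clip, levels = 5L) {
  dec <- dwt_decompose(clip$samples, levels)
  bands <- c(list(dec$approx), rev(dec$details))
  names(bands) <- c(paste0("a", dec$levels),
                    paste0("d", dec$levels:1))
  energies <- vapply(bands, function(b) sum(b^2), numeric(1))
  tot <- sum(energies)
  rel <- if (tot < EPS) rep(1 / length(bands), length(bands)) else energies / tot
  out <- numeric(0)
  for (i in seq_along(bands)) {
    b <- bands[[i]]
    p <- b^2 / max(sum(b^2), EPS)
    ent <- -sum(p * log(p + EPS))
    v <- c(rel[i], log(energies[i] + EPS), mean(abs(b)), stats::sd(b), ent)
    names(v) <- paste0("dwt.", names(bands)[i], ".",
                       c("rel_energy", "log_energy", "mean_abs", "sd", "entropy"))
    out <- c(out, v)
  }
  out[!is.finite(out)] <- 0
  out
}
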