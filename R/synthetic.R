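#' Specification for synthetic snore-like clips
#'
#' Defines four acoustic class templates standing in for snore
#' excitation-site classes: each class has its own fundamental
#' frequency, a harmonic stack, a formant-shaped noise band, an
#' attack-decay amplitude envelope, cycle-level jitter/shimmer
#' perturbation and additive white noise at a target SNR. The templates
#' mimic the statistical shape of site-labelled snores (different
#' vibration sources give different source frequencies and resonances)
#' without any clinical claim.
#'
#' @param n_per_class clips per class (default 50).
#' @param classes four class identifiers (default V, O, T, E).
#' @param fundamentals per-class fundamental frequency, Hz.
#' @param n_harmonics harmonics in the voiced stack.
#' @param formant_center,formant_width per-class formant band, Hz.
#' @param jitter_pct cycle-to-cycle period perturbation (sd, fraction).
#' @param shimmer_pct cycle-to-cycle amplitude perturbation (sd, fraction).
#' @param snr_db additive-noise SNR in dB (Inf for clean).
#' @param separability in (0, 1\]: 1 keeps class templates fully apart;
#'   smaller values shrink the class fundamentals toward their common
#'   mean, making classes overlap.
#' @param duration_s clip duration (default 1 s).
#' @param rate sample rate (16000 Hz).
#' @param seed RNG seed.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(n_per_class = 50L,
                       classes = c("V", "O", "T", "E"),
                       fundamentals = c(110, 180, 260, 340),
                       n_harmonics = 8L,
                       formant_center = c(500, 1000, 1800, 2600),
                       formant_width = c(200, 250, 300, 350),
                       jitter_pct = 0.01, shimmer_pct = 0.05,
                       snr_db = 20, separability = 1,
                       duration_s = 1, rate = 16000, seed = 1L) {
  stopifnot(length(classes) == length(fundamentals),
            separability > 0, separability <= 1)
  f_mean <- mean(fundamentals)
  fundamentals <- f_mean + separability * (fundamentals - f_mean)
  structure(list(n_per_class = n_per_class, classes = classes,
                 fundamentals = fundamentals, n_harmonics = n_harmonics,
                 formant_center = formant_center,
                 formant_width = formant_width,
                 jitter_pct = jitter_pct, shimmer_pct = shimmer_pct,
                 snr_db = snr_db, separability = separability,
                 duration_s = duration_s, rate = rate, seed = seed),
            class = "synth_spec")
}

#' Generate one synthetic snore-like clip
#'
#' Harmonic stack at the class fundamental with per-cycle jitter and
#' shimmer, formant-band noise, a linear-attack / exponential-decay
#' envelope and additive white noise at the spec's SNR; peak amplitude
#' is kept at or below 1.
#'
#' @param spec a [synth_spec].
#' @param class_id one of `spec$classes`.
#' @param clip_id identifier for the clip.
#' @return an [audio_clip] with `label = class_id`.
#' @export
make_clip <- function(spec, class_id, clip_id = paste0(class_id, "1")) {
  ci <- match(class_id, spec$classes)
  if (is.na(ci)) stop("unknown class", call. = FALSE)
  n <- as.integer(spec$duration_s * spec$rate)
  f0 <- spec$fundamentals[ci]
  dt <- 1 / spec$rate

  # phase track with per-cycle jitter: instantaneous frequency varies
  # smoothly, redrawn once per nominal period
  n_cycles <- ceiling(spec$duration_s * f0) + 2L
  cyc_f <- f0 * (1 + spec$jitter_pct * stats::rnorm(n_cycles))
  cyc_a <- pmax(1 + spec$shimmer_pct * stats::rnorm(n_cycles), 0.05)
  cyc_idx <- pmin(floor((0:(n - 1)) * dt * f0) + 1L, n_cycles)
  inst_f <- cyc_f[cyc_idx]
  phase <- 2 * pi * cumsum(inst_f) * dt

  voiced <- numeric(n)
  for (h in seq_len(spec$n_harmonics)) {
    voiced <- voiced + (1 / h) * sin(h * phase)
  }
  voiced <- voiced * cyc_a[cyc_idx]

  # formant-shaped noise: white noise through a narrow FFT-domain band
  wn <- stats::rnorm(n)
  W <- stats::fft(wn)
  fax <- (0:(n - 1)) / n * spec$rate
  fax <- pmin(fax, spec$rate - fax)  # mirror for the negative-frequency half
  gain <- exp(-0.5 * ((fax - spec$formant_center[ci]) / spec$formant_width[ci])^2)
  formant <- Re(stats::fft(W * gain, inverse = TRUE)) / n
  formant <- formant / max(stats::sd(formant), EPS)

  x <- voiced + 0.3 * formant

  # envelope: 10% linear attack then exponential decay
  na <- max(1L, round(0.1 * n))
  env <- c(seq(0, 1, length.out = na), exp(-2 * seq(0, 1, length.out = n - na)))
  x <- x * env

  if (is.finite(spec$snr_db)) {
    sig_rms <- sqrt(mean(x^2))
    noise <- stats::rnorm(n)
    noise <- noise / sqrt(mean(noise^2)) * sig_rms * 10^(-spec$snr_db / 20)
    x <- x + noise
  }
  pk <- max(abs(x))
  if (pk > 1) x <- x / pk
  audio_clip(x, spec$rate, label = class_id, clip_id = clip_id)
}

#' Generate a balanced labelled synthetic dataset
#'
#' `n_per_class` clips per class, generated under the spec seed and
#' shuffled (the shuffle is part of the seeded stream, so the same seed
#' reproduces the same dataset bit for bit).
#'
#' @param spec a [synth_spec].
#' @return list of [audio_clip] objects with labels set.
#' @export
make_dataset <- function(spec) {
  with_seed(spec$seed, {
    clips <- list()
    for (cls in spec$classes) {
      for (j in seq_len(spec$n_per_class)) {
        clips[[length(clips) + 1L]] <-
          make_clip(spec, cls, clip_id = sprintf("%s%03d", cls, j))
      }
    }
    clips[sample(length(clips))]
  })
}

#' Planted-structure feature table
#'
#' A direct test bed for the wrapper selectors: `n_informative` columns
#' carry class-conditional mean shifts of `class_sep` standard
#' deviations, `n_noise` columns are i.i.d. standard normal. The
#' informative column indices are returned as ground truth.
#'
#' @param n_samples total rows (balanced over `n_classes`).
#' @param n_informative,n_noise column counts.
#' @param n_classes number of classes (default 4).
#' @param class_sep mean shift in sd units (default 2).
#' @param seed RNG seed.
#' @return list with `table` (a [feature_table]) and `informative`
#'   (column indices).
#' @export
make_planted_table <- function(n_samples = 120L, n_informative = 10L,
                               n_noise = 90L, n_classes = 4L, class_sep = 2,
                               seed = 1L) {
  with_seed(seed, {
    classes <- LETTERS[seq_len(n_classes)]
    y <- rep(classes, length.out = n_samples)
    p <- n_informative + n_noise
    X <- matrix(stats::rnorm(n_samples * p), n_samples, p)
    # each informative column gets its own random class-mean pattern
    for (j in seq_len(n_informative)) {
      shifts <- stats::rnorm(n_classes)
      shifts <- (shifts - mean(shifts)) / max(stats::sd(shifts), EPS)
      X[, j] <- X[, j] + class_sep * shifts[match(y, classes)]
    }
    perm <- sample(p)                 # informative columns not all first
    X <- X[, perm]
    informative <- match(seq_len(n_informative), perm)
    colnames(X) <- paste0("f", seq_len(p))
    ord <- sample(n_samples)
    list(table = feature_table(X[ord, ], y[ord]),
         informative = sort(informative))
  })
}
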