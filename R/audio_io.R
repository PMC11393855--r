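#' Construct an audio clip
#'
#' The raw unit of input: a mono waveform with its sample rate and an
#' optional class label.
#'
#' @param samples numeric vector of amplitudes in \[-1, 1\].
#' @param rate sampling rate in Hz (> 0).
#' @param label optional class label (character) or NA.
#' @param clip_id identifier string.
#' @return an object of class `audio_clip` with fields `samples`, `rate`,
#'   `label`, `clip_id`.
#' @export
audio_clip <- function(samples, rate, label = NA_character_, clip_id = "clip") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("samples must be non-empty", call. = FALSE)
  if (!is.numeric(rate) || rate <= 0) stop("rate must be > 0", call. = FALSE)
  if (any(!is.finite(samples))) stop("samples must be finite", call. = FALSE)
  structure(
    list(samples = samples, rate = as.numeric(rate),
         label = as.character(label), clip_id = as.character(clip_id)),
    class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip '%s': %d samples @ %g Hz, label=%s>\n",
              x$clip_id, length(x$samples), x$rate, x$label))
  invisible(x)
}

#' Read a mono PCM WAV file
#'
#' Reads RIFF/WAVE files with 16-bit integer PCM encoding (the format of
#' the snore corpora this package targets). Multi-channel input is
#' averaged to mono; samples are scaled by 1/32768 into \[-1, 1\]. By
#' default the clip is resampled to 16 kHz, the working rate of all
#' feature extractors.
#'
#' @param path file path.
#' @param resample_to target rate in Hz, or NULL to keep the file's rate.
#' @param peak_normalize if TRUE divide by the clip's absolute peak
#'   (off by default so that energy features stay comparable across clips).
#' @param label,clip_id metadata attached to the returned clip; `clip_id`
#'   defaults to the file base name.
#' @return an [audio_clip].
#' @export
read_wav <- function(path, resample_to = 16000, peak_normalize = FALSE,
                     label = NA_character_, clip_id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file", call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file", call. = FALSE)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = sum(as.integer(body[1:2]) * c(1L, 256L)),
        channels     = sum(as.integer(body[3:4]) * c(1L, 256L)),
        rate         = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(body[15:16]) * c(1L, 256L)))
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("malformed WAV: missing fmt or data chunk", call. = FALSE)
  if (fmt$audio_format != 1L || fmt$bits != 16L)
    stop("unsupported WAV encoding: only 16-bit integer PCM is read",
         call. = FALSE)

  x <- readBin(data_raw, "integer", n = length(data_raw) %/% 2L, size = 2L,
               signed = TRUE, endian = "little") / 32768
  if (fmt$channels > 1L) {
    n <- length(x) %/% fmt$channels
    x <- rowMeans(matrix(x[seq_len(n * fmt$channels)],
                         nrow = n, byrow = TRUE))
  }
  rate <- fmt$rate
  if (!is.null(resample_to) && resample_to != rate) {
    x <- resample_signal(x, rate, resample_to)
    rate <- resample_to
  }
  if (peak_normalize) {
    pk <- max(abs(x))
    if (pk > 0) x <- x / pk
  }
  x <- pmin(pmax(x, -1), 1)
  audio_clip(x, rate, label = label,
             clip_id = if (is.null(clip_id)) sub("\\.wav$", "", basename(path)) else clip_id)
}

#' Write a clip as 16-bit PCM WAV
#'
#' @param clip an [audio_clip].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- pmin(pmax(clip$samples, -1), 1)
  pcm <- as.integer(pmin(round(x * 32768), 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")           # PCM
  writeBin(1L, con, size = 2L, endian = "little")           # mono
  writeBin(as.integer(clip$rate), con, size = 4L, endian = "little")
  writeBin(as.integer(clip$rate * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")           # block align
  writeBin(16L, con, size = 2L, endian = "little")          # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

# rational-factor resampling via signal::resample
resample_signal <- function(x, from, to) {
  if (from == to) return(x)
  g <- gcd_int(round(from), round(to))
  p <- round(to) %/% g
  q <- round(from) %/% g
  as.numeric(signal::resample(x, p, q))
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Slice a clip into overlapping windowed frames
#'
#' Splits the waveform into quasi-stationary segments for frame-level
#' feature extraction. Frame count is
#' `floor((n - frame_length)/hop) + 1`; a trailing partial frame is
#' dropped.
#'
#' @param clip an [audio_clip].
#' @param frame_ms frame length in milliseconds (default 25).
#' @param hop_ms hop between frame starts in milliseconds (default 10).
#' @param window one of "hamming", "hann", "rect".
#' @return object of class `frame_set`: list with `frames`
#'   (num_frames x frame_length matrix), `frame_length`, `hop`,
#'   `window_name`, `rate`.
#' @export
frame_signal <- function(clip, frame_ms = 25, hop_ms = 10, window = "hamming") {
  stopifnot(inherits(clip, "audio_clip"))
  N <- as.integer(round(frame_ms / 1000 * clip$rate))
  hop <- as.integer(round(hop_ms / 1000 * clip$rate))
  if (N < 2L) stop("frame shorter than 2 samples", call. = FALSE)
  if (hop < 1L) stop("hop must be positive", call. = FALSE)
  n <- length(clip$samples)
  if (n < N) stop("clip shorter than one frame", call. = FALSE)
  nf <- (n - N) %/% hop + 1L
  w <- switch(match.arg(window, c("hamming", "hann", "rect")),
              hamming = 0.54 - 0.46 * cos(2 * pi * (0:(N - 1)) / (N - 1)),
              hann    = 0.5 - 0.5 * cos(2 * pi * (0:(N - 1)) / (N - 1)),
              rect    = rep(1, N))
  starts <- (seq_len(nf) - 1L) * hop
  idx <- outer(starts, seq_len(N), `+`)
  frames <- matrix(clip$samples[idx], nrow = nf) *
    matrix(w, nrow = nf, ncol = N, byrow = TRUE)
  structure(list(frames = frames, frame_length = N, hop = hop,
                 window_name = window, rate = clip$rate),
            class = "frame_set")
}

# unwindowed framing used by time-domain descriptors that need raw
# amplitudes (ZCR, shimmer, pitch periods)
frame_raw <- function(clip, frame_ms = 25, hop_ms = 10) {
  frame_signal(clip, frame_ms, hop_ms, window = "rect")
}
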