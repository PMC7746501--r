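#' Read a WAV file
#'
#' Reads a RIFF WAV file (16-bit PCM or 32-bit IEEE float), mixes multiple
#' channels down to mono by averaging, and resamples to `target_rate` with a
#' polyphase filter. Amplitude is preserved up to resampling: no peak
#' normalization is applied.
#'
#' @param path Path to a WAV file.
#' @param target_rate Sampling rate of the returned signal in Hz
#'   (default 16000).
#' @return An [audio_signal] at `target_rate`.
#' @export
read_wav <- function(path, target_rate = 16000) {
  if (!file.exists(path)) {
    stop("cannot read WAV file (no such file): ", path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop("not a RIFF/WAV file: ", path, call. = FALSE)
  }
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop("not a WAVE file: ", path, call. = FALSE)
  }

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(sz) == 0) break
    if (identical(id, "fmt ")) {
      fmt <- list(
        format   = readBin(con, "integer", 1, size = 2, endian = "little",
                           signed = FALSE),
        channels = readBin(con, "integer", 1, size = 2, endian = "little",
                           signed = FALSE),
        rate     = readBin(con, "integer", 1, size = 4, endian = "little"),
        byterate = readBin(con, "integer", 1, size = 4, endian = "little"),
        align    = readBin(con, "integer", 1, size = 2, endian = "little",
                           signed = FALSE),
        bits     = readBin(con, "integer", 1, size = 2, endian = "little",
                           signed = FALSE)
      )
      extra <- sz - 16L
      if (extra > 0) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data before fmt", call. = FALSE)
      if (fmt$format == 1L && fmt$bits == 16L) {
        n <- sz %/% 2L
        x <- readBin(con, "integer", n, size = 2, endian = "little",
                     signed = TRUE)
        samples <- x / 32768
      } else if (fmt$format == 3L && fmt$bits == 32L) {
        n <- sz %/% 4L
        samples <- readBin(con, "double", n, size = 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (format ", fmt$format, ", ",
             fmt$bits, " bits); only 16-bit PCM and 32-bit float are read",
             call. = FALSE)
      }
      if (sz %% 2L == 1L) readBin(con, "raw", 1)  # pad byte
    } else {
      skip <- sz + (sz %% 2L)
      seek(con, skip, origin = "current")
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }

  if (is.null(fmt) || is.null(samples)) {
    stop("corrupt WAV file (missing fmt/data chunk): ", path, call. = FALSE)
  }
  if (length(samples) == 0) {
    stop("zero-length audio in ", path, call. = FALSE)
  }
  if (fmt$channels > 1L) {
    m <- matrix(samples, nrow = fmt$channels)
    samples <- colMeans(m)
  }
  sig <- audio_signal(samples, fmt$rate)
  resample_signal(sig, target_rate)
}

#' Write a mono signal as 16-bit PCM WAV
#'
#' Samples are clipped to [-1, 1] and quantized to 16 bits.
#'
#' @param signal An [audio_signal].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path) {
  stopifnot(inherits(signal, "audio_signal"))
  x <- pmin(pmax(signal$samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # PCM
  writeBin(1L, con, size = 2, endian = "little")                 # mono
  writeBin(as.integer(signal$rate), con, size = 4, endian = "little")
  writeBin(as.integer(signal$rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")                 # block align
  writeBin(16L, con, size = 2, endian = "little")                # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

# Polyphase resampling to a target rate; identity when rates already match.
resample_signal <- function(signal, target_rate) {
  if (signal$rate == target_rate) return(signal)
  g <- gcd_int(as.integer(target_rate), as.integer(signal$rate))
  p <- as.integer(target_rate) %/% g
  q <- as.integer(signal$rate) %/% g
  y <- signal::resample(signal$samples, p, q)
  n_out <- floor(length(signal$samples) * target_rate / signal$rate)
  y <- y[seq_len(min(n_out, length(y)))]
  if (length(y) < n_out) y <- c(y, numeric(n_out - length(y)))
  audio_signal(y, target_rate)
}

gcd_int <- function(a, b) {
  while (b != 0L) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}
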