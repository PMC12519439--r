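#' Construct a waveform
#'
#' A `waveform` is the package's container for sampled mono audio: a numeric
#' vector of finite amplitudes plus a sampling rate in Hz.
#'
#' @param samples Numeric vector of finite amplitudes (dimensionless).
#' @param rate Sampling rate in Hz, a single positive number.
#' @return An object of class `waveform`.
#' @examples
#' w <- waveform(sin(2 * pi * 5 * seq(0, 1, length.out = 4000)), rate = 4000)
#' wave_duration(w)
#' @export
waveform <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("waveform must contain at least one sample", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("waveform samples must all be finite", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("sampling rate must be a single positive number", call. = FALSE)
  }
  structure(list(samples = samples, rate = as.numeric(rate)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.3f s), peak %.4g>\n",
              length(x$samples), x$rate, wave_duration(x),
              max(abs(x$samples))))
  invisible(x)
}

#' Waveform duration in seconds
#' @param w A `waveform`.
#' @return Duration in seconds.
#' @export
wave_duration <- function(w) {
  stopifnot(inherits(w, "waveform"))
  length(w$samples) / w$rate
}

#' Peak-normalize a waveform
#'
#' Scales samples so that `max(abs(samples)) == 1`, making downstream
#' features invariant to recording gain. Silent input is returned unchanged.
#'
#' @param w A `waveform`.
#' @return A peak-normalized `waveform`.
#' @export
normalize_peak <- function(w) {
  stopifnot(inherits(w, "waveform"))
  peak <- max(abs(w$samples))
  if (peak > 0) w$samples <- w$samples / peak
  w
}

#' Read a mono PCM WAV file
#'
#' Reads 16-bit PCM mono RIFF/WAVE files (the format this package writes).
#' Samples are returned scaled to `[-1, 1)`.
#'
#' @param path Path to a WAV file.
#' @return A `waveform`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)
  rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      channels <- fmt[2]
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      extra <- size - 16L
      if (extra > 0L) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("malformed WAV: data before fmt", call. = FALSE)
      n <- size %/% (bits %/% 8L)
      samples <- readBin(con, "integer", n, size = bits %/% 8L,
                         signed = TRUE, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(samples)) stop("no data chunk in WAV: ", path, call. = FALSE)
  if (!identical(channels, 1L)) stop("only mono WAV is supported", call. = FALSE)
  if (!identical(bits, 16L)) stop("only 16-bit PCM WAV is supported", call. = FALSE)
  waveform(samples / 32768, rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' Samples are clipped to `[-1, 1]` and quantized to 16 bits.
#'
#' @param w A `waveform`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  x <- pmax(pmin(w$samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(round(w$rate)), con, size = 4, endian = "little")
  writeBin(as.integer(round(w$rate)) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

# Run code with a private RNG stream: saves and restores .Random.seed so
# seeded synthesis never perturbs the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
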