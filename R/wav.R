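#' Audio signal container
#'
#' A mono waveform on the 16-bit signed-integer amplitude scale. All volume
#' arithmetic downstream (pause thresholds of 30/20, the mean-volume cutoff of
#' 100) is defined on this scale, so [read_wav()] normalizes any source bit
#' depth to it.
#'
#' @param samples Numeric vector of amplitudes in the 16-bit range
#'   `[-32768, 32767]`.
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @param subject_id Optional subject identifier carried through extraction.
#' @return An object of class `audio_signal`: a list with elements `samples`,
#'   `sample_rate` and `subject_id`.
#' @examples
#' sig <- audio_signal(sin(2 * pi * 150 * seq(0, 1, by = 1 / 44100)) * 3000)
#' duration(sig)
#' @export
audio_signal <- function(samples, sample_rate = 44100, subject_id = NULL) {
  if (!is.numeric(samples) || length(samples) == 0L) {
    pdb_stop("input_error", "`samples` must be a non-empty numeric vector")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    pdb_stop("input_error", "`sample_rate` must be a single positive number")
  }
  if (max(samples) > 32767 + 1e-9 || min(samples) < -32768 - 1e-9) {
    pdb_stop("input_error",
             "samples exceed the 16-bit amplitude range [-32768, 32767]")
  }
  structure(
    list(samples = as.double(samples), sample_rate = as.double(sample_rate),
         subject_id = subject_id),
    class = "audio_signal"
  )
}

#' @rdname audio_signal
#' @param x,object An `audio_signal`.
#' @param ... Unused.
#' @export
duration <- function(object, ...) UseMethod("duration")

#' @export
duration.audio_signal <- function(object, ...) length(object$samples) / object$sample_rate

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %s: %d samples @ %g Hz (%.2f s)\n",
              if (is.null(x$subject_id)) "?" else x$subject_id,
              length(x$samples), x$sample_rate, duration(x)))
  invisible(x)
}

## ---- RIFF/PCM parsing --------------------------------------------------
## No installed package reads WAV, so the (small) PCM subset of RIFF is
## parsed directly: 8/16/24/32-bit integer PCM, mono or stereo.

read_u32 <- function(con) readBin(con, "integer", 1L, size = 4L, endian = "little")
read_u16 <- function(con) readBin(con, "integer", 1L, size = 2L, endian = "little", signed = FALSE)

#' Read a PCM WAV file
#'
#' Reads linear PCM WAV (8/16/24/32-bit integer, mono or stereo). Stereo is
#' averaged to mono, and samples are rescaled to the 16-bit signed range
#' `[-32768, 32767]` regardless of the source bit depth (higher depths by
#' integer truncation of the low bytes), so the absolute pause thresholds
#' used by the voice features keep their meaning.
#'
#' @param path Path to a `.wav` file.
#' @param subject_id Optional subject identifier to attach.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path, subject_id = NULL) {
  if (!file.exists(path)) pdb_stop("format_error", paste0("WAV file not found: ", path))
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  riff <- rawToChar(readBin(con, "raw", 4L))
  read_u32(con) # overall size, unused
  wave <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    pdb_stop("format_error", paste0("not a RIFF/WAVE file: ", path))
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id_raw <- readBin(con, "raw", 4L)
    if (length(id_raw) < 4L) break
    chunk_id <- rawToChar(id_raw)
    chunk_size <- read_u32(con)
    if (identical(chunk_id, "fmt ")) {
      audio_format <- read_u16(con)
      n_channels <- read_u16(con)
      sample_rate <- read_u32(con)
      read_u32(con); read_u16(con) # byte rate, block align
      bits <- read_u16(con)
      if (chunk_size > 16L) readBin(con, "raw", chunk_size - 16L)
      fmt <- list(format = audio_format, channels = n_channels,
                  rate = sample_rate, bits = bits)
    } else if (identical(chunk_id, "data")) {
      data_raw <- readBin(con, "raw", chunk_size)
    } else {
      readBin(con, "raw", chunk_size + chunk_size %% 2L) # skip (chunks are word-aligned)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    pdb_stop("format_error", paste0("missing fmt/data chunk in WAV file: ", path))
  }
  if (fmt$format != 1L) {
    pdb_stop("format_error",
             paste0("unsupported WAV encoding (only integer PCM is handled): ", path))
  }
  bits <- fmt$bits
  if (!bits %in% c(8L, 16L, 24L, 32L)) {
    pdb_stop("format_error", paste0("unsupported PCM bit depth ", bits, ": ", path))
  }

  samples <- switch(as.character(bits),
    "8" = {
      # 8-bit WAV is unsigned, midpoint 128
      (as.double(as.integer(data_raw)) - 128) * 256
    },
    "16" = {
      n <- length(data_raw) %/% 2L
      as.double(readBin(data_raw, "integer", n, size = 2L, endian = "little", signed = TRUE))
    },
    "24" = {
      n <- length(data_raw) %/% 3L
      b <- matrix(as.integer(data_raw[seq_len(n * 3L)]), nrow = 3L)
      v <- b[1L, ] + b[2L, ] * 256 + b[3L, ] * 65536
      v <- ifelse(v >= 8388608, v - 16777216, v)
      trunc(v / 256) # drop the low byte: literal 24 -> 16 bit conversion
    },
    "32" = {
      n <- length(data_raw) %/% 4L
      v <- as.double(readBin(data_raw, "integer", n, size = 4L, endian = "little"))
      trunc(v / 65536)
    })

  if (fmt$channels > 1L) {
    n_frames <- length(samples) %/% fmt$channels
    samples <- colMeans(matrix(samples[seq_len(n_frames * fmt$channels)],
                               nrow = fmt$channels))
  }
  if (length(samples) == 0L) pdb_stop("format_error", paste0("empty data chunk: ", path))
  audio_signal(samples, sample_rate = fmt$rate, subject_id = subject_id)
}

#' Write an audio signal as 16-bit PCM WAV
#'
#' @param signal An [audio_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path) {
  stopifnot(inherits(signal, "audio_signal"))
  s <- as.integer(pmin(32767, pmax(-32768, round(signal$samples))))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  n_bytes <- length(s) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")          # PCM
  writeBin(1L, con, size = 2L, endian = "little")          # mono
  writeBin(as.integer(signal$sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(signal$sample_rate * 2), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")          # block align
  writeBin(16L, con, size = 2L, endian = "little")         # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4L, endian = "little")
  writeBin(s, con, size = 2L, endian = "little")
  invisible(path)
}
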