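# Minimal RIFF/WAVE PCM-16 I/O. Only what the package needs: read mono or
# multichannel 16-bit PCM (returning samples scaled to [-1, 1]), write mono
# 16-bit PCM. No compression, no streaming.

read_wav <- function(path) {
  if (!file.exists(path)) input_error("WAV file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) input_error("not a RIFF/WAVE file: %s", path)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) input_error("not a RIFF/WAVE file: %s", path)

  sample_rate <- NULL; n_channels <- NULL; bits <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(size) == 0L) break
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "raw", size)
      audio_format <- sum(as.integer(fmt[1:2]) * c(1, 256))
      if (audio_format != 1L)
        input_error("unsupported WAV encoding (only PCM): %s", path)
      n_channels  <- sum(as.integer(fmt[3:4]) * c(1, 256))
      sample_rate <- sum(as.integer(fmt[5:8]) * c(1, 256, 65536, 16777216))
      bits        <- sum(as.integer(fmt[15:16]) * c(1, 256))
      if (bits != 16L)
        input_error("unsupported bit depth %d (only 16-bit PCM): %s", bits, path)
    } else if (identical(id, "data")) {
      data <- readBin(con, "integer", size / 2L, 2, signed = TRUE,
                      endian = "little")
      break
    } else {
      seek(con, size + size %% 2L, origin = "current")
    }
  }
  if (is.null(sample_rate) || is.null(data))
    input_error("malformed WAV (missing fmt/data chunk): %s", path)
  if (length(data) == 0L) input_error("empty WAV file: %s", path)
  samples <- matrix(data / 32768, ncol = n_channels, byrow = TRUE)
  list(samples = samples, sample_rate = sample_rate, n_channels = n_channels)
}

write_wav <- function(samples, sample_rate, path) {
  stopifnot(is.numeric(samples), sample_rate > 0)
  x <- pmax(-1, pmin(1, samples))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")                 # PCM
  writeBin(1L, con, 2, endian = "little")                 # mono
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")                 # block align
  writeBin(16L, con, 2, endian = "little")                # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
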