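#' Construct a PCG recording
#'
#' A `pcg_recording` holds a single-channel phonocardiogram: a numeric vector
#' of dimensionless amplitudes, the sampling rate in Hz, an optional class
#' label, and a provenance identifier.
#'
#' @param samples numeric vector of amplitudes.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param label optional heart-sound class label.
#' @param source_id provenance string (file name or synthesis tag).
#' @return an object of class `pcg_recording` with fields `samples`,
#'   `sample_rate`, `label`, `source_id`.
#' @export
pcg_recording <- function(samples, sample_rate, label = NULL, source_id = "") {
  if (!is.numeric(samples) || length(samples) < 1L)
    input_error("a recording needs at least one numeric sample")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    input_error("sample_rate must be a single positive number")
  if (any(!is.finite(samples)))
    input_error("recording contains non-finite samples")
  structure(
    list(samples = as.numeric(samples), sample_rate = as.numeric(sample_rate),
         label = label, source_id = source_id),
    class = "pcg_recording")
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("<pcg_recording> %s: %d samples @ %g Hz (%.3f s)%s\n",
              if (nzchar(x$source_id)) x$source_id else "(unnamed)",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              if (!is.null(x$label)) paste0(", label=", x$label) else ""))
  invisible(x)
}

#' Peak-normalize a recording
#'
#' Rescales so that `max(abs(samples)) == 1`; an all-zero recording is
#' returned unchanged.
#'
#' @param rec a [pcg_recording()].
#' @return the normalized `pcg_recording`.
#' @export
normalize_recording <- function(rec) {
  stopifnot(inherits(rec, "pcg_recording"))
  peak <- max(abs(rec$samples))
  if (peak > 0) rec$samples <- rec$samples / peak
  rec
}

#' Load a WAV file as a PCG recording
#'
#' Reads a 16-bit PCM WAV file, keeps the first channel, and peak-normalizes.
#'
#' @param path path to a WAV file.
#' @return a [pcg_recording()] at the file's native sample rate.
#' @export
load_recording <- function(path) {
  w <- read_wav(path)
  rec <- pcg_recording(w$samples[, 1L], w$sample_rate,
                       source_id = basename(path))
  normalize_recording(rec)
}

#' Write a PCG recording to a 16-bit PCM mono WAV file
#'
#' @param rec a [pcg_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_recording <- function(rec, path) {
  stopifnot(inherits(rec, "pcg_recording"))
  write_wav(rec$samples, rec$sample_rate, path)
}

#' Band-limited resampling of a recording
#'
#' Polyphase resampling to a new rate. The floor of 2000 Hz guarantees the
#' physiological PCG band (up to 1000 Hz) stays below Nyquist.
#'
#' @param rec a [pcg_recording()].
#' @param target_rate new sampling rate in Hz (>= 2000).
#' @return the resampled `pcg_recording`; samples unchanged if the rate
#'   already matches.
#' @export
resample_recording <- function(rec, target_rate) {
  stopifnot(inherits(rec, "pcg_recording"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate < 2000)
    config_error("target_rate must be >= 2000 Hz, got %s", deparse(target_rate))
  if (target_rate == rec$sample_rate) return(rec)
  g <- gcd_int(round(target_rate), round(rec$sample_rate))
  p <- round(target_rate) / g
  q <- round(rec$sample_rate) / g
  y <- signal::resample(rec$samples, p, q)
  out <- pcg_recording(y, target_rate, label = rec$label,
                       source_id = rec$source_id)
  out
}

gcd_int <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}
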