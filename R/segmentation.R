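# Variable-size-window heart-tone segmentation.
#
# PCG signals are non-stationary, so fixed-frame analysis (as in speech LPC)
# is inappropriate: each heart tone is isolated by a window sized to that
# tone. The detector is a normalized Shannon-energy envelope with a relative
# threshold, gap merging, a minimum duration, and boundary padding; all
# constants are exposed through the configuration object.

#' Segmentation configuration
#'
#' @param frame_length envelope frame length in seconds (default 0.02).
#' @param frame_hop hop between frames in seconds (default 0.01).
#' @param threshold_fraction detection threshold as a fraction of the
#'   envelope maximum, in (0, 1) (default 0.2).
#' @param merge_gap merge detections separated by less than this many
#'   seconds (default 0.05).
#' @param min_duration discard detections shorter than this (default 0.03 s).
#' @param pad seconds added to each boundary, clamped to the recording
#'   (default 0.01).
#' @return an object of class `segmentation_config`.
#' @export
segmentation_config <- function(frame_length = 0.02, frame_hop = 0.01,
                                threshold_fraction = 0.2, merge_gap = 0.05,
                                min_duration = 0.03, pad = 0.01) {
  vals <- c(frame_length, frame_hop, merge_gap, min_duration, pad)
  if (any(!is.finite(vals)) || any(vals[1:4] <= 0) || pad < 0)
    config_error("segmentation parameters must be positive (pad >= 0)")
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    config_error("threshold_fraction must lie in (0, 1), got %g", threshold_fraction)
  structure(list(frame_length = frame_length, frame_hop = frame_hop,
                 threshold_fraction = threshold_fraction, merge_gap = merge_gap,
                 min_duration = min_duration, pad = pad),
            class = "segmentation_config")
}

#' Construct a heart-tone segment
#'
#' @param samples numeric amplitudes of the excerpt.
#' @param sample_rate Hz.
#' @param start_time,end_time boundaries in seconds within the parent
#'   recording, half-open `[start, end)`.
#' @param parent_id identifier of the source recording.
#' @return an object of class `heart_tone_segment`.
#' @export
heart_tone_segment <- function(samples, sample_rate, start_time, end_time,
                               parent_id = "") {
  if (start_time < 0 || end_time <= start_time)
    input_error("segment times must satisfy 0 <= start < end")
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 start_time = start_time, end_time = end_time,
                 parent_id = parent_id),
            class = "heart_tone_segment")
}

#' @export
print.heart_tone_segment <- function(x, ...) {
  cat(sprintf("<heart_tone_segment> [%.3f, %.3f) s of %s (%d samples @ %g Hz)\n",
              x$start_time, x$end_time,
              if (nzchar(x$parent_id)) x$parent_id else "(unknown)",
              length(x$samples), x$sample_rate))
  invisible(x)
}

#' Normalized Shannon energy envelope
#'
#' Per-frame Shannon energy `-mean(x^2 log x^2)` (with `0 log 0 := 0`),
#' rescaled so the maximum is 1 (an all-zero envelope stays zero). Shannon
#' energy emphasizes medium-intensity tone activity over both background
#' noise and isolated spikes, which makes the subsequent relative threshold
#' robust.
#'
#' @param rec a [pcg_recording()], longer than one frame.
#' @param cfg a [segmentation_config()].
#' @return data.frame with columns `time` (frame center, s) and `envelope`.
#' @export
compute_energy_envelope <- function(rec, cfg = segmentation_config()) {
  stopifnot(inherits(rec, "pcg_recording"))
  fs <- rec$sample_rate
  frame_n <- max(1L, round(cfg$frame_length * fs))
  hop_n <- max(1L, round(cfg$frame_hop * fs))
  n <- length(rec$samples)
  if (n < frame_n)
    input_error("recording (%d samples) shorter than one frame (%d samples)",
                n, frame_n)
  n_frames <- (n - frame_n) %/% hop_n + 1L
  env <- numeric(n_frames)
  for (i in seq_len(n_frames)) {
    x2 <- rec$samples[((i - 1L) * hop_n + 1L):((i - 1L) * hop_n + frame_n)]^2
    term <- ifelse(x2 > 0, x2 * log(x2), 0)
    env[i] <- -mean(term)
  }
  env[env < 0] <- 0  # |x| > 1 would make terms positive; clamp for safety
  if (max(env) > 0) env <- env / max(env)
  time <- ((seq_len(n_frames) - 1L) * hop_n + frame_n / 2) / fs
  data.frame(time = time, envelope = env)
}

#' Segment heart tones with a variable-size time window
#'
#' Finds contiguous envelope regions above `threshold_fraction` of the
#' envelope maximum, merges regions separated by less than `merge_gap`,
#' drops regions shorter than `min_duration`, pads boundaries by `pad` and
#' clamps to the recording. Each surviving region is returned as a
#' [heart_tone_segment()] — the variable-size window around one tone.
#' Silence yields an empty list.
#'
#' @param rec a [pcg_recording()].
#' @param cfg a [segmentation_config()].
#' @return list of [heart_tone_segment()], time-ordered, non-overlapping.
#' @export
segment_heart_tones <- function(rec, cfg = segmentation_config()) {
  env <- compute_energy_envelope(rec, cfg)
  if (max(env$envelope) <= 0) return(list())
  fs <- rec$sample_rate
  frame_n <- max(1L, round(cfg$frame_length * fs))
  hop_n <- max(1L, round(cfg$frame_hop * fs))
  above <- env$envelope >= cfg$threshold_fraction
  if (!any(above)) return(list())

  r <- rle(above)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  runs <- which(r$values)
  # frame i spans [(i-1) hop, (i-1) hop + frame) seconds
  ivs <- cbind(start = ((starts_i[runs] - 1L) * hop_n) / fs,
               end = ((ends_i[runs] - 1L) * hop_n + frame_n) / fs)

  merged <- ivs[1, , drop = FALSE]
  for (k in seq_len(nrow(ivs))[-1]) {
    last <- nrow(merged)
    if (ivs[k, "start"] - merged[last, "end"] < cfg$merge_gap)
      merged[last, "end"] <- ivs[k, "end"]
    else merged <- rbind(merged, ivs[k, , drop = FALSE])
  }
  keep <- (merged[, "end"] - merged[, "start"]) >= cfg$min_duration
  merged <- merged[keep, , drop = FALSE]
  if (nrow(merged) == 0L) return(list())

  dur <- length(rec$samples) / fs
  merged[, "start"] <- pmax(0, merged[, "start"] - cfg$pad)
  merged[, "end"] <- pmin(dur, merged[, "end"] + cfg$pad)
  # padding may create overlaps; merge them
  final <- merged[1, , drop = FALSE]
  for (k in seq_len(nrow(merged))[-1]) {
    last <- nrow(final)
    if (merged[k, "start"] <= final[last, "end"])
      final[last, "end"] <- max(final[last, "end"], merged[k, "end"])
    else final <- rbind(final, merged[k, , drop = FALSE])
  }

  lapply(seq_len(nrow(final)), function(k) {
    i0 <- floor(final[k, "start"] * fs) + 1L
    i1 <- min(length(rec$samples), ceiling(final[k, "end"] * fs))
    heart_tone_segment(rec$samples[i0:i1], fs,
                       start_time = final[k, "start"],
                       end_time = final[k, "end"],
                       parent_id = rec$source_id)
  })
}

#' Write segment boundaries as CSV
#'
#' @param segments list of [heart_tone_segment()].
#' @param path output CSV path (columns `source_id,start_s,end_s`).
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  df <- data.frame(
    source_id = vapply(segments, function(s) s$parent_id, ""),
    start_s = vapply(segments, function(s) s$start_time, numeric(1)),
    end_s = vapply(segments, function(s) s$end_time, numeric(1)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
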