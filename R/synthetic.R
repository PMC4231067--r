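# Seeded synthetic phonocardiogram generator.
#
# Each heart-sound class is described by a small set of components: damped
# sinusoids (valve tones: distinct low-frequency spectral peaks) and
# amplitude-enveloped bandpass noise bursts (murmurs: broadband turbulent
# flow). Per-realization jitter and additive white noise give within-class
# variability; everything is a pure function of (spec, sample_rate, seed).

#' Describe one heart-sound class for the synthetic generator
#'
#' @param class_name class label (one of the twelve heart-sound classes for
#'   the defaults, but any name is accepted).
#' @param components list of components; each a list with fields
#'   `center_frequency` (Hz, 15--1000), `bandwidth` (Hz, used for
#'   `bandpass_noise`), `onset` (s, >= 0), `duration` (s, > 0), `amplitude`
#'   (relative), `type` (`"damped_sinusoid"` or `"bandpass_noise"`).
#' @param jitter fractional per-realization variability, a list with elements
#'   `frequency`, `duration`, `amplitude` (defaults 0.10, 0.20, 0.20).
#' @param snr_db additive white-noise level in dB relative to the rendered
#'   tone power (default 25).
#' @return an object of class `tone_class_spec`.
#' @export
tone_class_spec <- function(class_name, components,
                            jitter = list(frequency = 0.10, duration = 0.20,
                                          amplitude = 0.20),
                            snr_db = 25) {
  spec <- structure(
    list(class_name = class_name, components = components, jitter = jitter,
         snr_db = snr_db),
    class = "tone_class_spec")
  validate_tone_class_spec(spec)
  spec
}

component <- function(center_frequency, duration, amplitude = 1, onset = 0,
                      bandwidth = 0, type = "damped_sinusoid") {
  list(center_frequency = center_frequency, bandwidth = bandwidth,
       onset = onset, duration = duration, amplitude = amplitude, type = type)
}

validate_tone_class_spec <- function(spec) {
  comps <- spec$components
  if (length(comps) < 1L)
    input_error("spec '%s' has no components", spec$class_name)
  for (cm in comps) {
    if (cm$center_frequency < 15 || cm$center_frequency > 1000)
      input_error("spec '%s': component frequency %g Hz outside the 15-1000 Hz PCG band",
                  spec$class_name, cm$center_frequency)
    if (cm$duration <= 0)
      input_error("spec '%s': non-positive component duration", spec$class_name)
    if (cm$onset < 0)
      input_error("spec '%s': negative component onset", spec$class_name)
    if (!cm$type %in% c("damped_sinusoid", "bandpass_noise"))
      input_error("spec '%s': unknown component type '%s'", spec$class_name, cm$type)
  }
  ends <- vapply(comps, function(cm) cm$onset + cm$duration, numeric(1))
  if (max(ends) > 2)
    input_error("spec '%s': rendered length %.2f s exceeds 2 s", spec$class_name, max(ends))
  if (grepl("split", spec$class_name, fixed = TRUE)) {
    if (length(comps) != 2L ||
        !all(vapply(comps, function(cm) cm$type, "") == "damped_sinusoid"))
      input_error("split class '%s' must have exactly two damped-sinusoid components",
                  spec$class_name)
    gap <- abs(comps[[2]]$onset - comps[[1]]$onset)
    if (gap < 0.03 || gap > 0.08)
      input_error("split class '%s': component onset gap %.3f s outside [0.03, 0.08] s",
                  spec$class_name, gap)
  }
  if (grepl("murmur", spec$class_name, fixed = TRUE)) {
    if (!any(vapply(comps, function(cm) cm$type, "") == "bandpass_noise"))
      input_error("murmur class '%s' needs at least one bandpass_noise component",
                  spec$class_name)
  }
  invisible(spec)
}

#' Default specifications for the twelve heart-sound classes
#'
#' Four normal tones (S1, S2, S3, S4), the split and transient variants
#' (normal split S1/S2, ejection click, opening snap) and four noise-like
#' pathologies (early/late/pansystolic murmur, diastolic rumble). Tones are
#' one or two damped sinusoids with low-frequency peaks; murmurs are
#' broadband enveloped noise; the diastolic rumble keeps every component
#' below 150 Hz. The parameter table is qualitative (chosen for spectral
#' distinctness across classes), not a hemodynamic model.
#'
#' @return named list of twelve [tone_class_spec()] objects.
#' @export
default_class_specs <- function() {
  # Tone centers follow a coarse log-spaced ladder (ratio ~1.35) so that the
  # +-10% per-realization frequency jitter cannot push one class into the
  # band of its neighbour; spectral distinctness under jitter is the design
  # goal of this table, not hemodynamic fidelity.
  #
  # Tones carry two or three stacked resonances (real heart tones have rich
  # spectral envelopes, which is what makes a high-order all-pole fit
  # informative); split tones are constrained to exactly two components.
  specs <- list(
    tone_class_spec("S1", list(
      component(36, 0.14, 1.0), component(90, 0.10, 0.6),
      component(190, 0.08, 0.3))),
    tone_class_spec("S2", list(
      component(66, 0.12, 1.0), component(164, 0.09, 0.7),
      component(330, 0.07, 0.35))),
    tone_class_spec("S3", list(
      component(27, 0.12, 1.0), component(75, 0.08, 0.4))),
    tone_class_spec("S4", list(
      component(20, 0.12, 1.0), component(50, 0.08, 0.4))),
    tone_class_spec("ejection click", list(
      component(298, 0.08, 1.0), component(600, 0.06, 0.5))),
    tone_class_spec("normal split S1", list(
      component(49, 0.08, 1.0, onset = 0),
      component(121, 0.08, 0.9, onset = 0.045))),
    tone_class_spec("normal split S2", list(
      component(90, 0.07, 1.0, onset = 0),
      component(221, 0.07, 0.9, onset = 0.040))),
    tone_class_spec("opening snap", list(
      component(544, 0.08, 1.0), component(130, 0.08, 0.5))),
    tone_class_spec("early systolic murmur", list(
      component(250, 0.18, 1.0, bandwidth = 300, type = "bandpass_noise"))),
    tone_class_spec("late systolic murmur", list(
      component(420, 0.15, 1.0, bandwidth = 280, type = "bandpass_noise"))),
    tone_class_spec("pansystolic murmur", list(
      component(300, 0.35, 1.0, bandwidth = 450, type = "bandpass_noise"))),
    tone_class_spec("diastolic rumble", list(
      component(70, 0.30, 1.0, bandwidth = 90, type = "bandpass_noise")))
  )
  names(specs) <- vapply(specs, function(s) s$class_name, "")
  specs
}

#' Render one synthetic heart tone
#'
#' Sums the spec's components (damped sinusoids `a e^(-t/tau) sin(2 pi f t)`
#' with `tau = duration/4`, or Hann-enveloped Butterworth-bandpass noise),
#' applies per-component jitter, adds white noise at `snr_db`, and
#' peak-normalizes. Deterministic for a fixed seed.
#'
#' @param spec a [tone_class_spec()].
#' @param sample_rate sampling rate in Hz (>= 2000).
#' @param seed integer RNG seed for jitter and noise.
#' @return a [pcg_recording()] labeled with the spec's class name.
#' @export
generate_tone <- function(spec, sample_rate = 4000, seed = 1) {
  validate_tone_class_spec(spec)
  if (sample_rate < 2000)
    config_error("sample_rate must be >= 2000 Hz, got %g", sample_rate)
  with_seed(seed, {
    jit <- function(frac) if (frac > 0) 1 + stats::runif(1, -frac, frac) else 1
    jf <- spec$jitter$frequency %||% 0
    jd <- spec$jitter$duration  %||% 0
    ja <- spec$jitter$amplitude %||% 0

    ends <- vapply(spec$components, function(cm)
      cm$onset + cm$duration * (1 + jd), numeric(1))
    total <- min(2, max(ends) + 0.05)
    n <- round(total * sample_rate)
    t <- (0:(n - 1)) / sample_rate
    x <- numeric(n)

    for (cm in spec$components) {
      f   <- cm$center_frequency * jit(jf)
      dur <- cm$duration * jit(jd)
      amp <- cm$amplitude * jit(ja)
      idx <- which(t >= cm$onset & t < cm$onset + dur)
      if (length(idx) < 4L) next
      tl <- t[idx] - cm$onset
      if (cm$type == "damped_sinusoid") {
        tau <- dur / 4
        x[idx] <- x[idx] + amp * exp(-tl / tau) * sin(2 * pi * f * tl)
      } else {
        lo <- max(15, f - cm$bandwidth / 2)
        hi <- min(0.95 * sample_rate / 2, f + cm$bandwidth / 2)
        bf <- signal::butter(4, c(lo, hi) / (sample_rate / 2), type = "pass")
        noise <- stats::rnorm(length(idx))
        shaped <- signal::filtfilt(bf, noise)
        env <- 0.5 - 0.5 * cos(2 * pi * seq_along(idx) / length(idx))
        shaped <- shaped * env
        rms <- sqrt(mean(shaped^2))
        if (rms > 0) shaped <- shaped / rms
        x[idx] <- x[idx] + amp * shaped
      }
    }

    p_sig <- mean(x^2)
    if (is.finite(spec$snr_db) && p_sig > 0) {
      sd_noise <- sqrt(p_sig / 10^(spec$snr_db / 10))
      x <- x + stats::rnorm(n, sd = sd_noise)
    }
    rec <- pcg_recording(x, sample_rate, label = spec$class_name,
                         source_id = sprintf("synth:%s:%d", spec$class_name, seed))
    normalize_recording(rec)
  })
}

#' Generate a labeled synthetic PCG dataset
#'
#' Renders `per_class_count` jittered realizations of each class (class-major
#' order). The dataset is a pure function of its arguments: the same call
#' always yields identical recordings.
#'
#' @param per_class_count recordings per class (>= 1).
#' @param sample_rate sampling rate in Hz.
#' @param seed master integer seed; per-tone seeds are derived from it.
#' @param specs class specifications, default [default_class_specs()].
#' @return an object of class `pcg_dataset`: list with `recordings` (list of
#'   [pcg_recording()]), `labels` (character), `per_class_count`,
#'   `sample_rate`, `seed`.
#' @export
generate_dataset <- function(per_class_count, sample_rate = 4000, seed = 42,
                             specs = default_class_specs()) {
  if (per_class_count < 1L) config_error("per_class_count must be >= 1")
  recs <- list(); labels <- character(0)
  for (i in seq_along(specs)) {
    for (j in seq_len(per_class_count)) {
      s <- derive_seed(seed, i, j)
      rec <- generate_tone(specs[[i]], sample_rate, s)
      rec$source_id <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "-",
                                               specs[[i]]$class_name), j)
      recs[[length(recs) + 1L]] <- rec
      labels <- c(labels, specs[[i]]$class_name)
    }
  }
  structure(list(recordings = recs, labels = labels,
                 per_class_count = per_class_count,
                 sample_rate = sample_rate, seed = seed),
            class = "pcg_dataset")
}

#' @export
print.pcg_dataset <- function(x, ...) {
  cat(sprintf("<pcg_dataset> %d recordings (%d classes x %d) @ %g Hz, seed %d\n",
              length(x$recordings), length(unique(x$labels)),
              x$per_class_count, x$sample_rate, x$seed))
  invisible(x)
}

#' Write a synthetic dataset as WAV files plus a CSV manifest
#'
#' @param dataset a `pcg_dataset` from [generate_dataset()].
#' @param dir output directory (created if missing). The manifest
#'   `manifest.csv` has columns `filename,class_label,seed`.
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "pcg_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- data.frame(filename = character(0), class_label = character(0),
                     seed = integer(0), stringsAsFactors = FALSE)
  for (i in seq_along(dataset$recordings)) {
    rec <- dataset$recordings[[i]]
    fn <- paste0(rec$source_id, ".wav")
    save_recording(rec, file.path(dir, fn))
    rows <- rbind(rows, data.frame(filename = fn, class_label = dataset$labels[i],
                                   seed = dataset$seed, stringsAsFactors = FALSE))
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(rows, manifest, row.names = FALSE)
  invisible(manifest)
}
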