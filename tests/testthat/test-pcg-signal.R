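# WAV I/O, resampling, Shannon-energy envelope, tone segmentation.

write_stereo_wav <- function(left, right, sample_rate, path) {
  pcm <- as.integer(round(pmax(-1, pmin(1, c(rbind(left, right)))) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * length(pcm)), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL); writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(2L, con, 2, endian = "little")
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * 4), con, 4, endian = "little")
  writeBin(4L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * length(pcm)), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
}

test_that("WAV loading returns the first channel, peak-normalized", {
  dir <- withr::local_tempdir()
  t <- (0:3999) / 4000
  mono <- file.path(dir, "mono.wav")
  save_recording(pcg_recording(0.5 * sin(2 * pi * 100 * t), 4000), mono)
  rec <- load_recording(mono)
  expect_length(rec$samples, 4000)
  expect_equal(rec$sample_rate, 4000)
  expect_equal(max(abs(rec$samples)), 1)  # normalized on load

  stereo <- file.path(dir, "stereo.wav")
  write_stereo_wav(sin(2 * pi * 100 * t), sin(2 * pi * 300 * t), 4000, stereo)
  rec2 <- load_recording(stereo)
  expect_length(rec2$samples, 4000)
  expect_lt(abs(dominant_freq(rec2$samples, 4000) - 100), 2)

  empty <- file.path(dir, "empty.wav")
  pcgclassify:::write_wav(numeric(0), 4000, empty)
  expect_error(load_recording(empty), class = "pcg_input_error")
  expect_error(load_recording(file.path(dir, "nope.wav")),
               class = "pcg_input_error")
})

test_that("resampling preserves spectral content and rejects low rates", {
  t <- (0:44099) / 44100
  rec <- pcg_recording(sin(2 * pi * 100 * t), 44100)
  same <- resample_recording(rec, 44100)
  expect_identical(same$samples, rec$samples)

  down <- resample_recording(rec, 4000)
  expect_equal(length(down$samples) / 4000, 1, tolerance = 1e-3)
  expect_lt(abs(dominant_freq(down$samples, 4000) - 100), 2)

  expect_error(resample_recording(rec, 1000), class = "pcg_config_error")
})

test_that("Shannon energy envelope handles degenerate and localized signals", {
  cfg <- segmentation_config()
  zero <- pcg_recording(numeric(1000) + 0, 4000)
  zero$samples[] <- 0
  expect_true(all(compute_energy_envelope(zero, cfg)$envelope == 0))

  # time-invariance: constant input, constant envelope (rescaled to 1)
  const <- pcg_recording(rep(0.5, 1000), 4000)
  env <- compute_energy_envelope(const, cfg)$envelope
  expect_true(all(env == 1))

  # |x| = 1 makes x^2 log x^2 vanish identically
  unit <- pcg_recording(rep(c(1, -1), 500), 4000)
  expect_true(all(compute_energy_envelope(unit, cfg)$envelope == 0))

  burst <- numeric(4000)
  burst[401:800] <- sin(2 * pi * 100 * (1:400) / 4000)  # 0.10-0.20 s
  env2 <- compute_energy_envelope(pcg_recording(burst, 4000), cfg)
  hot <- env2$time[env2$envelope > 0.5]
  expect_true(all(hot > 0.10 - cfg$frame_length & hot < 0.20 + cfg$frame_length))

  expect_error(compute_energy_envelope(pcg_recording(1:10 / 10, 4000), cfg),
               class = "pcg_input_error")
  n_frames <- (4000 - 80) %/% 40 + 1
  expect_equal(nrow(env2), n_frames)
})

test_that("segmentation isolates bursts with near-true boundaries", {
  fs <- 4000
  x <- numeric(fs)  # 1 s
  x[(0.10 * fs):(0.18 * fs)] <- sin(2 * pi * 120 * seq_len(0.08 * fs + 1) / fs)
  x[(0.40 * fs):(0.46 * fs)] <- 0.8 * sin(2 * pi * 90 * seq_len(0.06 * fs + 1) / fs)
  rec <- pcg_recording(x, fs)
  segs <- segment_heart_tones(rec)
  expect_length(segs, 2)
  expect_lt(abs(segs[[1]]$start_time - 0.10), 0.03)
  expect_lt(abs(segs[[1]]$end_time - 0.18), 0.03)
  expect_lt(abs(segs[[2]]$start_time - 0.40), 0.03)
  expect_lt(abs(segs[[2]]$end_time - 0.46), 0.03)

  silence <- pcg_recording(numeric(2000), fs)
  expect_identical(segment_heart_tones(silence), list())
})

test_that("a synthetic S1+S2+S3 cycle yields three windows", {
  fs <- 4000
  x <- numeric(fs)
  place <- function(x, t0, dur, f, amp) {
    idx <- round(t0 * fs):round((t0 + dur) * fs)
    tl <- (idx - idx[1]) / fs
    x[idx] <- x[idx] + amp * exp(-tl / (dur / 4)) * sin(2 * pi * f * tl)
    x
  }
  x <- place(x, 0.10, 0.10, 45, 1.0)   # S1
  x <- place(x, 0.40, 0.07, 65, 0.8)   # S2
  x <- place(x, 0.55, 0.07, 32, 0.6)   # S3
  segs <- segment_heart_tones(pcg_recording(x, fs))
  expect_length(segs, 3)
})

test_that("segmentation is scale-invariant, non-overlapping and shift-covariant", {
  fs <- 4000
  tone <- generate_tone(default_class_specs()[["normal split S1"]], fs, 21)
  # leading silence keeps boundaries away from the t = 0 clamp
  rec <- pcg_recording(c(numeric(400), tone$samples), fs)
  segs <- segment_heart_tones(rec)
  expect_gt(length(segs), 0)

  scaled <- rec
  scaled$samples <- 0.05 * scaled$samples
  segs_s <- segment_heart_tones(scaled)
  expect_equal(length(segs_s), length(segs))
  expect_equal(vapply(segs_s, `[[`, numeric(1), "start_time"),
               vapply(segs, `[[`, numeric(1), "start_time"))

  starts <- vapply(segs, `[[`, numeric(1), "start_time")
  ends <- vapply(segs, `[[`, numeric(1), "end_time")
  expect_true(all(starts < ends))
  if (length(segs) > 1) expect_true(all(starts[-1] >= ends[-length(ends)]))
  expect_lte(sum(ends - starts), length(rec$samples) / fs)

  hop <- segmentation_config()$frame_hop
  for (k in c(200, 440)) {  # shift by k samples
    shifted <- pcg_recording(c(numeric(k), rec$samples), fs)
    segs_k <- segment_heart_tones(shifted)
    expect_equal(length(segs_k), length(segs))
    got <- vapply(segs_k, `[[`, numeric(1), "start_time")
    expect_true(all(abs(got - (starts + k / fs)) <= hop + 1e-9))
  }
})
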