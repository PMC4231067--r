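# LPC estimation: autocorrelation, Levinson-Durbin, spectra, fitness factor.

test_that("autocorrelation matches the brute-force windowed sum", {
  set.seed(1)
  x <- rnorm(400)
  r <- autocorrelate(x, 10)
  xw <- x * (0.54 - 0.46 * cos(2 * pi * (0:399) / 399))
  brute <- sapply(0:10, function(k)
    sum(xw[1:(400 - k)] * xw[(1 + k):400]) / 400)
  expect_equal(r, brute, tolerance = 1e-12)
  expect_gt(r[1], 0)
})

test_that("white-noise autocorrelation is near-delta; degenerate inputs rejected", {
  set.seed(2)
  x <- rnorm(8192)
  r <- autocorrelate(x, 24)
  expect_true(all(abs(r[-1] / r[1]) < 0.1))
  expect_error(autocorrelate(numeric(100), 10), class = "pcg_input_error")
  expect_error(autocorrelate(rnorm(10), 24), class = "pcg_input_error")
})

test_that("Levinson-Durbin solves hand-checkable systems", {
  c1 <- levinson_durbin(c(1, 0, 0, 0, 0), 4)
  expect_equal(c1$a, rep(0, 4))
  expect_equal(c1$gain, 1)

  c2 <- levinson_durbin(c(1, 0.5), 1)
  expect_equal(c2$a, -0.5)
  expect_equal(c2$gain, 0.75)

  expect_error(levinson_durbin(c(1, 0.5), 5), class = "pcg_input_error")
  expect_error(levinson_durbin(c(0, 0.5), 1), class = "pcg_input_error")
  # perfectly correlated sequence drives the error power to zero
  expect_error(levinson_durbin(c(1, 1, 1), 2), class = "pcg_numerical_error")
})

test_that("Levinson-Durbin agrees with the direct Yule-Walker solve", {
  set.seed(3)
  for (rep in 1:20) {
    p <- sample(1:24, 1)
    r <- autocorrelate(rnorm(200 + 10 * p), p)
    est <- levinson_durbin(r, p)
    expect_equal(est$a, yule_walker_solve(r, p), tolerance = 1e-8)
  }
})

test_that("filter spectra match direct transfer-function evaluation", {
  flat <- filter_spectrum(
    structure(list(order = 4, a = rep(0, 4), gain = 1),
              class = "lpc_coefficients"), 4000, 64)
  expect_equal(flat$magnitudes, rep(1, 64))

  # AR(2) with a pole pair at 100 Hz
  rho <- 0.97; theta <- 2 * pi * 100 / 4000
  a2 <- c(-2 * rho * cos(theta), rho^2)
  spec <- filter_spectrum(
    structure(list(order = 2, a = a2, gain = 1), class = "lpc_coefficients"),
    4000, 512)
  peak <- spec$frequencies[which.max(spec$magnitudes)]
  expect_lt(abs(peak - 100), 4000 / (2 * 512))

  # brute-force oracle: term-by-term evaluation of G / (1 + sum a_k e^-jwk)
  set.seed(4)
  a <- random_stable_ar(8)
  sp <- filter_spectrum(
    structure(list(order = 8, a = a, gain = 2), class = "lpc_coefficients"),
    4000, 128)
  brute <- sapply(sp$frequencies, function(f) {
    w <- 2 * pi * f / 4000
    A <- 1 + sum(a * exp(-1i * w * seq_along(a)))
    2 / Mod(A)
  })
  expect_equal(sp$magnitudes, brute, tolerance = 1e-10)
})

test_that("signal spectra resolve sinusoids and are linear in amplitude", {
  fs <- 4000
  t <- (0:3999) / fs
  s200 <- signal_spectrum(sin(2 * pi * 200 * t), fs)
  expect_lt(abs(s200$frequencies[which.max(s200$magnitudes)] - 200),
            fs / (2 * 512))

  two <- signal_spectrum(sin(2 * pi * 50 * t) + sin(2 * pi * 300 * t), fs)
  near <- function(f0) {
    idx <- which(abs(two$frequencies - f0) < 20)
    any(diff(sign(diff(two$magnitudes[idx]))) < 0)  # local maximum
  }
  expect_true(near(50))
  expect_true(near(300))

  x <- sin(2 * pi * 120 * t)
  expect_equal(signal_spectrum(2 * x, fs)$magnitudes,
               2 * signal_spectrum(x, fs)$magnitudes, tolerance = 1e-12)
  expect_error(signal_spectrum(numeric(0), fs), class = "pcg_input_error")
})

test_that("fitness factor reproduces direct arithmetic and boundary cases", {
  X <- make_spectrum(c(1, 0.5, 0.25, 0.125))
  expect_equal(fitness_factor(X, X), 100)

  zero <- make_spectrum(rep(0, 4))
  expect_equal(fitness_factor(zero, X), 0)  # total mismatch
  expect_error(fitness_factor(X, zero), class = "pcg_input_error")

  # independent arithmetic: unit-energy vectors, normalized squared error
  hf <- c(1, 0.4, 0.25, 0.125); hs <- c(1, 0.5, 0.25, 0.125)
  u <- function(v) v / sqrt(sum(v^2))
  expected <- 100 * (1 - sum((u(hf) - u(hs))^2))
  expect_equal(fitness_factor(make_spectrum(hf), X), expected,
               tolerance = 1e-12)
  expect_lt(expected, 100)
  expect_gt(expected, 99)  # a single mildly off bin barely dents the match

  expect_error(fitness_factor(X, make_spectrum(rep(1, 8))),
               class = "pcg_input_error")
})

test_that("feature extraction is deterministic and amplitude-invariant", {
  rec <- generate_tone(default_class_specs()[["S3"]], 4000, 5)
  seg <- segment_heart_tones(rec)[[1]]
  f1 <- extract_features(seg)
  expect_length(f1, 24)
  expect_named(f1, paste0("a", 1:24))
  expect_identical(f1, extract_features(seg))
  scaled <- seg
  scaled$samples <- 0.37 * scaled$samples
  expect_equal(extract_features(scaled), f1, tolerance = 1e-10)
})

test_that("long white noise yields a near-zero coefficient vector", {
  set.seed(6)
  f <- extract_features(rnorm(8192))
  expect_true(all(abs(f) < 0.1))
})

test_that("known all-pole filters are recovered from their output", {
  set.seed(7)
  for (rep in 1:3) {
    a_true <- random_stable_ar(24)
    x <- ar_signal(a_true, 8192)
    r <- autocorrelate(x, 24)
    est <- levinson_durbin(r, 24)
    rmse <- sqrt(mean((est$a - a_true)^2))
    expect_lt(rmse, 0.05)
    true_spec <- filter_spectrum(
      structure(list(order = 24, a = a_true, gain = 1),
                class = "lpc_coefficients"), 4000, 512)
    expect_gte(fitness_factor(filter_spectrum(est, 4000, 512), true_spec), 99)
  }
})

test_that("spectrum match improves with model order on heart tones", {
  specs <- default_class_specs()
  mean_ff <- function(order) {
    ffs <- unlist(lapply(seq_along(specs), function(i) {
      rec <- generate_tone(specs[[i]], 4000, 100 + i)
      seg <- segment_heart_tones(rec)
      if (length(seg) == 0) return(NULL)
      seg <- seg[[1]]
      est <- levinson_durbin(autocorrelate(seg, order), order)
      fitness_factor(filter_spectrum(est, 4000, 512),
                     signal_spectrum(seg, 4000, 512))
    }))
    mean(ffs)
  }
  ff5 <- mean_ff(5); ff18 <- mean_ff(18); ff24 <- mean_ff(24)
  expect_gte(ff24, ff18)
  expect_gte(ff18, ff5)
})
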