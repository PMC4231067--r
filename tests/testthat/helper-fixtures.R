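# Fixtures built in code, shared across test files.

component <- pcgclassify:::component

# Single-component tone spec without jitter or additive noise.
pure_tone_spec <- function(freq, duration = 0.5, type = "damped_sinusoid",
                           bandwidth = 0, snr_db = Inf) {
  tone_class_spec("test tone",
                  list(list(center_frequency = freq, bandwidth = bandwidth,
                            onset = 0, duration = duration, amplitude = 1,
                            type = type)),
                  jitter = list(frequency = 0, duration = 0, amplitude = 0),
                  snr_db = snr_db)
}

# Dominant-frequency estimate via periodogram.
dominant_freq <- function(x, fs) {
  n <- length(x)
  X <- Mod(stats::fft(x))[1:(n %/% 2)]
  (which.max(X) - 1) * fs / n
}

spectral_flatness <- function(x) {
  p <- Mod(stats::fft(x))[2:(length(x) %/% 2)]^2
  p <- p[p > 0]
  exp(mean(log(p))) / mean(p)
}

# Random stable AR coefficients via random reflection coefficients and the
# step-up recursion (construction only; stability is guaranteed because all
# reflection coefficients lie inside (-1, 1)). The default bound keeps the
# filters moderately damped: estimable from a few thousand samples, with a
# spectral dynamic range of tens of dB rather than razor-sharp resonances.
random_stable_ar <- function(order, kmax = 0.2) {
  k <- stats::runif(order, -kmax, kmax)
  a <- numeric(0)
  for (i in seq_len(order)) a <- c(a + k[i] * rev(a), k[i])
  a
}

# Drive white noise through the all-pole filter 1 / (1 + sum a_k z^-k).
ar_signal <- function(a, n, burn = 500) {
  e <- stats::rnorm(n + burn)
  x <- stats::filter(e, -a, method = "recursive")
  as.numeric(x[(burn + 1):(burn + n)])
}

# Direct Yule-Walker solve: the independent oracle for levinson_durbin.
yule_walker_solve <- function(r, p) {
  R <- stats::toeplitz(r[1:p])
  as.numeric(solve(R, -r[2:(p + 1)]))
}

make_spectrum <- function(mags, fs = 4000) {
  structure(list(frequencies = seq(0, fs / 2, length.out = length(mags)),
                 magnitudes = mags, n = length(mags)),
            class = "pcg_spectrum")
}

# Well-separated Gaussian clusters in d dimensions, k classes, n per class.
cluster_features <- function(k, n, d = 24, sep = 6, sd = 0.5, seed = 1) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(k * d, sd = sep / sqrt(d)), k, d)
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(stats::rnorm(n * d, sd = sd), n, d) +
      matrix(centers[i, ], n, d, byrow = TRUE)))
  list(x = x, y = rep(paste0("class", seq_len(k)), each = n))
}

simple_genome <- function(n_features, m, kind = "rbf", sigma = 2, C = 100) {
  g <- list(kind = kind, u = if (kind %in% c("polynomial")) 3 else
              if (kind == "quadratic") 2 else NULL,
            sigma = sigma, C = C)
  svm_genome(rep(TRUE, n_features), rep(list(g), m))
}

# The 72-recording synthetic feature table used by the end-to-end checks;
# computed once per test session.
study_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- dataset_features(generate_dataset(6, 4000, 42), run_config())
    cache
  }
})
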