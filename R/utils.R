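# Internal helpers: classed error conditions and seeded evaluation.

stop_pcg <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "pcg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

input_error    <- function(fmt, ...) stop_pcg("pcg_input_error", fmt, ...)
config_error   <- function(fmt, ...) stop_pcg("pcg_config_error", fmt, ...)
numerical_error<- function(fmt, ...) stop_pcg("pcg_numerical_error", fmt, ...)
training_error <- function(fmt, ...) stop_pcg("pcg_training_error", fmt, ...)
genome_error   <- function(fmt, ...) stop_pcg("pcg_invalid_genome_error", fmt, ...)
metric_error   <- function(fmt, ...) stop_pcg("pcg_undefined_metric_error", fmt, ...)

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    config_error("seed must be a single integer, got %s", deparse(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation, kept within 32-bit integer range.
derive_seed <- function(seed, ...) {
  parts <- c(as.integer(seed) %% 1000003L, as.integer(c(...)))
  h <- 0
  for (p in parts) h <- (h * 31 + (p %% 1000003)) %% 2147483587
  as.integer(h) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

hamming_window <- function(n) {
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}
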