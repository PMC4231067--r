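# Modified Cuckoo Search over the mixed model-selection space.
#
# A candidate ("egg") is a point in [0,1]^d with d = 24 + 3m: 24 relaxed
# binary feature-mask genes plus, for each of the m one-against-others
# members, a kernel-kind gene, a kernel-parameter gene and a penalty gene.
# Binary genes are optimized as continuous values and thresholded at 0.5;
# multiplicative parameters (sigma, C) are decoded log-uniformly. The search
# follows the Modified Cuckoo Search mechanics: Lévy-flight replacement of
# the discarded worst nests with a step size decaying as A0/sqrt(G),
# golden-ratio recombination between pairs of top nests, and strict elitism.

GOLDEN_RATIO <- (1 + sqrt(5)) / 2

#' Construct an SVM model-selection genome
#'
#' @param mask logical vector of length 24 selecting LPC coefficients.
#' @param kernels list of `m` per-class entries, each a list with `kind`
#'   (see [kernel_spec()]), `u`, `sigma`, `C`.
#' @return object of class `svm_genome`.
#' @export
svm_genome <- function(mask, kernels) {
  if (!is.logical(mask))
    config_error("mask must be logical")
  for (g in kernels) {
    if (!g$kind %in% KERNEL_KINDS) config_error("bad kernel kind '%s'", g$kind)
    if (is.null(g$C) || g$C <= 0) config_error("genome C must be positive")
  }
  structure(list(mask = mask, kernels = kernels), class = "svm_genome")
}

#' Fixed-kernel baseline genome
#'
#' The comparison systems (SVM-poly, SVM-rbf, SVM-quad) use all 24 LPC
#' coefficients and one fixed kernel with default parameters for every
#' class member.
#'
#' @param kind kernel kind.
#' @param m number of classes.
#' @param u polynomial degree (default 3, for `"polynomial"`).
#' @param sigma RBF width (default 1).
#' @param C penalty (default 1).
#' @return an [svm_genome()].
#' @export
baseline_genome <- function(kind, m, u = 3, sigma = 1, C = 1) {
  g <- list(kind = kind, u = if (kind == "quadratic") 2 else u,
            sigma = sigma, C = C)
  svm_genome(rep(TRUE, 24), rep(list(g), m))
}

#' @export
print.svm_genome <- function(x, ...) {
  kinds <- table(vapply(x$kernels, function(g) g$kind, ""))
  cat(sprintf("<svm_genome> %d/24 features; kernels: %s\n", sum(x$mask),
              paste(names(kinds), kinds, sep = "x", collapse = ", ")))
  invisible(x)
}

#' Optimizer configuration
#'
#' @param n_nests population size (default 25, >= 4).
#' @param discard_fraction fraction of worst nests replaced by Lévy flights
#'   each generation (default 0.25).
#' @param max_generations generation budget.
#' @param top_fraction fraction of nests treated as the "top" group for
#'   golden-ratio recombination (default 0.25).
#' @param initial_step Lévy step scale A0; the scale at generation G is
#'   `A0 / sqrt(G)` (default 1).
#' @param levy_exponent stability index of the Lévy steps (default 1.5).
#' @param seed integer RNG seed.
#' @param fitness_mode `"accuracy"` (maximize LOO balanced accuracy) or
#'   `"sv_count"` (minimize support vectors).
#' @param max_evaluations optional cap on objective evaluations.
#' @return object of class `mcs_config`.
#' @export
mcs_config <- function(n_nests = 25, discard_fraction = 0.25,
                       max_generations = 100, top_fraction = 0.25,
                       initial_step = 1, levy_exponent = 1.5, seed = 1,
                       fitness_mode = c("accuracy", "sv_count"),
                       max_evaluations = Inf) {
  if (n_nests < 4) config_error("n_nests must be >= 4")
  if (discard_fraction <= 0 || discard_fraction >= 1)
    config_error("discard_fraction must lie in (0, 1)")
  if (max_generations < 1) config_error("max_generations must be >= 1")
  structure(list(n_nests = as.integer(n_nests),
                 discard_fraction = discard_fraction,
                 max_generations = as.integer(max_generations),
                 top_fraction = top_fraction, initial_step = initial_step,
                 levy_exponent = levy_exponent, seed = as.integer(seed),
                 fitness_mode = match.arg(fitness_mode),
                 max_evaluations = max_evaluations),
            class = "mcs_config")
}

#' Draw one Lévy-flight step
#'
#' Heavy-tailed per-coordinate step via Mantegna's algorithm for stability
#' index `beta`, multiplied by `scale`. Uses (and advances) the current RNG
#' stream.
#'
#' @param scale positive step scale (multiplies the raw Lévy draw).
#' @param d dimension.
#' @param beta stability index in (1, 2] (default 1.5).
#' @return numeric vector of length `d`.
#' @export
levy_step <- function(scale, d, beta = 1.5) {
  if (scale <= 0) config_error("scale must be positive")
  sigma_u <- (gamma(1 + beta) * sin(pi * beta / 2) /
              (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- stats::rnorm(d, sd = sigma_u)
  v <- stats::rnorm(d)
  scale * u / abs(v)^(1 / beta)
}

#' Decode a position vector into an SVM genome
#'
#' Mask bit `i` is `position[i] >= 0.5`. Per class: the kernel-kind gene
#' maps through `floor(4 g)` (clamped) to linear / quadratic / polynomial /
#' rbf; the parameter gene decodes log-uniformly to the degree `u` in 1..6
#' (rounded) or `sigma` in `[2^-10, 2^3]`; the penalty gene decodes
#' log-uniformly to `C` in `[2^-5, 2^15]`.
#'
#' @param position numeric vector in `[0,1]^(24 + 3m)`.
#' @param m number of classes.
#' @return an [svm_genome()] (possibly with an empty mask, which downstream
#'   fitness functions penalize rather than reject here).
#' @export
decode_genome <- function(position, m) {
  d <- 24 + 3 * m
  if (length(position) != d)
    config_error("position has length %d; expected 24 + 3m = %d",
                 length(position), d)
  mask <- position[1:24] >= 0.5
  kernels <- vector("list", m)
  for (i in seq_len(m)) {
    g <- position[24 + 3 * (i - 1) + 1:3]
    kind <- KERNEL_KINDS[min(floor(4 * g[1]), 3) + 1]
    u <- sigma <- NULL
    if (kind == "polynomial") {
      u <- max(1L, min(6L, as.integer(round(exp(g[2] * log(6))))))
    } else if (kind == "quadratic") {
      u <- 2
    } else if (kind == "rbf") {
      sigma <- 2^(-10 + 13 * g[2])
    }
    C <- 2^(-5 + 20 * g[3])
    kernels[[i]] <- list(kind = kind, u = u, sigma = sigma, C = C)
  }
  structure(list(mask = mask, kernels = kernels), class = "svm_genome")
}

#' Initialize a nest population
#'
#' Seeded uniform positions in `[0,1]^d`, one row per nest, optionally
#' scored with an objective. [mcs_optimize()] draws its initial population
#' the same way from the same seed.
#'
#' @param cfg an [mcs_config()].
#' @param d search-space dimension.
#' @param objective optional scalar objective to evaluate per nest.
#' @return list with `positions` (`n_nests x d` matrix) and `fitness`
#'   (numeric, `NA` when no objective is given).
#' @export
init_nests <- function(cfg, d, objective = NULL) {
  if (d < 1) config_error("dimension must be >= 1, got %s", deparse(d))
  with_seed(cfg$seed, {
    positions <- matrix(stats::runif(cfg$n_nests * d), cfg$n_nests, d)
    fitness <- if (is.null(objective)) rep(NA_real_, cfg$n_nests)
               else apply(positions, 1L, objective)
    list(positions = positions, fitness = fitness)
  })
}

#' Modified Cuckoo Search over the unit hypercube
#'
#' Core optimizer, usable with any objective. Per generation: (i) the
#' bottom `discard_fraction` of nests are abandoned and replaced by
#' Lévy-flight walks from their positions with step scale
#' `initial_step / sqrt(G)`; (ii) each top nest is recombined with another
#' random top nest, placing a candidate at the golden-ratio point of the
#' connecting line (nearer the fitter endpoint) — or taking a fine local
#' Lévy step with scale `initial_step / G^2` when the pair coincides — and
#' the candidate replaces a randomly chosen nest if fitter; (iii) greedy
#' promotion of the best solution: two hill steps on the best nest with a
#' 1/5-success-rule adapted Lévy scale, accepted only on improvement;
#' (iv) the best nest always survives (elitism). Positions are clamped to
#' `[0, 1]^d`.
#'
#' @param objective function mapping a position vector to a scalar.
#' @param d search-space dimension.
#' @param cfg an [mcs_config()].
#' @param maximize if `TRUE` larger objective values are fitter.
#' @return list with `best_position`, `best_fitness`, `trace` (data.frame
#'   with `generation`, `best_fitness`, `mean_fitness`, `levy_scale`),
#'   `evaluations`.
#' @export
mcs_optimize <- function(objective, d, cfg = mcs_config(), maximize = TRUE) {
  sgn <- if (maximize) 1 else -1
  with_seed(cfg$seed, {
    n_evals <- 0L
    evaluate <- function(pos) {
      n_evals <<- n_evals + 1L
      sgn * objective(pos)
    }
    clamp <- function(p) pmin(1, pmax(0, p))
    n <- cfg$n_nests
    pos <- matrix(stats::runif(n * d), n, d)
    fit <- apply(pos, 1L, evaluate)

    trace <- data.frame(generation = integer(0), best_fitness = numeric(0),
                        mean_fitness = numeric(0), levy_scale = numeric(0))
    n_discard <- max(1L, round(cfg$discard_fraction * n))
    n_top <- max(2L, round(cfg$top_fraction * n))
    loc_scale <- cfg$initial_step / 10

    for (G in seq_len(cfg$max_generations)) {
      if (n_evals >= cfg$max_evaluations) break
      scale_G <- cfg$initial_step / sqrt(G)
      ord <- order(fit, decreasing = TRUE)

      # (i) abandon the worst nests: each is replaced by a Lévy flight
      # seeded at a randomly chosen top nest, with the decaying step scale
      # (replacement eggs explore around good solutions, not around the
      # abandoned ones)
      top0 <- ord[seq_len(n_top)]
      for (i in utils::tail(ord, n_discard)) {
        if (n_evals >= cfg$max_evaluations) break
        src <- if (length(top0) > 1L) sample(top0, 1L) else top0
        cand <- clamp(pos[src, ] + levy_step(scale_G, d, cfg$levy_exponent))
        pos[i, ] <- cand
        fit[i] <- evaluate(cand)
      }

      # (ii) golden-ratio recombination within the top group
      top <- order(fit, decreasing = TRUE)[seq_len(n_top)]
      for (i in top) {
        if (n_evals >= cfg$max_evaluations) break
        # partner drawn from the whole top group; drawing the same egg (or a
        # coincident one) triggers a fine local Lévy walk at scale A0/G^2
        j <- sample(top, 1L)
        dist_ij <- sqrt(sum((pos[i, ] - pos[j, ])^2))
        if (j == i || dist_ij < 1e-12) {
          cand <- clamp(pos[i, ] + levy_step(cfg$initial_step / G^2, d,
                                             cfg$levy_exponent))
        } else {
          better <- if (fit[i] >= fit[j]) i else j
          worse <- if (better == i) j else i
          cand <- clamp(pos[worse, ] +
                          (pos[better, ] - pos[worse, ]) / GOLDEN_RATIO)
        }
        cf <- evaluate(cand)
        k <- sample.int(n, 1L)
        if (cf > fit[k]) { pos[k, ] <- cand; fit[k] <- cf }
      }

      # greedy promotion of the best solution: two (1+1)-style hill steps on
      # the best nest per generation, with a 1/5-success-rule adapted step
      # scale, so refinement tracks the distance to the optimum instead of a
      # fixed schedule
      for (h in 1:2) {
        if (n_evals >= cfg$max_evaluations) break
        b <- which.max(fit)
        cand <- clamp(pos[b, ] + levy_step(loc_scale, d, cfg$levy_exponent))
        cf <- evaluate(cand)
        if (cf >= fit[b]) {
          # neutral moves are accepted: on plateaued (e.g. thresholded)
          # landscapes the climber drifts instead of collapsing its step
          pos[b, ] <- cand; fit[b] <- cf
          loc_scale <- min(loc_scale * 1.8, cfg$initial_step)
        } else loc_scale <- max(loc_scale * 0.85, 1e-14)
      }

      trace <- rbind(trace, data.frame(
        generation = G, best_fitness = sgn * max(fit),
        mean_fitness = sgn * mean(fit), levy_scale = scale_G))
    }
    best <- which.max(fit)
    list(best_position = pos[best, ], best_fitness = sgn * fit[best],
         trace = trace, evaluations = n_evals)
  })
}

#' Evolve an SVM classifier genome by Modified Cuckoo Search
#'
#' Runs [mcs_optimize()] over the `24 + 3m` dimensional relaxed genome
#' space, scoring each decoded genome with [accuracy_fitness()] (maximized)
#' or [sv_count_fitness()] (minimized) per `cfg$fitness_mode`. Fitness
#' values are cached by decoded genome — thresholding makes many positions
#' decode identically — and the cache is exact: a cached value equals a
#' fresh evaluation.
#'
#' @param x numeric matrix `n x 24` of LPC feature vectors.
#' @param y class labels.
#' @param cfg an [mcs_config()].
#' @return list with `best_genome`, `best_fitness`, `trace`, `evaluations`.
#' @export
evolve_classifier <- function(x, y, cfg = mcs_config()) {
  x <- as.matrix(x)
  y <- as.character(y)
  m <- length(unique(y))
  d <- 24 + 3 * m
  maximize <- cfg$fitness_mode == "accuracy"
  fitness_fun <- if (maximize) accuracy_fitness else sv_count_fitness
  cache <- new.env(parent = emptyenv())
  objective <- function(pos) {
    genome <- decode_genome(pos, m)
    key <- genome_key(genome)
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- fitness_fun(x, y, genome)
    cache[[key]] <- val
    val
  }
  res <- mcs_optimize(objective, d, cfg, maximize = maximize)
  list(best_genome = decode_genome(res$best_position, m),
       best_fitness = res$best_fitness, trace = res$trace,
       evaluations = res$evaluations)
}

genome_key <- function(genome) {
  paste(c(as.integer(genome$mask),
          vapply(genome$kernels, function(g)
            sprintf("%s:%s:%s:%.12g", g$kind,
                    if (is.null(g$u)) "-" else g$u,
                    if (is.null(g$sigma)) "-" else sprintf("%.12g", g$sigma),
                    g$C), "")),
        collapse = "|")
}

#' Write an optimizer trace as CSV
#'
#' @param trace the `trace` data.frame from [mcs_optimize()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
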