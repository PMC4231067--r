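# Soft-margin SVMs and the one-against-others ensemble.
#
# The binary dual is solved by libsvm (via e1071); the model-selection layer
# — per-class kernels, parameters, penalty C and a shared feature mask — is
# this package's own. Each trained member stores its support vectors, dual
# coefficients and bias so that the decision function can be reconstructed
# (and serialized) independently of the solver.

KERNEL_KINDS <- c("linear", "quadratic", "polynomial", "rbf")

#' Kernel specification
#'
#' Linear `x.y`; quadratic `(x.y + 1)^2`; polynomial `(x.y + 1)^u`; RBF
#' `exp(-||x-y||^2 / (2 sigma^2))`. Quadratic is the polynomial kernel with
#' `u = 2`, kept as a distinct kind to mirror the fixed-kernel baseline set.
#'
#' @param kind one of `"linear"`, `"quadratic"`, `"polynomial"`, `"rbf"`.
#' @param u polynomial degree (integer >= 1; required for `"polynomial"`).
#' @param sigma RBF width (> 0; required for `"rbf"`).
#' @return object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind, u = NULL, sigma = NULL) {
  if (!kind %in% KERNEL_KINDS)
    config_error("unknown kernel kind '%s'", kind)
  if (kind == "polynomial") {
    if (is.null(u) || u < 1 || u != round(u))
      config_error("polynomial kernel needs integer degree u >= 1")
  } else if (kind == "rbf") {
    if (is.null(sigma) || sigma <= 0)
      config_error("rbf kernel needs sigma > 0")
  }
  if (kind == "quadratic") u <- 2
  structure(list(kind = kind, u = u, sigma = sigma), class = "kernel_spec")
}

#' Evaluate a kernel on two feature vectors
#'
#' @param k a [kernel_spec()].
#' @param x,y numeric vectors of equal length.
#' @return the scalar kernel value.
#' @export
kernel_eval <- function(k, x, y) {
  stopifnot(inherits(k, "kernel_spec"))
  if (length(x) != length(y))
    input_error("kernel arguments have different dimensions (%d vs %d)",
                length(x), length(y))
  switch(k$kind,
    linear = sum(x * y),
    quadratic = (sum(x * y) + 1)^2,
    polynomial = (sum(x * y) + 1)^k$u,
    rbf = exp(-sum((x - y)^2) / (2 * k$sigma^2)))
}

# Kernel Gram matrix between the rows of A (n x d) and B (m x d).
kernel_matrix <- function(k, A, B) {
  G <- A %*% t(B)
  switch(k$kind,
    linear = G,
    quadratic = (G + 1)^2,
    polynomial = (G + 1)^k$u,
    rbf = {
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * G
      d2[d2 < 0] <- 0
      exp(-d2 / (2 * k$sigma^2))
    })
}

#' Train a soft-margin binary SVM
#'
#' Solves the C-SVM dual (libsvm) for labels in \{-1, +1\} under the given
#' kernel and penalty. The returned model stores support vectors, dual
#' coefficients (`alpha_i y_i`) and bias oriented so that a positive
#' decision value means class +1.
#'
#' @param x numeric matrix (rows = samples), already restricted to the
#'   active features.
#' @param y numeric or integer labels, -1 or +1, both present.
#' @param kernel a [kernel_spec()].
#' @param C penalty parameter (> 0).
#' @param tolerance SMO termination tolerance (default 0.01). Model
#'   selection sweeps C over many orders of magnitude; extreme penalties on
#'   overlapping classes make the dual ill-conditioned and a tight tolerance
#'   costs orders of magnitude in solver iterations without changing which
#'   genomes win. Pass a smaller value for high-precision fits.
#' @return object of class `binary_svm` with fields `sv`, `coefs`, `rho`,
#'   `kernel`, `C`.
#' @export
train_binary_svm <- function(x, y, kernel, C, tolerance = 0.01) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (C <= 0) config_error("penalty C must be positive")
  npos <- sum(y == 1); nneg <- sum(y == -1)
  if (npos + nneg != length(y))
    input_error("labels must be -1 or +1")
  if (npos == 0L || nneg == 0L)
    training_error("both classes required: %d positive, %d negative", npos, nneg)
  ek <- switch(kernel$kind,
    linear = list(kernel = "linear"),
    quadratic = list(kernel = "polynomial", degree = 2, gamma = 1, coef0 = 1),
    polynomial = list(kernel = "polynomial", degree = kernel$u, gamma = 1, coef0 = 1),
    rbf = list(kernel = "radial", gamma = 1 / (2 * kernel$sigma^2)))
  yf <- factor(y, levels = c(1, -1))
  fit <- do.call(e1071::svm, c(list(x = x, y = yf, scale = FALSE,
                                    type = "C-classification", cost = C,
                                    tolerance = tolerance), ek))
  coefs <- as.numeric(fit$coefs)
  rho <- fit$rho
  # libsvm orients the decision value toward its internally-first label;
  # flip so that positive decision always means class +1
  if (fit$levels[fit$labels[1]] != "1") { coefs <- -coefs; rho <- -rho }
  structure(list(sv = unname(as.matrix(fit$SV)), coefs = coefs, rho = rho,
                 kernel = kernel, C = C),
            class = "binary_svm")
}

#' Decision values of a binary SVM
#'
#' Reconstructs `f(x) = sum_i coefs_i K(sv_i, x) - rho` from the stored
#' model fields.
#'
#' @param model a `binary_svm`.
#' @param x matrix of samples (rows), same feature dimension as training.
#' @return numeric vector of decision values; positive means class +1.
#' @export
svm_decision <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$sv))
    input_error("feature dimension mismatch: model %d, input %d",
                ncol(model$sv), ncol(x))
  K <- kernel_matrix(model$kernel, x, model$sv)
  drop(K %*% model$coefs) - model$rho
}

#' Train a one-against-others SVM ensemble under a genome
#'
#' For each of the `m` classes, trains one binary member on labels +1 (that
#' class) versus -1 (all others), using the genome's per-class kernel and
#' penalty and its shared 24-bit feature mask.
#'
#' @param x numeric matrix, `n x 24`, full LPC feature vectors.
#' @param y class labels (character or factor), every class with >= 1 sample.
#' @param genome an [svm_genome()].
#' @return object of class `ovr_ensemble` with fields `members` (named list
#'   of `binary_svm`), `class_order`, `feature_mask`.
#' @export
train_ovr_ensemble <- function(x, y, genome) {
  x <- as.matrix(x)
  y <- as.character(y)
  stopifnot(inherits(genome, "svm_genome"))
  if (!any(genome$mask))
    genome_error("genome selects zero features")
  classes <- sort(unique(y))
  m <- length(classes)
  if (length(genome$kernels) != m)
    config_error("genome has %d per-class kernel entries but data has %d classes",
                 length(genome$kernels), m)
  xm <- x[, genome$mask, drop = FALSE]
  members <- vector("list", m)
  names(members) <- classes
  for (i in seq_len(m)) {
    yi <- ifelse(y == classes[i], 1, -1)
    g <- genome$kernels[[i]]
    members[[i]] <- train_binary_svm(xm, yi,
                                     kernel_spec(g$kind, u = g$u, sigma = g$sigma),
                                     C = g$C)
  }
  structure(list(members = members, class_order = classes,
                 feature_mask = genome$mask),
            class = "ovr_ensemble")
}

#' Per-class decision values of an ensemble
#'
#' @param ensemble an `ovr_ensemble`.
#' @param x matrix of full 24-dimensional feature vectors (rows); the
#'   ensemble's mask is applied internally.
#' @return numeric matrix, one column per class in `class_order`.
#' @export
decision_values <- function(ensemble, x) {
  stopifnot(inherits(ensemble, "ovr_ensemble"))
  x <- as.matrix(x)
  if (ncol(x) != length(ensemble$feature_mask))
    input_error("expected %d-dimensional feature vectors, got %d",
                length(ensemble$feature_mask), ncol(x))
  xm <- x[, ensemble$feature_mask, drop = FALSE]
  vals <- vapply(ensemble$members, function(mem) svm_decision(mem, xm),
                 numeric(nrow(xm)))
  if (nrow(xm) == 1L) vals <- matrix(vals, nrow = 1,
                                     dimnames = list(NULL, ensemble$class_order))
  vals
}

#' Predict class labels with a one-against-others ensemble
#'
#' Argmax over the members' real-valued decision functions; exact ties go to
#' the earliest class in `class_order`.
#'
#' @param object an `ovr_ensemble`.
#' @param newdata matrix (or vector) of 24-dimensional feature vectors.
#' @param ... unused.
#' @return character vector of predicted class labels.
#' @export
predict.ovr_ensemble <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  vals <- decision_values(object, newdata)
  object$class_order[apply(vals, 1L, which.max)]
}

#' Total number of support vectors in an ensemble
#'
#' @param ensemble an `ovr_ensemble`.
#' @return integer count, summed over the `m` members.
#' @export
count_support_vectors <- function(ensemble) {
  stopifnot(inherits(ensemble, "ovr_ensemble"))
  sum(vapply(ensemble$members, function(mem) nrow(mem$sv), integer(1)))
}

#' Serialize an ensemble to JSON
#'
#' The JSON document stores `class_order`, `feature_mask` and, per member,
#' the kernel specification, penalty, support vectors, dual coefficients and
#' bias — everything needed to reproduce predictions exactly.
#'
#' @param ensemble an `ovr_ensemble`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_model <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "ovr_ensemble"))
  doc <- list(
    format = "pcgclassify-ovr-svm",
    class_order = ensemble$class_order,
    feature_mask = ensemble$feature_mask,
    members = lapply(ensemble$members, function(mem) list(
      kernel = list(kind = mem$kernel$kind, u = mem$kernel$u,
                    sigma = mem$kernel$sigma),
      C = mem$C, sv = mem$sv, coefs = mem$coefs, rho = mem$rho)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load an ensemble serialized by [save_model()]
#'
#' @param path JSON path.
#' @return an `ovr_ensemble` whose predictions match the saved model exactly.
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "pcgclassify-ovr-svm"))
    input_error("not a pcgclassify model file: %s", path)
  members <- lapply(doc$members, function(mem) {
    k <- kernel_spec(mem$kernel$kind, u = mem$kernel$u, sigma = mem$kernel$sigma)
    structure(list(sv = as.matrix(mem$sv), coefs = as.numeric(mem$coefs),
                   rho = mem$rho, kernel = k, C = mem$C),
              class = "binary_svm")
  })
  names(members) <- doc$class_order
  structure(list(members = members, class_order = doc$class_order,
                 feature_mask = as.logical(doc$feature_mask)),
            class = "ovr_ensemble")
}

#' @export
print.ovr_ensemble <- function(x, ...) {
  cat(sprintf("<ovr_ensemble> %d classes, %d/%d features, %d support vectors\n",
              length(x$class_order), sum(x$feature_mask),
              length(x$feature_mask), count_support_vectors(x)))
  invisible(x)
}
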