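# Kernels, binary soft-margin training, the one-against-others ensemble,
# and model serialization.

test_that("kernel values match hand arithmetic and are symmetric", {
  expect_equal(kernel_eval(kernel_spec("linear"), c(1, 2), c(3, 4)), 11)
  expect_equal(kernel_eval(kernel_spec("quadratic"), c(1, 1), c(1, 1)), 9)
  expect_equal(kernel_eval(kernel_spec("polynomial", u = 3), c(1, 1), c(1, 1)), 27)
  expect_equal(kernel_eval(kernel_spec("rbf", sigma = 0.7), c(1, 2), c(1, 2)), 1)
  expect_error(kernel_eval(kernel_spec("linear"), c(1, 2), c(1, 2, 3)),
               class = "pcg_input_error")

  set.seed(1)
  for (k in list(kernel_spec("linear"), kernel_spec("quadratic"),
                 kernel_spec("polynomial", u = 4),
                 kernel_spec("rbf", sigma = 1.3))) {
    x <- rnorm(6); y <- rnorm(6)
    expect_equal(kernel_eval(k, x, y), kernel_eval(k, y, x))
  }

  # RBF bounds: in (0, 1], equal to 1 iff x == y
  k <- kernel_spec("rbf", sigma = 0.5)
  set.seed(2)
  for (i in 1:20) {
    x <- rnorm(4); y <- rnorm(4)
    v <- kernel_eval(k, x, y)
    expect_gt(v, 0); expect_lt(v, 1)
  }
})

test_that("kernel spec validation catches missing parameters", {
  expect_error(kernel_spec("polynomial"), class = "pcg_config_error")
  expect_error(kernel_spec("rbf", sigma = -1), class = "pcg_config_error")
  expect_error(kernel_spec("sigmoid"), class = "pcg_config_error")
  expect_equal(kernel_spec("quadratic")$u, 2)
})

test_that("the two-point max-margin problem is solved analytically", {
  x <- rbind(c(0, 0), c(1, 1))
  y <- c(-1, 1)
  m <- train_binary_svm(x, y, kernel_spec("linear"), C = 1000,
                        tolerance = 1e-8)
  d <- svm_decision(m, x)
  expect_true(d[1] < 0 && d[2] > 0)
  # margin boundary midway between the two points
  expect_lt(abs(svm_decision(m, matrix(c(0.5, 0.5), 1))), 1e-6)
  expect_equal(nrow(m$sv), 2)  # both points on the margin
})

test_that("XOR is unrealizable linearly but realizable with an RBF kernel", {
  x <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c(1, 1, -1, -1)
  lin <- train_binary_svm(x, y, kernel_spec("linear"), C = 10)
  expect_gt(sum(sign(svm_decision(lin, x)) != y), 0)
  rbf <- train_binary_svm(x, y, kernel_spec("rbf", sigma = 0.5), C = 1000)
  expect_equal(sum(sign(svm_decision(rbf, x)) != y), 0)
})

test_that("degenerate training inputs raise typed errors", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(train_binary_svm(x, rep(1, 5), kernel_spec("linear"), 1),
               class = "pcg_training_error")
  expect_error(train_binary_svm(x, c(1, 1, -1, -1, 2), kernel_spec("linear"), 1),
               class = "pcg_input_error")
  expect_error(train_binary_svm(x, rep(c(1, -1), c(2, 3)),
                                kernel_spec("linear"), -1),
               class = "pcg_config_error")
})

test_that("the stored model reconstructs libsvm's decision values", {
  set.seed(3)
  x <- matrix(rnorm(40 * 5), 40, 5)
  y <- ifelse(rowSums(x[, 1:2]) > 0, 1, -1)
  if (length(unique(y)) == 1) y[1] <- -y[1]
  kern <- kernel_spec("rbf", sigma = 1.2)
  m <- train_binary_svm(x, y, kern, C = 10, tolerance = 0.001)

  ref <- e1071::svm(x, factor(y, levels = c(1, -1)), scale = FALSE,
                    type = "C-classification", kernel = "radial",
                    gamma = 1 / (2 * 1.2^2), cost = 10, tolerance = 0.001)
  dv <- drop(attr(predict(ref, x, decision.values = TRUE), "decision.values"))
  if (ref$levels[ref$labels[1]] != "1") dv <- -dv
  expect_equal(svm_decision(m, x), unname(dv), tolerance = 1e-6)
})

test_that("one-against-others ensembles train one member per class", {
  fts <- study_features()
  genome <- simple_genome(24, 12, sigma = 2, C = 100)
  ens <- train_ovr_ensemble(fts$x, fts$y, genome)
  expect_length(ens$members, 12)
  expect_setequal(ens$class_order, unique(fts$y))
  expect_gte(count_support_vectors(ens), 12)

  zero_mask <- svm_genome(rep(FALSE, 24), genome$kernels)
  expect_error(train_ovr_ensemble(fts$x, fts$y, zero_mask),
               class = "pcg_invalid_genome_error")
})

test_that("two-class members have anti-correlated decision values", {
  cl <- cluster_features(2, 10, d = 6, seed = 4)
  ens <- train_ovr_ensemble(cl$x, cl$y, simple_genome(6, 2))
  dv <- decision_values(ens, cl$x)
  expect_lt(stats::cor(dv[, 1], dv[, 2]), -0.9)
})

test_that("prediction is argmax with deterministic tie-breaking", {
  cl <- cluster_features(3, 8, d = 10, seed = 5)
  ens <- train_ovr_ensemble(cl$x, cl$y, simple_genome(10, 3, sigma = 1, C = 1000))
  expect_equal(predict(ens, cl$x), cl$y)  # interpolation regime

  # far inside one cluster
  center <- colMeans(cl$x[cl$y == "class2", ])
  expect_equal(predict(ens, center), "class2")

  # exact tie between the first two members: constant equal decisions
  fake_member <- function(bias) structure(
    list(sv = matrix(0, 1, 2), coefs = 0, rho = -bias,
         kernel = kernel_spec("linear"), C = 1),
    class = "binary_svm")
  tie <- structure(list(
    members = list(A = fake_member(0.3), B = fake_member(0.3),
                   C = fake_member(-1)),
    class_order = c("A", "B", "C"), feature_mask = c(TRUE, TRUE)),
    class = "ovr_ensemble")
  expect_equal(predict(tie, c(0, 0)), "A")

  expect_error(predict(ens, matrix(0, 1, 24)), class = "pcg_input_error")
})

test_that("larger C does not increase the support-vector count on separable data", {
  cl <- cluster_features(2, 10, d = 4, sep = 10, sd = 0.3, seed = 6)
  y <- ifelse(cl$y == "class1", 1, -1)
  counts <- sapply(c(0.1, 1, 10, 1000), function(C)
    nrow(train_binary_svm(cl$x, y, kernel_spec("linear"), C)$sv))
  expect_true(all(diff(counts) <= 0))
})

test_that("model JSON round-trips to identical predictions", {
  fts <- study_features()
  genome <- simple_genome(24, 12, sigma = 1.5, C = 50)
  genome$mask[c(3, 11, 20)] <- FALSE
  ens <- train_ovr_ensemble(fts$x, fts$y, genome)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(ens, path)
  back <- load_model(path)
  expect_identical(predict(back, fts$x), predict(ens, fts$x))
  expect_equal(decision_values(back, fts$x), decision_values(ens, fts$x),
               tolerance = 1e-9)
  expect_identical(back$feature_mask, ens$feature_mask)
})
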