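# Confusion accounting, balanced accuracy, leave-one-out evaluation and the
# two optimizer fitness functions.

#' One-vs-rest confusion counts for one class
#'
#' @param predictions,truths equal-length label vectors.
#' @param target_class the class treated as positive.
#' @return object of class `confusion_counts`: list with `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion_counts <- function(predictions, truths, target_class) {
  if (length(predictions) != length(truths))
    input_error("predictions (%d) and truths (%d) differ in length",
                length(predictions), length(truths))
  p <- as.character(predictions) == target_class
  t <- as.character(truths) == target_class
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

#' Sensitivity (true positive rate) in percent
#'
#' `100 TP / (TP + FN)`. A zero denominator raises an undefined-metric
#' error rather than silently returning 0, which would corrupt fitness
#' rankings.
#'
#' @param c a [confusion_counts()].
#' @return percentage in `[0, 100]`.
#' @export
sensitivity <- function(c) {
  if (c$tp + c$fn == 0)
    metric_error("sensitivity undefined: no positive samples (TP + FN = 0)")
  100 * c$tp / (c$tp + c$fn)
}

#' Specificity (true negative rate) in percent
#'
#' `100 TN / (TN + FP)`.
#'
#' @inheritParams sensitivity
#' @return percentage in `[0, 100]`.
#' @export
specificity <- function(c) {
  if (c$tn + c$fp == 0)
    metric_error("specificity undefined: no negative samples (TN + FP = 0)")
  100 * c$tn / (c$tn + c$fp)
}

#' Balanced accuracy in percent
#'
#' Arithmetic mean of sensitivity and specificity; insensitive to the
#' class-frequency imbalance inherent in one-vs-rest reductions.
#'
#' @inheritParams sensitivity
#' @return percentage in `[0, 100]`.
#' @export
balanced_accuracy <- function(c) {
  (sensitivity(c) + specificity(c)) / 2
}

#' Build a per-class evaluation report from multiclass predictions
#'
#' Reduces the multiclass predictions one-vs-rest per class and reports
#' sensitivity, specificity and balanced accuracy with confusion counts.
#' `average` is the unweighted mean of per-class balanced accuracies and
#' `variance` their sample variance (the "Average" / "Average var." rows of
#' a comparison table).
#'
#' @param predictions,truths equal-length label vectors.
#' @param classes class set to report on; defaults to the classes present in
#'   `truths`.
#' @return object of class `evaluation_report`: list with `per_class`
#'   (data.frame), `average`, `variance`.
#' @export
evaluate_predictions <- function(predictions, truths, classes = NULL) {
  classes <- classes %||% sort(unique(as.character(truths)))
  rows <- lapply(classes, function(cl) {
    cc <- confusion_counts(predictions, truths, cl)
    data.frame(class = cl, sensitivity = sensitivity(cc),
               specificity = specificity(cc),
               balanced_accuracy = balanced_accuracy(cc),
               tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
               stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  structure(list(per_class = per_class,
                 average = mean(per_class$balanced_accuracy),
                 variance = stats::var(per_class$balanced_accuracy)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$per_class[, c("class", "sensitivity", "specificity",
                        "balanced_accuracy")], row.names = FALSE)
  cat(sprintf("Average balanced accuracy: %.2f%%  (variance %.3f)\n",
              x$average, x$variance))
  invisible(x)
}

#' Write an evaluation report as CSV
#'
#' Mirrors the per-class table layout with trailing `Average` and
#' `Average var.` rows.
#'
#' @param report an `evaluation_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  df <- report$per_class
  df$class <- as.character(df$class)
  tail_rows <- data.frame(
    class = c("Average", "Average var."),
    sensitivity = NA, specificity = NA,
    balanced_accuracy = c(report$average, report$variance),
    tp = NA, fp = NA, tn = NA, fn = NA, stringsAsFactors = FALSE)
  utils::write.csv(rbind(df, tail_rows), path, row.names = FALSE)
  invisible(path)
}

#' Leave-one-out evaluation of a genome
#'
#' For each sample, retrains the one-against-others ensemble on the
#' remaining samples under the genome and predicts the held-out sample; the
#' collected predictions are reduced to per-class confusion counts and a
#' balanced-accuracy report.
#'
#' @param x numeric matrix `n x 24` of LPC feature vectors.
#' @param y class labels, >= 2 samples per class.
#' @param genome an [svm_genome()].
#' @return an [evaluate_predictions()] report, with attributes
#'   `predictions` and `n_fits` (number of retrain-predict cycles).
#' @export
loo_evaluate <- function(x, y, genome) {
  x <- as.matrix(x)
  y <- as.character(y)
  counts <- table(y)
  if (any(counts < 2L))
    config_error("leave-one-out needs >= 2 samples per class (class '%s' has %d); use a stratified k-fold split instead",
                 names(counts)[which.min(counts)], min(counts))
  n <- nrow(x)
  preds <- character(n)
  for (i in seq_len(n)) {
    ens <- train_ovr_ensemble(x[-i, , drop = FALSE], y[-i], genome)
    preds[i] <- predict(ens, x[i, , drop = FALSE])
  }
  rep <- evaluate_predictions(preds, y)
  attr(rep, "predictions") <- preds
  attr(rep, "n_fits") <- n
  rep
}

#' Classification-accuracy fitness of a genome (maximize)
#'
#' Leave-one-out average balanced accuracy. Invalid genomes (empty feature
#' mask, degenerate training) are penalized with the worst fitness (0)
#' instead of raising, so an optimizer loop never stops on them.
#'
#' @inheritParams loo_evaluate
#' @return fitness in `[0, 100]`.
#' @export
accuracy_fitness <- function(x, y, genome) {
  tryCatch(loo_evaluate(x, y, genome)$average,
           pcg_invalid_genome_error = function(e) 0,
           pcg_training_error = function(e) 0)
}

#' Support-vector-count fitness of a genome (minimize)
#'
#' Total support vectors of the ensemble trained on the full dataset —
#' a complexity surrogate. Invalid genomes get `Inf`.
#'
#' @inheritParams loo_evaluate
#' @return positive count, or `Inf` for invalid genomes.
#' @export
sv_count_fitness <- function(x, y, genome) {
  tryCatch(count_support_vectors(train_ovr_ensemble(x, y, genome)),
           pcg_invalid_genome_error = function(e) Inf,
           pcg_training_error = function(e) Inf)
}
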