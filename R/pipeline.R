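# End-to-end orchestration: dataset ingestion, feature-table construction,
# fixed-kernel baselines, the MCS-optimized system, and the comparison table.

#' Experiment configuration
#'
#' @param sample_rate working sample rate in Hz; recordings at other rates
#'   are resampled (default 4000).
#' @param segmentation a [segmentation_config()].
#' @param lpc_order LPC model order (default 24).
#' @param mcs an [mcs_config()] for the optimized system.
#' @param baselines subset of `c("svm-poly", "svm-rbf", "svm-quad")`.
#' @param mode `"leave-one-out"` or `"half-split"` evaluation protocol.
#' @param seed integer seed propagated to every stochastic stage.
#' @return object of class `run_config`.
#' @export
run_config <- function(sample_rate = 4000,
                       segmentation = segmentation_config(),
                       lpc_order = 24,
                       mcs = mcs_config(),
                       baselines = c("svm-poly", "svm-rbf", "svm-quad"),
                       mode = c("leave-one-out", "half-split"),
                       seed = 1) {
  bad <- setdiff(baselines, c("svm-poly", "svm-rbf", "svm-quad"))
  if (length(bad)) config_error("unknown baselines: %s", paste(bad, collapse = ", "))
  structure(list(sample_rate = sample_rate, segmentation = segmentation,
                 lpc_order = lpc_order, mcs = mcs, baselines = baselines,
                 mode = match.arg(mode), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a WAV directory with a manifest into a dataset
#'
#' Expects `manifest.csv` with columns `filename,class_label` (as written by
#' [write_dataset()]).
#'
#' @param dir directory containing the WAV files and manifest.
#' @return a `pcg_dataset`.
#' @export
read_dataset_dir <- function(dir) {
  manifest <- file.path(dir, "manifest.csv")
  if (!dir.exists(dir) || !file.exists(manifest))
    input_error("ingestion failed: no manifest.csv in '%s'", dir)
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) input_error("ingestion failed: manifest in '%s' is empty", dir)
  recs <- lapply(seq_len(nrow(df)), function(i) {
    rec <- load_recording(file.path(dir, df$filename[i]))
    rec$label <- df$class_label[i]
    rec
  })
  rates <- unique(vapply(recs, function(r) r$sample_rate, numeric(1)))
  structure(list(recordings = recs, labels = df$class_label,
                 per_class_count = NA_integer_,
                 sample_rate = if (length(rates) == 1L) rates else NA_real_,
                 seed = NA_integer_),
            class = "pcg_dataset")
}

# The principal segment of a recording: the detected window with the most
# energy. Synthetic fixtures hold one tone (or merged tone pair) per
# recording, so this is normally the only segment.
principal_segment <- function(rec, cfg) {
  segs <- segment_heart_tones(rec, cfg$segmentation)
  if (length(segs) == 0L)
    input_error("segmentation stage found no heart tone in '%s'", rec$source_id)
  energies <- vapply(segs, function(s) sum(s$samples^2), numeric(1))
  segs[[which.max(energies)]]
}

#' Build the LPC feature table of a dataset
#'
#' Resamples each recording to the working rate if needed, segments it,
#' takes the highest-energy window, and extracts the LPC feature vector.
#'
#' @param dataset a `pcg_dataset`.
#' @param cfg a [run_config()].
#' @return list with `x` (`n x lpc_order` feature matrix), `y` (labels),
#'   `source_ids`.
#' @export
dataset_features <- function(dataset, cfg = run_config()) {
  stopifnot(inherits(dataset, "pcg_dataset"))
  n <- length(dataset$recordings)
  x <- matrix(NA_real_, n, cfg$lpc_order,
              dimnames = list(NULL, paste0("a", seq_len(cfg$lpc_order))))
  ids <- character(n)
  for (i in seq_len(n)) {
    rec <- dataset$recordings[[i]]
    if (rec$sample_rate != cfg$sample_rate)
      rec <- resample_recording(rec, cfg$sample_rate)
    seg <- principal_segment(rec, cfg)
    x[i, ] <- extract_features(seg, cfg$sample_rate, cfg$lpc_order)
    ids[i] <- rec$source_id
  }
  list(x = x, y = dataset$labels, source_ids = ids)
}

#' Write / read an LPC feature table as CSV
#'
#' Columns: `source_id`, `class_label`, `a1..a<p>`.
#'
#' @param features a list as returned by [dataset_features()].
#' @param path CSV path.
#' @return `path` invisibly; `read_feature_table()` returns the list form.
#' @export
write_feature_table <- function(features, path) {
  df <- data.frame(source_id = features$source_ids,
                   class_label = features$y, features$x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  acols <- grep("^a[0-9]+$", names(df), value = TRUE)
  list(x = as.matrix(df[, acols]), y = df$class_label,
       source_ids = df$source_id)
}

#' Stratified half-split evaluation of a genome
#'
#' Splits each class in half (seeded), trains the ensemble on the training
#' half, and evaluates on the held-out half.
#'
#' @param x feature matrix, `y` labels, `genome` an [svm_genome()].
#' @param y class labels.
#' @param genome an [svm_genome()].
#' @param seed integer seed for the stratified split.
#' @return an [evaluate_predictions()] report with attribute `test_idx`.
#' @export
half_split_evaluate <- function(x, y, genome, seed = 1) {
  x <- as.matrix(x); y <- as.character(y)
  test_idx <- with_seed(seed, {
    unlist(lapply(split(seq_along(y), y), function(idx) {
      sample(idx, floor(length(idx) / 2))
    }), use.names = FALSE)
  })
  if (length(test_idx) == 0L || length(test_idx) == length(y))
    config_error("half-split needs >= 2 samples per class")
  ens <- train_ovr_ensemble(x[-test_idx, , drop = FALSE], y[-test_idx], genome)
  preds <- predict(ens, x[test_idx, , drop = FALSE])
  rep <- evaluate_predictions(preds, y[test_idx], classes = sort(unique(y)))
  attr(rep, "test_idx") <- sort(test_idx)
  rep
}

evaluate_genome <- function(x, y, genome, mode, seed) {
  if (mode == "leave-one-out") loo_evaluate(x, y, genome)
  else half_split_evaluate(x, y, genome, seed)
}

baseline_genome_for <- function(name, m) {
  switch(name,
         "svm-poly" = baseline_genome("polynomial", m, u = 3),
         "svm-rbf" = baseline_genome("rbf", m, sigma = 1),
         "svm-quad" = baseline_genome("quadratic", m),
         config_error("unknown baseline '%s'", name))
}

#' Run the full comparison experiment
#'
#' Segments and featurizes the dataset, evaluates each requested
#' fixed-kernel baseline (all 24 coefficients, default parameters) and the
#' MCS-optimized system under the configured protocol, and assembles a
#' per-class comparison table with `Average` and `Average var.` rows.
#'
#' @param config a [run_config()].
#' @param data a `pcg_dataset` or a directory path readable by
#'   [read_dataset_dir()].
#' @return list with `table` (data.frame: class rows x system columns),
#'   `reports` (named list of evaluation reports), `best_genome`,
#'   `mcs_trace`, `features`, `models` (named list of trained
#'   `ovr_ensemble`s on the full data).
#' @export
run_experiment <- function(config, data) {
  dataset <- if (is.character(data)) read_dataset_dir(data) else data
  stopifnot(inherits(dataset, "pcg_dataset"))
  features <- dataset_features(dataset, config)
  x <- features$x; y <- features$y
  m <- length(unique(y))

  reports <- list(); models <- list()
  for (b in config$baselines) {
    genome <- baseline_genome_for(b, m)
    reports[[b]] <- evaluate_genome(x, y, genome, config$mode, config$seed)
    models[[b]] <- train_ovr_ensemble(x, y, genome)
  }

  mcs_cfg <- config$mcs
  mcs_cfg$seed <- config$seed
  evo <- evolve_classifier(x, y, mcs_cfg)
  reports[["svm-mcs"]] <- evaluate_genome(x, y, evo$best_genome, config$mode,
                                          config$seed)
  models[["svm-mcs"]] <- train_ovr_ensemble(x, y, evo$best_genome)

  classes <- sort(unique(y))
  tab <- data.frame(class = classes, stringsAsFactors = FALSE)
  for (nm in names(reports)) {
    pc <- reports[[nm]]$per_class
    tab[[nm]] <- pc$balanced_accuracy[match(classes, pc$class)]
  }
  tail_rows <- data.frame(class = c("Average", "Average var."),
                          stringsAsFactors = FALSE)
  for (nm in names(reports))
    tail_rows[[nm]] <- c(reports[[nm]]$average, reports[[nm]]$variance)
  tab <- rbind(tab, tail_rows)

  list(table = tab, reports = reports, best_genome = evo$best_genome,
       mcs_trace = evo$trace, features = features, models = models)
}

#' Classify the heart tones of a recording with a saved model
#'
#' Segments the recording, extracts an LPC feature vector per segment, and
#' predicts with the (possibly deserialized) ensemble. Predictions after a
#' [save_model()] / [load_model()] round trip are identical to in-memory
#' predictions.
#'
#' @param model an `ovr_ensemble` or a path to a model JSON.
#' @param recording a [pcg_recording()] or a WAV path.
#' @param cfg a [run_config()] (segmentation, sample rate, LPC order).
#' @return data.frame with one row per segment: `start_s`, `end_s`,
#'   `predicted_class`, plus one decision-value column per class. Silence
#'   gives zero rows.
#' @export
classify_recording <- function(model, recording, cfg = run_config()) {
  ens <- if (is.character(model)) load_model(model) else model
  stopifnot(inherits(ens, "ovr_ensemble"))
  rec <- if (is.character(recording)) load_recording(recording) else recording
  stopifnot(inherits(rec, "pcg_recording"))
  if (rec$sample_rate != cfg$sample_rate)
    rec <- resample_recording(rec, cfg$sample_rate)
  segs <- segment_heart_tones(rec, cfg$segmentation)
  cls <- ens$class_order
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      predicted_class = character(0), stringsAsFactors = FALSE)
  for (cl in cls) empty[[cl]] <- numeric(0)
  if (length(segs) == 0L) return(empty)
  rows <- lapply(segs, function(s) {
    fv <- extract_features(s, cfg$sample_rate, cfg$lpc_order)
    dv <- decision_values(ens, matrix(fv, nrow = 1))
    out <- data.frame(start_s = s$start_time, end_s = s$end_time,
                      predicted_class = cls[which.max(dv)],
                      stringsAsFactors = FALSE)
    for (k in seq_along(cls)) out[[cls[k]]] <- dv[1, k]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
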