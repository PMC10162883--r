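#' Train the network on a feature/target table and report split metrics
#'
#' Stage 3 of the four-stage chain (acquire -> texture features ->
#' train -> predict). Trains the 5-40-1 network and reports Pearson R and
#' MSE per split plus pooled over all rows, alongside the per-epoch MSE
#' curves.
#'
#' @param features data frame with columns
#'   `contrast, correlation, energy, homogeneity, entropy` (extra columns
#'   ignored) — e.g. [read_feature_table()] output or
#'   `generate_dataset()$features_qct`.
#' @param targets numeric BMD targets; defaults to `features$bmd`.
#' @param config a [training_config()].
#' @param model_path,report_path optional output JSON paths.
#' @return List with `network`, `record`, `split`, `metrics` (data frame:
#'   one row per split plus `overall`, columns `split, n, r, mse`), and
#'   `predictions` (per-row predicted vs target).
#' @export
run_training_phase <- function(features, targets = features$bmd,
                               config = training_config(),
                               model_path = NULL, report_path = NULL) {
  if (is.null(targets))
    ct2bmd_stop("ct2bmd_schema_error", "no targets: supply `targets` or a `bmd` column")
  fit <- train_bmd_network(features, targets, config)
  pred <- predict(fit$network, features)
  tgt <- as.numeric(targets)

  metric_row <- function(name, idx) {
    data.frame(split = name, n = length(idx),
               r = correlation_coefficient(pred[idx], tgt[idx]),
               mse = mse(pred[idx], tgt[idx]))
  }
  metrics <- rbind(metric_row("train", fit$split$train),
                   if (length(fit$split$val) >= 2L) metric_row("val", fit$split$val),
                   if (length(fit$split$test) >= 2L) metric_row("test", fit$split$test),
                   metric_row("overall", seq_along(tgt)))

  predictions <- data.frame(sample = seq_along(tgt), target = tgt,
                            predicted = pred)
  out <- list(network = fit$network, record = fit$record, split = fit$split,
              metrics = metrics, predictions = predictions)
  if (!is.null(model_path)) write_bmd_network(fit$network, model_path)
  if (!is.null(report_path)) {
    jsonlite::write_json(list(
      seed = config$seed, config = unclass(config), metrics = metrics,
      best_epoch = fit$record$best_epoch,
      stop_reason = fit$record$stop_reason,
      epochs = fit$record$epochs
    ), report_path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  message(sprintf("run_training_phase: %d rows -> splits %d/%d/%d, stop: %s (best epoch %d)",
                  length(tgt), length(fit$split$train), length(fit$split$val),
                  length(fit$split$test), fit$record$stop_reason,
                  fit$record$best_epoch))
  out
}

#' Evaluate a trained model on clinical-CT features
#'
#' Stage 4: predicts BMD from features extracted from (degraded) clinical
#' renderings and compares against the QCT-derived ground truth.
#'
#' @param net a trained `bmd_network`.
#' @param clinical_features data frame with the five feature columns.
#' @param truth numeric ground-truth BMD values, one per row.
#' @return List with `r` (Pearson), `mse`, and a per-sample data frame
#'   `table` (`truth, predicted, residual`).
#' @export
run_clinical_evaluation <- function(net, clinical_features, truth) {
  truth <- as.numeric(truth)
  if (nrow(clinical_features) != length(truth))
    ct2bmd_stop("ct2bmd_schema_error", "feature rows (%d) and truth (%d) differ",
                nrow(clinical_features), length(truth))
  pred <- predict(net, clinical_features)
  list(r = correlation_coefficient(pred, truth),
       mse = mse(pred, truth),
       table = data.frame(truth = truth, predicted = pred,
                          residual = pred - truth))
}

#' End-to-end synthetic experiment
#'
#' Runs the whole chain on synthetic phantoms: simulate paired QCT/clinical
#' renderings, extract texture features, train the network on the QCT
#' table, then evaluate on the clinical features of the held-out test
#' split. Reports the training-phase metrics (including the overall pooled
#' Pearson R) and the clinical-vs-truth Pearson R.
#'
#' @param n number of phantoms.
#' @param seed master seed (drives simulation, split and initialization).
#' @param bvtv_range bone-fraction range for the simulated population.
#' @param spec template [phantom_spec()].
#' @param config a [training_config()]; its seed is overridden by `seed`.
#' @param out_dir optional directory for report/model/dataset files.
#' @return List with `dataset`, `training` ([run_training_phase()] result)
#'   and `clinical` ([run_clinical_evaluation()] on the test split).
#' @export
run_synthetic_experiment <- function(n = 300L, seed = 7L,
                                     bvtv_range = c(0.1, 0.6),
                                     spec = phantom_spec(),
                                     config = training_config(),
                                     out_dir = NULL) {
  config$seed <- as.integer(seed)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  ds <- generate_dataset(n, bvtv_range = bvtv_range, seed = seed, spec = spec,
                         out_dir = out_dir)
  message(sprintf("run_synthetic_experiment: simulated %d phantoms (seed %d)", n, seed))
  training <- run_training_phase(
    ds$features_qct, config = config,
    model_path = if (!is.null(out_dir)) file.path(out_dir, "model.json"),
    report_path = if (!is.null(out_dir)) file.path(out_dir, "training_report.json"))
  test_idx <- training$split$test
  clinical <- run_clinical_evaluation(
    training$network,
    ds$features_clinical[test_idx, , drop = FALSE],
    ds$truth$true_bmd[test_idx])
  message(sprintf("run_synthetic_experiment: clinical eval on %d held-out phantoms, R = %.4f",
                  length(test_idx), clinical$r))
  if (!is.null(out_dir)) {
    jsonlite::write_json(list(
      seed = seed, n = n, bvtv_range = bvtv_range,
      spec = unclass(spec)[setdiff(names(spec), "seed")],
      config = unclass(config),
      training_metrics = training$metrics,
      clinical = list(n = length(test_idx), r = clinical$r, mse = clinical$mse)
    ), file.path(out_dir, "experiment_report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  list(dataset = ds, training = training, clinical = clinical)
}

#' Read/write feature tables
#'
#' CSV with header `contrast,correlation,energy,homogeneity,entropy,bmd`;
#' the `bmd` column may be absent for prediction-only tables. The packaged
#' sample table (nine rows of published texture features and densities) is
#' available via `ct2bmd_example_table()`.
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path)
  missing <- setdiff(FEATURE_NAMES, names(df))
  if (length(missing))
    ct2bmd_stop("ct2bmd_schema_error", "feature table lacks columns: %s",
                paste(missing, collapse = ", "))
  df
}

#' @rdname read_feature_table
#' @param df data frame with the feature columns (and optionally `bmd`).
#' @export
write_feature_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_feature_table
#' @export
ct2bmd_example_table <- function() {
  read_feature_table(system.file("extdata", "table1.csv", package = "ct2bmd",
                                 mustWork = TRUE))
}
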