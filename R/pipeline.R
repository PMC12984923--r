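#' Pipeline configuration
#'
#' Orchestration settings for the end-to-end flow: simulate (or ingest) ->
#' preprocess -> extract -> select -> classify. One global seed propagates
#' to every stochastic stage.
#'
#' @param synth A [synth_config()] describing the data source.
#' @param roi_size,sigma Preprocessing parameters.
#' @param algorithm Optimizer for the selection stage.
#' @param alpha,pop_size,max_iter,threshold Selection-stage parameters.
#' @param select Run the feature-selection stage? When `FALSE` the
#'   classifier consumes all 39 features.
#' @param model `"knn"` or `"svm"` for the final classifier.
#' @param folds Cross-validation folds of the final evaluation.
#' @param subsets Which split subsets feed the classification table
#'   (default `"test"`, emulating evaluation on held-out regions).
#' @param seed Global seed.
#' @param out_dir Optional directory; when set, `features.csv`,
#'   `selection.json`, `report.json` and a log are written there.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(), roi_size = 64,
                            sigma = 1, algorithm = "sfoa", alpha = 0.99,
                            pop_size = 50, max_iter = 100, threshold = 0.8,
                            select = TRUE, model = "knn", folds = 10,
                            subsets = "test", seed = 1L, out_dir = NULL) {
  structure(list(
    synth = synth, roi_size = roi_size, sigma = sigma,
    algorithm = algorithm, alpha = alpha, pop_size = pop_size,
    max_iter = max_iter, threshold = threshold, select = select,
    model = model, folds = folds, subsets = subsets,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

.log_event <- function(log, stage, msg) {
  entry <- list(stage = stage, message = msg,
                elapsed_s = round(as.numeric(proc.time()[3] - log$t0), 3))
  log$events[[length(log$events) + 1L]] <- entry
  log
}

#' Run the full pipeline on synthetic data
#'
#' Executes the stages in order — dataset generation, ROI preprocessing and
#' 1-D transformation, 39-feature extraction, wrapper feature selection,
#' cross-validated classification — and returns (optionally writes) the
#' feature table, the selection result and the evaluation report.
#' Re-running with an identical config reproduces every numeric output.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_report`: `features` (table),
#'   `selection` (`optim_trace` or `NULL`), `report`
#'   (`evaluation_report`), `ns`, `manifest`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  log <- list(t0 = proc.time()[3], events = list())
  cfg <- config$synth
  cfg$seed <- config$seed
  log <- .log_event(log, "simulate", sprintf("mode=%s seed=%d",
                                             cfg$mode, config$seed))
  dataset <- generate_dataset(cfg)
  pairs <- dataset_to_pairs(dataset, subsets = config$subsets,
                            roi_size = config$roi_size,
                            sigma = config$sigma)
  log <- .log_event(log, "preprocess",
                    sprintf("%d ROIs at %dx%d", length(pairs),
                            config$roi_size, config$roi_size))
  feats <- feature_table(pairs)
  log <- .log_event(log, "extract", sprintf("%d x 39 feature table",
                                            nrow(feats)))
  x <- as.matrix(feats[, -(1:2)])
  y <- feats$class
  selection <- NULL
  sel_cols <- seq_len(ncol(x))
  if (config$select) {
    ctx <- fitness_context(x, y, alpha = config$alpha,
                           seed = config$seed)
    oc <- optimizer_config(algorithm = config$algorithm,
                           pop_size = config$pop_size,
                           max_iter = config$max_iter, dim = ncol(x),
                           threshold = config$threshold,
                           seed = config$seed)
    selection <- run_optimizer(ctx, oc)
    sel_cols <- which(selection$best_mask$bits == 1L)
    log <- .log_event(log, "select",
                      sprintf("%s picked %d features", config$algorithm,
                              length(sel_cols)))
  }
  report <- cross_validate(x[, sel_cols, drop = FALSE], y,
                           spec = classifier_spec(config$model),
                           folds = config$folds, seed = config$seed)
  log <- .log_event(log, "classify",
                    sprintf("%s %d-fold accuracy %.4f", config$model,
                            config$folds, report$accuracy))
  out <- structure(list(
    features = feats, selection = selection, report = report,
    ns = length(sel_cols), selected = sel_cols,
    manifest = dataset$manifest, config = config, log = log$events
  ), class = "pipeline_report")
  if (!is.null(config$out_dir)) .write_pipeline_outputs(out, config)
  out
}

.write_pipeline_outputs <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_csv(out$features, file.path(config$out_dir, "features.csv"))
  if (!is.null(out$selection)) {
    sel <- out$selection
    jsonlite::write_json(list(
      algorithm = sel$algorithm, seed = config$seed,
      threshold = config$threshold, alpha = config$alpha,
      selected_features = names(out$features)[-(1:2)][out$selected],
      ns = out$ns, best_fitness = sel$best_fitness,
      convergence = sel$trace
    ), file.path(config$out_dir, "selection.json"), auto_unbox = TRUE,
    digits = NA)
  }
  r <- out$report
  jsonlite::write_json(list(
    model = config$model, folds = config$folds, seed = config$seed,
    ns = out$ns, confusion = as.list(r$confusion),
    accuracy = r$accuracy, precision = r$precision, recall = r$recall,
    f1 = r$f1, auc = r$auc, per_fold_accuracy = r$per_fold,
    roc = r$roc
  ), file.path(config$out_dir, "report.json"), auto_unbox = TRUE,
  digits = NA)
  jsonlite::write_json(out$log, file.path(config$out_dir, "log.json"),
                       auto_unbox = TRUE)
  invisible(NULL)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline run (", x$config$synth$mode, " mode, seed ",
      x$config$seed, ")\n", sep = "")
  cat("  feature table:", nrow(x$features), "x 39\n")
  cat("  selected features:", x$ns, "\n")
  cat(sprintf("  %s accuracy %.4f (AUC %.4f)\n", x$config$model,
              x$report$accuracy, x$report$auc))
  invisible(x)
}

#' Compare metaheuristic selectors on one feature table
#'
#' Runs each configured algorithm on the same features, labels and seed,
#' reporting the selected-feature count, best fitness, cross-validated
#' accuracy and the convergence curve per algorithm.
#'
#' @param features Feature matrix or feature table (see [entrosel()]).
#' @param labels Binary labels (optional for feature tables).
#' @param algorithms Character vector of at least two algorithms.
#' @param alpha,pop_size,max_iter,threshold,folds,seed Shared settings.
#' @return List: `table` (one row per algorithm), `traces` (named list of
#'   `optim_trace` objects).
#' @export
compare_optimizers <- function(features, labels = NULL,
                               algorithms = c("sfoa", "pso", "hho", "po"),
                               alpha = 0.99, pop_size = 50, max_iter = 100,
                               threshold = 0.8, folds = 10, seed = 1L) {
  if (length(algorithms) < 2L)
    stop("invalid argument: need at least two algorithms to compare")
  if (is.data.frame(features) &&
      all(c("sample_id", "class") %in% names(features))) {
    labels <- features$class
    features <- as.matrix(features[, setdiff(names(features),
                                             c("sample_id", "class")),
                                   drop = FALSE])
  }
  features <- as.matrix(features)
  traces <- list()
  rows <- list()
  for (alg in algorithms) {
    fit <- entrosel(features, labels, algorithm = alg, alpha = alpha,
                    pop_size = pop_size, max_iter = max_iter,
                    threshold = threshold, folds = folds, seed = seed)
    traces[[alg]] <- fit$optimization
    rows[[alg]] <- data.frame(
      algorithm = alg, ns = length(fit$selected),
      best_fitness = fit$optimization$best_fitness,
      accuracy = fit$report$accuracy, auc = fit$report$auc)
  }
  list(table = do.call(rbind, rows), traces = traces)
}
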