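#' Fit an entropy-feature selection + kNN classification model
#'
#' The package's core estimator: wrapper feature selection over the
#' 39-dimensional (or general) entropy feature space driven by a
#' metaheuristic — the superb fairy-wren optimizer by default — followed by
#' evaluation of the selected subset with a stratified cross-validated
#' 1-nearest-neighbor classifier. Returns a classed object with the usual
#' accessor methods.
#'
#' @param x Numeric feature matrix or data frame (rows = samples). A
#'   feature table from [feature_table()] may be passed directly; its
#'   `sample_id`/`class` columns are stripped and `class` used as `y`.
#' @param y Binary class labels (ignored when `x` is a feature table).
#' @param algorithm `"sfoa"`, `"pso"`, `"hho"` or `"po"`.
#' @param alpha Fitness trade-off weight (default 0.99).
#' @param pop_size,max_iter Optimizer budget (defaults 50 and 100).
#' @param threshold Mask binarization cut-off (default 0.8).
#' @param folds Folds of the final cross-validated evaluation (default 10).
#' @param validation Validation scheme inside the wrapper fitness
#'   (`"holdout"` or `"cv"`, see [fitness_context()]).
#' @param k Neighbor count of the kNN classifier (default 1).
#' @param seed Seed for the whole fit.
#' @param ... Further arguments passed to [optimizer_config()].
#' @return Object of class `entrosel`: the optimization trace, the selected
#'   mask, the cross-validated [cross_validate()] report on the selected
#'   features, and the training data needed by [predict.entrosel()].
#' @examples
#' set.seed(1)
#' pairs <- c(lapply(1:15, function(i)
#'              generate_signal_pair("tumor", 128, source_image_id = i)),
#'            lapply(1:15, function(i)
#'              generate_signal_pair("non_tumor", 128, source_image_id = i)))
#' tab <- feature_table(pairs)
#' fit <- entrosel(tab, pop_size = 10, max_iter = 10, folds = 5, seed = 1)
#' print(fit)
#' @export
entrosel <- function(x, y = NULL, algorithm = "sfoa", alpha = 0.99,
                     pop_size = 50, max_iter = 100, threshold = 0.8,
                     folds = 10, validation = "holdout", k = 1, seed = 1L,
                     ...) {
  if (is.data.frame(x) && all(c("sample_id", "class") %in% names(x))) {
    y <- x$class
    x <- as.matrix(x[, setdiff(names(x), c("sample_id", "class")),
                     drop = FALSE])
  }
  x <- as.matrix(x)
  if (is.null(y)) stop("invalid input: class labels required")
  ctx <- fitness_context(x, y, alpha = alpha, k = k,
                         validation = validation, seed = seed)
  config <- optimizer_config(algorithm = algorithm, pop_size = pop_size,
                             max_iter = max_iter, dim = ncol(x),
                             threshold = threshold, seed = seed, ...)
  trace <- run_optimizer(ctx, config)
  sel <- which(trace$best_mask$bits == 1L)
  report <- cross_validate(x[, sel, drop = FALSE], y,
                           spec = classifier_spec("knn", k = k),
                           folds = folds, seed = seed)
  structure(list(
    call = match.call(), algorithm = algorithm, seed = seed,
    feature_names = colnames(x),
    selected = sel, mask = trace$best_mask,
    optimization = trace, report = report,
    train_x = x, train_y = as.character(y), k = k
  ), class = "entrosel")
}

#' @export
print.entrosel <- function(x, ...) {
  cat("Entropy-feature wrapper selection model (", toupper(x$algorithm),
      " + ", x$k, "-NN)\n", sep = "")
  nm <- if (!is.null(x$feature_names)) x$feature_names[x$selected]
        else as.character(x$selected)
  cat("  selected ", length(x$selected), " of ", ncol(x$train_x),
      " features: ", paste(nm, collapse = ", "), "\n", sep = "")
  cat(sprintf("  best fitness %.5f; %d-fold CV accuracy %.4f (AUC %.4f)\n",
              x$optimization$best_fitness, x$report$folds,
              x$report$accuracy, x$report$auc))
  invisible(x)
}

#' @export
summary.entrosel <- function(object, ...) {
  r <- object$report
  cat("Selected features and cross-validated performance\n")
  print(object)
  cat("  confusion (TP TN FP FN):", r$confusion, "\n")
  cat(sprintf("  macro precision %.4f  recall %.4f  F1 %.4f\n",
              r$precision, r$recall, r$f1))
  cat("  per-fold accuracy:",
      paste(sprintf("%.3f", r$per_fold), collapse = " "), "\n")
  invisible(object)
}

#' @export
coef.entrosel <- function(object, ...) {
  bits <- object$mask$bits
  names(bits) <- if (!is.null(object$feature_names)) object$feature_names
                 else paste0("V", seq_along(bits))
  bits
}

#' Predict classes for new samples from a fitted model
#'
#' Standardizes the query rows with the training statistics of the
#' selected feature columns and applies the kNN rule against the full
#' training set.
#'
#' @param object An [entrosel()] fit.
#' @param newdata Matrix or data frame with the same feature columns.
#' @param ... Unused.
#' @return List: `labels`, `score` (kNN distance margin).
#' @export
predict.entrosel <- function(object, newdata, ...) {
  if (is.data.frame(newdata))
    newdata <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  sel <- object$selected
  std <- standardize(object$train_x[, sel, drop = FALSE],
                     newdata[, sel, drop = FALSE])
  knn_predict(std$train, object$train_y, std$apply, k = object$k)
}

#' Plot the optimizer convergence curve of a fit
#'
#' Best fitness per iteration (non-increasing under greedy acceptance).
#'
#' @param x An [entrosel()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.entrosel <- function(x, ...) {
  graphics::plot(seq_along(x$optimization$trace), x$optimization$trace,
                 type = "s", xlab = "iteration", ylab = "best fitness",
                 main = paste0("Convergence (", toupper(x$algorithm), ")"),
                 ...)
  invisible(x)
}
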