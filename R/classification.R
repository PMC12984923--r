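#' Classifier specification
#'
#' Settings of the final classifiers: kNN with `k = 1`, Euclidean distance
#' and uniform weights (primary), or a linear soft-margin SVM with box
#' constraint 1 (comparison). Feature standardization is on by default and
#' always fitted on training data only.
#'
#' @param kind `"knn"` or `"svm"`.
#' @param k Neighbor count for kNN (default 1).
#' @param cost SVM box constraint (default 1).
#' @param standardize Standardize features inside each fit (default TRUE).
#' @return List of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("knn", "svm"), k = 1, cost = 1,
                            standardize = TRUE) {
  kind <- match.arg(kind)
  if (k < 1) stop("invalid argument: k must be >= 1")
  if (cost <= 0) stop("invalid argument: cost must be > 0")
  structure(list(kind = kind, k = as.integer(k), cost = cost,
                 standardize = standardize), class = "classifier_spec")
}

#' Z-score standardization fitted on training data
#'
#' Per-feature centering and scaling using the training mean and SD;
#' zero-SD (constant) training features map to all-zeros and are flagged.
#' The apply set is always transformed with training statistics only.
#'
#' @param train_features Numeric matrix, `>= 2` rows.
#' @param apply_features Optional matrix transformed with the train scaler.
#' @return List: `train`, `apply` (or `NULL`), `center`, `scale`,
#'   `degenerate` (logical per feature).
#' @export
standardize <- function(train_features, apply_features = NULL) {
  train_features <- as.matrix(train_features)
  if (nrow(train_features) < 2L)
    stop("invalid input: need >= 2 training rows to standardize")
  ctr <- colMeans(train_features)
  scl <- apply(train_features, 2, stats::sd)
  degenerate <- !is.finite(scl) | scl == 0
  scl[degenerate] <- 1
  tr <- sweep(sweep(train_features, 2, ctr), 2, scl, "/")
  tr[, degenerate] <- 0
  ap <- NULL
  if (!is.null(apply_features)) {
    ap <- sweep(sweep(as.matrix(apply_features), 2, ctr), 2, scl, "/")
    ap[, degenerate] <- 0
  }
  list(train = tr, apply = ap, center = ctr, scale = scl,
       degenerate = degenerate)
}

#' k-nearest-neighbor prediction with a margin score
#'
#' Euclidean distances, majority vote over the `k` nearest training points.
#' Ties (equal distances, or split votes at even `k`) resolve to the
#' nearest neighbor by index order. The returned score, used for ROC
#' curves, is the signed distance margin: nearest other-class distance
#' minus nearest voted-class distance (larger = more confident).
#'
#' @param train_features,train_labels Training set (matrix + labels).
#' @param query_features Rows to classify.
#' @param k Neighbor count, `<= nrow(train_features)`.
#' @param positive Label treated as positive when signing scores; default
#'   the first level encountered.
#' @return List: `labels` (character), `score` (numeric, oriented so larger
#'   means more positive-class evidence).
#' @export
knn_predict <- function(train_features, train_labels, query_features, k = 1,
                        positive = NULL) {
  train_features <- as.matrix(train_features)
  query_features <- as.matrix(query_features)
  train_labels <- as.character(train_labels)
  if (nrow(train_features) == 0L) stop("invalid input: empty training set")
  if (k > nrow(train_features))
    stop("invalid argument: k exceeds training size")
  if (is.null(positive)) positive <- train_labels[1]
  nq <- nrow(query_features)
  labels <- character(nq)
  margin <- numeric(nq)
  # squared Euclidean distances via the expansion trick
  tn <- rowSums(train_features^2)
  for (i in seq_len(nq)) {
    q <- query_features[i, ]
    d2 <- tn - 2 * drop(train_features %*% q) + sum(q^2)
    d2[d2 < 0] <- 0
    ord <- order(d2)                  # stable: index order breaks ties
    nb <- ord[seq_len(k)]
    votes <- table(train_labels[nb])
    top <- names(votes)[votes == max(votes)]
    lab <- if (length(top) == 1L) top else train_labels[nb[1]]
    labels[i] <- lab
    d_same <- sqrt(min(d2[train_labels == lab]))
    other <- train_labels != lab
    d_other <- if (any(other)) sqrt(min(d2[other])) else Inf
    m <- d_other - d_same
    margin[i] <- if (lab == positive) m else -m
  }
  list(labels = labels, score = margin, positive = positive)
}

#' Linear SVM training and prediction
#'
#' Soft-margin linear SVM at the configured box constraint (libsvm backend)
#' on standardized features; decision values are returned for ROC analysis.
#'
#' @param train_features,train_labels Training set; both classes required.
#' @param query_features Rows to classify.
#' @param spec A [classifier_spec()] of kind `"svm"`.
#' @param positive Label whose decision values are oriented positive.
#' @return List: `labels`, `score` (decision values), `positive`.
#' @export
svm_train_predict <- function(train_features, train_labels, query_features,
                              spec = classifier_spec("svm"),
                              positive = NULL) {
  train_labels <- as.character(train_labels)
  if (length(unique(train_labels)) < 2L)
    stop("invalid input: training set must contain both classes")
  if (is.null(positive)) positive <- train_labels[1]
  fit <- e1071::svm(as.matrix(train_features), factor(train_labels),
                    kernel = "linear", cost = spec$cost, scale = FALSE)
  pred <- stats::predict(fit, as.matrix(query_features),
                         decision.values = TRUE)
  dv <- drop(attr(pred, "decision.values"))
  # orient decision values so larger = positive class
  dv_name <- colnames(attr(pred, "decision.values"))[1]
  first <- strsplit(dv_name, "/")[[1]][1]
  if (first != positive) dv <- -dv
  list(labels = as.character(pred), score = dv, positive = positive)
}

#' Confusion-matrix metrics
#'
#' Accuracy `(TP + TN) / (TP + TN + FP + FN)` plus per-class precision,
#' recall and F1 (each class treated as positive in turn), macro-averaged
#' with equal class weight. Classes with no predicted (or true) members
#' contribute zero to the corresponding ratio.
#'
#' @param y_true,y_pred Equal-length binary label vectors.
#' @param positive Label reported as the positive class in the confusion
#'   matrix (default `"tumor"` when present, else the first level).
#' @return List: `confusion` (TP, TN, FP, FN), `accuracy`, `precision`,
#'   `recall`, `f1` (macro), `per_class` data frame.
#' @export
confusion_metrics <- function(y_true, y_pred, positive = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("invalid input: label length mismatch")
  levels <- sort(unique(c(y_true, y_pred)))
  if (length(levels) > 2L) stop("invalid input: labels must be binary")
  if (is.null(positive))
    positive <- if ("tumor" %in% levels) "tumor" else levels[1]
  negative <- setdiff(levels, positive)
  if (length(negative) == 0L) negative <- positive  # degenerate single class
  tp <- sum(y_true == positive & y_pred == positive)
  tn <- sum(y_true == negative & y_pred == negative)
  fp <- sum(y_true == negative & y_pred == positive)
  fn <- sum(y_true == positive & y_pred == negative)
  per_class <- do.call(rbind, lapply(c(positive, negative), function(cl) {
    tpc <- sum(y_true == cl & y_pred == cl)
    fpc <- sum(y_true != cl & y_pred == cl)
    fnc <- sum(y_true == cl & y_pred != cl)
    prec <- if (tpc + fpc > 0) tpc / (tpc + fpc) else 0
    rec <- if (tpc + fnc > 0) tpc / (tpc + fnc) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1)
  }))
  if (positive == negative) per_class <- per_class[1, , drop = FALSE]
  list(
    confusion = c(TP = tp, TN = tn, FP = fp, FN = fn),
    accuracy = (tp + tn) / length(y_true),
    precision = mean(per_class$precision),
    recall = mean(per_class$recall),
    f1 = mean(per_class$f1),
    per_class = per_class,
    positive = positive
  )
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the unique score values as thresholds (predict positive when
#' `score >= threshold`), returning the (FPR, TPR) points and the
#' trapezoid-rule AUC — equal to the rank statistic: the probability that a
#' positive outscores a negative, ties counting one half.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Binary labels.
#' @param positive Positive-class label (default `"tumor"` when present).
#' @return List: `points` (data frame fpr/tpr/threshold), `auc`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  levels <- unique(labels)
  if (length(levels) < 2L) stop("invalid input: both classes required")
  if (is.null(positive))
    positive <- if ("tumor" %in% levels) "tumor" else levels[1]
  pos <- labels == positive
  np <- sum(pos); nn <- sum(!pos)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(th) sum(scores[pos] >= th) / np, numeric(1))
  fpr <- vapply(thr, function(th) sum(scores[!pos] >= th) / nn, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr, threshold = thr), auc = auc)
}

#' Stratified k-fold cross-validation
#'
#' Seeded stratified folds (per-class sizes differing by at most one);
#' standardization is fitted inside each training fold; every sample is
#' predicted exactly once. Returns the pooled confusion-matrix metrics,
#' per-fold accuracies, pooled ROC/AUC from the classifier scores, and the
#' out-of-fold predictions.
#'
#' @param features Numeric matrix or data frame.
#' @param labels Binary labels, every class with at least `folds` members.
#' @param spec A [classifier_spec()].
#' @param folds Number of folds, `>= 2` (default 10).
#' @param seed Seed for the fold shuffle.
#' @return List of class `evaluation_report`: metrics of
#'   [confusion_metrics()] plus `per_fold`, `roc`, `auc`, `folds`, `seed`,
#'   `predictions`.
#' @export
cross_validate <- function(features, labels, spec = classifier_spec("knn"),
                           folds = 10, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (folds < 2) stop("invalid argument: folds must be >= 2")
  tab <- table(labels)
  if (any(tab < folds))
    stop("invalid input: every class needs at least `folds` members")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  fold_id <- integer(length(labels))
  for (cl in names(tab)) {
    idx <- sample(which(labels == cl))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  preds <- character(length(labels))
  scores <- numeric(length(labels))
  per_fold <- numeric(folds)
  positive <- if ("tumor" %in% labels) "tumor" else sort(unique(labels))[1]
  for (f in seq_len(folds)) {
    te <- which(fold_id == f); tr <- which(fold_id != f)
    xtr <- features[tr, , drop = FALSE]; xte <- features[te, , drop = FALSE]
    if (spec$standardize) {
      std <- standardize(xtr, xte)
      xtr <- std$train; xte <- std$apply
    }
    res <- if (spec$kind == "knn")
      knn_predict(xtr, labels[tr], xte, k = spec$k, positive = positive)
    else
      svm_train_predict(xtr, labels[tr], xte, spec, positive = positive)
    preds[te] <- res$labels
    scores[te] <- res$score
    per_fold[f] <- mean(res$labels == labels[te])
  }
  cm <- confusion_metrics(labels, preds, positive = positive)
  roc <- roc_auc(scores, labels, positive = positive)
  structure(c(cm, list(per_fold = per_fold, roc = roc$points,
                       auc = roc$auc, folds = folds, seed = seed,
                       fold_id = fold_id,
                       predictions = preds, scores = scores)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Cross-validated evaluation (", x$folds, "-fold)\n", sep = "")
  cat("  confusion (TP TN FP FN):", x$confusion, "\n")
  cat(sprintf("  accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  cat(sprintf("  AUC %.4f\n", x$auc))
  invisible(x)
}
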