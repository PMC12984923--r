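test_that("standardization uses training statistics only", {
  set.seed(1)
  tr <- matrix(rnorm(60, 5, 3), 20, 3)
  te <- matrix(rnorm(15, 5, 3), 5, 3)
  s <- standardize(tr, te)
  expect_equal(colMeans(s$train), rep(0, 3), tolerance = 1e-9)
  expect_equal(apply(s$train, 2, sd), rep(1, 3), tolerance = 1e-9)
  # a test row equal to the train mean standardizes to zero
  s2 <- standardize(tr, matrix(colMeans(tr), 1, 3))
  expect_equal(as.numeric(s2$apply), rep(0, 3), tolerance = 1e-12)
  # constant columns map to zeros with a flag
  tr2 <- cbind(tr, 7)
  s3 <- standardize(tr2, cbind(te, 9))
  expect_true(s3$degenerate[4])
  expect_true(all(s3$train[, 4] == 0) && all(s3$apply[, 4] == 0))
  expect_error(standardize(tr[1, , drop = FALSE]), "invalid")
})

test_that("kNN predicts by majority vote over Euclidean neighbors", {
  train <- matrix(c(0, 0, 1, 0, 0, 1, 5, 5, 6, 5), ncol = 2, byrow = TRUE)
  lab <- c("a", "a", "a", "b", "b")
  # query identical to a training point
  p <- knn_predict(train, lab, train[4, , drop = FALSE], k = 1)
  expect_equal(p$labels, "b")
  # two points at distances 1 and 2
  p2 <- knn_predict(matrix(c(1, 0, 2, 0), 2, 2, byrow = TRUE), c("x", "y"),
                    matrix(c(0, 0), 1, 2), k = 1)
  expect_equal(p2$labels, "x")
  # k = 3 against the brute-force oracle on a fixture and random data
  q <- matrix(c(0.5, 0.2, 4, 4, 2.5, 2.5), 3, 2, byrow = TRUE)
  p3 <- knn_predict(train, lab, q, k = 3)
  expect_equal(p3$labels, unname(o_knn(train, lab, q, 3)))
  set.seed(2)
  rtrain <- matrix(rnorm(40), 20, 2)
  rlab <- rep(c("a", "b"), 10)
  rq <- matrix(rnorm(14), 7, 2)
  expect_equal(knn_predict(rtrain, rlab, rq, k = 3)$labels,
               unname(o_knn(rtrain, rlab, rq, 3)))
  # independent cross-check against the classic implementation at k = 1
  skip_if_not_installed("class")
  expect_equal(knn_predict(rtrain, rlab, rq, k = 1)$labels,
               as.character(class::knn(rtrain, rq, rlab, k = 1)))
  # margin score sign: positive-class predictions carry positive margins
  p4 <- knn_predict(train, lab, q, k = 1, positive = "a")
  expect_true(all((p4$labels == "a") == (p4$score > 0)))
  # resubstitution at k = 1 is perfect for distinct points
  expect_equal(knn_predict(rtrain, rlab, rtrain, k = 1)$labels, rlab)
})

test_that("linear SVM separates separable fixtures and signs decisions", {
  x <- matrix(c(0, 0, 0, 1, 4, 4, 4, 5), 4, 2, byrow = TRUE)
  y <- c("a", "a", "b", "b")
  p <- svm_train_predict(x, y, x)
  expect_equal(p$labels, y)
  expect_true(all(p$score[y == p$positive] > 0))
  expect_true(all(p$score[y != p$positive] < 0))
  expect_error(svm_train_predict(x, rep("a", 4), x), "invalid")
  # cross-check predictions against an independent SVM solver
  skip_if_not_installed("kernlab")
  set.seed(3)
  x6 <- matrix(rnorm(12), 6, 2) + c(0, 0, 0, 3, 3, 3)
  y6 <- rep(c("a", "b"), each = 3)
  mine <- svm_train_predict(x6, y6, x6)
  ref <- kernlab::ksvm(x6, factor(y6), kernel = "vanilladot", C = 1,
                       scaled = FALSE, kpar = list())
  expect_equal(mine$labels, as.character(kernlab::predict(ref, x6)))
})

test_that("confusion metrics reproduce their defining identities", {
  y <- rep(c("tumor", "non_tumor"), each = 10)
  m <- confusion_metrics(y, y)
  expect_equal(unname(m$confusion), c(10, 10, 0, 0))
  expect_equal(c(m$accuracy, m$precision, m$recall, m$f1), rep(1, 4))
  flipped <- ifelse(y == "tumor", "non_tumor", "tumor")
  m0 <- confusion_metrics(y, flipped)
  expect_equal(c(m0$accuracy, m0$precision, m0$recall, m0$f1), rep(0, 4))
  # the printed arithmetic case
  yy <- c(rep("tumor", 128), rep("non_tumor", 128))
  pp <- c(rep("tumor", 127), "non_tumor", rep("non_tumor", 126),
          rep("tumor", 2))
  mm <- confusion_metrics(yy, pp, positive = "tumor")
  expect_equal(unname(mm$confusion), c(127, 126, 2, 1))
  expect_equal(mm$accuracy, 253 / 256)
  # property: random confusion tables satisfy the formulas exactly
  set.seed(4)
  for (i in 1:20) {
    cts <- rmultinom(1, 40, c(0.3, 0.3, 0.2, 0.2))[, 1] + 1
    yt <- c(rep("tumor", cts[1]), rep("non_tumor", cts[2]),
            rep("non_tumor", cts[3]), rep("tumor", cts[4]))
    yp <- c(rep("tumor", cts[1]), rep("non_tumor", cts[2]),
            rep("tumor", cts[3]), rep("non_tumor", cts[4]))
    r <- confusion_metrics(yt, yp, positive = "tumor")
    tp <- cts[1]; tn <- cts[2]; fp <- cts[3]; fn <- cts[4]
    expect_equal(r$accuracy, (tp + tn) / sum(cts))
    prec_t <- tp / (tp + fp); rec_t <- tp / (tp + fn)
    prec_n <- tn / (tn + fn); rec_n <- tn / (tn + fp)
    expect_equal(r$precision, mean(c(prec_t, prec_n)))
    expect_equal(r$recall, mean(c(rec_t, rec_n)))
    f1_t <- 2 * prec_t * rec_t / (prec_t + rec_t)
    f1_n <- 2 * prec_n * rec_n / (prec_n + rec_n)
    expect_equal(r$f1, mean(c(f1_t, f1_n)))
  }
  expect_error(confusion_metrics(y, y[-1]), "invalid")
})

test_that("ROC/AUC equals the pairwise rank statistic", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c("n", "n", "p", "p"), positive = "p")
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c("n", "n", "p", "p"), "p")$auc, 1)
  expect_equal(roc_auc(c(4, 3, 2, 1), c("n", "n", "p", "p"), "p")$auc, 0)
  set.seed(5)
  for (i in 1:10) {
    sc <- round(rnorm(30), 1)                  # ties on purpose
    lb <- sample(c("p", "n"), 30, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb, "p")$auc, o_auc_rank(sc, lb, "p"),
                 tolerance = 1e-12)
  }
  # independent cross-check against pROC
  skip_if_not_installed("pROC")
  set.seed(6)
  sc <- rnorm(50); lb <- rep(c("p", "n"), 25)
  expect_equal(roc_auc(sc, lb, "p")$auc,
               as.numeric(pROC::auc(pROC::roc(lb, sc, levels = c("n", "p"),
                                              direction = "<", quiet = TRUE))),
               tolerance = 1e-12)
  expect_error(roc_auc(1:5, rep("p", 5)), "invalid")
})

test_that("stratified cross-validation partitions and evaluates correctly", {
  set.seed(7)
  n <- 46                                       # odd fold sizes on purpose
  y <- c(rep("tumor", 24), rep("non_tumor", 22))
  x <- cbind(ifelse(y == "tumor", 3, 0) + rnorm(n, 0, 0.3), rnorm(n))
  rep10 <- cross_validate(x, y, classifier_spec("knn"), folds = 10, seed = 2)
  # every sample in exactly one test fold; per-class sizes within 1
  expect_equal(sum(table(rep10$fold_id)), n)
  for (cl in unique(y)) {
    sizes <- table(rep10$fold_id[y == cl])
    expect_lte(diff(range(sizes)), 1)
  }
  expect_equal(rep10$accuracy, 1)               # separable clusters
  expect_equal(sum(rep10$confusion), n)
  # reproducible for a fixed seed
  rep10b <- cross_validate(x, y, classifier_spec("knn"), folds = 10, seed = 2)
  expect_identical(rep10$predictions, rep10b$predictions)
  expect_error(cross_validate(x[1:12, ], y[1:12], folds = 10),
               "invalid")
  # svm path works end to end
  reps <- cross_validate(x, y, classifier_spec("svm"), folds = 5, seed = 3)
  expect_gte(reps$accuracy, 0.9)
  expect_true(reps$auc >= 0 && reps$auc <= 1)
})
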