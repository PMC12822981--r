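make_blobs <- function(n_per_class = 100, sep = 3, seed = 1, p = 2,
                       patients_per_class = 10) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * p), n_per_class, p),
             matrix(rnorm(n_per_class * p, sep), n_per_class, p))
  y <- rep(c("regular", "irregular"), each = n_per_class)
  pid <- paste0(rep(c("R", "I"), each = n_per_class),
                rep(seq_len(patients_per_class),
                    length.out = n_per_class))
  out <- tibble::as_tibble(as.data.frame(X))
  names(out) <- paste0("f", seq_len(p))
  dplyr::bind_cols(
    tibble::tibble(image_id = paste0("img", seq_len(2 * n_per_class)),
                   patient_id = pid, class_label = y, image_type = "raw"),
    out)
}

test_that("confusion metrics reproduce the closed forms", {
  perfect <- confusion_metrics(list(TP = 5, FP = 0, TN = 7, FN = 0))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  sym <- confusion_metrics(list(TP = 1, FP = 1, TN = 1, FN = 1))
  expect_equal(unlist(sym[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 0.5, precision = 0.5, recall = 0.5, f1 = 0.5))
  m <- confusion_metrics(list(TP = 3, FP = 1, TN = 4, FN = 2))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$fpr, 0.2)
  expect_error(confusion_metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)),
               "empty")
})

test_that("confusion metrics match the formulas on exhaustive small tables", {
  for (total in 1:12) {
    parts <- expand.grid(TP = 0:total, FP = 0:total, TN = 0:total)
    parts$FN <- total - parts$TP - parts$FP - parts$TN
    parts <- parts[parts$FN >= 0, ]
    for (r in seq_len(nrow(parts))) {
      cc <- as.list(parts[r, ])
      m <- suppressWarnings(confusion_metrics(cc))
      expect_equal(m$accuracy, (cc$TP + cc$TN) / total)
      if (cc$TP + cc$FP > 0) {
        expect_equal(m$precision, cc$TP / (cc$TP + cc$FP))
      }
      if (cc$TP + cc$FN > 0) {
        expect_equal(m$recall, cc$TP / (cc$TP + cc$FN))
      }
      if (cc$FP + cc$TN > 0) {
        expect_equal(m$fpr, cc$FP / (cc$FP + cc$TN))
      }
    }
  }
})

test_that("zero-denominator metrics return 0 and are flagged", {
  m <- confusion_metrics(list(TP = 0, FP = 0, TN = 5, FN = 2))
  expect_equal(m$precision, 0)
  expect_true("precision" %in% attr(m, "zero_denominator"))
})

test_that("AUC: separable, tied and textbook cases", {
  expect_equal(roc_auc(c("a", "a", "b", "b"), c(1, 2, 3, 4), positive = "b"), 1)
  expect_equal(roc_auc(c("a", "a", "b", "b"), rep(1, 4), positive = "b"), 0.5)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8), positive = 1),
               0.75)
  expect_error(roc_auc(c("a", "a"), c(1, 2), positive = "b"), "both classes")
})

test_that("pair-counting AUC equals trapezoidal integration on seeded scores", {
  set.seed(44)
  for (k in 1:100) {
    n <- sample(6:30, 1)
    labels <- sample(c("neg", "pos"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("neg", "pos")
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    expect_equal(roc_auc(labels, scores, positive = "pos"),
                 oracle_auc_trapezoid(labels, scores, "pos"),
                 tolerance = 1e-12)
  }
})

test_that("pair-counting AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  labels <- sample(c("neg", "pos"), 40, replace = TRUE)
  scores <- rnorm(40)
  expect_equal(roc_auc(labels, scores, positive = "pos"),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              levels = c("neg", "pos"),
                                              direction = "<", quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("all three classifiers separate well-separated blobs", {
  blobs <- make_blobs(100, sep = 8, seed = 5)
  idx <- rep(c(TRUE, FALSE), length.out = nrow(blobs))
  train <- blobs[idx, ]; test <- blobs[!idx, ]
  for (kind in c("knn", "svm", "lr")) {
    pr <- fit_predict(classifier_spec(kind), train, test)
    acc <- mean(pr$labels == test$class_label)
    expect_equal(acc, 1.0)
  }
  # LR scores land on the correct side of 0.5 on a separable toy
  pr <- fit_predict(classifier_spec("lr"), train, test)
  expect_true(all((pr$scores > 0.5) == (test$class_label == "irregular")))
})

test_that("classifier specs carry their fixed hyperparameters", {
  expect_equal(classifier_spec("knn")$k, 7)
  svm <- classifier_spec("svm")
  expect_equal(svm$cost, 100)
  expect_equal(svm$gamma, 1e-4)
  expect_equal(svm$tolerance, 1e-3)
  lr <- classifier_spec("lr")
  expect_equal(lr$C, 1.0)
  expect_equal(lr$tol, 1e-4)
  expect_error(classifier_spec("knn", cost = 2), "unknown")
})

test_that("grouped folds never split a patient and balance classes", {
  blobs <- make_blobs(50, sep = 1, seed = 2, patients_per_class = 10)
  rep <- grouped_stratified_cv(blobs, classifier_spec("knn"), k = 5,
                               seed = 11)
  expect_equal(rep$k, 5)
  audit <- dplyr::distinct(rep$folds, .data$patient_id, .data$fold)
  expect_equal(nrow(audit), dplyr::n_distinct(audit$patient_id))
  # per class, fold patient counts differ by at most 1
  pat <- dplyr::distinct(
    dplyr::left_join(rep$folds,
                     dplyr::distinct(blobs, .data$patient_id,
                                     .data$class_label),
                     by = "patient_id"),
    .data$patient_id, .data$fold, .data$class_label)
  counts <- table(pat$class_label, pat$fold)
  expect_lte(max(apply(counts, 1, function(r) diff(range(r)))), 1)
})

test_that("fold count shrinks with a warning and errors when impossible", {
  blobs <- make_blobs(12, sep = 1, seed = 3, patients_per_class = 3)
  expect_warning(rep <- grouped_stratified_cv(blobs, classifier_spec("knn"),
                                              k = 5, select_k = 2),
                 "folds")
  expect_equal(rep$k, 3)
  one_pat <- make_blobs(8, sep = 1, seed = 3, patients_per_class = 1)
  expect_error(suppressWarnings(
    grouped_stratified_cv(one_pat, classifier_spec("knn"), k = 5)),
    "fewer distinct groups")
})

test_that("duplicated images do not inflate grouped CV, but leak through image-level splits", {
  fe <- null_features()
  dup <- dplyr::bind_rows(
    fe,
    dplyr::mutate(fe, image_id = paste0(image_id, "_copy1")),
    dplyr::mutate(fe, image_id = paste0(image_id, "_copy2")))
  # nearest-neighbour classifier makes memorization visible: an exact
  # duplicate in the training fold decides the prediction outright
  nn <- classifier_spec("knn", k = 1)
  base <- grouped_stratified_cv(fe, nn, k = 5, seed = 4, select_k = 10)
  grouped <- grouped_stratified_cv(dup, nn, k = 5, seed = 4, select_k = 10)
  naive <- grouped_stratified_cv(dup, nn, k = 5, seed = 4,
                                 select_k = 10, grouping = "image")
  acc <- function(r) r$summary$mean[r$summary$metric == "accuracy"]
  sd_acc <- function(r) r$summary$sd[r$summary$metric == "accuracy"]
  # grouped splitting keeps every copy with its patient: accuracy moves by
  # no more than the fold-to-fold SD
  expect_lte(acc(grouped), acc(base) + sd_acc(base))
  # image-level splitting trains on duplicates of the test images and
  # memorizes them
  expect_gt(acc(naive), acc(grouped) + sd_acc(grouped))
  expect_gt(acc(naive), 0.8)
})

test_that("cross-validated accuracy grows with the class-separation dial", {
  accs <- vapply(c("null", "weak", "strong"), function(pr) {
    co <- generate_cohort(small_cfg(pr, n_reg = 5, n_irr = 5, ipp = 2,
                                    seed = 9))
    fe <- suppressWarnings(extract_features(co, "entropy"))
    rep <- grouped_stratified_cv(fe, classifier_spec("knn"), k = 5, seed = 9,
                                 select_k = 10)
    rep$summary$mean[rep$summary$metric == "accuracy"]
  }, numeric(1))
  expect_lt(accs["null"], accs["weak"])
  expect_lte(accs["weak"], accs["strong"])
  expect_gt(accs["strong"], 0.9)
})

test_that("tidy and glance summarize cross-validation reports", {
  blobs <- make_blobs(30, sep = 3, seed = 6, patients_per_class = 5)
  rep <- grouped_stratified_cv(blobs, classifier_spec("lr"), k = 5,
                               select_k = 2)
  td <- tidy(rep)
  expect_setequal(unique(td$fold), 1:5)
  gl <- glance(rep)
  expect_equal(gl$classifier, "lr")
  expect_equal(gl$accuracy_mean,
               mean(td$value[td$metric == "accuracy"]))
  expect_equal(gl$accuracy_sd, sd(td$value[td$metric == "accuracy"]))
})

test_that("paper mode fits selection before splitting and still reports 5 folds", {
  fe <- strong_features()
  rep <- grouped_stratified_cv(fe, classifier_spec("lr"), k = 5,
                               mode = "paper")
  expect_equal(rep$mode, "paper")
  expect_equal(nrow(rep$metrics), 5)
})

test_that("the experiment grid covers the full factorial with flagged maxima", {
  co <- generate_cohort(small_cfg("strong", n_reg = 3, n_irr = 3, ipp = 2,
                                  size = 24, seed = 13))
  ex <- suppressWarnings(run_experiment(co, k = 3, select_k = 10))
  cells <- dplyr::distinct(ex$grid, .data$image_type, .data$feature_set,
                           .data$classifier)
  expect_equal(nrow(cells), 27)
  expect_setequal(
    unique(ex$grid$metric),
    c("accuracy", "precision", "recall", "f1", "specificity", "fpr", "auc"))
  # every (feature set, classifier, metric) has at least one flagged max
  flags <- dplyr::summarise(
    dplyr::group_by(ex$grid, .data$feature_set, .data$classifier,
                    .data$metric),
    ok = any(.data$is_max), .groups = "drop")
  expect_true(all(flags$ok))
  # mean +/- SD equals independent recomputation from the stored folds
  rep <- ex$reports[["raw.entropy.knn"]]
  expect_equal(
    ex$grid$mean[ex$grid$image_type == "raw" &
                 ex$grid$feature_set == "entropy" &
                 ex$grid$classifier == "knn" &
                 ex$grid$metric == "accuracy"],
    mean(rep$metrics$accuracy))
  expect_equal(
    ex$grid$sd[ex$grid$image_type == "raw" &
               ex$grid$feature_set == "entropy" &
               ex$grid$classifier == "knn" &
               ex$grid$metric == "accuracy"],
    sd(rep$metrics$accuracy))
})
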