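# Fixed-hyperparameter classifiers, confusion-matrix metrics, ROC AUC, and
# patient-grouped stratified cross-validation.

#' Classifier specification
#'
#' The three classifiers of the pipeline with their fixed hyperparameters:
#' * `"knn"` — k-nearest neighbours, k = 7, Euclidean distance, uniform
#'   weights; AUC scores are the fraction of the 7 neighbours voting for
#'   the positive class.
#' * `"svm"` — support vector machine, cost C = 100, radial-basis kernel
#'   with gamma = 1e-4, numerical tolerance 1e-3; scores are the decision
#'   function oriented toward the positive class.
#' * `"lr"` — L2-penalized logistic regression (inverse regularization
#'   strength C = 1, intercept unpenalized) fitted by BFGS; scores are
#'   positive-class probabilities.
#'
#' @param model `"knn"`, `"svm"` or `"lr"`.
#' @param ... Named overrides of the default hyperparameters.
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(model = c("knn", "svm", "lr"), ...) {
  kind <- match.arg(model)
  defaults <- switch(kind,
    knn = list(k = 7),
    svm = list(cost = 100, gamma = 1e-4, tolerance = 1e-3),
    lr = list(tol = 1e-4, C = 1.0))
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad) > 0) {
    stop("unknown hyperparameter(s) for ", kind, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  defaults[names(over)] <- over
  structure(c(list(kind = kind), defaults), class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- x[setdiff(names(x), "kind")]
  cat(sprintf("<classifier_spec> %s (%s)\n", x$kind,
              paste(names(hp), unlist(hp), sep = " = ", collapse = ", ")))
  invisible(x)
}

# L2-penalized logistic regression: sum of logistic losses plus
# ||w||^2 / (2C) on the slopes (intercept unpenalized), minimized by BFGS.
fit_logistic_l2 <- function(X, y01, C = 1.0) {
  X1 <- cbind(1, X)
  t_ <- ifelse(y01 == 1, 1, -1)
  p <- ncol(X1)
  pen_mask <- c(0, rep(1, p - 1))
  fn <- function(beta) {
    eta <- drop(X1 %*% beta)
    sum(log1p(exp(-t_ * eta))) + sum(pen_mask * beta^2) / (2 * C)
  }
  gr <- function(beta) {
    eta <- drop(X1 %*% beta)
    d <- -t_ * plogis(-t_ * eta)
    drop(crossprod(X1, d)) + pen_mask * beta / C
  }
  fit <- optim(rep(0, p), fn, gr, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  fit$par
}

#' Fit a classifier and predict a test set
#'
#' @param spec A [classifier_spec()].
#' @param train Feature tibble with `class_label` (training data; assumed
#'   standardized).
#' @param test Feature tibble with the same feature columns.
#' @param positive Label of the positive class (default `"irregular"`, the
#'   high-entropy squamous-like class).
#' @return A list with `labels` (predicted class per test row) and `scores`
#'   (continuous positive-class score: vote fraction, decision value or
#'   probability).
#' @export
fit_predict <- function(spec, train, test, positive = "irregular") {
  stopifnot(inherits(spec, "classifier_spec"))
  fn <- feature_names(train)
  ytr <- factor(train$class_label)
  if (nlevels(ytr) < 2) stop("training data must contain both classes",
                             call. = FALSE)
  Xtr <- as.matrix(train[fn])
  Xte <- as.matrix(test[fn])
  neg <- setdiff(levels(ytr), positive)
  if (spec$kind == "knn") {
    pred <- class::knn(Xtr, Xte, ytr, k = spec$k, prob = TRUE)
    win <- attr(pred, "prob")
    scores <- ifelse(pred == positive, win, 1 - win)
    labels <- as.character(pred)
  } else if (spec$kind == "svm") {
    fit <- e1071::svm(Xtr, ytr, type = "C-classification", kernel = "radial",
                      cost = spec$cost, gamma = spec$gamma,
                      tolerance = spec$tolerance, scale = FALSE)
    pr <- predict(fit, Xte, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # libsvm orients the decision value toward the first class in the
    # column name "first/second"
    first <- strsplit(colnames(dv)[1], "/")[[1]][1]
    scores <- if (first == positive) dv[, 1] else -dv[, 1]
    labels <- as.character(pr)
  } else {
    beta <- fit_logistic_l2(Xtr, as.integer(ytr == positive), C = spec$C)
    scores <- plogis(drop(cbind(1, Xte) %*% beta))
    labels <- ifelse(scores > 0.5, positive, neg)
  }
  list(labels = unname(labels), scores = unname(as.numeric(scores)))
}

#' Confusion counts for a binary prediction
#'
#' @param truth,pred Vectors of class labels.
#' @param positive Label of the positive class.
#' @return Named list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, pred, positive = "irregular") {
  stopifnot(length(truth) == length(pred))
  list(TP = sum(pred == positive & truth == positive),
       FP = sum(pred == positive & truth != positive),
       TN = sum(pred != positive & truth != positive),
       FN = sum(pred != positive & truth == positive))
}

#' Metrics from confusion counts
#'
#' Accuracy = (TP+TN)/total, precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = harmonic mean of precision and recall, plus specificity =
#' TN/(TN+FP) and the false positive rate FPR = FP/(FP+TN). Metrics with a
#' zero denominator return 0 and are flagged (attribute
#' `zero_denominator`), never raising mid-experiment.
#'
#' @param counts A list with `TP`, `FP`, `TN`, `FN`.
#' @return One-row tibble of metrics in \[0, 1\].
#' @export
confusion_metrics <- function(counts) {
  with(counts, {
    total <- TP + FP + TN + FN
    if (total == 0) stop("empty confusion counts", call. = FALSE)
    safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
    precision <- safe_div(TP, TP + FP)
    recall <- safe_div(TP, TP + FN)
    f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
      NA_real_
    } else 2 * precision * recall / (precision + recall)
    out <- tibble::tibble(
      accuracy = (TP + TN) / total,
      precision = precision,
      recall = recall,
      f1 = f1,
      specificity = safe_div(TN, TN + FP),
      fpr = safe_div(FP, FP + TN))
    flagged <- names(out)[vapply(out, is.na, logical(1))]
    out[is.na(out)] <- 0
    attr(out, "zero_denominator") <- flagged
    out
  })
}

#' Area under the ROC curve
#'
#' Pair-counting (Mann-Whitney) AUC: the fraction of positive-negative
#' pairs ranked correctly by the score, ties counted half. Equivalent to
#' trapezoidal integration of the ROC curve over all thresholds.
#'
#' @param labels Vector of class labels (both classes present).
#' @param scores Numeric scores, larger = more positive.
#' @param positive Label of the positive class.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores, positive = "irregular") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Assign each patient (or image) to a fold: per class, shuffle by seed and
# deal round-robin, so fold patient counts per class differ by at most 1.
make_grouped_folds <- function(features, k, seed,
                               grouping = c("patient", "image")) {
  grouping <- match.arg(grouping)
  unit_col <- if (grouping == "patient") "patient_id" else "image_id"
  units <- dplyr::distinct(features, unit = .data[[unit_col]],
                           class = .data$class_label)
  counts <- table(units$class)
  if (min(counts) < 2) {
    stop("fewer distinct groups than folds: need at least 2 per class",
         call. = FALSE)
  }
  k_eff <- min(k, min(counts))
  if (k_eff < k) {
    warning(sprintf("only %d groups in the smallest class: using %d folds",
                    min(counts), k_eff), call. = FALSE)
  }
  set.seed(seed)
  units <- units[sample.int(nrow(units)), ]
  units <- dplyr::group_by(units, .data$class)
  units <- dplyr::mutate(units, fold = (dplyr::row_number() - 1L) %% k_eff + 1L)
  units <- dplyr::ungroup(units)
  fold_of <- stats::setNames(units$fold, units$unit)
  list(fold = unname(fold_of[features[[unit_col]]]), k = k_eff)
}

#' Patient-grouped stratified cross-validation
#'
#' Splits patients (never single images) into `k` folds with class
#' proportions balanced at the patient level, then evaluates the classifier
#' fold by fold. In the default leakage-safe mode, standardization and
#' feature selection are refitted inside each training fold; in
#' `"paper"` mode both are fitted once on the full table before splitting
#' (the order of operations as a pre-registered protocol would read).
#'
#' @param features A feature tibble (one image type).
#' @param spec A [classifier_spec()].
#' @param k Number of folds (default 5); reduced with a warning when the
#'   smallest class has fewer patients.
#' @param seed Seed for the fold shuffle.
#' @param mode `"safe"` (default) or `"paper"`.
#' @param select_k,n_trees,rf_seed Passed to [select_top_k()].
#' @param positive Positive class label.
#' @param grouping `"patient"` (default) or `"image"` (a naive image-level
#'   split, retained to demonstrate patient leakage).
#' @return A `cv_report` with per-fold metrics, mean +/- SD aggregation and
#'   the fold assignment.
#' @export
grouped_stratified_cv <- function(features, spec, k = 5, seed = 42,
                                  mode = c("safe", "paper"),
                                  select_k = 25, n_trees = 100, rf_seed = 42,
                                  positive = "irregular",
                                  grouping = c("patient", "image")) {
  mode <- match.arg(mode)
  grouping <- match.arg(grouping)
  stopifnot(inherits(spec, "classifier_spec"))
  fd <- make_grouped_folds(features, k, seed, grouping)
  fold <- fd$fold; k_eff <- fd$k
  meta <- c("image_id", "patient_id", "class_label", "image_type")
  if (mode == "paper") {
    std <- standardize_fit(features)
    z <- standardize_apply(std, features)
    sel <- select_top_k(z, k = select_k, n_trees = n_trees, seed = rf_seed)
    features <- dplyr::select(z, dplyr::all_of(c(meta, sel$selected)))
  }
  per_fold <- purrr::map(seq_len(k_eff), function(f) {
    train <- features[fold != f, ]
    test <- features[fold == f, ]
    if (mode == "safe") {
      std <- standardize_fit(train)
      train <- standardize_apply(std, train)
      test <- standardize_apply(std, test)
      sel <- select_top_k(train, k = select_k, n_trees = n_trees,
                          seed = rf_seed)
      keep <- c(meta, sel$selected)
      train <- dplyr::select(train, dplyr::all_of(keep))
      test <- dplyr::select(test, dplyr::all_of(keep))
    }
    pr <- fit_predict(spec, train, test, positive)
    met <- confusion_metrics(confusion_counts(test$class_label, pr$labels,
                                              positive))
    met$auc <- roc_auc(test$class_label, pr$scores, positive)
    met$fold <- f
    met
  })
  metrics <- dplyr::bind_rows(per_fold)
  metrics <- dplyr::select(metrics, "fold", dplyr::everything())
  long <- tidyr::pivot_longer(metrics, -"fold", names_to = "metric")
  summary <- dplyr::summarise(
    dplyr::group_by(long, .data$metric),
    mean = mean(.data$value), sd = sd(.data$value), .groups = "drop")
  structure(list(metrics = metrics, summary = summary,
                 folds = tibble::tibble(image_id = features$image_id,
                                        patient_id = features$patient_id,
                                        fold = fold),
                 spec = spec, mode = mode, seed = seed, k = k_eff,
                 positive = positive),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, %d folds (%s mode, seed %d)\n",
              x$spec$kind, x$k, x$mode, x$seed))
  main <- dplyr::filter(x$summary,
                        .data$metric %in% c("accuracy", "precision", "recall",
                                            "f1", "auc"))
  for (i in seq_len(nrow(main))) {
    cat(sprintf("  %-9s %.3f +/- %.3f\n", main$metric[i], main$mean[i],
                main$sd[i]))
  }
  invisible(x)
}

#' Tidy a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return A long tibble: `fold`, `metric`, `value`.
#' @export
tidy.cv_report <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, -"fold", names_to = "metric")
}

#' One-row summary of a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return A one-row tibble: classifier, mode, folds, then
#'   `<metric>_mean` / `<metric>_sd` columns.
#' @export
glance.cv_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"),
                             names_glue = "{metric}_{.value}")
  dplyr::bind_cols(tibble::tibble(classifier = x$spec$kind, mode = x$mode,
                                  folds = x$k), wide)
}

#' Run the full factorial classification experiment
#'
#' Evaluates every combination of image type (raw, normalize, median),
#' feature set (statistical, entropy, combined) and classifier (kNN, SVM,
#' LR) with patient-grouped stratified cross-validation — a 27-cell grid
#' with five reported metrics per cell (accuracy, precision, recall, F1,
#' AUC), each as mean +/- SD over folds. Per feature set and classifier,
#' the best image type per metric is flagged (`is_max`), mirroring the
#' bold-max convention of results tables.
#'
#' @param cohort A raw cohort tibble from [generate_cohort()] or
#'   [load_cohort()].
#' @param image_types,feature_sets,classifiers Subsets of the factorial.
#' @param k,seed,mode,select_k,n_trees,rf_seed,positive Passed to
#'   [grouped_stratified_cv()].
#' @param L,params Passed to [extract_features()].
#' @param median_radius Passed to [filter_cohort()].
#' @return An `experiment_result`: `grid` (long tibble of cell x metric
#'   with `mean`, `sd`, `is_max`) and `reports` (named list of
#'   `cv_report`s).
#' @export
run_experiment <- function(cohort,
                           image_types = c("raw", "normalize", "median"),
                           feature_sets = c("statistical", "entropy",
                                            "combined"),
                           classifiers = c("knn", "svm", "lr"),
                           k = 5, seed = 42, mode = "safe",
                           select_k = 25, n_trees = 100, rf_seed = 42,
                           positive = "irregular", L = 32,
                           params = entropy_params(), median_radius = 1) {
  filtered <- filter_cohort(cohort, image_types, median_radius)
  ent_cols <- NULL
  reports <- list()
  rows <- list()
  for (tp in image_types) {
    sub <- dplyr::filter(filtered, .data$image_type == tp)
    all_feats <- extract_features(sub, "combined", L = L, params = params)
    fn <- feature_names(all_feats)
    ent_cols <- fn[grepl("^(SampEn2D|FuzzEn2D|PermEn2D|DispEn2D|DistEn2D)_s",
                         fn)]
    meta <- c("image_id", "patient_id", "class_label", "image_type")
    for (fs in feature_sets) {
      feats <- switch(fs,
        combined = all_feats,
        entropy = dplyr::select(all_feats, dplyr::all_of(c(meta, ent_cols))),
        statistical = dplyr::select(all_feats,
                                    -dplyr::all_of(ent_cols)))
      for (cl in classifiers) {
        rep <- grouped_stratified_cv(feats, classifier_spec(cl), k = k,
                                     seed = seed, mode = mode,
                                     select_k = select_k, n_trees = n_trees,
                                     rf_seed = rf_seed, positive = positive)
        reports[[paste(tp, fs, cl, sep = ".")]] <- rep
        cell <- dplyr::mutate(rep$summary, image_type = tp, feature_set = fs,
                              classifier = cl)
        rows[[length(rows) + 1L]] <- cell
      }
    }
  }
  grid <- dplyr::bind_rows(rows)
  grid <- dplyr::select(grid, "image_type", "feature_set", "classifier",
                        "metric", "mean", "sd")
  grid <- dplyr::mutate(
    dplyr::group_by(grid, .data$feature_set, .data$classifier, .data$metric),
    is_max = .data$mean == max(.data$mean))
  grid <- dplyr::ungroup(grid)
  structure(list(grid = grid, reports = reports),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cells <- dplyr::n_distinct(paste(x$grid$image_type, x$grid$feature_set,
                                   x$grid$classifier))
  cat(sprintf("<experiment_result> %d cells x %d metrics\n", cells,
              dplyr::n_distinct(x$grid$metric)))
  acc <- dplyr::filter(x$grid, .data$metric == "accuracy")
  acc <- dplyr::arrange(acc, dplyr::desc(.data$mean))
  cat("  best accuracy:\n")
  for (i in seq_len(min(3, nrow(acc)))) {
    cat(sprintf("    %s / %s / %s: %.3f +/- %.3f\n", acc$image_type[i],
                acc$feature_set[i], acc$classifier[i], acc$mean[i],
                acc$sd[i]))
  }
  invisible(x)
}
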