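# Standardization and select-from-model feature selection (random-forest
# importances, top-k retained).

#' Fit a feature standardizer
#'
#' Learns per-feature location (mean) and scale (sample SD) from a fitting
#' table. Constant features get unit scale and are flagged; applying the
#' standardizer maps them to zero.
#'
#' @param features A feature tibble (metadata columns are ignored).
#' @return A `standardizer` object.
#' @export
standardize_fit <- function(features) {
  fn <- feature_names(features)
  if (nrow(features) == 0 || length(fn) == 0) {
    stop("fitting table is empty", call. = FALSE)
  }
  center <- vapply(features[fn], mean, numeric(1))
  scale <- vapply(features[fn], sd, numeric(1))
  constant <- !is.finite(scale) | scale == 0
  scale[constant] <- 1
  structure(list(feature = fn, center = center, scale = scale,
                 constant = constant),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' Centers and scales every feature column with the statistics stored at
#' fit time; the table must carry exactly the fitted feature columns.
#'
#' @param std A `standardizer` from [standardize_fit()].
#' @param features A feature tibble with matching feature columns.
#' @return The table with standardized feature columns.
#' @export
standardize_apply <- function(std, features) {
  stopifnot(inherits(std, "standardizer"))
  fn <- feature_names(features)
  if (!setequal(fn, std$feature)) {
    stop("feature columns do not match the fitted standardizer",
         call. = FALSE)
  }
  for (f in std$feature) {
    features[[f]] <- (features[[f]] - std$center[[f]]) / std$scale[[f]]
  }
  features
}

#' Select the top-k features by random-forest importance
#'
#' Fits a seeded random forest (default 100 trees, seed 42) to the feature
#' table and retains the `k` features (default 25) with the highest mean
#' decrease in Gini impurity. Importances are normalized to sum to 1. Ties
#' at the k-th rank are broken by column order after a seeded shuffle that
#' is recorded in the result.
#'
#' @param features A feature tibble with a two-class `class_label` column
#'   and no non-finite feature values.
#' @param k Number of features to retain.
#' @param n_trees Number of trees.
#' @param seed Integer seed for the shuffle and the forest.
#' @param importance `"gini"` (mean impurity decrease, default) or
#'   `"permutation"` (mean decrease in accuracy).
#' @return A `selection_result` with `selected` (descending importance),
#'   `importances`, `k`, `n_trees`, `seed`.
#' @export
select_top_k <- function(features, k = 25, n_trees = 100, seed = 42,
                         importance = c("gini", "permutation")) {
  importance <- match.arg(importance)
  fn <- feature_names(features)
  y <- factor(features$class_label)
  if (nlevels(y) < 2) stop("class_label must contain two classes",
                           call. = FALSE)
  X <- as.data.frame(features[fn])
  if (any(!vapply(X, function(col) all(is.finite(col)), logical(1)))) {
    stop("feature table contains non-finite values", call. = FALSE)
  }
  set.seed(seed)
  tie_shuffle <- sample.int(length(fn))
  rf <- randomForest::randomForest(
    x = X, y = y, ntree = n_trees,
    importance = importance == "permutation")
  imp <- if (importance == "gini") {
    randomForest::importance(rf, type = 2)[, 1]
  } else {
    randomForest::importance(rf, type = 1)[, 1]
  }
  imp <- pmax(imp, 0)
  total <- sum(imp)
  if (total > 0) imp <- imp / total
  names(imp) <- fn
  ord <- order(-imp, tie_shuffle)
  k_eff <- min(k, length(fn))
  structure(list(selected = fn[ord][seq_len(k_eff)],
                 importances = imp, k = k_eff, n_trees = n_trees,
                 seed = seed, tie_shuffle = tie_shuffle,
                 importance_type = importance),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d of %d features (forest: %d trees, seed %d)\n",
              x$k, length(x$importances), x$n_trees, x$seed))
  top <- utils::head(x$selected, 5)
  cat("  top:", paste(top, collapse = ", "),
      if (x$k > 5) "..." else "", "\n")
  invisible(x)
}

#' Tidy a selection result
#'
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return A tibble with `feature`, `group`, `importance`, `rank`,
#'   `selected`, sorted by descending importance.
#' @export
tidy.selection_result <- function(x, ...) {
  ord <- order(-x$importances, x$tie_shuffle)
  fn <- names(x$importances)[ord]
  tibble::tibble(feature = fn,
                 group = feature_group(fn),
                 importance = unname(x$importances[ord]),
                 rank = seq_along(fn),
                 selected = fn %in% x$selected)
}
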