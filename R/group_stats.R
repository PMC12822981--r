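# Two-group comparison machinery: Shapiro-Wilk routing between Student's
# t-test and the Mann-Whitney U test, figure-style significance stars, and
# coefficients of variation.

star_thresholds <- c(0.0001, 0.001, 0.01, 0.05)
star_symbols <- c("++", "+", "**", "*")

star_code <- function(p) {
  vapply(p, function(pp) {
    hit <- which(pp < star_thresholds)
    if (length(hit) == 0) "" else star_symbols[hit[1]]
  }, character(1))
}

# Shapiro-Wilk p-value with a guard for (near-)degenerate samples, which
# the test itself rejects; a sample with almost no distinct values is
# treated as decisively non-normal.
shapiro_p <- function(x) {
  if (length(unique(x)) < 3 || sd(x) == 0) return(0)
  shapiro.test(x)$p.value
}

#' Route a two-group comparison by normality
#'
#' Applies the Shapiro-Wilk test to each sample separately; the comparison
#' is parametric (t-test) only if both samples pass at p > 0.05, otherwise
#' nonparametric (Mann-Whitney U).
#'
#' @param a,b Numeric samples with at least 3 values each.
#' @param alpha Normality level (default 0.05).
#' @return `"parametric"` or `"nonparametric"`.
#' @export
normality_route <- function(a, b, alpha = 0.05) {
  if (length(a) < 3 || length(b) < 3) {
    stop("each sample needs at least 3 values", call. = FALSE)
  }
  if (shapiro_p(a) > alpha && shapiro_p(b) > alpha) "parametric"
  else "nonparametric"
}

#' Compare two groups on one feature
#'
#' Two-sided Student's t-test (pooled variance) or Mann-Whitney U test,
#' chosen by [normality_route()]; significance is star-coded as in the
#' figure convention: `*` p < 0.05, `**` p < 0.01, `+` p < 0.001,
#' `++` p < 0.0001 (strict upper bounds, smallest threshold first).
#'
#' @param a,b Numeric samples (>= 3 values each).
#' @param alpha Significance level.
#' @param route Force `"parametric"` or `"nonparametric"`; `NULL` (default)
#'   routes by normality.
#' @param welch Use Welch's unequal-variance t-test in the parametric
#'   branch instead of the pooled-variance test.
#' @return One-row tibble: `test_name`, `statistic`, `p_value`,
#'   `significant`, `star_code`.
#' @export
compare_groups <- function(a, b, alpha = 0.05, route = NULL, welch = FALSE) {
  if (length(a) < 3 || length(b) < 3) {
    stop("each sample needs at least 3 values", call. = FALSE)
  }
  route <- route %||% normality_route(a, b)
  if (sd(c(a, b)) == 0) {
    # all observations identical: no evidence of any difference
    return(tibble::tibble(test_name = "Mann-Whitney U", statistic = NA_real_,
                          p_value = 1, significant = FALSE, star_code = ""))
  }
  if (route == "parametric") {
    tt <- t.test(a, b, var.equal = !welch)
    res <- tibble::tibble(test_name = "t-test",
                          statistic = unname(tt$statistic),
                          p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, exact = NULL))
    res <- tibble::tibble(test_name = "Mann-Whitney U",
                          statistic = unname(wt$statistic),
                          p_value = wt$p.value)
  }
  dplyr::mutate(res, significant = .data$p_value < alpha,
                star_code = star_code(.data$p_value))
}

#' Coefficient of variation
#'
#' Sample SD (n-1 denominator) divided by the mean; undefined for zero-mean
#' samples.
#'
#' @param x Numeric sample.
#' @return Scalar CV.
#' @export
coefficient_of_variation <- function(x) {
  if (mean(x) == 0) stop("coefficient of variation undefined for zero mean",
                         call. = FALSE)
  sd(x) / mean(x)
}

#' Per-feature two-group significance table
#'
#' Runs [compare_groups()] on every feature column of a feature table,
#' comparing the two class labels, and reports per-class coefficients of
#' variation. Multiple-testing correction is off by default, with a
#' Benjamini-Hochberg option.
#'
#' @param features A feature tibble from [extract_features()] (single image
#'   type; exactly two classes with >= 3 images each).
#' @param alpha Significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param welch Passed to [compare_groups()].
#' @return A tibble with one row per feature: `feature`, `group`,
#'   `image_type`, `test_name`, `statistic`, `p_value`, `significant`,
#'   `star_code`, `cv_<class>` columns.
#' @export
significance_table <- function(features, alpha = 0.05,
                               adjust = c("none", "BH"), welch = FALSE) {
  adjust <- match.arg(adjust)
  labs <- unique(features$class_label)
  if (length(labs) != 2) stop("exactly two classes required", call. = FALSE)
  counts <- table(features$class_label)
  if (any(counts < 3)) stop("each class needs at least 3 images", call. = FALSE)
  fn <- feature_names(features)
  rows <- purrr::map(fn, function(f) {
    a <- features[[f]][features$class_label == labs[1]]
    b <- features[[f]][features$class_label == labs[2]]
    res <- compare_groups(a, b, alpha, welch = welch)
    res$feature <- f
    res$cv_a <- if (mean(a) != 0) coefficient_of_variation(a) else NA_real_
    res$cv_b <- if (mean(b) != 0) coefficient_of_variation(b) else NA_real_
    res
  })
  out <- dplyr::bind_rows(rows)
  names(out)[names(out) == "cv_a"] <- paste0("cv_", labs[1])
  names(out)[names(out) == "cv_b"] <- paste0("cv_", labs[2])
  if (adjust == "BH") {
    out$p_value <- stats::p.adjust(out$p_value, "BH")
    out$significant <- out$p_value < alpha
    out$star_code <- star_code(out$p_value)
  }
  out$group <- feature_group(out$feature)
  out$image_type <- features$image_type[1]
  dplyr::select(out, "feature", "group", "image_type", "test_name",
                "statistic", "p_value", "significant", "star_code",
                dplyr::starts_with("cv_"))
}
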