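#' Parameters of the 2D multiscale entropy measures
#'
#' Houses the template size `m` (windows are `m` x `m`), the tolerance
#' factor (tolerance `r = r_factor *` SD of the scale-1 image), the fuzzy
#' membership exponent, the dispersion class count `c`, the histogram bin
#' count for distribution entropy and the scale list. The defaults (m = 2,
#' r_factor = 0.2, fuzzy_n = 2, c = 4, bins_B = 64, scales 1..5) are the
#' standard choices of the 2D entropy literature; all are recorded alongside
#' extracted features.
#'
#' @param m Template side length (>= 1).
#' @param r_factor Tolerance multiplier (> 0).
#' @param fuzzy_n Fuzzy membership exponent (> 0).
#' @param c Number of dispersion classes (>= 2).
#' @param bins_B Histogram bins for distribution entropy (>= 2).
#' @param scales Strictly increasing positive integer scale factors.
#' @return An `entropy_params` list.
#' @export
entropy_params <- function(m = 2, r_factor = 0.2, fuzzy_n = 2, c = 4,
                           bins_B = 64, scales = 1:5) {
  stopifnot(m >= 1, r_factor > 0, fuzzy_n > 0, c >= 2, bins_B >= 2,
            length(scales) >= 1, all(scales >= 1),
            all(diff(scales) > 0))
  structure(list(m = as.integer(m), r_factor = r_factor, fuzzy_n = fuzzy_n,
                 c = as.integer(c), bins_B = as.integer(bins_B),
                 scales = as.integer(scales)),
            class = "entropy_params")
}

entropy_methods <- c("SampEn2D", "FuzzEn2D", "PermEn2D", "DispEn2D",
                     "DistEn2D")

#' Coarse-grain an image by a scale factor
#'
#' Replaces each non-overlapping `s` x `s` block by its mean and
#' down-samples; trailing rows/columns that do not fill a block are dropped.
#'
#' @param image Numeric matrix.
#' @param s Integer scale factor (>= 1); `s = 1` returns the input.
#' @return A `floor(H/s)` x `floor(W/s)` numeric matrix.
#' @export
coarse_grain <- function(image, s) {
  check_image(image)
  s <- as.integer(s)
  if (s < 1) stop("scale factor s must be >= 1", call. = FALSE)
  if (s == 1) return(image)
  H <- nrow(image) %/% s
  W <- ncol(image) %/% s
  if (H < 1 || W < 1) {
    stop(sprintf("image too small for scale %d", s), call. = FALSE)
  }
  x <- image[seq_len(H * s), seq_len(W * s), drop = FALSE]
  # block means via two grouped row sums
  y <- rowsum(x, rep(seq_len(H), each = s)) / s
  out <- t(rowsum(t(y), rep(seq_len(W), each = s))) / s
  dimnames(out) <- NULL
  out
}

#' Two-dimensional sample entropy
#'
#' Counts ordered pairs of distinct `m` x `m` windows (taken at positions
#' where an `(m+1)` x `(m+1)` window also fits) whose Chebyshev distance is
#' at most `r` (count B), and the same for `(m+1)`-windows (count A), and
#' returns `-ln(A/B)`. Self-matches are excluded. Regular or periodic
#' images keep their matches when the template grows and score near 0;
#' irregular images lose them and score high. If no pairs match at either
#' size the value is undefined and `NA` is returned with a warning.
#'
#' @param image Numeric matrix, at least `(m+1)` x `(m+1)`.
#' @param m Template side length.
#' @param r Tolerance (>= 0), on the intensity scale of `image`.
#' @return A non-negative scalar, or `NA` if undefined.
#' @export
sampen2d <- function(image, m = 2, r) {
  check_image(image)
  if (r < 0) stop("tolerance r must be >= 0", call. = FALSE)
  if (nrow(image) < m + 1 || ncol(image) < m + 1) {
    stop("image too small for template size m+1", call. = FALSE)
  }
  ab <- cpp_sampen2d_counts(image, as.integer(m), r)
  if (ab[1] == 0 || ab[2] == 0) {
    warning("sample entropy undefined (no matching window pairs)",
            call. = FALSE)
    return(NA_real_)
  }
  -log(ab[1] / ab[2])
}

#' Two-dimensional fuzzy entropy
#'
#' As [sampen2d()] but with mean-centered windows and a continuous
#' exponential membership `exp(-(d^fuzzy_n)/r)` in place of the hard
#' threshold; returns `-ln(phi_{m+1} / phi_m)` where `phi` is the average
#' pairwise similarity over distinct window pairs.
#'
#' @inheritParams sampen2d
#' @param r Tolerance (> 0).
#' @param fuzzy_n Membership exponent (> 0).
#' @return A non-negative scalar (up to floating-point rounding).
#' @export
fuzzen2d <- function(image, m = 2, r, fuzzy_n = 2) {
  check_image(image)
  if (r <= 0) stop("tolerance r must be > 0 for fuzzy membership", call. = FALSE)
  if (nrow(image) < m + 1 || ncol(image) < m + 1) {
    stop("image too small for template size m+1", call. = FALSE)
  }
  phi <- cpp_fuzzen2d_phis(image, as.integer(m), r, fuzzy_n)
  -log(phi[2] / phi[1])
}

#' Two-dimensional permutation entropy
#'
#' Every `m` x `m` window is flattened row-major and encoded by its ordinal
#' pattern (stable ranks; ties broken by earlier index). Returns the
#' Shannon entropy (natural log) of the pattern frequencies normalized by
#' `ln((m^2)!)`, so values lie in \[0, 1\] with 1 for fully random data.
#'
#' @inheritParams sampen2d
#' @return A scalar in \[0, 1\].
#' @export
permen2d <- function(image, m = 2) {
  check_image(image)
  if (m * m > 9) {
    stop("m^2 > 9 unsupported (factorial pattern space)", call. = FALSE)
  }
  if (nrow(image) < m || ncol(image) < m) {
    stop("image too small for template size m", call. = FALSE)
  }
  w <- window_matrix(image, m)
  rk <- stable_row_ranks(w)
  M <- m * m
  code <- as.vector((rk - 1) %*% M^(seq_len(M) - 1))
  shannon(table(code)) / log(factorial(M))
}

#' Two-dimensional dispersion entropy
#'
#' Pixels are mapped through the normal CDF (location = image mean, spread =
#' population SD), linearly scaled and rounded into classes `1..c`; each
#' `m` x `m` window yields a dispersion pattern whose frequency distribution
#' is summarized by Shannon entropy (natural log) normalized by
#' `ln(c^(m^2))`. A constant image maps every pixel to the middle class and
#' scores 0.
#'
#' @inheritParams sampen2d
#' @param c Number of dispersion classes (>= 2).
#' @return A scalar in \[0, 1\].
#' @export
dispen2d <- function(image, m = 2, c = 4) {
  check_image(image)
  if (c < 2) stop("class count c must be >= 2", call. = FALSE)
  if (nrow(image) < m || ncol(image) < m) {
    stop("image too small for template size m", call. = FALSE)
  }
  s <- sd_pop(image)
  if (s == 0) {
    cls <- matrix(round((c + 1) / 2), nrow(image), ncol(image))
  } else {
    z <- pnorm(image, mean(image), s)
    cls <- clip(round(c * z + 0.5), 1, c)
  }
  w <- window_matrix(cls, m)
  M <- m * m
  code <- as.vector((w - 1) %*% c^(seq_len(M) - 1))
  shannon(table(code)) / (M * log(c))
}

#' Two-dimensional distribution entropy
#'
#' Chebyshev distances of all unordered distinct `m` x `m` window pairs are
#' histogrammed into `bins_B` equal-width bins spanning \[0, max distance\];
#' the empirical probability density is summarized by Shannon entropy
#' (log base 2) normalized by `log2(bins_B)`.
#'
#' @inheritParams sampen2d
#' @param bins_B Number of histogram bins (>= 2).
#' @return A scalar in \[0, 1\].
#' @export
disten2d <- function(image, m = 2, bins_B = 64) {
  check_image(image)
  if (bins_B < 2) stop("bins_B must be >= 2", call. = FALSE)
  if (nrow(image) < m || ncol(image) < m) {
    stop("image too small for template size m", call. = FALSE)
  }
  counts <- cpp_disten2d_hist(image, as.integer(m), as.integer(bins_B))
  shannon(counts, base = 2) / log2(bins_B)
}

#' Multiscale entropy profile of one image
#'
#' Coarse-grains the image at each scale in `params$scales` and applies the
#' named entropy. The tolerance for sample and fuzzy entropy is fixed once
#' as `r_factor` times the population SD of the scale-1 image and held
#' across scales, the standard multiscale-entropy convention that keeps
#' scales comparable. For a constant image (zero SD) the tolerance falls
#' back to `r_factor` itself; every entropy is then 0 at all scales.
#'
#' @param image Numeric matrix.
#' @param method One of `"SampEn2D"`, `"FuzzEn2D"`, `"PermEn2D"`,
#'   `"DispEn2D"`, `"DistEn2D"`.
#' @param params An [entropy_params()].
#' @return A tibble with columns `method`, `scale`, `value`.
#' @export
multiscale_profile <- function(image, method = entropy_methods,
                               params = entropy_params()) {
  method <- match.arg(method)
  check_image(image)
  s1_sd <- sd_pop(image)
  r <- params$r_factor * s1_sd
  if (r == 0) r <- params$r_factor
  vals <- vapply(params$scales, function(s) {
    cg <- coarse_grain(image, s)
    min_side <- if (method %in% c("SampEn2D", "FuzzEn2D")) params$m + 1
                else params$m
    if (nrow(cg) < min_side || ncol(cg) < min_side) {
      stop(sprintf("coarse-grained image too small for %s at scale %d",
                   method, s), call. = FALSE)
    }
    switch(method,
      SampEn2D = sampen2d(cg, params$m, r),
      FuzzEn2D = fuzzen2d(cg, params$m, r, params$fuzzy_n),
      PermEn2D = permen2d(cg, params$m),
      DispEn2D = dispen2d(cg, params$m, params$c),
      DistEn2D = disten2d(cg, params$m, params$bins_B))
  }, numeric(1))
  tibble::tibble(method = method, scale = params$scales, value = vals)
}

#' Multiscale entropy features for a cohort
#'
#' Computes all five 2D entropies at every scale for each image, yielding
#' `5 * length(params$scales)` feature columns named `<method>_s<scale>`
#' (25 with the defaults). Undefined sample-entropy values (no matching
#' window pairs) are imputed as 0 with a warning.
#'
#' @param cohort A cohort tibble.
#' @param params An [entropy_params()].
#' @return A tibble: `image_id`, `patient_id`, `class_label`, `image_type`,
#'   then one column per method x scale.
#' @export
entropy_features <- function(cohort, params = entropy_params()) {
  feats <- purrr::map(cohort$pixels, function(px) {
    vals <- unlist(lapply(entropy_methods, function(me) {
      prof <- multiscale_profile(px, me, params)
      stats::setNames(prof$value, paste0(me, "_s", prof$scale))
    }))
    nan_policy(vals, "entropy features")
  })
  dplyr::bind_cols(
    dplyr::select(cohort, "image_id", "patient_id", "class_label",
                  "image_type"),
    dplyr::bind_rows(feats))
}
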