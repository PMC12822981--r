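# First-order and gray-level-matrix texture features. Formulas follow the
# IBSI-conformant standard radiomics definitions; the exact name lists
# (17 FOS / 22 GLCM / 14 GLDM / 16 GLRLM / 16 GLSZM / 5 NGTDM) are frozen
# as this package's contract and exercised by the test suite.

#' Quantize an image to L gray levels
#'
#' Equal-width bins spanning the image's own min-max; the maximum value is
#' assigned to level `L`, and a constant image maps entirely to level 1.
#'
#' @param image Numeric matrix.
#' @param L Number of gray levels (>= 1).
#' @return An integer matrix with values in `1..L` and attribute `L`.
#' @export
quantize <- function(image, L = 32) {
  check_image(image)
  L <- as.integer(L)
  if (L < 1) stop("L must be >= 1", call. = FALSE)
  rng <- range(image)
  if (rng[1] == rng[2] || L == 1) {
    q <- matrix(1L, nrow(image), ncol(image))
  } else {
    q <- floor((image - rng[1]) / (rng[2] - rng[1]) * L) + 1
    q[q > L] <- L
    storage.mode(q) <- "integer"
  }
  attr(q, "L") <- L
  q
}

#' First-order statistics (17 features)
#'
#' Histogram-level statistics of the intensity distribution: energy, total
#' energy, entropy (32-bin histogram, log2), minimum, 10th/90th percentile,
#' maximum, mean, median, interquartile range, range, mean absolute
#' deviation, robust MAD (restricted to the 10-90 percentile core), root
#' mean squared, skewness, kurtosis (non-excess) and population variance.
#' Undefined moments on degenerate input fall back to 0.
#'
#' @param image Numeric matrix.
#' @return Named numeric vector of length 17 (prefix `fos_`).
#' @export
fos_features <- function(image) {
  check_image(image)
  x <- as.numeric(image)
  n <- length(x)
  qs <- quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  mu <- mean(x)
  v <- mean((x - mu)^2)
  core <- x[x >= qs[1] & x <= qs[4]]
  hist_p <- tabulate(quantize(image, 32L), 32L)
  out <- c(
    energy = sum(x^2),
    total_energy = sum(x^2),  # unit pixel area
    entropy = shannon(hist_p, base = 2),
    minimum = min(x),
    p10 = qs[1],
    p90 = qs[4],
    maximum = max(x),
    mean = mu,
    median = median(x),
    iqr = qs[3] - qs[2],
    range = max(x) - min(x),
    mad = mean(abs(x - mu)),
    rmad = mean(abs(core - mean(core))),
    rms = sqrt(mean(x^2)),
    skewness = mean((x - mu)^3) / v^1.5,
    kurtosis = mean((x - mu)^4) / v^2,
    variance = v)
  names(out) <- paste0("fos_", names(out))
  nan_policy(out, "FOS")
}

# the four unique distance-1 2D directions as (di, dj) offsets
texture_directions <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))

# Co-occurrence counts of quantized levels at one offset (unsymmetrized).
glcm_matrix <- function(q, offset, L) {
  H <- nrow(q); W <- ncol(q)
  di <- offset[1]; dj <- offset[2]
  ri <- seq_len(H)[seq_len(H) + di >= 1 & seq_len(H) + di <= H]
  cj <- seq_len(W)[seq_len(W) + dj >= 1 & seq_len(W) + dj <= W]
  a <- q[ri, cj, drop = FALSE]
  b <- q[ri + di, cj + dj, drop = FALSE]
  m <- matrix(0, L, L)
  tab <- table(factor(a, levels = 1:L), factor(b, levels = 1:L))
  m + tab
}

glcm_features_one <- function(P, L) {
  P <- P + t(P)                       # symmetrize
  P <- P / sum(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(i * P); muy <- sum(j * P)
  sx <- sqrt(sum((i - mux)^2 * P)); sy <- sqrt(sum((j - muy)^2 * P))
  # diagonal (difference) and cross-diagonal (sum) marginals
  kdiff <- 0:(L - 1)
  pdiff <- vapply(kdiff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  ksum <- 2:(2 * L)
  psum <- vapply(ksum, function(k) sum(P[(i + j) == k]), numeric(1))
  da <- sum(kdiff * pdiff)
  hx <- shannon(px, 2); hy <- shannon(py, 2)
  hxy <- shannon(P, 2)
  pp <- outer(px, py)
  nz <- P > 0
  hxy1 <- -sum(P[nz] * log2(pp[nz]))
  hxy2 <- -sum(pp[pp > 0] * log2(pp[pp > 0]))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  offdiag <- i != j
  c(autocorrelation = sum(i * j * P),
    joint_average = mux,
    cluster_prominence = sum((i + j - mux - muy)^4 * P),
    cluster_shade = sum((i + j - mux - muy)^3 * P),
    cluster_tendency = sum((i + j - mux - muy)^2 * P),
    contrast = sum((i - j)^2 * P),
    correlation = if (sx > 0 && sy > 0) (sum(i * j * P) - mux * muy) / (sx * sy) else 0,
    difference_average = da,
    difference_entropy = shannon(pdiff, 2),
    difference_variance = sum((kdiff - da)^2 * pdiff),
    joint_energy = sum(P^2),
    joint_entropy = hxy,
    imc1 = imc1,
    imc2 = imc2,
    idm = sum(P / (1 + (i - j)^2)),
    idmn = sum(P / (1 + ((i - j) / L)^2)),
    id = sum(P / (1 + abs(i - j))),
    idn = sum(P / (1 + abs(i - j) / L)),
    inverse_variance = sum(P[offdiag] / (i[offdiag] - j[offdiag])^2),
    maximum_probability = max(P),
    sum_entropy = shannon(psum, 2),
    sum_squares = sum((i - mux)^2 * P))
}

#' Gray-level co-occurrence features (22 features)
#'
#' Co-occurrence matrices at offset distance 1 in the four unique 2D
#' directions (0, 45, 90, 135 degrees), each symmetrized and normalized;
#' the 22 standard co-occurrence features are computed per direction and
#' averaged. Correlation-type features of degenerate (zero-variance)
#' matrices fall back to 0.
#'
#' @param qimg A [quantize()]d image.
#' @return Named numeric vector of length 22 (prefix `glcm_`).
#' @export
glcm_features <- function(qimg) {
  L <- attr(qimg, "L")
  per_dir <- vapply(texture_directions,
                    function(o) glcm_features_one(glcm_matrix(qimg, o, L), L),
                    numeric(22))
  out <- rowMeans(per_dir)
  names(out) <- paste0("glcm_", names(out))
  nan_policy(out, "GLCM")
}

# count of 8-connected neighbors within `alpha` gray levels of each pixel
dependence_counts <- function(q, alpha = 0) {
  H <- nrow(q); W <- ncol(q)
  dep <- matrix(0L, H, W)
  shifts <- list(c(-1L,-1L), c(-1L,0L), c(-1L,1L), c(0L,-1L),
                 c(0L,1L), c(1L,-1L), c(1L,0L), c(1L,1L))
  for (sh in shifts) {
    di <- sh[1]; dj <- sh[2]
    ri <- seq_len(H)[seq_len(H) + di >= 1 & seq_len(H) + di <= H]
    cj <- seq_len(W)[seq_len(W) + dj >= 1 & seq_len(W) + dj <= W]
    ok <- abs(q[ri, cj, drop = FALSE] - q[ri + di, cj + dj, drop = FALSE]) <= alpha
    dep[ri, cj] <- dep[ri, cj] + ok
  }
  dep
}

#' Gray-level dependence features (14 features)
#'
#' Counts, for every pixel, its number of 8-connected neighbors within
#' `alpha` gray levels (its "dependence"); the level-by-dependence count
#' matrix yields the 14 standard dependence features. Dependence size `j`
#' indexes columns as dependence + 1.
#'
#' @param qimg A [quantize()]d image.
#' @param alpha Gray-level tolerance for dependence (default 0: exact).
#' @return Named numeric vector of length 14 (prefix `gldm_`).
#' @export
gldm_features <- function(qimg, alpha = 0) {
  L <- attr(qimg, "L")
  dep <- dependence_counts(qimg, alpha)
  P <- table(factor(qimg, levels = 1:L), factor(dep + 1L, levels = 1:9))
  P <- matrix(as.numeric(P), L, 9)
  Nz <- sum(P)
  p <- P / Nz
  i <- row(P); j <- col(P)
  pi_ <- rowSums(p); pj <- colSums(p)
  mui <- sum(i * p); muj <- sum(j * p)
  out <- c(
    small_dependence_emphasis = sum(P / j^2) / Nz,
    large_dependence_emphasis = sum(P * j^2) / Nz,
    gray_level_nonuniformity = sum(rowSums(P)^2) / Nz,
    dependence_nonuniformity = sum(colSums(P)^2) / Nz,
    dependence_nonuniformity_normalized = sum(colSums(P)^2) / Nz^2,
    gray_level_variance = sum(p * (i - mui)^2),
    dependence_variance = sum(p * (j - muj)^2),
    dependence_entropy = shannon(p, 2),
    low_gray_level_emphasis = sum(P / i^2) / Nz,
    high_gray_level_emphasis = sum(P * i^2) / Nz,
    small_dependence_low_gray_level_emphasis = sum(P / (i^2 * j^2)) / Nz,
    small_dependence_high_gray_level_emphasis = sum(P * i^2 / j^2) / Nz,
    large_dependence_low_gray_level_emphasis = sum(P * j^2 / i^2) / Nz,
    large_dependence_high_gray_level_emphasis = sum(P * i^2 * j^2) / Nz)
  names(out) <- paste0("gldm_", names(out))
  nan_policy(out, "GLDM")
}

# run-length counts (level x length) along one direction
glrlm_matrix <- function(q, offset, L) {
  H <- nrow(q); W <- ncol(q)
  seqs <- switch(paste(offset, collapse = ","),
    "0,1" = split(q, row(q)),                 # horizontal runs
    "-1,0" = split(q, col(q)),                # vertical runs
    "-1,1" = split(q, row(q) + col(q)),       # 45-degree diagonals
    "-1,-1" = split(q, row(q) - col(q)))      # 135-degree diagonals
  maxlen <- max(H, W)
  P <- matrix(0, L, maxlen)
  for (s in seqs) {
    r <- rle(as.vector(s))
    for (k in seq_along(r$lengths)) {
      P[r$values[k], r$lengths[k]] <- P[r$values[k], r$lengths[k]] + 1
    }
  }
  P
}

rl_features_one <- function(P, Np, kind = c("run", "zone")) {
  kind <- match.arg(kind)
  Nr <- sum(P)
  p <- P / Nr
  i <- row(P); j <- col(P)
  mui <- sum(i * p); muj <- sum(j * p)
  vals <- c(
    sum(P / j^2) / Nr,
    sum(P * j^2) / Nr,
    sum(rowSums(P)^2) / Nr,
    sum(rowSums(P)^2) / Nr^2,
    sum(colSums(P)^2) / Nr,
    sum(colSums(P)^2) / Nr^2,
    Nr / Np,
    sum(p * (i - mui)^2),
    sum(p * (j - muj)^2),
    shannon(p, 2),
    sum(P / i^2) / Nr,
    sum(P * i^2) / Nr,
    sum(P / (i^2 * j^2)) / Nr,
    sum(P * i^2 / j^2) / Nr,
    sum(P * j^2 / i^2) / Nr,
    sum(P * i^2 * j^2) / Nr)
  size <- if (kind == "run") "run" else "area"
  unit <- if (kind == "run") "run" else "zone"
  names(vals) <- c(
    paste0("short_", size, "_emphasis"),
    paste0("long_", size, "_emphasis"),
    "gray_level_nonuniformity",
    "gray_level_nonuniformity_normalized",
    paste0(unit, "_length_nonuniformity"),
    paste0(unit, "_length_nonuniformity_normalized"),
    paste0(unit, "_percentage"),
    "gray_level_variance",
    paste0(unit, "_variance"),
    paste0(unit, "_entropy"),
    paste0("low_gray_level_", unit, "_emphasis"),
    paste0("high_gray_level_", unit, "_emphasis"),
    paste0("short_", size, "_low_gray_level_emphasis"),
    paste0("short_", size, "_high_gray_level_emphasis"),
    paste0("long_", size, "_low_gray_level_emphasis"),
    paste0("long_", size, "_high_gray_level_emphasis"))
  if (kind == "zone") {
    names(vals)[c(1, 2, 13:16)] <-
      c("small_area_emphasis", "large_area_emphasis",
        "small_area_low_gray_level_emphasis",
        "small_area_high_gray_level_emphasis",
        "large_area_low_gray_level_emphasis",
        "large_area_high_gray_level_emphasis")
    names(vals)[5:6] <- c("size_zone_nonuniformity",
                          "size_zone_nonuniformity_normalized")
  }
  vals
}

#' Gray-level run-length features (16 features)
#'
#' Run-length matrices (runs of equal level along a direction) in the four
#' unique directions, the 16 standard run-length features computed per
#' direction and averaged.
#'
#' @param qimg A [quantize()]d image.
#' @return Named numeric vector of length 16 (prefix `glrlm_`).
#' @export
glrlm_features <- function(qimg) {
  L <- attr(qimg, "L")
  Np <- length(qimg)
  per_dir <- vapply(texture_directions, function(o) {
    rl_features_one(glrlm_matrix(qimg, o, L), Np, "run")
  }, numeric(16))
  out <- rowMeans(per_dir)
  names(out) <- paste0("glrlm_", names(out))
  nan_policy(out, "GLRLM")
}

#' Gray-level size-zone features (16 features)
#'
#' Sizes of 8-connected zones of equal gray level (direction-free); the 16
#' standard size-zone features of the level-by-size count matrix.
#'
#' @param qimg A [quantize()]d image.
#' @return Named numeric vector of length 16 (prefix `glszm_`).
#' @export
glszm_features <- function(qimg) {
  L <- attr(qimg, "L")
  q <- qimg; storage.mode(q) <- "integer"
  lab <- cpp_label_zones(q)
  sizes <- tabulate(lab)
  levels <- vapply(seq_along(sizes), function(z) q[which(lab == z)[1]],
                   integer(1))
  P <- matrix(0, L, max(sizes))
  for (z in seq_along(sizes)) {
    P[levels[z], sizes[z]] <- P[levels[z], sizes[z]] + 1
  }
  out <- rl_features_one(P, length(q), "zone")
  names(out) <- paste0("glszm_", names(out))
  nan_policy(out, "GLSZM")
}

# mean of the valid 8-neighbors of every pixel
neighborhood_mean <- function(x) {
  H <- nrow(x); W <- ncol(x)
  acc <- matrix(0, H, W); cnt <- matrix(0, H, W)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ri <- seq_len(H)[seq_len(H) + di >= 1 & seq_len(H) + di <= H]
    cj <- seq_len(W)[seq_len(W) + dj >= 1 & seq_len(W) + dj <= W]
    acc[ri, cj] <- acc[ri, cj] + x[ri + di, cj + dj, drop = FALSE]
    cnt[ri, cj] <- cnt[ri, cj] + 1
  }
  acc / cnt
}

#' Neighborhood gray-tone difference features (5 features)
#'
#' From the per-level sums of absolute differences between each pixel and
#' the mean of its 8-neighborhood: coarseness, contrast, busyness,
#' complexity and strength. Zero denominators are capped (coarseness at
#' 1e6) or fall back to 0.
#'
#' @param qimg A [quantize()]d image.
#' @return Named numeric vector of length 5 (prefix `ngtdm_`).
#' @export
ngtdm_features <- function(qimg) {
  L <- attr(qimg, "L")
  A <- neighborhood_mean(qimg)
  N <- length(qimg)
  n_g <- tabulate(qimg, L)
  s_g <- vapply(1:L, function(g) sum(abs(qimg[qimg == g] - A[qimg == g])),
                numeric(1))
  p_g <- n_g / N
  nz <- which(p_g > 0)
  Ngp <- length(nz)
  denom_c <- sum(p_g * s_g)
  coarseness <- if (denom_c > 0) 1 / denom_c else 1e6
  contrast <- if (Ngp > 1) {
    sum(outer(p_g[nz], p_g[nz]) * outer(nz, nz, "-")^2) /
      (Ngp * (Ngp - 1)) * sum(s_g) / N
  } else 0
  busy_den <- sum(abs(outer(nz * p_g[nz], nz * p_g[nz], "-")))
  busyness <- if (busy_den > 0) sum(p_g * s_g) / busy_den else 0
  pairs <- expand.grid(i = nz, j = nz)
  complexity <- sum(abs(pairs$i - pairs$j) *
                    (p_g[pairs$i] * s_g[pairs$i] + p_g[pairs$j] * s_g[pairs$j]) /
                    (p_g[pairs$i] + p_g[pairs$j])) / N
  strength <- if (sum(s_g) > 0) {
    sum((p_g[pairs$i] + p_g[pairs$j]) * (pairs$i - pairs$j)^2) / sum(s_g)
  } else 0
  out <- c(ngtdm_coarseness = coarseness, ngtdm_contrast = contrast,
           ngtdm_busyness = busyness, ngtdm_complexity = complexity,
           ngtdm_strength = strength)
  nan_policy(out, "NGTDM")
}

#' Statistical (first- plus second-order) features for a cohort
#'
#' The 17 first-order features plus the 73 gray-level-matrix features
#' (22 GLCM + 14 GLDM + 16 GLRLM + 16 GLSZM + 5 NGTDM), 90 columns total.
#'
#' @param cohort A cohort tibble.
#' @param L Quantization level count (default 32, equal-width over each
#'   ROI's own min-max).
#' @param gldm_alpha Dependence tolerance for GLDM.
#' @return A tibble: metadata columns then 90 feature columns.
#' @export
statistical_features <- function(cohort, L = 32, gldm_alpha = 0) {
  feats <- purrr::map(cohort$pixels, function(px) {
    q <- quantize(px, L)
    c(fos_features(px), glcm_features(q), gldm_features(q, gldm_alpha),
      glrlm_features(q), glszm_features(q), ngtdm_features(q))
  })
  dplyr::bind_cols(
    dplyr::select(cohort, "image_id", "patient_id", "class_label",
                  "image_type"),
    dplyr::bind_rows(feats))
}
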