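# Internal helpers shared across modules.

# Population (N-denominator) standard deviation.
sd_pop <- function(x) {
  x <- as.numeric(x)
  sqrt(mean((x - mean(x))^2))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

check_image <- function(x, arg = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  invisible(x)
}

# All m x m windows of `x` as rows of an (n_windows x m^2) matrix; window
# pixels are flattened row-major ((0,0), (0,1), ..., (1,0), ...).
window_matrix <- function(x, m) {
  H <- nrow(x); W <- ncol(x)
  if (H < m || W < m) stop("image too small for template size m", call. = FALSE)
  nh <- H - m + 1L; nw <- W - m + 1L
  cols <- vector("list", m * m)
  k <- 1L
  for (di in 0:(m - 1L)) {
    for (dj in 0:(m - 1L)) {
      cols[[k]] <- as.vector(x[(1L + di):(nh + di), (1L + dj):(nw + dj)])
      k <- k + 1L
    }
  }
  do.call(cbind, cols)
}

# Stable ranks of each row (ties resolved in favour of the earlier index),
# vectorized over rows. Equivalent to applying order()/rank() per row with a
# first-come tie-break.
stable_row_ranks <- function(w) {
  M <- ncol(w)
  r <- matrix(1L, nrow(w), M)
  for (j in seq_len(M)) {
    for (k in seq_len(M)) {
      if (k == j) next
      lt <- w[, k] < w[, j]
      if (k < j) lt <- lt | (w[, k] == w[, j])
      r[, j] <- r[, j] + lt
    }
  }
  r
}

# Shannon entropy (given log base) of a count/probability vector, ignoring
# empty cells.
shannon <- function(p, base = exp(1)) {
  p <- p[p > 0]
  p <- p / sum(p)
  -sum(p * log(p) / log(base))
}

# Replace non-finite values by `fill`, warning once with a context tag.
nan_policy <- function(x, context, fill = 0) {
  bad <- !is.finite(x)
  if (any(bad)) {
    warning(sprintf("%s: %d undefined value(s) replaced by %g",
                    context, sum(bad), fill), call. = FALSE)
    x[bad] <- fill
  }
  x
}

# Deterministic per-image seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647L)
  mult <- c(7919, 104729, 1299709, 15485863)
  for (i in seq_along(idx)) {
    s <- (s + mult[((i - 1) %% 4) + 1] * as.double(idx[i])) %% 2147483647
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
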