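# Brute-force twin implementations used as independent oracles. These are
# deliberately naive (explicit loops, per-window extraction, sort-based
# medians) and share no code with the package internals they check.

oracle_windows <- function(x, m) {
  H <- nrow(x); W <- ncol(x)
  out <- list()
  for (j in 1:(W - m + 1)) {
    for (i in 1:(H - m + 1)) {
      out[[length(out) + 1]] <- x[i:(i + m - 1), j:(j + m - 1)]
    }
  }
  out
}

# windows restricted to positions where the (m+1)-window also fits
oracle_windows_common <- function(x, m, size) {
  H <- nrow(x); W <- ncol(x)
  out <- list()
  for (j in 1:(W - m)) {
    for (i in 1:(H - m)) {
      out[[length(out) + 1]] <- x[i:(i + size - 1), j:(j + size - 1)]
    }
  }
  out
}

oracle_sampen2d <- function(x, m, r) {
  wm <- oracle_windows_common(x, m, m)
  wm1 <- oracle_windows_common(x, m, m + 1)
  n <- length(wm)
  A <- 0; B <- 0
  for (p in 1:(n - 1)) {
    for (q in (p + 1):n) {
      if (max(abs(wm[[p]] - wm[[q]])) <= r) B <- B + 1
      if (max(abs(wm1[[p]] - wm1[[q]])) <= r) A <- A + 1
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

oracle_fuzzen2d <- function(x, m, r, nexp) {
  cm <- lapply(oracle_windows_common(x, m, m), function(w) w - mean(w))
  cm1 <- lapply(oracle_windows_common(x, m, m + 1), function(w) w - mean(w))
  n <- length(cm)
  phi <- c(0, 0)
  for (p in 1:(n - 1)) {
    for (q in (p + 1):n) {
      phi[1] <- phi[1] + exp(-max(abs(cm[[p]] - cm[[q]]))^nexp / r)
      phi[2] <- phi[2] + exp(-max(abs(cm1[[p]] - cm1[[q]]))^nexp / r)
    }
  }
  -log(phi[2] / phi[1])
}

oracle_permen2d <- function(x, m) {
  # row-major flattening with stable ordering is part of the contract
  keys <- vapply(oracle_windows(x, m), function(w) {
    paste(order(as.vector(t(w))), collapse = ",")
  }, character(1))
  p <- table(keys) / length(keys)
  -sum(p * log(p)) / log(factorial(m * m))
}

oracle_dispen2d <- function(x, m, c) {
  s <- sqrt(mean((x - mean(x))^2))
  cls <- if (s == 0) {
    matrix(round((c + 1) / 2), nrow(x), ncol(x))
  } else {
    pmin(pmax(round(c * pnorm(x, mean(x), s) + 0.5), 1), c)
  }
  keys <- vapply(oracle_windows(cls, m), function(w) {
    paste(as.vector(w), collapse = ",")
  }, character(1))
  p <- table(keys) / length(keys)
  -sum(p * log(p)) / (m * m * log(c))
}

oracle_disten2d <- function(x, m, B) {
  w <- oracle_windows(x, m)
  n <- length(w)
  d <- c()
  for (p in 1:(n - 1)) {
    for (q in (p + 1):n) d <- c(d, max(abs(w[[p]] - w[[q]])))
  }
  maxd <- max(d)
  bin <- if (maxd == 0) rep(1, length(d)) else pmin(floor(d / maxd * B) + 1, B)
  p <- tabulate(bin, B) / length(d)
  p <- p[p > 0]
  -sum(p * log2(p)) / log2(B)
}

oracle_median_filter <- function(x, radius) {
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  for (i in 1:H) {
    for (j in 1:W) {
      vals <- c()
      for (di in -radius:radius) {
        for (dj in -radius:radius) {
          ci <- min(max(i + di, 1), H)
          cj <- min(max(j + dj, 1), W)
          vals <- c(vals, x[ci, cj])
        }
      }
      sv <- sort(vals)
      out[i, j] <- sv[(length(sv) + 1) / 2]
    }
  }
  out
}

naive_glcm <- function(q, offset, L) {
  H <- nrow(q); W <- ncol(q)
  P <- matrix(0, L, L)
  for (i in 1:H) {
    for (j in 1:W) {
      ni <- i + offset[1]; nj <- j + offset[2]
      if (ni >= 1 && ni <= H && nj >= 1 && nj <= W) {
        P[q[i, j], q[ni, nj]] <- P[q[i, j], q[ni, nj]] + 1
      }
    }
  }
  P
}

naive_dependence <- function(q, alpha) {
  H <- nrow(q); W <- ncol(q)
  dep <- matrix(0, H, W)
  for (i in 1:H) {
    for (j in 1:W) {
      for (di in -1:1) {
        for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          ni <- i + di; nj <- j + dj
          if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
              abs(q[i, j] - q[ni, nj]) <= alpha) {
            dep[i, j] <- dep[i, j] + 1
          }
        }
      }
    }
  }
  dep
}

# run-length matrix by explicit line scanning in one direction
naive_glrlm <- function(q, offset, L) {
  H <- nrow(q); W <- ncol(q)
  P <- matrix(0, L, max(H, W))
  seen <- matrix(FALSE, H, W)
  for (i in 1:H) {
    for (j in 1:W) {
      pi_ <- i - offset[1]; pj <- j - offset[2]
      in_prev <- pi_ >= 1 && pi_ <= H && pj >= 1 && pj <= W
      if (in_prev && q[pi_, pj] == q[i, j]) next  # not a run start
      len <- 1
      ni <- i + offset[1]; nj <- j + offset[2]
      while (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
             q[ni, nj] == q[i, j]) {
        len <- len + 1
        ni <- ni + offset[1]; nj <- nj + offset[2]
      }
      P[q[i, j], len] <- P[q[i, j], len] + 1
    }
  }
  P
}

# 8-connected zones by queue-based flood fill
naive_zone_sizes <- function(q) {
  H <- nrow(q); W <- ncol(q)
  lab <- matrix(0L, H, W)
  zones <- list()
  nz <- 0
  for (i in 1:H) {
    for (j in 1:W) {
      if (lab[i, j] != 0) next
      nz <- nz + 1
      queue <- list(c(i, j)); lab[i, j] <- nz; size <- 0
      while (length(queue) > 0) {
        c0 <- queue[[1]]; queue <- queue[-1]; size <- size + 1
        for (di in -1:1) for (dj in -1:1) {
          ni <- c0[1] + di; nj <- c0[2] + dj
          if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
              lab[ni, nj] == 0 && q[ni, nj] == q[i, j]) {
            lab[ni, nj] <- nz
            queue[[length(queue) + 1]] <- c(ni, nj)
          }
        }
      }
      zones[[nz]] <- c(level = q[i, j], size = size)
    }
  }
  do.call(rbind, zones)
}

naive_ngtdm <- function(q, L) {
  H <- nrow(q); W <- ncol(q)
  s_g <- rep(0, L); n_g <- rep(0, L)
  for (i in 1:H) {
    for (j in 1:W) {
      vals <- c()
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ni <- i + di; nj <- j + dj
        if (ni >= 1 && ni <= H && nj >= 1 && nj <= W) {
          vals <- c(vals, q[ni, nj])
        }
      }
      g <- q[i, j]
      n_g[g] <- n_g[g] + 1
      s_g[g] <- s_g[g] + abs(g - mean(vals))
    }
  }
  list(s = s_g, n = n_g)
}

oracle_auc_trapezoid <- function(labels, scores, positive) {
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  tpr <- vapply(ths, function(t) sum(scores >= t & pos) / n1, numeric(1))
  fpr <- vapply(ths, function(t) sum(scores >= t & !pos) / n0, numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
enumerate_mw_p <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pool), n1)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u_obs <- u_of(a, b)
  us <- apply(idx, 2, function(k) u_of(pool[k], pool[-k]))
  p_lo <- mean(us <= u_obs); p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

checkerboard <- function(n, low = 0, high = 255) {
  outer(1:n, 1:n, function(i, j) ifelse((i + j) %% 2 == 0, low, high))
}
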