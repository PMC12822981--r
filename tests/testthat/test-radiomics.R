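test_that("quantization: degenerate range, single bin, exact ramp", {
  cst <- matrix(5, 4, 4)
  expect_true(all(quantize(cst, 8) == 1))
  expect_true(all(quantize(matrix(rnorm(16), 4), 1) == 1))
  ramp <- matrix(seq(0, 31), 4, 8)
  q <- quantize(ramp, 32)
  expect_equal(sort(unique(as.vector(q))), 1:32)
  expect_equal(as.vector(table(q)), rep(1, 32))
  expect_equal(max(quantize(ramp, 32)), 32)  # max maps to level L
})

test_that("feature groups emit exactly their contracted counts", {
  set.seed(2)
  x <- matrix(runif(64, 0, 255), 8, 8)
  q <- quantize(x, 8)
  expect_length(fos_features(x), 17)
  expect_length(glcm_features(q), 22)
  expect_length(gldm_features(q), 14)
  expect_length(glrlm_features(q), 16)
  expect_length(glszm_features(q), 16)
  expect_length(ngtdm_features(q), 5)
})

test_that("first-order statistics match hand arithmetic", {
  x <- matrix(1:9, 3, 3)
  f <- fos_features(x)
  expect_equal(unname(f["fos_mean"]), 5)
  expect_equal(unname(f["fos_median"]), 5)
  expect_equal(unname(f["fos_range"]), 8)
  expect_equal(unname(f["fos_variance"]), 20 / 3)
  expect_equal(unname(f["fos_minimum"]), 1)
  expect_equal(unname(f["fos_maximum"]), 9)
  expect_equal(unname(f["fos_energy"]), sum((1:9)^2))
  expect_equal(unname(f["fos_rms"]), sqrt(mean((1:9)^2)))
})

test_that("degenerate first-order input falls back cleanly", {
  suppressWarnings(f <- fos_features(matrix(4, 3, 3)))
  expect_equal(unname(f["fos_variance"]), 0)
  expect_equal(unname(f["fos_range"]), 0)
  expect_equal(unname(f["fos_skewness"]), 0)
  expect_equal(unname(f["fos_kurtosis"]), 0)
  expect_true(all(is.finite(f)))
})

test_that("checkerboard co-occurrence at 0 degrees matches the hand count", {
  cb <- checkerboard(4, 1, 2)  # values 1/2, already levels
  q <- structure(cb, L = 2L)
  P <- texent:::glcm_matrix(q, c(0L, 1L), 2L)
  # 12 horizontal pairs, all between levels 1 and 2
  expect_equal(sum(P), 12)
  f <- texent:::glcm_features_one(P, 2L)
  expect_equal(unname(f["contrast"]), 1)
  expect_equal(unname(f["joint_energy"]), 0.5)
})

test_that("constant image: zero GLCM contrast, full dependence, one zone", {
  q <- quantize(matrix(3, 5, 5), 8)
  suppressWarnings({
    expect_equal(unname(glcm_features(q)["glcm_contrast"]), 0)
    expect_equal(unname(ngtdm_features(q)["ngtdm_contrast"]), 0)
  })
  dep <- texent:::dependence_counts(q, 0)
  expect_equal(dep[3, 3], 8)   # interior pixel: all 8 neighbors equal
  expect_equal(dep[1, 1], 3)   # corner: 3 valid neighbors
  expect_equal(dep, naive_dependence(q, 0))
  # single 8-connected zone covering the image
  zs <- naive_zone_sizes(q)
  expect_equal(nrow(zs), 1)
  expect_equal(unname(zs[1, "size"]), 25)
})

test_that("all-distinct image has zero dependence at alpha 0", {
  q <- structure(matrix(1:16, 4, 4), L = 16L)
  expect_true(all(texent:::dependence_counts(q, 0) == 0))
})

test_that("run-length matrices match run inspection and the constant case", {
  row5 <- structure(matrix(c(1, 1, 2, 2, 2), 1, 5), L = 2L)
  P <- texent:::glrlm_matrix(row5, c(0L, 1L), 2L)
  expect_equal(P[1, 2], 1)  # one run of level 1, length 2
  expect_equal(P[2, 3], 1)  # one run of level 2, length 3
  expect_equal(sum(P), 2)

  cstq <- structure(matrix(2, 6, 6), L = 2L)
  P0 <- texent:::glrlm_matrix(cstq, c(0L, 1L), 2L)
  expect_equal(P0[2, 6], 6)  # six runs (rows) of length 6
  expect_equal(sum(P0), 6)
})

test_that("size-zone matrix agrees with a hand-labeled blob image", {
  img <- matrix(1, 5, 5)
  img[1, 1:2] <- 2          # blob A: two pixels
  img[4:5, 5] <- 2          # blob B: two pixels
  q <- structure(img, L = 2L)
  lab <- texent:::cpp_label_zones(matrix(as.integer(img), 5, 5))
  sizes <- tabulate(lab)
  expect_equal(sort(sizes), c(2, 2, 21))
  zs <- naive_zone_sizes(img)
  expect_equal(sort(zs[, "size"]), c(2, 2, 21))
  f <- glszm_features(q)
  expect_length(f, 16)
})

test_that("NGTDM on a fixed two-level image matches direct summation", {
  img <- matrix(c(1, 2, 1, 2,
                  2, 1, 2, 1,
                  1, 1, 2, 2,
                  2, 2, 1, 1), 4, 4, byrow = TRUE)
  q <- structure(img, L = 2L)
  nv <- naive_ngtdm(img, 2)
  p <- nv$n / 16
  f <- ngtdm_features(q)
  expect_equal(unname(f["ngtdm_coarseness"]), 1 / sum(p * nv$s))
  contrast_o <- (sum(outer(p, p) * outer(1:2, 1:2, "-")^2) / (2 * 1)) *
    sum(nv$s) / 16
  expect_equal(unname(f["ngtdm_contrast"]), contrast_o)
})

test_that("matrix builders equal naive twins on seeded random images", {
  set.seed(99)
  for (k in 1:50) {
    q <- structure(matrix(sample(1:4, 36, replace = TRUE), 6, 6), L = 4L)
    qi <- matrix(as.integer(q), 6, 6)
    for (o in texent:::texture_directions) {
      expect_equal(unname(as.matrix(texent:::glcm_matrix(q, o, 4L))),
                   naive_glcm(q, o, 4L), ignore_attr = TRUE)
      expect_equal(texent:::glrlm_matrix(q, o, 4L), naive_glrlm(q, o, 4L))
    }
    expect_equal(texent:::dependence_counts(q, 0), naive_dependence(q, 0))
    expect_equal(sort(tabulate(texent:::cpp_label_zones(qi))),
                 sort(naive_zone_sizes(q)[, "size"]), ignore_attr = TRUE)
    nv <- naive_ngtdm(q, 4L)
    A <- texent:::neighborhood_mean(q)
    s_g <- vapply(1:4, function(g) sum(abs(q[q == g] - A[q == g])),
                  numeric(1))
    expect_equal(s_g, nv$s, tolerance = 1e-12)
  }
})

test_that("direction-averaged and direction-free features are transpose invariant", {
  set.seed(12)
  x <- matrix(runif(100, 0, 255), 10, 10)
  q <- quantize(x, 6)
  qt <- quantize(t(x), 6)
  expect_equal(glcm_features(q), glcm_features(qt), tolerance = 1e-12)
  expect_equal(glrlm_features(q), glrlm_features(qt), tolerance = 1e-12)
  expect_equal(glszm_features(q), glszm_features(qt), tolerance = 1e-12)
  expect_equal(ngtdm_features(q), ngtdm_features(qt), tolerance = 1e-12)
  expect_equal(fos_features(x), fos_features(t(x)), tolerance = 1e-12)
})

test_that("feature sets assemble with the contracted column counts", {
  co <- generate_cohort(small_cfg("strong", n_reg = 1, n_irr = 1, ipp = 1,
                                  size = 16))
  stat <- suppressWarnings(extract_features(co, "statistical"))
  ent <- suppressWarnings(extract_features(co, "entropy"))
  comb <- suppressWarnings(extract_features(co, "combined"))
  expect_length(feature_names(stat), 90)
  expect_length(feature_names(ent), 25)
  expect_length(feature_names(comb), 115)
  expect_setequal(feature_names(comb),
                  union(feature_names(stat), feature_names(ent)))
  expect_false(any(duplicated(feature_names(comb))))
  counts <- table(feature_group(feature_names(stat)))
  expect_equal(unname(counts[c("FOS", "GLCM", "GLDM", "GLRLM", "GLSZM",
                               "NGTDM")]), c(17, 22, 14, 16, 16, 5),
               ignore_attr = TRUE)
})
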