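test_that("quantization bins uniformly and handles constant patches", {
  patch <- matrix(0:255, 16, 16)
  q <- quantize_gray(patch, 2)
  expect_true(all(q[patch < 128] == 0))
  expect_true(all(q[patch >= 128] == 1))
  expect_equal(unique(as.vector(quantize_gray(matrix(7, 5, 5), 8))), 0L)
  q16 <- quantize_gray(patch, 16)
  g <- glcm(q16, 0)
  expect_equal(dim(g), c(16L, 16L))
})

test_that("directional counts match hand enumeration on the 2x2 example", {
  p <- matrix(c(0L, 1L, 0L, 1L), 2, 2) # [[0,0],[1,1]] in row-major reading
  g0 <- glcm(p, 0, levels = 2)
  expect_equal(unclass(g0), matrix(c(1, 0, 0, 1), 2, 2), ignore_attr = TRUE)
  g90 <- glcm(p, 90, levels = 2)
  expect_equal(g90[2, 1], 2) # ordered pairs bottom -> top
  expect_equal(sum(g90), 2)
  const <- glcm(matrix(0L, 3, 3), 0, levels = 4)
  expect_equal(const[1, 1], 6)
  expect_equal(sum(const), 6)
})

test_that("glcm equals the brute-force pair-enumeration oracle", {
  set.seed(601)
  for (rep in 1:10) {
    nr <- sample(4:10, 1); nc <- sample(4:10, 1)
    L <- sample(2:6, 1)
    patch <- matrix(sample(0:(L - 1), nr * nc, replace = TRUE), nr, nc)
    mask <- matrix(runif(nr * nc) < 0.8, nr, nc)
    mask[1:2, 1:2] <- TRUE # guarantee pairs exist
    for (th in c(0, 45, 90, 135)) {
      got <- glcm(patch, th, d = 1, mask = mask, levels = L)
      expect_equal(unclass(got), oracle_glcm(patch, mask, th, 1, L),
                   ignore_attr = TRUE)
    }
  }
})

test_that("masked pairs require both endpoints inside the mask", {
  patch <- matrix(c(0L, 1L, 2L, 3L), 2, 2)
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2) # only first column
  g <- glcm(patch, 90, mask = mask, levels = 4)
  expect_equal(sum(g), 1) # single vertical pair in column 1
  expect_error(glcm(patch, 0, mask = mask, levels = 4), "no valid")
})

test_that("mean_glcm averages counts element-wise", {
  mk <- function(m) structure(m, class = c("glcm", class(m)), theta = 0,
                              d = 1L, levels = 2L, normalized = FALSE)
  a <- mk(matrix(c(1, 0, 0, 1), 2, 2))
  b <- mk(matrix(c(0, 2, 2, 0), 2, 2))
  out <- mean_glcm(list(a, a, a, b))
  expect_equal(unclass(out), matrix(c(0.75, 0.5, 0.5, 0.75), 2, 2),
               ignore_attr = TRUE)
  same <- mean_glcm(list(a, a, a, a))
  expect_equal(unclass(same), unclass(a), ignore_attr = TRUE)
})

test_that("normalization sums to one and is idempotent", {
  m <- matrix(c(3, 1, 0, 0), 2, 2)
  n1 <- normalize_glcm(m)
  expect_equal(unclass(n1), matrix(c(0.75, 0.25, 0, 0), 2, 2),
               ignore_attr = TRUE)
  expect_equal(sum(n1), 1, tolerance = 1e-12)
  expect_equal(unclass(normalize_glcm(n1)), unclass(n1),
               ignore_attr = TRUE)
  expect_equal(unclass(normalize_glcm(matrix(1, 2, 2))),
               matrix(0.25, 2, 2), ignore_attr = TRUE)
  expect_error(normalize_glcm(matrix(0, 2, 2)), "all-zero")
})

test_that("haralick statistics match closed forms on tiny matrices", {
  point <- matrix(0, 2, 2); point[1, 1] <- 1
  f <- haralick_features(point)
  expect_equal(f[["energy"]], 1)
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["entropy"]], 0)
  expect_equal(f[["homogeneity"]], 1)
  expect_equal(f[["max_probability"]], 1)

  diagm <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  f <- haralick_features(diagm)
  expect_equal(f[["energy"]], 0.5)
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["entropy"]], 1)
  expect_equal(f[["correlation"]], 1)
  expect_equal(f[["max_probability"]], 0.5)
  expect_equal(f[["sum_average"]], 1) # p_{x+y}: mass at k=0 and k=2
  expect_equal(f[["sum_entropy"]], 1)
  expect_equal(f[["difference_entropy"]], 0)

  anti <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  f <- haralick_features(anti)
  expect_equal(f[["contrast"]], 1)
  expect_equal(f[["correlation"]], -1)
  expect_equal(f[["homogeneity"]], 0.5)
  expect_error(haralick_features(matrix(1, 2, 2)), "normalized")
})

test_that("region descriptors have 70 finite values in fixed order", {
  set.seed(602)
  patch <- matrix(runif(256, 0, 255), 16, 16)
  v <- region_feature_vector(patch)
  expect_length(v, 70)
  expect_true(all(is.finite(v)))
  expect_equal(
    names(v)[1:14],
    paste0(c("energy", "contrast", "correlation", "entropy", "variance",
             "sum_average", "sum_variance", "homogeneity",
             "difference_variance", "sum_entropy", "difference_entropy",
             "cluster_shade", "cluster_prominence", "max_probability"),
           "_d0"))
  expect_equal(sum(grepl("_mean$", names(v))), 14)
  # range contracts
  expect_true(all(v[grepl("^energy", names(v))] > 0 &
                    v[grepl("^energy", names(v))] <= 1))
  expect_true(all(v[grepl("^contrast", names(v))] >= 0))
  expect_true(all(v[grepl("^max_probability", names(v))] > 0 &
                    v[grepl("^max_probability", names(v))] <= 1))
})

test_that("a constant region is pure energy with zero contrast", {
  v <- region_feature_vector(matrix(128, 12, 12))
  expect_equal(unname(v[grepl("^energy", names(v))]), rep(1, 5))
  expect_equal(unname(v[grepl("^contrast", names(v))]), rep(0, 5))
  expect_equal(unname(v[grepl("^entropy", names(v))]), rep(0, 5))
})

test_that("rotating a patch 90 degrees permutes the direction blocks", {
  set.seed(603)
  patch <- matrix(runif(256, 0, 255), 16, 16)
  rot <- t(patch)[ncol(patch):1, ] # counter-clockwise 90 degrees
  v <- region_feature_vector(patch)
  vr <- region_feature_vector(rot)
  block <- function(v, tag) unname(v[grepl(paste0("_", tag, "$"), names(v))])
  expect_equal(block(v, "d0"), block(vr, "d90"), tolerance = 1e-9)
  expect_equal(block(v, "d90"), block(vr, "d0"), tolerance = 1e-9)
  expect_equal(block(v, "d45"), block(vr, "d135"), tolerance = 1e-9)
  expect_equal(block(v, "d135"), block(vr, "d45"), tolerance = 1e-9)
  # with ordered (non-symmetric) matrices, rotation transposes two of the
  # four count matrices entering the mean, so only the statistics that
  # ignore pair order are exactly invariant in the mean-direction block
  order_free <- c("contrast", "variance", "sum_average", "sum_variance",
                  "homogeneity", "difference_variance", "sum_entropy",
                  "difference_entropy", "cluster_shade",
                  "cluster_prominence")
  vm <- v[paste0(order_free, "_mean")]
  vrm <- vr[paste0(order_free, "_mean")]
  expect_equal(unname(vm), unname(vrm), tolerance = 1e-9)
})

test_that("concentric-ring texture is higher-contrast than flat texture", {
  ring <- generate_concentric_texture(12, 4, 160, 60)
  flat <- matrix(160, 25, 25)
  vr <- region_feature_vector(ring)
  vf <- region_feature_vector(flat)
  expect_gt(vr[["contrast_mean"]], vf[["contrast_mean"]])
})

test_that("region_features builds a tidy table with one row per region", {
  ph <- default_test_phantom(seed = 11)
  lum <- extract_lumina(ph$image)
  regs <- segment_suspicious_regions(ph$gray, lum$lumen_mask)
  tab <- region_features(regs, image_id = "ph1")
  expect_s3_class(tab, "tbl_df")
  expect_equal(nrow(tab), length(regs))
  expect_equal(ncol(tab), 72) # image_id + region_id + 70 features
  expect_true(all(is.finite(as.matrix(tab[, -(1:2)]))))
})
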