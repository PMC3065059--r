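test_that("standardization is an exact population z-score and idempotent", {
  tab <- tibble::tibble(a = c(1, 2, 3), b = c(10, 0, 5))
  z <- standardize(tab)
  expect_equal(z$a, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)
  expect_equal(unname(colMeans(as.matrix(z))), c(0, 0), tolerance = 1e-12)
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  expect_equal(unname(vapply(z, sd_pop, numeric(1))), c(1, 1),
               tolerance = 1e-12)
  z2 <- standardize(z)
  expect_equal(as.matrix(z2), as.matrix(z), tolerance = 1e-9)
})

test_that("constant columns are dropped with a warning; labels pass through", {
  tab <- tibble::tibble(a = c(1, 2, 3), k = c(5, 5, 5), label = c(0, 1, 0))
  expect_warning(z <- standardize(tab), "constant")
  expect_named(z, c("a", "label"))
  expect_equal(z$label, c(0, 1, 0))
  expect_error(standardize(tab[0, ]), "empty")
})

test_that("held-out data reuses the training standardization parameters", {
  set.seed(701)
  tr <- tibble::tibble(a = rnorm(20, 5, 2), b = rnorm(20, -3, 4))
  te <- tibble::tibble(a = rnorm(5, 5, 2), b = rnorm(5, -3, 4))
  z_tr <- standardize(tr)
  z_te <- standardize_apply(te, z_tr)
  expect_equal(z_te$a, (te$a - attr(z_tr, "center")[["a"]]) /
                 attr(z_tr, "scale")[["a"]], tolerance = 1e-12)
})

test_that("two perfectly correlated columns collapse to one component", {
  tab <- tibble::tibble(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  pca <- pca_fit(standardize(tab), alpha = 0.9)
  expect_equal(pca$k, 1L)
  expect_equal(pca$contribution[1], 1, tolerance = 1e-12)
})

test_that("eigen shares match an independent decomposition and k is minimal", {
  set.seed(702)
  tab <- tibble::as_tibble(as.data.frame(matrix(rnorm(300), 30, 10)))
  z <- standardize(tab)
  pca <- pca_fit(z, alpha = 0.98)
  # independent oracle: prcomp on the standardized matrix
  pr <- stats::prcomp(as.matrix(z), center = FALSE, scale. = FALSE)
  shares <- pr$sdev^2 / sum(pr$sdev^2)
  # prcomp uses n-1; shares are scale-free so they match the correlation
  # eigenvalue shares up to the population/sample sd convention
  expect_equal(pca$contribution, shares, tolerance = 1e-8)
  cum <- cumsum(shares)
  k_oracle <- which(cum >= 0.98)[1]
  expect_equal(pca$k, k_oracle)
  expect_true(pca$cumulative[pca$k] >= 0.98)
  if (pca$k > 1) expect_lt(pca$cumulative[pca$k - 1], 0.98)
  expect_equal(pca_fit(z, alpha = 1)$k, qr(as.matrix(z))$rank)
})

test_that("projection is consistent, variance-ordered and invertible at full rank", {
  set.seed(703)
  tab <- tibble::as_tibble(as.data.frame(matrix(rnorm(200), 20, 10)))
  z <- standardize(tab)
  pca <- pca_fit(z, alpha = 1)
  sc <- pca_transform(pca, z)
  vars <- apply(as.matrix(sc), 2, stats::var)
  expect_true(all(diff(vars) <= 1e-9))
  # back-projection at k = rank reconstructs the standardized data
  back <- as.matrix(sc) %*% t(pca$loadings[, seq_len(pca$k)])
  expect_equal(back, unname(as.matrix(z)), tolerance = 1e-9)
  expect_error(pca_transform(pca, tab[, 1:3]))
})

test_that("rbf svm separates well-separated clouds and is stable", {
  set.seed(704)
  n <- 50
  X <- rbind(matrix(rnorm(2 * n), n, 2), matrix(rnorm(2 * n, 6), n, 2))
  y <- rep(c(0, 1), each = n)
  fit <- svm_train(X, y)
  expect_equal(svm_predict(fit, X), y) # 100% training accuracy
  # duplicating every training sample leaves predictions unchanged
  fit2 <- svm_train(rbind(X, X), c(y, y))
  probe <- rbind(X, X + matrix(rnorm(4 * n, 0, 0.5), 2 * n, 2))
  expect_equal(svm_predict(fit, probe), svm_predict(fit2, probe))
  expect_error(svm_train(X, rep(0, 2 * n)), "both classes")
})

test_that("confusion metrics implement the percent identities", {
  m <- confusion_metrics(c(TNS = 91, FPS = 6, FNS = 3, TPS = 25))
  expect_equal(m$accuracy, 92.8)
  expect_equal(m$sensitivity, 100 * 25 / 28)
  expect_equal(m$specificity, 100 * 91 / 97)
  m2 <- confusion_metrics(c(TNS = 92, FPS = 5, FNS = 6, TPS = 22))
  expect_equal(m2$accuracy, 91.2)
  m3 <- confusion_metrics(c(TNS = 5, FPS = 1, FNS = 0, TPS = 0))
  expect_true(is.na(m3$sensitivity))
  expect_false(m3$sensitivity_defined)
  expect_error(confusion_metrics(c(TNS = 0, FPS = 0, FNS = 0, TPS = 0)),
               "all-zero")
})

test_that("fold partitions are disjoint, exhaustive and balanced at n=125", {
  tab <- generate_feature_dataset(28, 97, 20, separation = 3, seed = 21)
  cv <- repeated_kfold_cv(tab, k = 5, repeats = 3, seed = 31)
  folds <- attr(cv, "fold_assignments")
  expect_length(folds, 3)
  for (f in folds) {
    expect_length(f, 125)
    expect_equal(unname(table(f)), rep(25L, 5L), ignore_attr = TRUE)
  }
  # distinct shuffles across repeats
  expect_false(identical(folds[[1]], folds[[2]]))
  # counts identity: TNS+FPS+FNS+TPS = n for every run
  expect_equal(cv$TNS + cv$FPS + cv$FNS + cv$TPS, rep(125, 3))
})

test_that("metric identities hold when recomputed from counts", {
  tab <- generate_feature_dataset(30, 50, 15, separation = 2, seed = 41)
  cv <- repeated_kfold_cv(tab, k = 4, repeats = 2, seed = 51)
  n <- 80
  expect_equal(cv$test_accuracy, 100 * (cv$TNS + cv$TPS) / n)
  expect_equal(cv$sensitivity, 100 * cv$TPS / (cv$TPS + cv$FNS))
  expect_equal(cv$specificity, 100 * cv$TNS / (cv$TNS + cv$FPS))
})

test_that("cross-validation is reproducible and seed-sensitive", {
  tab <- generate_feature_dataset(20, 40, 10, separation = 2, seed = 61)
  a <- repeated_kfold_cv(tab, k = 5, repeats = 2, seed = 71)
  b <- repeated_kfold_cv(tab, k = 5, repeats = 2, seed = 71)
  expect_equal(tidy(a), tidy(b))
  c <- repeated_kfold_cv(tab, k = 5, repeats = 2, seed = 72)
  expect_false(identical(attr(a, "fold_assignments"),
                         attr(c, "fold_assignments")))
})

test_that("test accuracy grows with class separation", {
  accs <- vapply(c(0.5, 2, 5), function(sep) {
    tab <- generate_feature_dataset(30, 30, 20, separation = sep, seed = 81)
    mean(repeated_kfold_cv(tab, k = 5, repeats = 2, seed = 91)$test_accuracy)
  }, numeric(1))
  expect_true(all(diff(accs) > -2)) # monotone within simulation error
  expect_gt(accs[3], accs[1])
})

test_that("combined-PCA mode runs and differs only in projection fitting", {
  tab <- generate_feature_dataset(20, 30, 12, separation = 4, seed = 101)
  cv_comb <- repeated_kfold_cv(tab, k = 5, repeats = 2,
                               pca_mode = "combined", seed = 111)
  expect_equal(nrow(cv_comb), 2)
  expect_gt(mean(cv_comb$test_accuracy), 90)
  # on null data train_only stays near the majority rate
  null_tab <- generate_feature_dataset(20, 30, 12, separation = 0,
                                       seed = 121)
  cv_null <- repeated_kfold_cv(null_tab, k = 5, repeats = 2,
                               pca_mode = "train_only", seed = 131)
  expect_lt(mean(cv_null$test_accuracy), 75)
})

test_that("degenerate cross-validation inputs error with diagnostics", {
  tab <- generate_feature_dataset(2, 60, 10, separation = 2, seed = 141)
  expect_error(repeated_kfold_cv(tab, k = 5, repeats = 1, seed = 151),
               "single-class")
  expect_error(repeated_kfold_cv(tab[, 1:10], k = 5, repeats = 1,
                                 seed = 1), "label")
})

test_that("tidy and glance summarize cv results", {
  tab <- generate_feature_dataset(20, 30, 10, separation = 3, seed = 161)
  cv <- repeated_kfold_cv(tab, k = 5, repeats = 3, seed = 171)
  td <- tidy(cv)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3)
  g <- glance(cv)
  expect_equal(g$n_runs, 3)
  expect_equal(g$mean_test_accuracy, mean(cv$test_accuracy))
  p <- autoplot(cv)
  expect_s3_class(p, "ggplot")
})
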