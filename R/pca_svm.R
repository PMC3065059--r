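#' Z-score standardization of a feature table
#'
#' Centers every feature column to mean 0 and scales to standard deviation 1
#' (population sd, i.e. divisor `n`). Constant columns carry no information
#' and are dropped with a warning. The fitted center/scale parameters are
#' attached so held-out data can be transformed identically with
#' [standardize_apply()].
#'
#' @param table data frame / tibble of numeric feature columns (a `label`
#'   column, if present, is passed through untouched).
#' @return tibble of standardized features (plus any `label` column) with
#'   attributes `center` and `scale` (named numeric vectors).
#' @export
standardize <- function(table) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0) stop("empty table")
  label <- if ("label" %in% names(table)) table[["label"]] else NULL
  X <- as.matrix(table[setdiff(names(table), "label")])
  if (!is.numeric(X) || ncol(X) == 0) stop("no numeric feature columns")
  n <- nrow(X)
  ctr <- colMeans(X)
  scl <- sqrt(colMeans(sweep(X, 2, ctr)^2)) # population sd
  keep <- scl > 0
  if (!all(keep)) {
    warning(sum(!keep), " constant column(s) dropped: ",
            paste(colnames(X)[!keep], collapse = ", "))
  }
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], `/`)
  out <- tibble::as_tibble(as.data.frame(Z))
  if (!is.null(label)) out$label <- label
  attr(out, "center") <- ctr[keep]
  attr(out, "scale") <- scl[keep]
  out
}

#' Apply previously fitted standardization parameters
#'
#' @param table data frame with the columns the parameters were fitted on.
#' @param params a standardized tibble from [standardize()] (its
#'   `center`/`scale` attributes are reused), or a list with `center` and
#'   `scale`.
#' @return standardized tibble (plus any `label` column).
#' @export
standardize_apply <- function(table, params) {
  ctr <- attr(params, "center") %||% params$center
  scl <- attr(params, "scale") %||% params$scale
  stopifnot(!is.null(ctr), !is.null(scl))
  label <- if ("label" %in% names(table)) table[["label"]] else NULL
  X <- as.matrix(table[names(ctr)])
  Z <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  out <- tibble::as_tibble(as.data.frame(Z))
  if (!is.null(label)) out$label <- label
  out
}

#' Principal components by cumulative contribution rate
#'
#' Eigendecomposition of the correlation coefficient matrix of the
#' (standardized) features. The number of retained components `k` is the
#' smallest count whose cumulative eigenvalue share — the cumulative
#' contribution rate — reaches `alpha` (default 0.98, i.e. 98%).
#'
#' @param table standardized feature table (a `label` column is ignored).
#' @param alpha contribution-rate threshold as a fraction in (0, 1].
#' @return object of class `pca_ct`: list with `loadings` (orthonormal
#'   columns), `eigenvalues` (descending), `contribution` (eigenvalue
#'   shares), `cumulative` (their cumsum), `k`, `alpha`, and `feature_names`.
#' @export
pca_fit <- function(table, alpha = 0.98) {
  stopifnot(is.data.frame(table), alpha > 0, alpha <= 1)
  X <- as.matrix(table[setdiff(names(table), "label")])
  if (nrow(X) < 2) stop("need at least 2 rows")
  R <- stats::cor(X)
  if (any(!is.finite(R))) stop("correlation matrix has non-finite entries; ",
                               "standardize() drops constant columns first")
  eig <- eigen(R, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  contrib <- ev / sum(ev)
  cum <- cumsum(contrib)
  k <- which(cum >= alpha - 1e-12)[1L]
  structure(list(loadings = eig$vectors, eigenvalues = ev,
                 contribution = contrib, cumulative = cum,
                 k = as.integer(k), alpha = alpha,
                 feature_names = colnames(X)),
            class = "pca_ct")
}

#' @export
print.pca_ct <- function(x, ...) {
  cat(sprintf(
    "PCA on the correlation matrix: %d feature(s), k = %d component(s) at alpha = %g (cumulative contribution %.2f%%)\n",
    length(x$feature_names), x$k, x$alpha, 100 * x$cumulative[x$k]))
  invisible(x)
}

#' Project a feature table onto the retained principal components
#'
#' @param model a `pca_ct` from [pca_fit()].
#' @param table table with the same feature columns the model was fitted on.
#' @param k number of components (default `model$k`).
#' @return tibble of scores `PC1..PCk` (plus any `label` column).
#' @export
pca_transform <- function(model, table, k = model$k) {
  stopifnot(inherits(model, "pca_ct"))
  label <- if ("label" %in% names(table)) table[["label"]] else NULL
  X <- as.matrix(table[model$feature_names])
  if (ncol(X) != nrow(model$loadings)) stop("feature dimension mismatch")
  S <- X %*% model$loadings[, seq_len(k), drop = FALSE]
  colnames(S) <- paste0("PC", seq_len(k))
  out <- tibble::as_tibble(as.data.frame(S))
  if (!is.null(label)) out$label <- label
  out
}

#' Train an RBF-kernel support vector machine
#'
#' Thin wrapper around a C-classification SVM with a radial basis function
#' kernel. The default `gamma` follows the `1 / (p * var(X))` convention,
#' with `p` the feature count and `var(X)` the overall variance of the
#' training matrix.
#'
#' @param features numeric matrix or data frame (no `label` column).
#' @param labels 0/1 vector, one per row; both classes must be present.
#' @param cost soft-margin cost `C` (default 1).
#' @param gamma RBF width; default `1 / (p * var(X))`.
#' @return fitted classifier (class `svm`).
#' @export
svm_train <- function(features, labels, cost = 1, gamma = NULL) {
  X <- as.matrix(features)
  y <- factor(as.integer(labels), levels = c(0L, 1L))
  if (length(unique(y[!is.na(y)])) < 2) {
    stop("training set must contain both classes")
  }
  if (is.null(gamma)) {
    v <- stats::var(as.vector(X))
    gamma <- if (is.finite(v) && v > 0) 1 / (ncol(X) * v) else 1 / ncol(X)
  }
  e1071::svm(x = X, y = y, type = "C-classification", kernel = "radial",
             cost = cost, gamma = gamma, scale = FALSE)
}

#' Predict 0/1 labels from a fitted SVM
#'
#' @param classifier result of [svm_train()].
#' @param features matrix or data frame of rows to classify.
#' @return integer vector of 0/1 predictions.
#' @export
svm_predict <- function(classifier, features) {
  as.integer(as.character(stats::predict(classifier, as.matrix(features))))
}

#' Confusion counts from truth and prediction
#'
#' @param truth,predicted 0/1 vectors of equal length.
#' @return named integer vector `c(TNS, FPS, FNS, TPS)`: true negative,
#'   false positive, false negative and true positive sample counts.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  stopifnot(length(truth) == length(predicted),
            all(truth %in% 0:1), all(predicted %in% 0:1))
  c(TNS = sum(truth == 0L & predicted == 0L),
    FPS = sum(truth == 0L & predicted == 1L),
    FNS = sum(truth == 1L & predicted == 0L),
    TPS = sum(truth == 1L & predicted == 1L))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `accuracy = 100 * (TNS + TPS) / n`, `sensitivity = 100 * TPS /
#' (TPS + FNS)`, `specificity = 100 * TNS / (TNS + FPS)`, all in percent.
#' A ratio with a zero denominator is reported as `NA` with the
#' corresponding `*_defined` flag set to `FALSE`.
#'
#' @param counts named vector or list with `TNS`, `FPS`, `FNS`, `TPS`.
#' @return tibble with one row: the three metrics (percent), their
#'   `*_defined` flags, and the four counts.
#' @export
confusion_metrics <- function(counts) {
  cnt <- as.list(counts)
  need <- c("TNS", "FPS", "FNS", "TPS")
  stopifnot(all(need %in% names(cnt)))
  tns <- as.numeric(cnt$TNS); fps <- as.numeric(cnt$FPS)
  fns <- as.numeric(cnt$FNS); tps <- as.numeric(cnt$TPS)
  stopifnot(all(c(tns, fps, fns, tps) >= 0))
  n <- tns + fps + fns + tps
  if (n == 0) stop("all-zero confusion counts")
  sens_def <- (tps + fns) > 0
  spec_def <- (tns + fps) > 0
  tibble::tibble(
    accuracy = 100 * (tns + tps) / n,
    sensitivity = if (sens_def) 100 * tps / (tps + fns) else NA_real_,
    specificity = if (spec_def) 100 * tns / (tns + fps) else NA_real_,
    sensitivity_defined = sens_def,
    specificity_defined = spec_def,
    TNS = tns, FPS = fps, FNS = fns, TPS = tps
  )
}

# split shuffled indices into k folds as evenly as possible
make_folds <- function(n, k) {
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  rep(seq_len(k), times = sizes)
}

#' Repeated k-fold cross-validation of the PCA-SVM classifier
#'
#' For each repeat, shuffles the samples with a repeat-specific seed
#' (`seed + r`), forms `k` folds as even as possible, and for every fold:
#' standardizes, reduces with PCA at contribution threshold `alpha`, trains
#' an RBF-SVM on the training folds and predicts the held-out fold.
#' Confusion counts accumulate across the `k` folds of a repeat — every
#' sample is tested exactly once per repeat — yielding one result row per
#' repeat.
#'
#' `pca_mode` controls where standardization and PCA are fitted:
#' `"train_only"` (default) fits them on the training folds only — the
#' statistically clean protocol; `"combined"` fits them on training and test
#' features pooled, replicating the original experiment's protocol (which
#' leaks test-set feature structure into the projection).
#'
#' @param table feature table; either contains a `label` column or `labels`
#'   is supplied separately.
#' @param labels optional 0/1 vector overriding the `label` column.
#' @param k number of folds (default 5).
#' @param repeats number of repeated runs (default 10).
#' @param pca_mode `"train_only"` or `"combined"`.
#' @param alpha PCA contribution threshold (default 0.98).
#' @param cost,gamma SVM hyperparameters, see [svm_train()].
#' @param seed master seed; repeat `r` uses `seed + r`.
#' @return object of class `cv_result`: a tibble with one row per repeat
#'   (`run`, `train_accuracy`, `test_accuracy`, `sensitivity`,
#'   `specificity`, `TNS`, `FPS`, `FNS`, `TPS`, `n_components` —
#'   the mean retained-component count across folds), with the per-repeat
#'   fold assignments in attribute `fold_assignments` and the call settings
#'   in attribute `settings`.
#' @export
repeated_kfold_cv <- function(table, labels = NULL, k = 5L, repeats = 10L,
                              pca_mode = c("train_only", "combined"),
                              alpha = 0.98, cost = 1, gamma = NULL,
                              seed = 1L) {
  pca_mode <- match.arg(pca_mode)
  stopifnot(is.data.frame(table), k >= 2, repeats >= 1)
  if (is.null(labels)) {
    if (!"label" %in% names(table)) stop("no `label` column and no `labels`")
    labels <- table[["label"]]
  }
  labels <- as.integer(labels)
  stopifnot(all(labels %in% 0:1), length(labels) == nrow(table))
  feats <- table[setdiff(names(table), "label")]
  n <- nrow(feats)
  if (n < k) stop("fewer samples than folds")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  fold_log <- vector("list", repeats)
  rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    perm <- sample.int(n)
    fold_of <- integer(n)
    fold_of[perm] <- make_folds(n, k)
    fold_log[[r]] <- fold_of

    truth_all <- integer(0); pred_all <- integer(0)
    train_acc <- numeric(k); kcomp <- integer(k)
    for (f in seq_len(k)) {
      te <- which(fold_of == f); tr <- which(fold_of != f)
      if (length(unique(labels[tr])) < 2) {
        stop("fold ", f, " of repeat ", r,
             " has a single-class training set (n_train = ", length(tr),
             "); use fewer folds or more samples per class")
      }
      if (pca_mode == "combined") {
        z_all <- standardize(feats)
        pca <- pca_fit(z_all, alpha = alpha)
        sc <- pca_transform(pca, z_all)
        sc_tr <- sc[tr, , drop = FALSE]; sc_te <- sc[te, , drop = FALSE]
      } else {
        z_tr <- standardize(feats[tr, , drop = FALSE])
        z_te <- standardize_apply(feats[te, , drop = FALSE], z_tr)
        pca <- pca_fit(z_tr, alpha = alpha)
        sc_tr <- pca_transform(pca, z_tr)
        sc_te <- pca_transform(pca, z_te)
      }
      kcomp[f] <- pca$k
      fit <- svm_train(sc_tr, labels[tr], cost = cost, gamma = gamma)
      train_acc[f] <- mean(svm_predict(fit, sc_tr) == labels[tr])
      pred <- svm_predict(fit, sc_te)
      truth_all <- c(truth_all, labels[te])
      pred_all <- c(pred_all, pred)
    }
    cnt <- confusion_counts(truth_all, pred_all)
    met <- confusion_metrics(cnt)
    rows[[r]] <- tibble::tibble(
      run = r,
      train_accuracy = 100 * mean(train_acc),
      test_accuracy = met$accuracy,
      sensitivity = met$sensitivity,
      specificity = met$specificity,
      TNS = cnt[["TNS"]], FPS = cnt[["FPS"]],
      FNS = cnt[["FNS"]], TPS = cnt[["TPS"]],
      n_components = mean(kcomp)
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "fold_assignments") <- fold_log
  attr(out, "settings") <- list(k = as.integer(k),
                                repeats = as.integer(repeats),
                                pca_mode = pca_mode, alpha = alpha,
                                cost = cost, gamma = gamma,
                                seed = as.integer(seed), n = n)
  class(out) <- c("cv_result", class(out))
  out
}

#' Reference cross-validation runs of the original calculus-recognition
#' experiment
#'
#' Ten 5-fold cross-validation runs (125 regions: 28 calculus, 97
#' non-calculus after exclusions) as published for the original
#' prostatic-calculus recognition experiment: per-run confusion counts
#' (`TNS`, `FPS`, `FNS`, `TPS`), average training time and accuracy, test
#' accuracy, and the reported sensitivity/specificity. Note the reported
#' per-run sensitivity and specificity are not all consistent with the
#' counts in the same column (e.g. run 1: 25/28 = 89.29 vs reported 89.5);
#' [confusion_metrics()] recomputes them from the counts.
#'
#' @return tibble with one row per run and columns `run`, `att_s`,
#'   `train_accuracy`, `test_accuracy`, `TNS`, `FPS`, `FNS`, `TPS`,
#'   `sensitivity`, `specificity`.
#' @export
cv_reference_runs <- function() {
  path <- system.file("extdata", "cv_reference_runs.csv",
                      package = "calculoscope", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path))
}
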