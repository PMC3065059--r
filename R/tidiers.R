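#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang %||%
NULL

#' Tidy a cross-validation result
#'
#' One row per repeated run with the confusion counts and the metrics
#' recomputed from them.
#'
#' @param x a `cv_result` from [repeated_kfold_cv()].
#' @param ... unused.
#' @return tibble.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Summarize a cross-validation result across repeats
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @return one-row tibble with the number of runs and the means of training
#'   accuracy, test accuracy, sensitivity and specificity (percent), plus
#'   the mean retained-component count.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    n_runs = nrow(x),
    mean_train_accuracy = mean(x$train_accuracy),
    mean_test_accuracy = mean(x$test_accuracy),
    mean_sensitivity = mean(x$sensitivity, na.rm = TRUE),
    mean_specificity = mean(x$specificity, na.rm = TRUE),
    mean_n_components = mean(x$n_components)
  )
}

#' Tidy a fitted PCA model
#'
#' @param x a `pca_ct` from [pca_fit()].
#' @param ... unused.
#' @return tibble with one row per component: `component`, `eigenvalue`,
#'   `contribution` (share of total variance), `cumulative`, and `retained`.
#' @method tidy pca_ct
#' @export
tidy.pca_ct <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    contribution = x$contribution,
    cumulative = x$cumulative,
    retained = seq_along(x$eigenvalues) <= x$k
  )
}

#' Summarize a fitted PCA model
#'
#' @param x a `pca_ct`.
#' @param ... unused.
#' @return one-row tibble with `n_features`, `k`, `alpha` and the cumulative
#'   contribution of the retained components.
#' @method glance pca_ct
#' @export
glance.pca_ct <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_names),
    k = x$k,
    alpha = x$alpha,
    cumulative_contribution = x$cumulative[x$k]
  )
}

#' @export
print.cv_result <- function(x, ...) {
  s <- attr(x, "settings")
  cat(sprintf("%d x %d-fold cross-validation (pca_mode = %s, alpha = %g)\n",
              s$repeats, s$k, s$pca_mode, s$alpha))
  print(tidy(x), ...)
  g <- glance(x)
  cat(sprintf(
    "mean: train %.2f%%, test %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
    g$mean_train_accuracy, g$mean_test_accuracy,
    g$mean_sensitivity, g$mean_specificity))
  invisible(x)
}

#' Plot per-run cross-validation metrics
#'
#' Test accuracy, sensitivity and specificity per repeated run, with
#' run-mean reference lines.
#'
#' @param object a `cv_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tidy(object)[c("run", "test_accuracy", "sensitivity", "specificity")],
    -"run", names_to = "metric", values_to = "percent")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$run, y = .data$percent,
                                     color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(long$run)) +
    ggplot2::labs(x = "cross-validation run", y = "percent",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Scree / cumulative-contribution plot of a fitted PCA
#'
#' @param object a `pca_ct`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pca_ct
#' @export
autoplot.pca_ct <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$contribution,
                                   fill = .data$retained)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative)) +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = 2) +
    ggplot2::labs(x = "principal component",
                  y = "contribution rate (fraction)",
                  fill = "retained") +
    ggplot2::theme_minimal()
}

#' Plot a phantom with its ground-truth outlines
#'
#' Gray scene as a raster with lumen and calculus masks overlaid.
#'
#' @param object a `phantom` from [generate_phantom()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot phantom
#' @export
autoplot.phantom <- function(object, ...) {
  d <- tibble::tibble(
    row = as.vector(row(object$gray)),
    col = as.vector(col(object$gray)),
    gray = as.vector(object$gray),
    lumen = as.vector(object$lumen_mask),
    calculus = as.vector(object$calculus_mask)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$gray)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::geom_point(data = dplyr::filter(d, .data$calculus),
                        color = "red", size = 0.1, alpha = 0.2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "gray") +
    ggplot2::theme_void()
}

#' @importFrom rlang .data
NULL
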