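#' Read a histology image as a 0-255 array
#'
#' Reads PNG/TIFF/JPEG via EBImage and returns a `height x width x 3`
#' numeric array on the 0-255 scale (gray images are replicated across the
#' three channels).
#'
#' @param path image file path.
#' @return numeric array `H x W x 3`.
#' @export
read_histology_image <- function(path) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  # EBImage stores x (columns) first; transpose into (row, col)
  if (length(dim(dat)) == 2) {
    m <- t(dat)
    dat <- array(rep(m, 3L), c(dim(m), 3L))
  } else {
    dat <- aperm(dat[, , 1:3, drop = FALSE], c(2, 1, 3))
  }
  dat * 255
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask logical matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(mask * 1)), path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline. Unknown names in
#' `...` are rejected rather than silently ignored.
#'
#' @param window local-entropy window (odd pixels).
#' @param compose_mode channel-entropy composition rule.
#' @param morph a [morph_config()].
#' @param levels GLCM quantization levels.
#' @param d GLCM pair distance (pixels).
#' @param alpha PCA contribution threshold (fraction).
#' @param cost,gamma SVM hyperparameters.
#' @param folds,repeats cross-validation protocol.
#' @param pca_mode `"train_only"` or `"combined"`.
#' @param seed master seed.
#' @param ... must be empty (typo guard).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(window = 9L, compose_mode = "mean",
                            morph = morph_config(), levels = 16L, d = 1L,
                            alpha = 0.98, cost = 1, gamma = NULL,
                            folds = 5L, repeats = 10L,
                            pca_mode = "train_only", seed = 1L, ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown configuration field(s): ",
         paste(names(extra), collapse = ", "))
  }
  structure(list(window = as.integer(window), compose_mode = compose_mode,
                 morph = morph, levels = as.integer(levels),
                 d = as.integer(d), alpha = alpha, cost = cost,
                 gamma = gamma, folds = as.integer(folds),
                 repeats = as.integer(repeats), pca_mode = pca_mode,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full calculus-recognition pipeline
#'
#' For every image: lumen extraction (entropy + Otsu + morphology),
#' suspicious-region segmentation, and the 70-feature texture descriptor per
#' region. If region labels are supplied, finishes with repeated k-fold
#' cross-validation of the PCA-SVM classifier. Unreadable images are
#' recorded as per-file errors and the run continues.
#'
#' @param images character vector of image paths, or a list of in-memory
#'   `H x W x 3` arrays / `phantom` objects.
#' @param labels optional 0/1 vector, one per extracted region (in region
#'   order of the returned feature table).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, masks, the feature table
#'   and the CV summary are persisted there.
#' @return list of class `pipeline_report`: `regions` (per-image inventory
#'   tibble), `features` (feature table with `image_id` and `region_id`),
#'   `cv` (a `cv_result`, or `NULL` when no labels), `errors` (per-file
#'   error messages), and `config`.
#' @export
run_pipeline <- function(images, labels = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  if (length(images) == 0) stop("need at least one image")
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  ids <- names(images) %||% as.character(seq_along(images))
  if (is.character(images)) ids <- basename(images)

  feats <- list(); inventory <- list(); errors <- list()
  for (i in seq_along(images)) {
    id <- ids[[i]]
    res <- tryCatch({
      img <- images[[i]]
      if (inherits(img, "phantom")) img <- img$image
      if (is.character(img)) {
        img <- suppressWarnings(read_histology_image(img))
      }
      gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
      lum <- extract_lumina(img, window = config$window,
                            compose_mode = config$compose_mode,
                            morph = config$morph)
      regs <- segment_suspicious_regions(gray, lum$lumen_mask,
                                         morph = config$morph)
      ft <- region_features(regs, levels = config$levels, d = config$d,
                            image_id = id)
      inv <- tibble::tibble(
        image_id = id,
        n_lumina = lum$labels$n_regions,
        n_regions = length(regs)
      )
      if (!is.null(out_dir)) {
        write_mask_png(lum$lumen_mask,
                       file.path(out_dir, paste0(id, "_lumen.png")))
      }
      list(ft = ft, inv = inv)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[id]] <- conditionMessage(res)
    } else {
      feats[[id]] <- res$ft
      inventory[[id]] <- res$inv
    }
  }
  if (!length(feats)) stop("no image could be processed; first error: ",
                           errors[[1]])
  features <- dplyr::bind_rows(feats)
  inventory <- dplyr::bind_rows(inventory)

  cv <- NULL
  if (!is.null(labels) && nrow(features) > 0) {
    if (length(labels) != nrow(features)) {
      stop("`labels` must have one value per extracted region (",
           nrow(features), ")")
    }
    cv <- repeated_kfold_cv(
      features[setdiff(names(features), c("image_id", "region_id"))],
      labels = labels, k = config$folds, repeats = config$repeats,
      pca_mode = config$pca_mode, alpha = config$alpha,
      cost = config$cost, gamma = config$gamma, seed = config$seed)
  } else if (is.null(labels)) {
    message("no region labels supplied; cross-validation stage skipped")
  }

  if (!is.null(out_dir)) {
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    if (!is.null(cv)) {
      utils::write.csv(tidy(cv), file.path(out_dir, "cv_runs.csv"),
                       row.names = FALSE)
    }
  }
  structure(list(regions = inventory, features = features, cv = cv,
                 errors = errors, config = config),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline report: %d image(s), %d region(s)\n",
              nrow(x$regions), nrow(x$features)))
  if (length(x$errors)) {
    cat("errors:\n")
    for (nm in names(x$errors)) cat("  ", nm, ": ", x$errors[[nm]], "\n",
                                    sep = "")
  }
  if (!is.null(x$cv)) {
    g <- glance(x$cv)
    cat(sprintf(
      "cross-validation mean: test %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
      g$mean_test_accuracy, g$mean_sensitivity, g$mean_specificity))
  }
  invisible(x)
}
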