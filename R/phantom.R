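#' Phantom configuration
#'
#' Geometry and noise settings for the synthetic histology phantom: a
#' textured stroma background, bright near-constant elliptical gland lumina,
#' and round calculus bodies with a concentric "tree-ring" lamellar texture
#' placed inside some of the lumina. Intensities are 8-bit (0-255): stroma
#' around 120 with heavy bounded (uniform) texture noise, lumina around 230
#' with faint noise, calculus rings oscillating roughly 100-220 — so the entropy
#' contrast between homogeneous lumina and textured stroma mirrors real
#' H&E sections.
#'
#' @param image_height,image_width raster size in pixels.
#' @param n_lumina number of elliptical lumina.
#' @param n_calculi number of calculi (`<= n_lumina`; one per chosen lumen).
#' @param lumen_axis_range min/max semi-axis of the lumen ellipses (pixels).
#' @param calculus_radius_range min/max calculus radius (pixels).
#' @param n_rings full texture periods from calculus center to rim.
#' @param stroma_noise_sd stroma texture noise standard deviation (intensity
#'   units; the noise itself is bounded uniform).
#' @param seed integer; fully determines the phantom.
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(image_height = 256L, image_width = 256L,
                           n_lumina = 4L, n_calculi = 2L,
                           lumen_axis_range = c(22L, 34L),
                           calculus_radius_range = c(7L, 11L),
                           n_rings = 4L, stroma_noise_sd = 29,
                           seed = 1L) {
  stopifnot(image_height >= 32, image_width >= 32,
            n_lumina >= 0, n_calculi >= 0, n_calculi <= n_lumina,
            length(lumen_axis_range) == 2, all(lumen_axis_range > 0),
            lumen_axis_range[1] <= lumen_axis_range[2],
            length(calculus_radius_range) == 2,
            all(calculus_radius_range > 0),
            calculus_radius_range[1] <= calculus_radius_range[2],
            n_rings >= 1, stroma_noise_sd >= 0)
  if (2 * lumen_axis_range[2] + 4 > min(image_height, image_width)) {
    stop("lumina do not fit inside the image")
  }
  structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    n_lumina = as.integer(n_lumina), n_calculi = as.integer(n_calculi),
    lumen_axis_range = as.numeric(lumen_axis_range),
    calculus_radius_range = as.numeric(calculus_radius_range),
    n_rings = as.integer(n_rings), stroma_noise_sd = stroma_noise_sd,
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Concentric "tree-ring" texture patch
#'
#' Square patch of side `2 * radius + 1` whose intensity oscillates
#' periodically with distance from the center — `n_rings` full periods from
#' center to rim, phase 0 at the center (center pixel = `base + amplitude`) —
#' emulating the concentric lamellar texture of corpora amylacea. Pixels
#' outside the inscribed disk are constant at `base`.
#'
#' @param radius disk radius in pixels (>= 1, and >= `n_rings`).
#' @param n_rings number of full rings (>= 1).
#' @param base base intensity.
#' @param amplitude oscillation amplitude (>= 0).
#' @return numeric matrix of side `2 * radius + 1`.
#' @export
generate_concentric_texture <- function(radius, n_rings = 3L, base = 160,
                                        amplitude = 60) {
  if (!is.finite(radius) || radius < 1) stop("`radius` must be positive")
  stopifnot(n_rings >= 1, radius >= n_rings, amplitude >= 0)
  side <- 2L * as.integer(radius) + 1L
  ax <- seq_len(side) - (radius + 1)
  rho <- sqrt(outer(ax^2, ax^2, `+`))
  patch <- matrix(base, side, side)
  inside <- rho <= radius
  patch[inside] <- base + amplitude * cos(2 * pi * n_rings * rho[inside] /
                                            radius)
  patch
}

# logical mask of an axis-aligned ellipse
ellipse_mask <- function(h, w, cr, cc, a, b) {
  rr <- matrix(seq_len(h), h, w)
  cc_ <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((rr - cr) / a)^2 + ((cc_ - cc) / b)^2 <= 1
}

#' Generate a synthetic histology phantom with ground truth
#'
#' Builds the gray scene (textured stroma, bright elliptical lumina,
#' concentric-ring calculi inside `n_calculi` of the lumina), tints it into
#' three channels for an H&E-like appearance, and returns the image together
#' with ground-truth masks. Lumen placement uses rejection sampling of
#' non-overlapping ellipses; an impossible geometry errors out after a fixed
#' retry budget rather than silently degrading. The same configuration and
#' seed always reproduce the phantom bit for bit.
#'
#' @param config a [phantom_config()].
#' @return list of class `phantom` with `image` (`H x W x 3` array, 0-255),
#'   `gray` (mean of channels), `lumen_mask`, `calculus_mask` (logical
#'   matrices; every calculus pixel lies inside a lumen), `calculus_centers`
#'   (matrix of (row, col)), `calculus_radii`, and `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  h <- config$image_height; w <- config$image_width
  # bounded uniform texture noise with the requested sd: dense fibrous
  # texture has no extreme outliers, and heavy tails would seed spurious
  # low-entropy pockets that violate the segmentation premise
  amp <- sqrt(3) * config$stroma_noise_sd
  gray <- 120 + matrix(stats::runif(h * w, -amp, amp), h, w)

  lumen_mask <- matrix(FALSE, h, w)
  calculus_mask <- matrix(FALSE, h, w)
  centers <- matrix(numeric(0), 0, 2,
                    dimnames = list(NULL, c("row", "col")))
  radii <- numeric(0)

  placed <- list()
  for (k in seq_len(config$n_lumina)) {
    ok <- FALSE
    for (try in seq_len(200L)) {
      a <- stats::runif(1, config$lumen_axis_range[1],
                        config$lumen_axis_range[2])
      b <- stats::runif(1, config$lumen_axis_range[1],
                        config$lumen_axis_range[2])
      margin <- max(a, b) + 3
      cr <- stats::runif(1, margin, h - margin)
      cc <- stats::runif(1, margin, w - margin)
      # center-distance separation with a 4 px gap keeps lumina disjoint
      clear <- all(vapply(placed, function(p) {
        sqrt((p$cr - cr)^2 + (p$cc - cc)^2) >
          max(p$a, p$b) + max(a, b) + 4
      }, logical(1)))
      if (clear) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place non-overlapping lumina; ",
                  "reduce n_lumina or lumen_axis_range")
    placed[[k]] <- list(cr = cr, cc = cc, a = a, b = b)
    em <- ellipse_mask(h, w, cr, cc, a, b)
    lumen_mask <- lumen_mask | em
    gray[em] <- 230 + stats::rnorm(sum(em), 0, 2)
  }

  # calculi go into the first n_calculi lumina (placement order is random)
  for (k in seq_len(config$n_calculi)) {
    p <- placed[[k]]
    rmax <- min(config$calculus_radius_range[2], 0.6 * min(p$a, p$b))
    rmin <- min(config$calculus_radius_range[1], rmax)
    r <- floor(stats::runif(1, rmin, rmax + 1e-9))
    r <- max(r, config$n_rings)
    patch <- generate_concentric_texture(r, config$n_rings,
                                         base = 160, amplitude = 60)
    cr <- round(p$cr); cc <- round(p$cc)
    side <- 2L * r + 1L
    rows <- (cr - r):(cr + r); cols <- (cc - r):(cc + r)
    ax <- seq_len(side) - (r + 1)
    disk <- sqrt(outer(ax^2, ax^2, `+`)) <= r
    sub <- gray[rows, cols]
    sub[disk] <- patch[disk] + stats::rnorm(sum(disk), 0, 2)
    gray[rows, cols] <- sub
    calculus_mask[rows, cols] <- calculus_mask[rows, cols] | disk
    centers <- rbind(centers, c(cr, cc))
    radii <- c(radii, r)
  }
  if (any(calculus_mask & !lumen_mask)) {
    stop("internal error: calculus placed outside its lumen")
  }

  gray <- pmin(pmax(gray, 0), 255)
  # H&E-ish tint: pinkish stroma, near-white lumina
  img <- array(0, c(h, w, 3L))
  img[, , 1L] <- pmin(gray * 1.06, 255)
  img[, , 2L] <- gray * 0.88
  img[, , 3L] <- gray * 0.97

  structure(list(image = img, gray = gray,
                 lumen_mask = lumen_mask, calculus_mask = calculus_mask,
                 calculus_centers = centers, calculus_radii = radii,
                 config = config),
            class = "phantom")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Synthetic labeled feature table
#'
#' Draws two multivariate-Gaussian classes with unit within-class variance:
#' the first `n_informative` features of the positive class are shifted by
#' `separation` standard deviations, and the remaining features are
#' correlated nuisance dimensions built from shared latent factors (so
#' principal-component reduction has redundancy to remove). Column names are
#' `f01..fNN` plus a `label` column with values 0/1.
#'
#' @param n_pos,n_neg class sizes (>= 1); positives are labeled 1.
#' @param n_features total feature count (default 70).
#' @param separation mean shift, in within-class sd units, on each
#'   informative feature.
#' @param n_informative number of shifted features (default
#'   `max(1, round(n_features / 7))`).
#' @param seed integer seed.
#' @return tibble with `n_pos + n_neg` rows (positives first) and
#'   `n_features + 1` columns.
#' @export
generate_feature_dataset <- function(n_pos, n_neg, n_features = 70L,
                                     separation = 3,
                                     n_informative = NULL, seed = 1L) {
  stopifnot(n_pos >= 1, n_neg >= 1, separation >= 0)
  if (n_features < 1) stop("`n_features` must be >= 1")
  if (is.null(n_informative)) {
    n_informative <- max(1L, round(n_features / 7))
  }
  n_informative <- min(as.integer(n_informative), as.integer(n_features))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  n <- n_pos + n_neg
  label <- c(rep(1L, n_pos), rep(0L, n_neg))
  X <- matrix(stats::rnorm(n * n_features), n, n_features)
  # informative block: mean shift on the positive class
  X[label == 1L, seq_len(n_informative)] <-
    X[label == 1L, seq_len(n_informative), drop = FALSE] + separation
  # nuisance block: latent-factor mixing induces correlation, rescaled back
  # to unit variance so no feature dominates by scale
  n_nuis <- n_features - n_informative
  if (n_nuis > 0) {
    n_latent <- max(2L, min(5L, n_nuis))
    Z <- matrix(stats::rnorm(n * n_latent), n, n_latent)
    W <- matrix(stats::rnorm(n_latent * n_nuis), n_latent, n_nuis)
    mix <- Z %*% W + 0.5 * X[, n_informative + seq_len(n_nuis), drop = FALSE]
    sc <- sqrt(colSums(W^2) + 0.25)
    X[, n_informative + seq_len(n_nuis)] <- sweep(mix, 2, sc, `/`)
  }
  colnames(X) <- sprintf("f%02d", seq_len(n_features))
  out <- tibble::as_tibble(as.data.frame(X))
  out$label <- label
  out
}
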