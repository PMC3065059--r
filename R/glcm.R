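#' Uniform gray-level quantization of a patch
#'
#' Maps the patch's own intensity range uniformly onto integer levels
#' `0..levels-1`. A constant patch quantizes to all zeros.
#'
#' @param patch numeric matrix.
#' @param levels number of gray levels `L` (>= 2).
#' @param mask optional logical matrix; when given, the range is taken over
#'   masked pixels only (background never stretches the scale).
#' @return integer matrix of levels with attribute `levels`.
#' @export
quantize_gray <- function(patch, levels = 16L, mask = NULL) {
  stopifnot(is.matrix(patch), levels >= 2)
  vals <- if (is.null(mask)) patch else patch[mask]
  lo <- min(vals); hi <- max(vals)
  if (hi <= lo) {
    q <- matrix(0L, nrow(patch), ncol(patch))
  } else {
    q <- floor((patch - lo) / (hi - lo) * levels)
    q[q >= levels] <- levels - 1L
    q[q < 0L] <- 0L
    mode(q) <- "integer"
  }
  attr(q, "levels") <- as.integer(levels)
  q
}

# (row, col) offsets for the four basic directions at distance d
glcm_offset <- function(theta, d) {
  switch(as.character(theta),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d),
    stop("`theta` must be one of 0, 45, 90, 135")
  )
}

#' Gray-level co-occurrence matrix for one direction
#'
#' Accumulates ordered co-occurrence counts `C[i, j]` over pixel pairs
#' `(p, p + offset)` where the offset is `(0,+d)` for 0 degrees, `(-d,+d)`
#' for 45, `(-d,0)` for 90 and `(-d,-d)` for 135 (rows increase downward).
#' Both pixels of a pair must lie inside the mask, so background never
#' contaminates the texture statistics. The matrix is ordered
#' (non-symmetric) unless `symmetric = TRUE`.
#'
#' @param patch integer matrix of quantized levels `0..levels-1`, as from
#'   [quantize_gray()].
#' @param theta direction in degrees: 0, 45, 90 or 135.
#' @param d pair distance in pixels (>= 1).
#' @param mask optional logical matrix (default: all pixels).
#' @param levels number of gray levels; defaults to the `levels` attribute of
#'   `patch`.
#' @param symmetric also count each pair in the reverse order.
#' @return `levels x levels` numeric count matrix of class `glcm` with
#'   attributes `theta`, `d`, `levels`, `normalized = FALSE`.
#' @export
glcm <- function(patch, theta, d = 1L, mask = NULL, levels = NULL,
                 symmetric = FALSE) {
  stopifnot(is.matrix(patch), d >= 1)
  if (is.null(levels)) levels <- attr(patch, "levels")
  if (is.null(levels)) levels <- max(patch) + 1L
  levels <- as.integer(levels)
  if (any(patch < 0L | patch >= levels)) {
    stop("patch values must lie in 0..levels-1")
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(patch), ncol(patch))
  stopifnot(all(dim(mask) == dim(patch)))
  off <- glcm_offset(theta, as.integer(d))
  nr <- nrow(patch); nc <- ncol(patch)
  # source window such that source + offset stays in bounds
  r1 <- max(1L, 1L - off[1L]); r2 <- min(nr, nr - off[1L])
  c1 <- max(1L, 1L - off[2L]); c2 <- min(nc, nc - off[2L])
  counts <- matrix(0, levels, levels)
  if (r1 <= r2 && c1 <= c2) {
    src_r <- r1:r2; src_c <- c1:c2
    dst_r <- src_r + off[1L]; dst_c <- src_c + off[2L]
    ok <- mask[src_r, src_c, drop = FALSE] &
      mask[dst_r, dst_c, drop = FALSE]
    if (any(ok)) {
      i <- patch[src_r, src_c, drop = FALSE][ok]
      j <- patch[dst_r, dst_c, drop = FALSE][ok]
      tab <- tabulate(i * levels + j + 1L, nbins = levels * levels)
      counts <- counts + matrix(tab, levels, levels, byrow = TRUE)
      if (symmetric) counts <- counts + t(counts)
    }
  }
  if (sum(counts) == 0) {
    stop("no valid pixel pairs for this direction (mask or patch too small)")
  }
  structure(counts, class = c("glcm", class(counts)),
            theta = theta, d = as.integer(d), levels = levels,
            normalized = FALSE)
}

#' Mean of the four directional co-occurrence matrices
#'
#' Element-wise mean of the raw count matrices for 0, 45, 90 and 135 degrees,
#' forming the fifth, direction-averaged matrix.
#'
#' @param four list of four `glcm` objects with identical level count.
#' @return a `glcm` with `theta = "mean"`.
#' @export
mean_glcm <- function(four) {
  stopifnot(length(four) == 4)
  L <- unique(vapply(four, function(m) attr(m, "levels"), integer(1)))
  if (length(L) != 1) stop("all four matrices must share the same levels")
  m <- Reduce(`+`, lapply(four, unclass)) / 4
  structure(m, class = c("glcm", class(m)), theta = "mean",
            d = attr(four[[1L]], "d"), levels = L, normalized = FALSE)
}

#' Normalize a co-occurrence matrix to probabilities
#'
#' Divides by the total count so entries sum to 1; idempotent.
#'
#' @param m a `glcm` (or bare matrix).
#' @return normalized `glcm` with attribute `normalized = TRUE`.
#' @export
normalize_glcm <- function(m) {
  s <- sum(m)
  if (s <= 0) stop("cannot normalize an all-zero matrix")
  out <- unclass(m) / s
  structure(out, class = c("glcm", class(out)),
            theta = attr(m, "theta"), d = attr(m, "d"),
            levels = if (is.null(attr(m, "levels"))) nrow(out)
                     else attr(m, "levels"),
            normalized = TRUE)
}

#' The 14 Haralick texture statistics of a normalized GLCM
#'
#' Computes, in this fixed order: energy, contrast, correlation, entropy,
#' variance (sum of squares about the grand mean index), sum average,
#' sum variance, homogeneity (inverse difference moment), difference
#' variance, sum entropy, difference entropy, cluster shade, cluster
#' prominence, and maximum probability. Logarithms are base 2 with the
#' convention `0 * log(0) = 0`; when either marginal standard deviation is
#' zero the correlation is defined as 0.
#'
#' @param p normalized `glcm` (entries sum to 1).
#' @return named numeric vector of length 14.
#' @export
haralick_features <- function(p) {
  if (abs(sum(p) - 1) > 1e-8) {
    stop("`p` must be normalized (sum to 1); see normalize_glcm()")
  }
  p <- unclass(p)
  L <- nrow(p)
  lev <- seq_len(L) - 1L
  i <- matrix(lev, L, L)        # row index (first pixel level)
  j <- matrix(lev, L, L, byrow = TRUE)

  px <- rowSums(p); py <- colSums(p)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sdx <- sqrt(sum((lev - mux)^2 * px))
  sdy <- sqrt(sum((lev - muy)^2 * py))

  # distributions of i+j (support 0..2L-2) and |i-j| (support 0..L-1)
  ks <- 0:(2L * L - 2L)
  pxy_sum <- vapply(ks, function(k) sum(p[(i + j) == k]), numeric(1))
  kd <- 0:(L - 1L)
  pxy_diff <- vapply(kd, function(k) sum(p[abs(i - j) == k]), numeric(1))

  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  sa <- sum(ks * pxy_sum)
  da <- sum(kd * pxy_diff)
  mu_grand <- (mux + muy) / 2

  corr <- if (sdx == 0 || sdy == 0) 0 else
    (sum(i * j * p) - mux * muy) / (sdx * sdy)

  c(
    energy = sum(p^2),
    contrast = sum((i - j)^2 * p),
    correlation = corr,
    entropy = ent(p),
    # symmetric in the two coordinates, so a transposed (pair-reversed)
    # matrix scores identically; equals the classic definition when p is
    # symmetric
    variance = sum(((i - mu_grand)^2 + (j - mu_grand)^2) / 2 * p),
    sum_average = sa,
    sum_variance = sum((ks - sa)^2 * pxy_sum),
    homogeneity = sum(p / (1 + (i - j)^2)),
    difference_variance = sum((kd - da)^2 * pxy_diff),
    sum_entropy = ent(pxy_sum),
    difference_entropy = ent(pxy_diff),
    cluster_shade = sum((i + j - mux - muy)^3 * p),
    cluster_prominence = sum((i + j - mux - muy)^4 * p),
    max_probability = max(p)
  )
}

glcm_direction_tags <- c("d0", "d45", "d90", "d135", "mean")

#' 70-dimensional texture descriptor of a suspicious region
#'
#' Quantizes the region's gray patch, accumulates the four directional
#' co-occurrence matrices at distance `d` plus their mean as a fifth
#' direction, normalizes each, and evaluates the 14 Haralick statistics on
#' every one: 14 statistics x 5 directions = 70 ordered features. Names
#' follow `<feature>_<direction>` with directions `d0, d45, d90, d135, mean`,
#' grouped direction-major.
#'
#' @param region a `region` (list with `patch` and `mask`), or a bare gray
#'   matrix (full mask assumed).
#' @param levels quantization levels, default 16.
#' @param d pair distance in pixels, default 1.
#' @return named numeric vector of length 70.
#' @export
region_feature_vector <- function(region, levels = 16L, d = 1L) {
  if (is.matrix(region)) {
    region <- list(patch = region,
                   mask = matrix(TRUE, nrow(region), ncol(region)))
  }
  stopifnot(is.list(region), is.matrix(region$patch), is.matrix(region$mask))
  q <- quantize_gray(region$patch, levels = levels, mask = region$mask)
  four <- lapply(c(0, 45, 90, 135), function(th) {
    glcm(q, theta = th, d = d, mask = region$mask, levels = levels)
  })
  mats <- c(four, list(mean_glcm(four)))
  out <- unlist(lapply(seq_along(mats), function(k) {
    f <- haralick_features(normalize_glcm(mats[[k]]))
    names(f) <- paste0(names(f), "_", glcm_direction_tags[k])
    f
  }))
  stopifnot(length(out) == 70L)
  out
}

#' Texture feature table for a list of regions
#'
#' @param regions list of `region` objects (see
#'   [segment_suspicious_regions()]).
#' @param levels,d passed to [region_feature_vector()].
#' @param image_id optional identifier column value.
#' @return tibble with `region_id` (and `image_id` if given) plus 70 feature
#'   columns; zero-row tibble for an empty list.
#' @export
region_features <- function(regions, levels = 16L, d = 1L, image_id = NULL) {
  rows <- purrr::map(seq_along(regions), function(k) {
    v <- region_feature_vector(regions[[k]], levels = levels, d = d)
    tibble::tibble(region_id = k, !!!as.list(v))
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    proto <- region_feature_vector(matrix(rep(0:15, 16), 16, 16),
                                   levels = levels, d = d)
    tibble::as_tibble(c(list(region_id = integer()),
                        lapply(as.list(proto), function(x) double())))
  }
  if (!is.null(image_id)) {
    out <- dplyr::mutate(out, image_id = image_id, .before = 1L)
  }
  out
}
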