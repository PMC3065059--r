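#' Gray-value local entropy transform
#'
#' Replaces every pixel by the entropy of the *normalized gray values* in its
#' `window` x `window` neighborhood: the window values `f` are turned into a
#' probability distribution `p = f / sum(f)` and the pixel receives
#' `H = -sum(p * log2(p))`. Texturally homogeneous areas (glandular lumina)
#' score close to the upper bound `log2(window^2)` and nearly uniformly, while
#' stroma with nuclei and fibrous texture produces lower, spatially varying
#' entropy; thresholding the entropy image therefore separates lumina from
#' stroma. Note this is the entropy of normalized gray values, not of the
#' gray-level histogram.
#'
#' The transform requires strictly positive gray values, so `offset` (default
#' 1) is added to every pixel first; a global positive scaling of the input
#' leaves the result unchanged. Borders are handled by reflection padding.
#'
#' @param image numeric matrix of intensities (any non-negative scale;
#'   8-bit 0-255 is typical).
#' @param window odd window side length in pixels, >= 3.
#' @param offset value added to every pixel to enforce positivity.
#' @return numeric matrix of local entropies in bits, same shape as `image`,
#'   with attribute `window`. Values lie in `[0, log2(window^2)]`.
#' @export
#' @examples
#' img <- matrix(runif(400, 0, 255), 20, 20)
#' H <- local_entropy(img, window = 5)
#' range(H) # within [0, log2(25)]
local_entropy <- function(image, window = 9L, offset = 1) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (!is.finite(window) || window %% 2 != 1 || window < 3 ||
      window > min(dim(image))) {
    stop("`window` must be odd, >= 3 and <= min(dim(image))")
  }
  f <- image + offset
  if (any(!is.finite(f))) stop("image contains non-finite values")
  if (any(f <= 0)) stop("all gray values must be > 0 after `offset`")

  r <- (window - 1L) / 2L
  fp <- pad_reflect(f, r)
  flp <- fp * log2(fp)
  s <- box_sum(fp, window)    # sum of f over each window
  t <- box_sum(flp, window)   # sum of f*log2(f) over each window
  # -sum(p log2 p) with p = f/S collapses to log2(S) - T/S
  H <- log2(s) - t / s
  hmax <- log2(window^2)
  H[H < 0] <- 0
  H[H > hmax] <- hmax
  attr(H, "window") <- as.integer(window)
  H
}

# reflection padding by r pixels on each side (edge row/col not duplicated)
pad_reflect <- function(m, r) {
  if (r == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(r < nr, r < nc)
  ri <- c((r + 1L):2L, 1L:nr, (nr - 1L):(nr - r))
  ci <- c((r + 1L):2L, 1L:nc, (nc - 1L):(nc - r))
  m[ri, ci]
}

# sliding-window sum over a padded matrix; returns the unpadded-size result.
# Separable: cumulative sums along rows then columns.
box_sum <- function(padded, window) {
  run_sum <- function(m, w) {
    cs <- apply(m, 2, cumsum)
    if (!is.matrix(cs)) cs <- matrix(cs, nrow = nrow(m))
    rbind(cs[w, , drop = FALSE],
          cs[(w + 1L):nrow(m), , drop = FALSE] -
            cs[1L:(nrow(m) - w), , drop = FALSE])
  }
  out <- run_sum(padded, window)
  t(run_sum(t(out), window))
}

#' Per-channel local entropy of a color image, composed into one map
#'
#' Transforms each of the three channels into a gray image, applies
#' [local_entropy()] to each, and combines the three entropy maps pixel-wise.
#'
#' @param image numeric array `height x width x 3`, or a matrix (treated as a
#'   single channel).
#' @param window odd window side length passed to [local_entropy()].
#' @param mode pixel-wise combination rule: `"mean"` (default), `"min"` or
#'   `"max"`.
#' @param offset positivity offset passed to [local_entropy()].
#' @return numeric entropy matrix with attribute `window`.
#' @export
channel_entropy_compose <- function(image, window = 9L,
                                    mode = c("mean", "min", "max"),
                                    offset = 1) {
  mode <- match.arg(mode)
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  d <- dim(image)
  if (length(d) != 3 || !(d[3] %in% c(1L, 3L))) {
    stop("`image` must be a matrix or a height x width x 3 array")
  }
  maps <- lapply(seq_len(d[3]), function(ch) {
    local_entropy(image[, , ch], window = window, offset = offset)
  })
  out <- switch(mode,
    mean = Reduce(`+`, maps) / length(maps),
    min  = Reduce(pmin, maps),
    max  = Reduce(pmax, maps)
  )
  attr(out, "window") <- as.integer(window)
  out
}

#' Otsu threshold by exhaustive between-class variance maximization
#'
#' Quantizes the image to `n_bins` levels and scans every cut `T`, maximizing
#' the between-class variance
#' `g = omega0 * (mu0 - mu)^2 + omega1 * (mu1 - mu)^2`, where `omega0, mu0`
#' are the probability and mean of the class at or below the cut and
#' `omega1, mu1` those above. Ties are broken by the lowest threshold.
#'
#' @param image numeric matrix (an intensity or entropy image).
#' @param n_bins number of quantization levels (default 256).
#' @return an object of class `otsu_result`: a list with `threshold` (on the
#'   original intensity scale; "below" means `<= threshold`), `omega0`,
#'   `omega1`, `mu0`, `mu1`, `mu`, and `g` (the maximized between-class
#'   variance, on the original scale).
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  x <- as.numeric(image)
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("image has no finite pixels")
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stop("constant image: no threshold separates two classes")

  # uniform bins over [lo, hi]; bin index 0..n_bins-1
  q <- floor((x - lo) / (hi - lo) * n_bins)
  q[q >= n_bins] <- n_bins - 1L
  counts <- tabulate(q + 1L, nbins = n_bins)
  p <- counts / length(x)
  # per-bin first moment from the actual pixel values, so class means are
  # exact gray means rather than bin-center approximations
  bin_sum <- numeric(n_bins)
  rs <- rowsum(x, q)
  bin_sum[as.integer(rownames(rs)) + 1L] <- rs[, 1L]
  w0 <- cumsum(p)
  m0c <- cumsum(bin_sum) / length(x)  # cumulative first moment
  mu <- m0c[n_bins]
  # cut after bin t (t = 1..n_bins-1): class0 = bins 1..t
  t_idx <- seq_len(n_bins - 1L)
  om0 <- w0[t_idx]; om1 <- 1 - om0
  valid <- om0 > 0 & om1 > 0
  g <- rep(-Inf, n_bins - 1L)
  mu0 <- m0c[t_idx] / om0
  mu1 <- (mu - m0c[t_idx]) / om1
  g[valid] <- om0[valid] * (mu0[valid] - mu)^2 +
    om1[valid] * (mu1[valid] - mu)^2
  if (!any(is.finite(g))) stop("no valid split found")
  best <- which.max(g) # which.max returns the first (lowest) maximizer
  # threshold = largest gray value in class 0, so `x <= threshold` is exactly
  # the low class
  thr <- max(x[q <= best - 1L])

  structure(list(
    threshold = thr,
    omega0 = om0[best], omega1 = om1[best],
    mu0 = mu0[best], mu1 = mu1[best], mu = mu,
    g = g[best], n_bins = as.integer(n_bins)
  ), class = "otsu_result")
}

#' @export
print.otsu_result <- function(x, ...) {
  cat(sprintf(
    "Otsu threshold: T = %.4f (g = %.4f)\n  class 0 (<= T): omega0 = %.3f, mu0 = %.3f\n  class 1 (>  T): omega1 = %.3f, mu1 = %.3f\n",
    x$threshold, x$g, x$omega0, x$mu0, x$omega1, x$mu1))
  invisible(x)
}

#' Binarize an image at an Otsu threshold
#'
#' @param image numeric matrix.
#' @param result an `otsu_result` from [otsu_threshold()], or a bare numeric
#'   threshold.
#' @param polarity `"below"` marks pixels `<= T`; `"above"` marks pixels
#'   `> T` (on an entropy image the homogeneous lumina sit near the maximum,
#'   i.e. above).
#' @return logical matrix, same shape as `image`.
#' @export
binarize <- function(image, result, polarity = c("below", "above")) {
  polarity <- match.arg(polarity)
  thr <- if (inherits(result, "otsu_result")) result$threshold else
    as.numeric(result)
  stopifnot(is.matrix(image), length(thr) == 1, is.finite(thr))
  if (polarity == "below") image <= thr else image > thr
}
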