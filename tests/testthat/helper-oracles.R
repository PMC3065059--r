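# Independent brute-force oracles, deliberately naive implementations.

# local entropy by direct per-pixel evaluation with reflection padding
oracle_local_entropy <- function(image, window, offset = 1) {
  r <- (window - 1) / 2
  f <- image + offset
  nr <- nrow(f); nc <- ncol(f)
  reflect <- function(i, n) {
    i <- ifelse(i < 1, 2 - i, i)
    ifelse(i > n, 2 * n - i, i)
  }
  H <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- reflect((i - r):(i + r), nr)
    ci <- reflect((j - r):(j + r), nc)
    vals <- f[ri, ci]
    p <- vals / sum(vals)
    H[i, j] <- -sum(p * log2(p))
  }
  H
}

# exhaustive Otsu: for every distinct-value cut compute g from first
# principles on the raw pixels
oracle_otsu_g <- function(x, thr) {
  lo <- x <= thr
  w0 <- mean(lo); w1 <- 1 - w0
  if (w0 == 0 || w1 == 0) return(-Inf)
  mu <- mean(x)
  w0 * (mean(x[lo]) - mu)^2 + w1 * (mean(x[!lo]) - mu)^2
}

# GLCM by explicit pair enumeration
oracle_glcm <- function(patch, mask, theta, d, levels) {
  off <- switch(as.character(theta),
                "0" = c(0, d), "45" = c(-d, d),
                "90" = c(-d, 0), "135" = c(-d, -d))
  counts <- matrix(0, levels, levels)
  for (i in seq_len(nrow(patch))) for (j in seq_len(ncol(patch))) {
    i2 <- i + off[1]; j2 <- j + off[2]
    if (i2 >= 1 && i2 <= nrow(patch) && j2 >= 1 && j2 <= ncol(patch) &&
        mask[i, j] && mask[i2, j2]) {
      a <- patch[i, j] + 1; b <- patch[i2, j2] + 1
      counts[a, b] <- counts[a, b] + 1
    }
  }
  counts
}

# connected components by BFS flood fill
oracle_label_count <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  if (connectivity == 8) {
    nb <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    nb <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  n <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (mask[i, j] && !seen[i, j]) {
      n <- n + 1
      queue <- list(c(i, j)); seen[i, j] <- TRUE
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(nb))) {
          q <- p + nb[k, ]
          if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
              mask[q[1], q[2]] && !seen[q[1], q[2]]) {
            seen[q[1], q[2]] <- TRUE
            queue[[length(queue) + 1]] <- q
          }
        }
      }
    }
  }
  n
}

# small deterministic phantom shared across tests
default_test_phantom <- function(seed = 11, n_lumina = 4, n_calculi = 3) {
  generate_phantom(phantom_config(n_lumina = n_lumina,
                                  n_calculi = n_calculi, seed = seed))
}

# does any region's bounding box contain the point (row, col)?
region_covering <- function(regions, row, col) {
  which(vapply(regions, function(r) {
    row >= r$bbox[["min_row"]] && row <= r$bbox[["max_row"]] &&
      col >= r$bbox[["min_col"]] && col <= r$bbox[["max_col"]]
  }, logical(1)))
}
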