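# Independent brute-force oracles used across the suite. These share no
# code with the package: convolution is a literal double loop, labeling a
# literal flood fill, and the classification rule a nested if.

# Half-sample symmetric reflection of an arbitrary integer index into
# 1..n, by walking instead of modular arithmetic.
oracle_reflect <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# Direct 2D convolution with a symmetric kernel and reflect padding.
oracle_conv2 <- function(image, kernel) {
  h <- nrow(image)
  w <- ncol(image)
  kr <- (nrow(kernel) - 1) / 2
  kc <- (ncol(kernel) - 1) / 2
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      acc <- 0
      for (di in -kr:kr) {
        for (dj in -kc:kc) {
          ii <- oracle_reflect(i + di, h)
          jj <- oracle_reflect(j + dj, w)
          acc <- acc + kernel[di + kr + 1, dj + kc + 1] * image[ii, jj]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Sampled normalized 1D Gaussian, written out independently.
oracle_gaussian_1d <- function(sigma, truncate = 4) {
  r <- ceiling(truncate * sigma)
  x <- -r:r
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# Flood-fill component count and label partition.
oracle_flood_fill <- function(binary, connectivity = 8) {
  h <- nrow(binary)
  w <- ncol(binary)
  seen <- matrix(FALSE, h, w)
  labels <- matrix(0L, h, w)
  steps <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  n_comp <- 0L
  for (j in seq_len(w)) {
    for (i in seq_len(h)) {
      if (binary[i, j] != 0 && !seen[i, j]) {
        n_comp <- n_comp + 1L
        queue <- list(c(i, j))
        seen[i, j] <- TRUE
        while (length(queue)) {
          p <- queue[[1]]
          queue <- queue[-1]
          labels[p[1], p[2]] <- n_comp
          for (s in seq_len(nrow(steps))) {
            ni <- p[1] + steps[s, 1]
            nj <- p[2] + steps[s, 2]
            if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
                binary[ni, nj] != 0 && !seen[ni, nj]) {
              seen[ni, nj] <- TRUE
              queue <- c(queue, list(c(ni, nj)))
            }
          }
        }
      }
    }
  }
  list(labels = labels, n_components = n_comp)
}

# The printed classification rule, evaluated literally.
oracle_classify <- function(area, aspect, a_min = 9, aspect_min = 3) {
  if (area < a_min) return("noise")
  if (aspect > aspect_min) return("vessel")
  "cell"
}

# Compact near-circular pixel mask of exactly `area` pixels: take the
# `area` grid pixels closest to the centre of a grid (ties broken by
# angle so the shape stays rounded).
compact_blob_mask <- function(area, side = 15) {
  ctr <- (side + 1) / 2
  d <- expand.grid(row = seq_len(side), col = seq_len(side))
  d$dist <- (d$row - ctr)^2 + (d$col - ctr)^2
  d$ang <- atan2(d$row - ctr, d$col - ctr)
  d <- d[order(d$dist, d$ang), ]
  m <- matrix(0, side, side)
  m[cbind(d$row[seq_len(area)], d$col[seq_len(area)])] <- 1
  m
}

# Small deterministic detection-result stub for scoring tests.
fake_detection <- function(centroids, classes = NULL) {
  n <- nrow(centroids)
  if (is.null(classes)) classes <- rep("cell", n)
  blobs <- tibble::tibble(
    label_id = seq_len(n), area = rep(20, n),
    l_maj = rep(5, n), l_min = rep(5, n), aspect = rep(1, n),
    centroid_row = centroids[, 1], centroid_col = centroids[, 2],
    class = factor(classes, levels = c("cell", "vessel", "noise")))
  structure(list(blobs = blobs,
                 n_cells = sum(classes == "cell"),
                 n_vessels = sum(classes == "vessel"),
                 n_noise = sum(classes == "noise"),
                 n_blobs = n, labels = NULL, image = NULL, params = NULL),
            class = "darc_detection")
}
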