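# Stage 2: thresholding, connected components, blob morphometry and
# rule-based classification.

#' Global threshold on the filtered response
#'
#' Zeroes every pixel whose value lies at or below `mean + k * sd` of the
#' whole response image (sample SD over all pixels, borders included) and
#' retains the rest unchanged. One-sided by design: with the
#' bright-positive filter polarity, the negative surround rings of the
#' band-pass response must not survive thresholding. A zero-variance image
#' has no structure and maps to all zeros.
#'
#' @param response Numeric matrix, typically from [preprocess_image()].
#' @param k Positive threshold multiplier (default 1.8).
#' @return A matrix of the same dimensions with sub-threshold pixels set
#'   to zero.
#' @examples
#' r <- matrix(rnorm(100), 10)
#' sum(threshold_response(r, k = 1.8) != 0)
#' @export
threshold_response <- function(response, k = 1.8) {
  check_image(response, "response")
  stopifnot(is.numeric(k), length(k) == 1, is.finite(k), k > 0)
  m <- mean(response)
  d <- sd(as.vector(response))
  # a variance at the rounding level of the values is no structure at all
  if (!is.finite(d) || d <= 1e-12 * max(abs(response), 1e-300)) {
    return(matrix(0, nrow(response), ncol(response)))
  }
  out <- response
  out[out <= m + k * d] <- 0
  out
}

#' Label connected components
#'
#' Assigns a distinct positive integer label to each maximal connected set
#' of nonzero pixels under 4- or 8-connectivity (background stays 0).
#' Labels are numbered 1..n in order of each component's first pixel in
#' column-major scan order, so the labeling is deterministic.
#'
#' @param binary Numeric matrix; nonzero pixels are foreground.
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
#' @return An integer matrix of labels with attribute `n_components`.
#' @examples
#' m <- matrix(0, 3, 3); m[1, 1] <- 1; m[2, 2] <- 1
#' attr(label_components(m, 8), "n_components")  # 1
#' attr(label_components(m, 4), "n_components")  # 2
#' @export
label_components <- function(binary, connectivity = 8) {
  check_image(binary, "binary")
  stopifnot(length(connectivity) == 1, connectivity %in% c(4, 8))
  h <- nrow(binary)
  w <- ncol(binary)
  fg <- which(binary != 0)
  labels <- matrix(0L, h, w)
  if (length(fg) == 0L) {
    attr(labels, "n_components") <- 0L
    return(labels)
  }
  is_fg <- binary != 0
  rows <- ((fg - 1L) %% h) + 1L
  # Neighbour offsets in linear (column-major) index space; row guards
  # prevent wrapping across matrix columns.
  offs <- list(c(1L, +1L),   # down
               c(h, 0L))     # right
  if (connectivity == 8) {
    offs <- c(offs, list(c(h + 1L, +1L),   # down-right
                         c(h - 1L, -1L)))  # up-right
  }
  ea <- integer(0)
  eb <- integer(0)
  for (o in offs) {
    nb <- fg + o[1L]
    ok <- nb >= 1L & nb <= h * w &
      (rows + o[2L]) >= 1L & (rows + o[2L]) <= h
    ok[ok] <- is_fg[nb[ok]]
    ea <- c(ea, fg[ok])
    eb <- c(eb, nb[ok])
  }
  # Union-find over foreground pixels, compressed id space.
  id <- integer(h * w)
  id[fg] <- seq_along(fg)
  parent <- seq_along(fg)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (length(ea)) {
    ua <- id[ea]
    ub <- id[eb]
    for (i in seq_along(ua)) {
      ra <- find(ua[i])
      rb <- find(ub[i])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  # Resolve all roots (iterated pointer jumping).
  repeat {
    nxt <- parent[parent]
    if (identical(nxt, parent)) break
    parent <- nxt
  }
  roots <- parent
  # Renumber components by first appearance in scan order. fg is sorted,
  # and unions always point to the smaller id, so each root is its
  # component's first pixel.
  uniq <- sort(unique(roots))
  comp <- match(roots, uniq)
  labels[fg] <- comp
  attr(labels, "n_components") <- length(uniq)
  labels
}

#' Blob morphometry
#'
#' Computes, for every labeled connected component, the features the
#' classifier uses: area `A` (pixel count), centroid (mean of 1-based
#' pixel row/column coordinates), and the major/minor axis lengths of the
#' moment-equivalent ellipse. The second central moments of the pixel
#' coordinates get `1/12` added to each diagonal term (the variance of a
#' unit pixel extent), and the axis lengths are `4 * sqrt(eigenvalue)`;
#' this reproduces the standard region-properties definition, and keeps
#' the minor axis positive (so the aspect ratio defined) even for
#' single-pixel-wide blobs.
#'
#' @param labels Integer label matrix from [label_components()].
#' @return A tibble with one row per blob: `label_id`, `area`, `l_maj`,
#'   `l_min`, `aspect`, `centroid_row`, `centroid_col`.
#' @examples
#' m <- matrix(0, 5, 8); m[3, 2:5] <- 1
#' blob_features(label_components(m))  # one 1x4 blob, aspect 4
#' @export
blob_features <- function(labels) {
  stopifnot(is.matrix(labels))
  h <- nrow(labels)
  fg <- which(labels != 0)
  empty <- tibble(label_id = integer(), area = numeric(),
                  l_maj = numeric(), l_min = numeric(), aspect = numeric(),
                  centroid_row = numeric(), centroid_col = numeric())
  if (length(fg) == 0L) return(empty)
  lab <- as.integer(labels[fg])
  r <- ((fg - 1L) %% h) + 1L
  cc <- ((fg - 1L) %/% h) + 1L
  n <- tabulate(lab)
  ids <- which(n > 0L)
  rbar <- unname(rowsum(r, lab)[, 1]) / n[ids]
  cbar <- unname(rowsum(cc, lab)[, 1]) / n[ids]
  dr <- r - rbar[match(lab, ids)]
  dc <- cc - cbar[match(lab, ids)]
  mrr <- unname(rowsum(dr^2, lab)[, 1]) / n[ids] + 1 / 12
  mcc <- unname(rowsum(dc^2, lab)[, 1]) / n[ids] + 1 / 12
  mrc <- unname(rowsum(dr * dc, lab)[, 1]) / n[ids]
  tr2 <- (mrr + mcc) / 2
  det_part <- sqrt(((mrr - mcc) / 2)^2 + mrc^2)
  l1 <- tr2 + det_part
  l2 <- tr2 - det_part
  tibble(label_id = ids,
         area = as.numeric(n[ids]),
         l_maj = 4 * sqrt(l1),
         l_min = 4 * sqrt(l2),
         aspect = sqrt(l1 / l2),
         centroid_row = rbar,
         centroid_col = cbar)
}

#' Classify blobs as cell, vessel or noise
#'
#' Applies the fixed classification rule to a table of blob features:
#' a blob is noise if its area is strictly below `a_min`; otherwise a
#' vessel if its aspect ratio is strictly above `aspect_min`; all other
#' blobs are cells. The area test takes precedence, so small elongated
#' fragments are noise, not vessels. Both inequalities are strict: a blob
#' of area exactly `a_min` is not noise, and aspect exactly `aspect_min`
#' is not a vessel.
#'
#' @param features A data frame with columns `area` and `aspect` (or
#'   `l_maj`/`l_min`, from which `aspect` is derived), e.g. from
#'   [blob_features()].
#' @param params A [detection_params()].
#' @return `features` with a `class` factor column added (levels `cell`,
#'   `vessel`, `noise`).
#' @examples
#' classify_blobs(tibble::tibble(area = c(8, 9, 50), aspect = c(1, 1, 4)))
#' @export
classify_blobs <- function(features, params = detection_params()) {
  stopifnot(is.data.frame(features), inherits(params, "detection_params"))
  if (!"aspect" %in% names(features)) {
    if (!all(c("l_maj", "l_min") %in% names(features))) {
      abort("`features` needs an `aspect` column or `l_maj` and `l_min`")
    }
    features$aspect <- features$l_maj / features$l_min
  }
  cls <- dplyr::case_when(
    features$area < params$a_min ~ "noise",
    features$aspect > params$aspect_min ~ "vessel",
    .default = "cell"
  )
  features$class <- factor(cls, levels = c("cell", "vessel", "noise"))
  as_tibble(features)
}

#' Detect and count cells in one image
#'
#' Runs the full pipeline on a luminance image: Stage-1 pre-processing
#' (local gain control then Laplacian-of-Gaussian filtering), global
#' thresholding at `mean + k * sd` of the response, connected-component
#' labeling, blob morphometry and cell/vessel/noise classification.
#'
#' @param image Numeric matrix of at least 16 x 16 pixels (the local
#'   statistics of the gain-control stage are meaningless below that).
#' @param gain_control,band_pass,detection Parameter sets; see
#'   [pipeline-params].
#' @param apply_gain_control Set `FALSE` to skip Stage 1a and band-pass
#'   the raw image directly (used for ablation studies of the
#'   gain-control stage).
#' @return An object of class `darc_detection`: a list with `blobs` (the
#'   classified feature tibble), `n_cells`, `n_vessels`, `n_noise`,
#'   `n_blobs`, the `labels` matrix, the source `image`, and the
#'   parameter sets in `params`. Supports [tidy()] (per-blob table),
#'   [glance()] (one-row count summary) and [autoplot()].
#' @examples
#' img <- generate_image(synthetic_spec(height = 128, width = 128,
#'                                      n_cells = 4, seed = 1))
#' det <- detect_cells(img$image)
#' glance(det)
#' @export
detect_cells <- function(image,
                         gain_control = gain_control_params(),
                         band_pass = band_pass_params(),
                         detection = detection_params(),
                         apply_gain_control = TRUE) {
  check_image(image)
  if (nrow(image) < 16 || ncol(image) < 16) {
    abort("`image` must be at least 16 x 16 pixels")
  }
  z <- if (apply_gain_control) local_gain_control(image, gain_control)
       else image
  response <- log_filter(z, band_pass)
  thresholded <- threshold_response(response, detection$k)
  labels <- label_components(thresholded, detection$connectivity)
  blobs <- classify_blobs(blob_features(labels), detection)
  counts <- table(blobs$class)
  structure(list(
    blobs = blobs,
    n_cells = as.integer(counts[["cell"]]),
    n_vessels = as.integer(counts[["vessel"]]),
    n_noise = as.integer(counts[["noise"]]),
    n_blobs = nrow(blobs),
    labels = labels,
    image = image,
    params = list(gain_control = gain_control, band_pass = band_pass,
                  detection = detection,
                  apply_gain_control = apply_gain_control)
  ), class = "darc_detection")
}

#' @export
print.darc_detection <- function(x, ...) {
  cat(sprintf(
    "<darc_detection> %d x %d image: %d blobs (%d cells, %d vessels, %d noise)\n",
    nrow(x$image), ncol(x$image), x$n_blobs, x$n_cells, x$n_vessels,
    x$n_noise))
  invisible(x)
}

#' @rdname detect_cells
#' @param x A `darc_detection` object.
#' @param ... Unused.
#' @method tidy darc_detection
#' @export
tidy.darc_detection <- function(x, ...) {
  x$blobs
}

#' @rdname detect_cells
#' @method glance darc_detection
#' @export
glance.darc_detection <- function(x, ...) {
  tibble(n_cells = x$n_cells, n_vessels = x$n_vessels,
         n_noise = x$n_noise, n_blobs = x$n_blobs,
         height = nrow(x$image), width = ncol(x$image))
}

#' @rdname detect_cells
#' @param object A `darc_detection` object.
#' @method autoplot darc_detection
#' @export
autoplot.darc_detection <- function(object, ...) {
  img_df <- tidyr::expand_grid(row = seq_len(nrow(object$image)),
                               col = seq_len(ncol(object$image)))
  img_df$value <- as.vector(object$image)[
    (img_df$col - 1L) * nrow(object$image) + img_df$row]
  ggplot2::ggplot(img_df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::geom_point(
      data = object$blobs,
      ggplot2::aes(.data$centroid_col, .data$centroid_row,
                   colour = .data$class),
      shape = 1, size = 3, stroke = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(cell = "green3", vessel = "red", noise = "orange"),
      drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL,
                  title = sprintf("%d cells, %d vessels, %d noise",
                                  object$n_cells, object$n_vessels,
                                  object$n_noise)) +
    ggplot2::theme_minimal()
}
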