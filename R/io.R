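# Image reading/writing, pre-analysis geometry (crop, bilinear resize),
# overlay rendering and tabular outputs.

#' Convert a multi-channel image to luminance
#'
#' A 3-channel (RGB) array is reduced with the Rec. 601 luma weights
#' (0.299 R + 0.587 G + 0.114 B, ITU-R BT.601, the convention of
#' common image-processing environments; the weights sum to one so a
#' grey input is unchanged); a single-channel image is returned
#' unchanged. Any other channel count is an error.
#'
#' @param image A numeric matrix, or an `h x w x c` array with `c` 1
#'   or 3.
#' @return A numeric matrix.
#' @examples
#' to_grayscale(array(0.5, c(4, 4, 3)))
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) return(image)
  if (!is.array(image) || length(dim(image)) != 3) {
    abort("`image` must be a matrix or a 3-dimensional array")
  }
  ch <- dim(image)[3]
  if (ch == 1) return(image[, , 1])
  if (ch == 3) {
    return(0.299 * image[, , 1] + 0.587 * image[, , 2] +
             0.114 * image[, , 3])
  }
  abort(sprintf("unsupported channel count: %d (expected 1 or 3)", ch))
}

#' Read an image file as a luminance matrix
#'
#' Reads PNG, TIFF or JPEG (by file extension), drops any alpha channel,
#' converts colour images to luminance with [to_grayscale()], and returns
#' values scaled to `[0, 1]` (integer images are normalized by their bit
#' depth's maximum, which the underlying readers already apply).
#'
#' @param path Path to a `.png`, `.tif(f)`, `.jpg` or `.jpeg` file.
#' @return A numeric matrix with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("image file does not exist: ", path))
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    abort(paste0("unsupported image format: .", ext,
                 " (expected png, tiff or jpeg)"))
  )
  if (is.array(raw) && length(dim(raw)) == 3 && dim(raw)[3] %in% c(2, 4)) {
    raw <- raw[, , -dim(raw)[3], drop = FALSE]  # drop alpha
    if (dim(raw)[3] == 1) raw <- raw[, , 1]
  }
  to_grayscale(raw)
}

#' Write a luminance matrix as an 8-bit grayscale PNG
#'
#' Values are clipped to `[0, 1]`.
#'
#' @param image Numeric matrix, or an `h x w x 3` colour array such as an
#'   overlay from [render_overlay()].
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  img <- pmin(pmax(image, 0), 1)
  png::writePNG(img, path)
  invisible(path)
}

#' Crop box
#'
#' A rectangular region given by its top-left corner (1-based, inclusive)
#' and its height and width in pixels.
#'
#' @param top,left 1-based row/column of the top-left pixel.
#' @param height,width Extent in pixels (at least 1).
#' @return A list of class `"crop_box"`.
#' @export
crop_box <- function(top, left, height, width) {
  stopifnot(top >= 1, left >= 1, height >= 1, width >= 1)
  structure(list(top = as.integer(top), left = as.integer(left),
                 height = as.integer(height), width = as.integer(width)),
            class = "crop_box")
}

#' Crop an image
#'
#' Exact pixel-subset copy; the box must lie entirely within the image.
#'
#' @param image Numeric matrix.
#' @param box A [crop_box()].
#' @return A `box$height x box$width` numeric matrix.
#' @export
crop <- function(image, box) {
  check_image(image)
  stopifnot(inherits(box, "crop_box"))
  if (box$top + box$height - 1L > nrow(image) ||
      box$left + box$width - 1L > ncol(image)) {
    abort(sprintf(
      "crop box (%d,%d)+%dx%d exceeds the %d x %d image",
      box$top, box$left, box$height, box$width, nrow(image), ncol(image)))
  }
  image[box$top:(box$top + box$height - 1L),
        box$left:(box$left + box$width - 1L), drop = FALSE]
}

# target x n interpolation operator for one axis under the
# align-corners-false (half-pixel centre) convention; sample coordinates
# outside the source are clamped to the border pixel.
bilinear_operator <- function(n, target) {
  scale <- n / target
  # 0-based source coordinate of each 0-based output pixel centre
  src <- (seq_len(target) - 0.5) * scale - 0.5
  src <- pmin(pmax(src, 0), n - 1)
  lo <- floor(src)
  frac <- src - lo
  hi <- pmin(lo + 1, n - 1)
  M <- matrix(0, target, n)
  i <- seq_len(target)
  M[cbind(i, lo + 1)] <- M[cbind(i, lo + 1)] + (1 - frac)
  M[cbind(i, hi + 1)] <- M[cbind(i, hi + 1)] + frac
  M
}

#' Bilinear resize to a square
#'
#' Resizes an image to `target x target` pixels by separable bilinear
#' interpolation under the align-corners-false convention (output pixel
#' centres back-projected at half-pixel offsets; border samples clamped).
#' Aspect ratio is not preserved: non-square inputs are stretched to the
#' square target, mirroring the pre-analysis protocol the pipeline
#' parameters were fixed for.
#'
#' @param image Numeric matrix.
#' @param target Side length in pixels (at least 2).
#' @return A `target x target` numeric matrix. Resizing a `target x
#'   target` image is the identity.
#' @export
resize_bilinear <- function(image, target = 600) {
  check_image(image)
  stopifnot(is.numeric(target), length(target) == 1)
  if (target < 2) abort("`target` must be at least 2")
  target <- as.integer(target)
  bilinear_operator(nrow(image), target) %*% image %*%
    t(bilinear_operator(ncol(image), target))
}

#' Render a labeled overlay
#'
#' Paints the pixels of every blob classified as a cell green and every
#' other blob (vessel or noise) red over the grayscale source image, the
#' display convention of the automated labeling output.
#'
#' @param image Numeric matrix in `[0, 1]` (same dimensions the detection
#'   was run on).
#' @param result A [detect_cells()] result.
#' @return An `h x w x 3` numeric array with attribute `n_cells` (the
#'   annotated total cell count); write it with [write_image()].
#' @export
render_overlay <- function(image, result) {
  check_image(image)
  stopifnot(inherits(result, "darc_detection"))
  if (!all(dim(image) == dim(result$labels))) {
    abort("`image` dimensions do not match the detection result")
  }
  base <- pmin(pmax(image, 0), 1)
  out <- array(base, c(dim(base), 3))
  cls <- result$blobs$class
  cell_ids <- result$blobs$label_id[cls == "cell"]
  other_ids <- result$blobs$label_id[cls != "cell"]
  cell_px <- which(result$labels %in% cell_ids)
  other_px <- which(result$labels %in% other_ids)
  npx <- length(base)
  out[cell_px] <- 0;          out[cell_px + npx] <- 1
  out[cell_px + 2 * npx] <- 0
  out[other_px] <- 1;         out[other_px + npx] <- 0
  out[other_px + 2 * npx] <- 0
  attr(out, "n_cells") <- result$n_cells
  out
}

#' Write per-image counts to CSV
#'
#' One row per image with columns `image_id`, `n_cells`, `n_vessels`,
#' `n_noise`, `n_blobs`, in input order.
#'
#' @param results A named list of [detect_cells()] results (names become
#'   `image_id`; unnamed lists get `image_1`, ...), or a single result.
#' @param path Output CSV path.
#' @return The counts tibble, invisibly.
#' @export
write_counts <- function(results, path) {
  if (inherits(results, "darc_detection")) results <- list(results)
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, TRUE, "darc_detection")))
  ids <- names(results)
  if (is.null(ids) || any(!nzchar(ids))) {
    ids <- paste0("image_", seq_along(results))
  }
  tab <- purrr::map2_dfr(results, ids, function(res, id) {
    tibble(image_id = id, n_cells = res$n_cells,
           n_vessels = res$n_vessels, n_noise = res$n_noise,
           n_blobs = res$n_blobs)
  })
  readr::write_csv(tab, path)
  invisible(tab)
}

#' Read a count table CSV
#'
#' Reads a CSV with an image-id column and one numeric count column per
#' method/rater, validating it for the evaluation functions: equal-length
#' columns, no missing cells, non-negative counts.
#'
#' @param path CSV path (e.g. written by [write_counts()] or a
#'   multi-rater study table).
#' @param id Name of the image-id column (default: first column).
#' @return A tibble.
#' @export
read_counts <- function(path, id = NULL) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (is.null(id)) id <- names(tab)[1]
  num_cols <- setdiff(names(tab), id)
  for (col in num_cols) {
    if (!is.numeric(tab[[col]])) {
      abort(paste0("count column `", col, "` is not numeric"))
    }
    if (anyNA(tab[[col]])) {
      abort(paste0("count column `", col, "` has missing values"))
    }
    if (any(tab[[col]] < 0)) {
      abort(paste0("count column `", col, "` has negative values"))
    }
  }
  tab
}

#' Export per-blob features as JSON records
#'
#' Writes one JSON record per blob (`label_id`, `class`, `area`, `l_maj`,
#' `l_min`, `aspect`, `centroid_row`, `centroid_col`).
#'
#' @param result A [detect_cells()] result.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_blob_features <- function(result, path) {
  stopifnot(inherits(result, "darc_detection"))
  blobs <- result$blobs
  blobs$class <- as.character(blobs$class)
  jsonlite::write_json(blobs, path, dataframe = "rows", digits = NA)
  invisible(path)
}
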