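# Stage 1: separable convolution machinery, local gain control, and the
# Laplacian-of-Gaussian band-pass filter.
#
# Convolution along one image axis is expressed as multiplication by an
# n x n operator matrix that folds reflect (half-sample symmetric) padding
# back into the valid range; a separable 2D convolution is then
# K_row %*% I %*% t(K_col), which hands the heavy lifting to BLAS. Kernels
# here are symmetric, so convolution and correlation coincide.

# Map out-of-range 1-based indices back into 1..n by half-sample symmetric
# reflection (edge pixel repeated), valid for arbitrarily distant indices.
reflect_index <- function(i, n) {
  m <- (i - 1L) %% (2L * n)
  ifelse(m >= n, 2L * n - 1L - m, m) + 1L
}

# n x n operator applying a symmetric 1D kernel along one axis with
# reflect padding.
conv_operator <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  M <- matrix(0, n, n)
  idx <- seq_len(n)
  for (k in seq(-r, r)) {
    j <- reflect_index(idx + k, n)
    ij <- cbind(idx, j)
    M[ij] <- M[ij] + kernel[k + r + 1L]
  }
  M
}

conv_separable <- function(image, kernel_row, kernel_col) {
  conv_operator(nrow(image), kernel_row) %*% image %*%
    t(conv_operator(ncol(image), kernel_col))
}

check_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort(paste0("`", arg, "` must be a numeric matrix"))
  }
  if (nrow(image) < 1 || ncol(image) < 1) {
    abort(paste0("`", arg, "` must have at least one row and column"))
  }
  if (!all(is.finite(image))) {
    abort(paste0("`", arg, "` must contain only finite values"))
  }
  invisible(image)
}

#' Sampled Gaussian kernel
#'
#' A 1D Gaussian of standard deviation `sigma`, sampled at integer offsets,
#' truncated at `truncate * sigma` and normalized to sum to one. This is
#' the smoothing kernel used by the gain-control stage and the Gaussian
#' component from which the Laplacian-of-Gaussian kernel is built.
#'
#' @param sigma Standard deviation in pixels; must be positive.
#' @param truncate Half-width of the kernel support as a multiple of
#'   `sigma`.
#' @return A numeric vector of odd length `2 * ceiling(truncate * sigma)
#'   + 1` summing to one, with attribute `offsets` giving the integer
#'   sample positions.
#' @examples
#' g <- gaussian_kernel(1.5)
#' sum(g)  # 1
#' @export
gaussian_kernel <- function(sigma, truncate = 4) {
  stopifnot(is.numeric(sigma), length(sigma) == 1, is.finite(sigma))
  if (sigma <= 0) abort("`sigma` must be positive")
  r <- as.integer(ceiling(truncate * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  attr(g, "offsets") <- x
  g
}

#' Gaussian blur
#'
#' Convolves an image with a normalized 2D Gaussian (applied separably)
#' under reflect (half-sample symmetric) boundary extension. A constant
#' image is returned unchanged because the kernel sums to one.
#'
#' @param image Numeric matrix (rows = image rows, columns = image
#'   columns).
#' @param sigma Gaussian standard deviation in pixels.
#' @param truncate Kernel half-width as a multiple of `sigma`.
#' @return A numeric matrix with the dimensions of `image`.
#' @examples
#' gaussian_blur(matrix(1, 5, 5), sigma = 2)
#' @export
gaussian_blur <- function(image, sigma, truncate = 4) {
  check_image(image)
  g <- gaussian_kernel(sigma, truncate)
  conv_separable(image, g, g)
}

# 1D second-derivative-of-Gaussian factor paired with gaussian_kernel():
# d2/dx2 G(x) = G(x) (x^2 - sigma^2) / sigma^4, sampled and mean-centred
# so the assembled 2D kernel sums to exactly zero despite truncation.
log_deriv_component <- function(sigma, truncate = 4) {
  g <- gaussian_kernel(sigma, truncate)
  x <- attr(g, "offsets")
  a <- as.numeric(g) * (x^2 - sigma^2) / sigma^4
  a - mean(a)
}

#' Laplacian-of-Gaussian kernel
#'
#' The explicit 2D band-pass kernel of scale `u`: the sum of the sampled
#' second derivatives of a 2D Gaussian along each axis, mean-corrected to
#' sum to exactly zero, and negated so that a bright blob produces a
#' positive central response. The Gaussian component used to build it is
#' attached as attribute `gaussian` (see [gaussian_kernel()]).
#'
#' @param u Standard deviation in pixels of the underlying Gaussian.
#' @param truncate Kernel half-width as a multiple of `u`.
#' @return A square numeric matrix of side `2 * ceiling(truncate * u) + 1`
#'   summing to zero, with attributes `gaussian` (the 1D Gaussian
#'   component) and `offsets`.
#' @examples
#' k <- log_kernel(1.5)
#' sum(k)      # 0
#' k[7, 7] > 0 # bright-positive polarity
#' @export
log_kernel <- function(u, truncate = 4) {
  stopifnot(is.numeric(u), length(u) == 1, is.finite(u))
  if (u <= 0) abort("`u` must be positive")
  g <- gaussian_kernel(u, truncate)
  a <- log_deriv_component(u, truncate)
  k <- -(outer(a, as.numeric(g)) + outer(as.numeric(g), a))
  attr(k, "gaussian") <- g
  attr(k, "offsets") <- attr(g, "offsets")
  k
}

#' Laplacian-of-Gaussian band-pass filter
#'
#' Convolves the image with the [log_kernel()] of scale `params$u` under
#' reflect boundary extension. The kernel is rank-2 separable
#' (`a(x) g(y) + g(x) a(y)`), so the filter runs as two separable passes
#' that reproduce the explicit 2D kernel convolution to machine precision.
#' With the bright-positive polarity convention, isolated bright spots
#' yield positive central responses so a one-sided threshold selects cell
#' centres.
#'
#' @param image Numeric matrix.
#' @param params A [band_pass_params()].
#' @return Filtered image, same dimensions; exactly zero (to rounding) on
#'   constant input.
#' @export
log_filter <- function(image, params = band_pass_params()) {
  check_image(image)
  stopifnot(inherits(params, "band_pass_params"))
  g <- as.numeric(gaussian_kernel(params$u, params$truncate))
  a <- log_deriv_component(params$u, params$truncate)
  -(conv_separable(image, a, g) + conv_separable(image, g, a))
}

#' Local luminance/contrast gain control
#'
#' Converts each pixel grey level into a local z-score: the local mean
#' `mu` is a Gaussian blur (standard deviation `s`) of the image, the
#' local standard deviation is `sqrt(blur(I^2) - mu^2)` (clamped at zero
#' before the square root), and the output is `(I - mu) / (sd +
#' sigma_floor)`. This flattens the slowly varying luminance and contrast
#' structure that otherwise dominates global thresholding, so that
#' identical spots in dim and bright image regions produce comparable
#' responses.
#'
#' @param image Numeric matrix.
#' @param params A [gain_control_params()]. When `sigma_floor` is `NULL`
#'   it is taken as `1e-6 * diff(range(image))`, or `1e-6` for a constant
#'   image.
#' @return The z-score image, same dimensions; identically zero for a
#'   constant image.
#' @examples
#' z <- local_gain_control(matrix(rnorm(400), 20), gain_control_params(s = 3))
#' @export
local_gain_control <- function(image, params = gain_control_params()) {
  check_image(image)
  stopifnot(inherits(params, "gain_control_params"))
  rng <- diff(range(image))
  if (rng == 0) {
    return(matrix(0, nrow(image), ncol(image)))  # no contrast to normalize
  }
  floor_val <- params$sigma_floor
  if (is.null(floor_val)) {
    floor_val <- 1e-6 * rng
  }
  g <- gaussian_kernel(params$s, params$truncate)
  mu <- conv_separable(image, g, g)
  m2 <- conv_separable(image^2, g, g)
  sigma <- sqrt(pmax(m2 - mu^2, 0)) + floor_val
  (image - mu) / sigma
}

#' Full Stage-1 pre-processing
#'
#' [local_gain_control()] followed by [log_filter()]: the band-pass
#' response image that Stage 2 thresholds.
#'
#' @param image Numeric matrix.
#' @param gain_control A [gain_control_params()].
#' @param band_pass A [band_pass_params()].
#' @return Filtered response image, same dimensions as `image`.
#' @export
preprocess_image <- function(image,
                             gain_control = gain_control_params(),
                             band_pass = band_pass_params()) {
  log_filter(local_gain_control(image, gain_control), band_pass)
}
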