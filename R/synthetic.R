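# Seeded generator of synthetic retinal-fluorescence-like images with
# known ground truth: bright Gaussian-profile spots on a slowly varying
# background with granular noise, optional vessel-like ridges, and the
# documented failure-mode variants (dim/small spots, aberrated elongated
# spots, heavy granular background, strong luminance gradients).

#' Specification of a synthetic image
#'
#' Collects every knob of the synthetic generator into a validated list.
#' Defaults describe an "easy" image at the density of a typical
#' post-insult retina: a 600-pixel-square field with 126 well-separated
#' bright spots (the average cell count of the images the pipeline was
#' calibrated against; Gaussian profile, SD 2-3 px, amplitude 0.15-0.35
#' above background) on a background of level 0.2 with a low-frequency
#' luminance gradient (amplitude 0.3) and granular noise of SD 0.01
#' smoothed at 0.5 px (speckle grains of about 1 px extent), i.e. spot
#' SNR of 15-35. Because the detection threshold is a multiple of the
#' whole-image standard deviation, the realized behaviour depends on the
#' total amount of structure in the scene, so the default density
#' matters and is deliberately realistic.
#'
#' @param height,width Image dimensions in pixels.
#' @param n_cells Number of spots ("cells") to place.
#' @param cell_radius_range Range (pixels) of the Gaussian profile SD of a
#'   spot, drawn uniformly per spot.
#' @param cell_amplitude_range Range of peak spot amplitudes above the
#'   local background, drawn uniformly per spot.
#' @param n_vessels Number of bright straight ridges crossing the image.
#' @param vessel_width Gaussian half-width (pixels) of a ridge profile.
#' @param vessel_amplitude Peak ridge amplitude above background.
#' @param background_level Base luminance, arbitrary units in `[0, 1]`.
#' @param gradient_amplitude Amplitude of the multiplicative
#'   low-frequency luminance field (two random-orientation cosine waves,
#'   normalized to peak 1): the whole scene is scaled by
#'   `1 + gradient_amplitude * S(x)`, clamped at 0.05, so mean luminance
#'   and local contrast vary together as under uneven illumination.
#'   The local z-score of the gain-control stage is invariant to such a
#'   slowly varying factor; a global threshold on the raw band-pass
#'   response is not.
#' @param contrast_gradient Amplitude of an additional multiplicative
#'   low-frequency field applied to the granular noise only (local
#'   contrast varying independently of mean luminance); 0 disables it.
#' @param noise_sd Standard deviation of the granular background noise.
#' @param noise_grain Smoothing scale (pixels) of the noise; the smoothed
#'   field is renormalized to unit SD before scaling by `noise_sd`, so
#'   `noise_sd` is the realized pixel SD at any grain.
#' @param min_separation Minimum centre-to-centre distance (pixels)
#'   between spots.
#' @param margin Minimum distance (pixels) of spot centres from the image
#'   border.
#' @param aberration_elongation Axis-stretch factor applied to every spot
#'   (major axis `elongation * radius`, minor axis `radius`, random
#'   orientation); 1 means isotropic spots.
#' @param max_place_tries Rejection-sampling budget per spot before
#'   placement fails with an error.
#' @param seed Integer seed; the seed fully determines the generated
#'   image (Mersenne-Twister, inversion normal generator).
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(height = 600, width = 600,
                           n_cells = 126,
                           cell_radius_range = c(2, 3),
                           cell_amplitude_range = c(0.15, 0.35),
                           n_vessels = 0,
                           vessel_width = 3,
                           vessel_amplitude = 0.25,
                           background_level = 0.2,
                           gradient_amplitude = 0.3,
                           contrast_gradient = 0,
                           noise_sd = 0.01,
                           noise_grain = 0.5,
                           min_separation = 18,
                           margin = 12,
                           aberration_elongation = 1,
                           max_place_tries = 5000,
                           seed = 1) {
  stopifnot(height >= 1, width >= 1, n_cells >= 0, n_vessels >= 0,
            all(cell_radius_range > 0), diff(cell_radius_range) >= 0,
            all(cell_amplitude_range > 0), diff(cell_amplitude_range) >= 0,
            vessel_width > 0, vessel_amplitude >= 0,
            background_level >= 0, gradient_amplitude >= 0,
            contrast_gradient >= 0, noise_sd >= 0, noise_grain > 0,
            min_separation >= 0, margin >= 0,
            aberration_elongation >= 1, max_place_tries >= 1,
            is.numeric(seed), length(seed) == 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

# Low-frequency random field: sum of two cosine waves of random
# orientation and phase, normalized to peak magnitude 1. `freq` is the
# cycles-per-image range; the default keeps variation well below one
# cycle per image axis, the scale of illumination falloff, so the field
# is close to constant within a gain-control window.
random_smooth_field <- function(h, w, freq = c(0.25, 0.6)) {
  r <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  f <- matrix(0, h, w)
  for (i in 1:2) {
    fr <- runif(1, freq[1], freq[2])
    fc <- runif(1, freq[1], freq[2])
    sgn <- sample(c(-1, 1), 2, replace = TRUE)
    ph <- runif(1, 0, 2 * pi)
    f <- f + cos(2 * pi * (sgn[1] * fr * r / h + sgn[2] * fc * cc / w) + ph)
  }
  f / max(abs(f))
}

# Add one anisotropic Gaussian spot into `img` (in place semantics via
# return), over a local patch only.
add_spot <- function(img, row, col, sd_major, sd_minor, amplitude, theta) {
  h <- nrow(img)
  w <- ncol(img)
  ext <- ceiling(4 * sd_major)
  r0 <- max(1L, floor(row - ext))
  r1 <- min(h, ceiling(row + ext))
  c0 <- max(1L, floor(col - ext))
  c1 <- min(w, ceiling(col + ext))
  rr <- seq(r0, r1)
  cols <- seq(c0, c1)
  dr <- matrix(rr - row, length(rr), length(cols))
  dc <- matrix(cols - col, length(rr), length(cols), byrow = TRUE)
  a <- dr * cos(theta) + dc * sin(theta)
  b <- -dr * sin(theta) + dc * cos(theta)
  img[rr, cols] <- img[rr, cols] +
    amplitude * exp(-(a^2 / (2 * sd_major^2) + b^2 / (2 * sd_minor^2)))
  img
}

#' Generate a synthetic image with ground truth
#'
#' Builds `background + luminance gradient + spots + vessels + granular
#' noise` from a [synthetic_spec()]. Spot centres are rejection-sampled
#' uniformly (respecting `margin` and `min_separation`); each spot is an
#' anisotropic 2D Gaussian profile (isotropic when
#' `aberration_elongation = 1`); vessels are straight constant-width
#' bright ridges crossing the full image. The same spec (including seed)
#' always produces a bit-identical image; the generator restores the
#' caller's RNG state.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `"synthetic_image"` with elements `image`
#'   (numeric matrix) and `truth`, where `truth` holds `cell_centers` (a
#'   tibble with `row`, `col`, `radius`, `amplitude`, `elongation`,
#'   `theta`), `vessel_masks` (list of linear pixel index vectors),
#'   `true_n_cells`, `true_n_vessels`, and the originating `spec`.
#' @examples
#' sim <- generate_image(synthetic_spec(height = 120, width = 120,
#'                                      n_cells = 5, seed = 42))
#' sim$truth$true_n_cells
#' @export
generate_image <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  # Seed locally with a fixed generator; restore the caller's RNG state
  # (the saved .Random.seed encodes both kind and state).
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  }, add = TRUE)
  set.seed(spec$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  h <- spec$height
  w <- spec$width
  img <- matrix(spec$background_level, h, w)
  lum <- matrix(1, h, w)
  if (spec$gradient_amplitude > 0) {
    lum <- pmax(1 + spec$gradient_amplitude * random_smooth_field(h, w),
                0.05)
  }
  contrast <- matrix(1, h, w)
  if (spec$contrast_gradient > 0) {
    contrast <- pmax(1 + spec$contrast_gradient * random_smooth_field(h, w),
                     0.05)
  }

  # Spot placement by rejection sampling with a retry budget.
  centers <- matrix(numeric(0), 0, 2)
  if (spec$n_cells > 0) {
    lo_r <- spec$margin
    hi_r <- h - spec$margin
    lo_c <- spec$margin
    hi_c <- w - spec$margin
    if (hi_r <= lo_r || hi_c <= lo_c) {
      abort("image too small for the requested spot margin")
    }
    for (i in seq_len(spec$n_cells)) {
      placed <- FALSE
      for (try in seq_len(spec$max_place_tries)) {
        cand <- c(runif(1, lo_r, hi_r), runif(1, lo_c, hi_c))
        if (nrow(centers) == 0 ||
            min(sqrt(colSums((t(centers) - cand)^2))) >=
              spec$min_separation) {
          centers <- rbind(centers, cand)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(sprintf(
          "could not place spot %d with min_separation %.1f after %d tries",
          i, spec$min_separation, spec$max_place_tries))
      }
    }
  }
  n <- nrow(centers)
  radius <- if (n) runif(n, spec$cell_radius_range[1],
                         spec$cell_radius_range[2]) else numeric(0)
  amplitude <- if (n) runif(n, spec$cell_amplitude_range[1],
                            spec$cell_amplitude_range[2]) else numeric(0)
  theta <- if (n) runif(n, 0, pi) else numeric(0)
  for (i in seq_len(n)) {
    img <- add_spot(img, centers[i, 1], centers[i, 2],
                    sd_major = radius[i] * spec$aberration_elongation,
                    sd_minor = radius[i],
                    amplitude = amplitude[i], theta = theta[i])
  }

  # Vessels: straight bright ridges through a random interior point.
  vessel_masks <- list()
  if (spec$n_vessels > 0) {
    rgrid <- matrix(seq_len(h), h, w)
    cgrid <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (v in seq_len(spec$n_vessels)) {
      p <- c(runif(1, 0.2 * h, 0.8 * h), runif(1, 0.2 * w, 0.8 * w))
      ang <- runif(1, 0, pi)
      nvec <- c(-sin(ang), cos(ang))  # unit normal to the ridge
      d <- (rgrid - p[1]) * nvec[1] + (cgrid - p[2]) * nvec[2]
      img <- img + spec$vessel_amplitude *
        exp(-d^2 / (2 * spec$vessel_width^2))
      vessel_masks[[v]] <- which(abs(d) <= 2 * spec$vessel_width)
    }
  }

  if (spec$noise_sd > 0) {
    noise <- matrix(rnorm(h * w), h, w)
    if (spec$noise_grain > 0.3) {
      noise <- gaussian_blur(noise, spec$noise_grain)
      noise <- noise / sd(as.vector(noise))
    }
    img <- img + spec$noise_sd * noise * contrast
  }

  img <- img * lum

  truth <- list(
    cell_centers = tibble(row = centers[, 1], col = centers[, 2],
                          radius = radius, amplitude = amplitude,
                          elongation = rep(spec$aberration_elongation, n),
                          theta = theta),
    vessel_masks = vessel_masks,
    true_n_cells = n,
    true_n_vessels = spec$n_vessels,
    spec = spec
  )
  structure(list(image = img, truth = truth), class = "synthetic_image")
}

#' @export
print.synthetic_image <- function(x, ...) {
  cat(sprintf("<synthetic_image> %d x %d, %d cells, %d vessels (seed %d)\n",
              nrow(x$image), ncol(x$image), x$truth$true_n_cells,
              x$truth$true_n_vessels, x$truth$spec$seed))
  invisible(x)
}

#' Generate a documented failure-mode image
#'
#' Variants of [generate_image()] reproducing the image conditions under
#' which the pipeline is known to miscount:
#' * `"dim_small_spots"`: spots of profile SD ~1 px and amplitude a few
#'   times the noise SD, which land below the area cutoff or below
#'   threshold (undercounting of small, low-luminance cells);
#' * `"aberrated_elongated_spots"`: spots stretched along a random axis
#'   (default elongation 4), which the aspect-ratio rule labels as
#'   vessels;
#' * `"granular_background"`: heavier, coarser-grained background noise;
#' * `"luminance_gradient"`: a strong low-frequency luminance field with
#'   ordinary high-SNR spots — the condition the gain-control stage
#'   exists to neutralize.
#'
#' @param kind One of the four failure-mode names above.
#' @param spec Base [synthetic_spec()] to modify; its seed is kept.
#' @param elongation Stretch factor for `"aberrated_elongated_spots"`.
#' @return A `synthetic_image` list, as from [generate_image()].
#' @export
generate_edge_case <- function(kind = c("dim_small_spots",
                                        "aberrated_elongated_spots",
                                        "granular_background",
                                        "luminance_gradient"),
                               spec = synthetic_spec(),
                               elongation = 4) {
  kind <- match.arg(kind)
  tweak <- switch(kind,
    dim_small_spots = list(cell_radius_range = c(0.7, 1.1),
                           cell_amplitude_range = c(0.02, 0.035),
                           noise_sd = 0.01),
    aberrated_elongated_spots = list(aberration_elongation = elongation),
    granular_background = list(noise_sd = 0.03, noise_grain = 1.5),
    luminance_gradient = list(gradient_amplitude = 0.9)
  )
  spec2 <- do.call(synthetic_spec,
                   modifyList(unclass(spec), tweak))
  out <- generate_image(spec2)
  out$truth$kind <- kind
  out
}

#' Score a detection against synthetic ground truth
#'
#' Greedy nearest-neighbour matching of detected cell centroids to true
#' spot centres: candidate pairs within `match_radius` are sorted by
#' distance and matched one-to-one. Precision is the matched fraction of
#' detections, recall the matched fraction of true spots, and
#' `count_error = n_cells - true_n_cells`. With no detections precision
#' is 1 by convention (no false claims); with no true spots recall is 1.
#'
#' @param result A [detect_cells()] result.
#' @param truth Ground truth from [generate_image()] (the `truth`
#'   element, or the whole `synthetic_image`).
#' @param match_radius Maximum centroid-to-centre distance (pixels) for a
#'   match.
#' @return A one-row tibble: `precision`, `recall`, `count_error`,
#'   `n_matched`, `n_detected`, `n_true`.
#' @export
score_detection <- function(result, truth, match_radius = 3) {
  stopifnot(inherits(result, "darc_detection"))
  if (inherits(truth, "synthetic_image")) truth <- truth$truth
  det <- dplyr::filter(result$blobs, .data$class == "cell")
  n_det <- nrow(det)
  n_true <- truth$true_n_cells
  n_matched <- 0L
  if (n_det > 0 && n_true > 0) {
    d2 <- outer(det$centroid_row, truth$cell_centers$row, "-")^2 +
      outer(det$centroid_col, truth$cell_centers$col, "-")^2
    pairs <- which(d2 <= match_radius^2, arr.ind = TRUE)
    if (nrow(pairs)) {
      ord <- order(d2[pairs])
      used_det <- logical(n_det)
      used_true <- logical(n_true)
      for (i in ord) {
        a <- pairs[i, 1]
        b <- pairs[i, 2]
        if (!used_det[a] && !used_true[b]) {
          used_det[a] <- TRUE
          used_true[b] <- TRUE
          n_matched <- n_matched + 1L
        }
      }
    }
  }
  tibble(
    precision = if (n_det == 0) 1 else n_matched / n_det,
    recall = if (n_true == 0) 1 else n_matched / n_true,
    count_error = n_det - n_true,
    n_matched = n_matched,
    n_detected = n_det,
    n_true = n_true
  )
}
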