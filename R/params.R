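#' Pipeline parameters
#'
#' Constructors for the parameter sets controlling the three stages of the
#' detection pipeline. The five scientific parameters (`s`, `u`, `k`,
#' `a_min`, `aspect_min`) default to the values fixed for automated
#' quantification of 600-pixel-square retinal images; the remaining fields
#' are implementation knobs (boundary handling, kernel truncation,
#' connectivity) with documented defaults.
#'
#' @details
#' * `gain_control_params()` controls Stage 1a, the local luminance/contrast
#'   gain control. `s` is the standard deviation (pixels) of the Gaussian
#'   used to estimate the local mean and SD; `sigma_floor` is a small
#'   positive constant added to the local SD so flat regions do not divide
#'   by zero (`NULL` means: derived per image as `1e-6` times the image
#'   dynamic range, or `1e-6` for a flat image); `truncate` is the kernel
#'   half-width in units of `s`; `pad_mode` is the boundary extension rule
#'   (only `"reflect"`, half-sample symmetric, is implemented).
#' * `band_pass_params()` controls Stage 1b, the Laplacian-of-Gaussian
#'   band-pass filter of scale `u` (pixels). The kernel is negated so an
#'   isolated bright spot yields a positive central response
#'   (`polarity = "bright_positive"`).
#' * `detection_params()` controls Stage 2. The global threshold is
#'   `mean + k * sd` of the filtered image; blobs with area below `a_min`
#'   square pixels are noise; blobs with major/minor axis ratio strictly
#'   above `aspect_min` are vessels; everything else is a cell.
#'   `connectivity` (4 or 8) is the neighbourhood rule for connected
#'   components.
#'
#' @param s Gaussian standard deviation of the gain-control filter, pixels.
#' @param sigma_floor Positive constant added to the local SD, or `NULL`
#'   for the per-image default.
#' @param truncate Kernel half-width as a multiple of the standard
#'   deviation (must be at least 3).
#' @param pad_mode Boundary extension rule; `"reflect"`.
#' @param u Standard deviation of the Gaussian underlying the
#'   Laplacian-of-Gaussian filter, pixels.
#' @param polarity `"bright_positive"`: bright blobs give positive
#'   responses.
#' @param k Threshold multiplier on the filtered-image standard deviation.
#' @param a_min Minimum blob area (square pixels) for a candidate cell.
#' @param aspect_min Minimum major/minor aspect ratio for a candidate
#'   vessel.
#' @param connectivity 4 or 8, the connected-component neighbourhood rule.
#'
#' @return A named list of class `"gain_control_params"`,
#'   `"band_pass_params"` or `"detection_params"`.
#' @examples
#' gain_control_params()
#' detection_params(k = 2.0)
#' @name pipeline-params
NULL

#' @rdname pipeline-params
#' @export
gain_control_params <- function(s = 64, sigma_floor = NULL, truncate = 4,
                                pad_mode = "reflect") {
  stopifnot(is.numeric(s), length(s) == 1, is.finite(s), s > 0)
  if (!is.null(sigma_floor)) {
    stopifnot(is.numeric(sigma_floor), length(sigma_floor) == 1,
              is.finite(sigma_floor), sigma_floor > 0)
  }
  stopifnot(is.numeric(truncate), length(truncate) == 1, truncate >= 3)
  pad_mode <- match.arg(pad_mode, "reflect")
  structure(list(s = s, sigma_floor = sigma_floor, truncate = truncate,
                 pad_mode = pad_mode),
            class = "gain_control_params")
}

#' @rdname pipeline-params
#' @export
band_pass_params <- function(u = 1.5, truncate = 4,
                             polarity = "bright_positive") {
  stopifnot(is.numeric(u), length(u) == 1, is.finite(u), u > 0)
  stopifnot(is.numeric(truncate), length(truncate) == 1, truncate >= 3)
  polarity <- match.arg(polarity, "bright_positive")
  structure(list(u = u, truncate = truncate, polarity = polarity),
            class = "band_pass_params")
}

#' @rdname pipeline-params
#' @export
detection_params <- function(k = 1.8, a_min = 9.0, aspect_min = 3.0,
                             connectivity = 8) {
  stopifnot(is.numeric(k), length(k) == 1, is.finite(k), k > 0)
  stopifnot(is.numeric(a_min), length(a_min) == 1, a_min >= 1)
  stopifnot(is.numeric(aspect_min), length(aspect_min) == 1,
            aspect_min >= 1)
  stopifnot(length(connectivity) == 1, connectivity %in% c(4, 8))
  structure(list(k = k, a_min = a_min, aspect_min = aspect_min,
                 connectivity = as.integer(connectivity)),
            class = "detection_params")
}

#' Run configuration
#'
#' Bundles every pipeline parameter plus the pre-analysis geometry
#' (optional crop, bilinear resize target) and the simulation seed into one
#' serializable object, so a whole batch run is reproducible from a single
#' plain-text file.
#'
#' @param gain_control,band_pass,detection Parameter sets from
#'   [gain_control_params()], [band_pass_params()], [detection_params()].
#' @param resize_target Side length (pixels) images are resized to before
#'   analysis; the pipeline was calibrated on 600-pixel-square images.
#' @param crop Optional [crop_box()] applied before resizing, or `NULL`.
#' @param seed Integer seed for the `simulate` subcommand, or `NULL`.
#' @return A list of class `"run_config"`.
#' @seealso [write_run_config()], [read_run_config()]
#' @export
run_config <- function(gain_control = gain_control_params(),
                       band_pass = band_pass_params(),
                       detection = detection_params(),
                       resize_target = 600,
                       crop = NULL,
                       seed = NULL) {
  stopifnot(inherits(gain_control, "gain_control_params"),
            inherits(band_pass, "band_pass_params"),
            inherits(detection, "detection_params"))
  stopifnot(is.numeric(resize_target), length(resize_target) == 1,
            resize_target >= 2)
  if (!is.null(crop)) stopifnot(inherits(crop, "crop_box"))
  if (!is.null(seed)) stopifnot(is.numeric(seed), length(seed) == 1)
  structure(list(gain_control = gain_control, band_pass = band_pass,
                 detection = detection,
                 resize_target = as.integer(resize_target),
                 crop = crop, seed = if (!is.null(seed)) as.integer(seed),
                 rng_kind = "Mersenne-Twister"),
            class = "run_config")
}

#' Serialize a run configuration to a plain-text key-value file
#'
#' One `key = value` pair per line; numeric values are written with full
#' precision so that `read_run_config(write_run_config(cfg))` reproduces
#' `cfg` exactly.
#'
#' @param config A [run_config()].
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  num <- function(x) format(x, digits = 17, scientific = TRUE)
  kv <- c(
    s = num(config$gain_control$s),
    sigma_floor = if (is.null(config$gain_control$sigma_floor)) "auto"
                  else num(config$gain_control$sigma_floor),
    gc_truncate = num(config$gain_control$truncate),
    pad_mode = config$gain_control$pad_mode,
    u = num(config$band_pass$u),
    bp_truncate = num(config$band_pass$truncate),
    polarity = config$band_pass$polarity,
    k = num(config$detection$k),
    a_min = num(config$detection$a_min),
    aspect_min = num(config$detection$aspect_min),
    connectivity = as.character(config$detection$connectivity),
    resize_target = as.character(config$resize_target),
    crop = if (is.null(config$crop)) "none"
           else paste(config$crop$top, config$crop$left,
                      config$crop$height, config$crop$width, sep = ","),
    seed = if (is.null(config$seed)) "none" else as.character(config$seed),
    rng_kind = config$rng_kind
  )
  writeLines(paste(names(kv), kv, sep = " = "), path)
  invisible(path)
}

#' Read a run configuration written by [write_run_config()]
#'
#' @param path File path to read.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  m <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*?)\\s*$", lines))
  bad <- lengths(m) != 3
  if (any(bad)) {
    abort(paste0("malformed config line: ", lines[which(bad)[1]]))
  }
  kv <- stats::setNames(vapply(m, `[`, "", 3), vapply(m, `[`, "", 2))
  get_num <- function(key, default) {
    if (!key %in% names(kv)) return(default)
    as.numeric(kv[[key]])
  }
  crop <- NULL
  if (!is.null(kv[["crop"]]) && !identical(kv[["crop"]], "none")) {
    v <- as.numeric(strsplit(kv[["crop"]], ",")[[1]])
    if (length(v) != 4) abort("crop must be 'top,left,height,width'")
    crop <- crop_box(v[1], v[2], v[3], v[4])
  }
  sf <- kv[["sigma_floor"]] %||% "auto"
  run_config(
    gain_control = gain_control_params(
      s = get_num("s", 64),
      sigma_floor = if (identical(sf, "auto")) NULL else as.numeric(sf),
      truncate = get_num("gc_truncate", 4),
      pad_mode = kv[["pad_mode"]] %||% "reflect"
    ),
    band_pass = band_pass_params(
      u = get_num("u", 1.5),
      truncate = get_num("bp_truncate", 4),
      polarity = kv[["polarity"]] %||% "bright_positive"
    ),
    detection = detection_params(
      k = get_num("k", 1.8),
      a_min = get_num("a_min", 9),
      aspect_min = get_num("aspect_min", 3),
      connectivity = get_num("connectivity", 8)
    ),
    resize_target = get_num("resize_target", 600),
    crop = crop,
    seed = if (identical(kv[["seed"]] %||% "none", "none")) NULL
           else as.integer(kv[["seed"]])
  )
}
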