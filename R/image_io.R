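#' Grayscale image container
#'
#' Wraps an H x W integer matrix of 8-bit gray levels together with a text
#' label for its origin. Rows are image rows (top to bottom), columns image
#' columns (left to right). All downstream analysis (binarization, box
#' counting, co-occurrence matrices) consumes this container.
#'
#' @param pixels numeric or integer matrix; values must lie in [0, 255] and
#'   are stored as integers.
#' @param source optional text label (typically the file path).
#' @return An object of class `gray_image` with elements `pixels`, `height`,
#'   `width` and `source`.
#' @export
gray_image <- function(pixels, source = "") {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have at least one row and one column")
  }
  if (anyNA(pixels)) stop("image contains missing values")
  if (any(pixels < 0 | pixels > 255)) {
    stop("gray levels must lie in [0, 255]")
  }
  if (any(pixels != round(pixels))) {
    stop("gray levels must be integers; round or rescale before constructing")
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         source = as.character(source)),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, gray range [%d, %d]%s\n",
              x$height, x$width, min(x$pixels), max(x$pixels),
              if (nzchar(x$source)) paste0(", source: ", x$source) else ""))
  invisible(x)
}

#' Binary (foreground) mask
#'
#' @param mask logical matrix; `TRUE` marks foreground (particle) pixels.
#' @param threshold gray level the mask was binarized at, or `NA` for masks
#'   constructed directly (e.g. analytic fractal fixtures).
#' @return An object of class `binary_image`.
#' @export
binary_image <- function(mask, threshold = NA_integer_) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("`mask` must be a logical matrix")
  }
  if (anyNA(mask)) stop("mask contains missing values")
  structure(list(mask = mask, threshold = threshold), class = "binary_image")
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image> %d x %d px, %d foreground (%.1f%%), threshold %s\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask), format(x$threshold)))
  invisible(x)
}

# BT.601 luminance weights; equal channels map to themselves because the
# weights sum to 1.
.lum_weights <- c(0.299, 0.587, 0.114)

# round-half-up (base round() is half-to-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Load an image file as a grayscale image
#'
#' Reads an 8-bit grayscale or RGB raster (PNG, TIFF or JPEG) and converts it
#' to a [gray_image]. RGB inputs are reduced with the ITU-R BT.601 luminance
#' weights 0.299 R + 0.587 G + 0.114 B, rounded half-up. Decoders report
#' intensities on [0, 1]; they are mapped back to [0, 255]. Inputs with more
#' than 8 bits per channel are rescaled onto [0, 255] when `rescale_depth`
#' is `TRUE` and rejected otherwise.
#'
#' @param path path to the image file.
#' @param rescale_depth logical; rescale deeper-than-8-bit inputs instead of
#'   failing.
#' @return A [gray_image].
#' @export
load_image <- function(path, rescale_depth = TRUE) {
  if (!file.exists(path)) stop("cannot read image, file not found: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot decode image '", path,
                                           "': ", conditionMessage(e)))
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L) {
    if (dim(dat)[3] >= 3L) {
      dat <- .lum_weights[1] * dat[, , 1] +
        .lum_weights[2] * dat[, , 2] +
        .lum_weights[3] * dat[, , 3]
    } else {
      dat <- dat[, , 1]
    }
  }
  g <- dat * 255
  if (max(g) > 255 + 1e-9) {
    if (!rescale_depth) stop("image '", path, "' exceeds 8-bit range; ",
                             "set rescale_depth = TRUE to rescale")
    g <- g / max(g) * 255
  }
  g <- pmin(pmax(round_half_up(g), 0), 255)
  # EBImage stores (x, y): transpose to rows = image rows
  gray_image(t(g), source = path)
}

#' Binarize a grayscale image at a threshold
#'
#' Foreground is defined as strictly darker than the threshold
#' (`intensity < T`): in transmitted light, particles are dark on a bright
#' field. Masks are therefore nested: the foreground at a lower threshold is
#' a subset of the foreground at any higher threshold.
#'
#' @param img a [gray_image].
#' @param threshold gray level in [0, 255].
#' @return A [binary_image]. Degenerate all-`TRUE`/all-`FALSE` masks are valid.
#' @export
binarize <- function(img, threshold) {
  stopifnot(inherits(img, "gray_image"))
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 255) {
    stop("`threshold` must be a single gray level in [0, 255]")
  }
  binary_image(img$pixels < threshold, threshold = as.integer(threshold))
}

#' Binarize across a sweep of thresholds
#'
#' Applies [binarize()] at every threshold of an arithmetic sequence, by
#' default 0, 5, ..., 255 (52 levels).
#'
#' @param img a [gray_image].
#' @param start,stop,step sweep parameters; `start <= stop`, `step >= 1`.
#' @return A named list of [binary_image] objects, names `"T<level>"`, in
#'   ascending threshold order, with the numeric thresholds in attribute
#'   `"thresholds"`.
#' @export
threshold_sweep <- function(img, start = 0, stop = 255, step = 5) {
  stopifnot(inherits(img, "gray_image"))
  if (start > stop) stop("`start` must not exceed `stop`")
  if (step < 1) stop("`step` must be at least 1")
  ts <- seq(start, stop, by = step)
  out <- lapply(ts, function(T) binarize(img, T))
  names(out) <- paste0("T", ts)
  attr(out, "thresholds") <- ts
  out
}

#' Spatial calibration record
#'
#' Links pixel lengths to physical lengths. Supply either the measured
#' pixels-per-millimetre or a micrometres-per-pixel value directly; the
#' default is the rounded 1.7 um/px of a 1x transmitted-light acquisition in
#' which 1 mm spans 575 +/- 10 pixels.
#'
#' @param pixels_per_mm measured pixels per millimetre (optional).
#' @param um_per_pixel micrometres per pixel; derived as
#'   `1000 / pixels_per_mm` when not given explicitly.
#' @return An object of class `calibration`.
#' @export
calibration <- function(pixels_per_mm = NULL, um_per_pixel = NULL) {
  if (is.null(um_per_pixel)) {
    if (is.null(pixels_per_mm)) {
      um_per_pixel <- 1.7
      pixels_per_mm <- 1000 / um_per_pixel
    } else {
      if (pixels_per_mm <= 0) stop("`pixels_per_mm` must be positive")
      um_per_pixel <- 1000 / pixels_per_mm
    }
  } else {
    if (um_per_pixel <= 0) stop("`um_per_pixel` must be positive")
    if (is.null(pixels_per_mm)) pixels_per_mm <- 1000 / um_per_pixel
  }
  structure(list(pixels_per_mm = pixels_per_mm, um_per_pixel = um_per_pixel),
            class = "calibration")
}

#' Convert a pixel length to micrometres
#'
#' Multiplies by the calibration's um-per-pixel factor and truncates to the
#' integer part, which reproduces conventional reported box sizes (e.g.
#' 128 px at 1.7 um/px is 217.6, reported as 217 um).
#'
#' @param length_px non-negative pixel length(s).
#' @param calib a [calibration]; defaults to 1.7 um/px.
#' @return Integer micrometre length(s).
#' @export
px_to_um <- function(length_px, calib = calibration()) {
  stopifnot(inherits(calib, "calibration"))
  if (any(length_px < 0)) stop("`length_px` must be non-negative")
  as.integer(floor(length_px * calib$um_per_pixel))
}

#' Write a binary mask as an 8-bit PNG (foreground 255, background 0)
#'
#' @param bimg a [binary_image].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(bimg, path) {
  stopifnot(inherits(bimg, "binary_image"))
  EBImage::writeImage(EBImage::Image(t(bimg$mask) * 1), path, type = "png")
  invisible(path)
}

#' Write a grayscale image as an 8-bit PNG
#'
#' @param img a [gray_image].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  stopifnot(inherits(img, "gray_image"))
  EBImage::writeImage(EBImage::Image(t(img$pixels) / 255), path, type = "png")
  invisible(path)
}
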