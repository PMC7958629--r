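#' Grayscale image container
#'
#' A `gray_image` is a numeric matrix (rows = image rows, 0-based `(row, col)`
#' coordinates in all exported geometry) carrying a `depth` attribute:
#' `"8bit"`, `"16bit"` or `"float"`. Integer depths hold whole-number
#' intensities in `[0, 2^depth - 1]`; float images hold finite doubles.
#'
#' @param pixels numeric matrix of intensities.
#' @param depth one of `"8bit"`, `"16bit"`, `"float"`.
#' @return a `gray_image` object.
#' @export
gray_image <- function(pixels, depth = c("8bit", "16bit", "float")) {
  depth <- match.arg(depth)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must be at least 1x1")
  # drop any reader metadata attributes; keep the bare grid
  pixels <- matrix(as.double(pixels), nrow(pixels), ncol(pixels))
  if (!all(is.finite(pixels))) stop("pixel values must be finite")
  if (depth != "float") {
    mx <- depth_max(depth)
    if (any(pixels < 0 | pixels > mx))
      stop(sprintf("values outside [0, %d] for %s depth", mx, depth))
    if (any(pixels != floor(pixels)))
      stop("integer depths require whole-number intensities")
  }
  structure(pixels, depth = depth, class = c("gray_image", "matrix", "array"))
}

#' @rdname gray_image
#' @param x object to test or coerce.
#' @export
is_gray_image <- function(x) inherits(x, "gray_image")

#' @rdname gray_image
#' @export
gray_depth <- function(x) {
  d <- attr(x, "depth")
  if (is.null(d)) "float" else d
}

depth_max <- function(depth) switch(depth, "8bit" = 255L, "16bit" = 65535L,
                                    stop("float depth has no fixed maximum"))

#' @rdname gray_image
#' @export
as_gray_image <- function(x, depth = NULL) {
  if (is_gray_image(x) && is.null(depth)) return(x)
  if (is_gray_image(x)) return(gray_image(pixels(x), depth))
  if (is.null(depth)) {
    depth <- if (all(x == floor(x))) {
      if (max(x) <= 255) "8bit" else if (max(x) <= 65535) "16bit" else "float"
    } else "float"
  }
  gray_image(as.matrix(x), depth)
}

#' @rdname gray_image
#' @export
pixels <- function(x) {
  y <- unclass(x)
  attr(y, "depth") <- NULL
  y
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %dx%d, %s, range [%g, %g]>\n",
              nrow(x), ncol(x), gray_depth(x), min(x), max(x)))
  invisible(x)
}

# round-half-up, the rounding convention used throughout
round_half_up <- function(x) floor(x + 0.5)

#' Read a grayscale image from PNG or TIFF
#'
#' RGB inputs are converted by ITU-R 601 luminance weighting
#' (`0.299 R + 0.587 G + 0.114 B`, rounded half-up); the stored bit depth is
#' preserved (8- or 16-bit).
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return a [gray_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    bits <- attr(arr, "info")$bit.depth
    if (is.null(bits)) bits <- 8L
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(arr, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
  } else {
    stop("unsupported image format: .", ext, " (PNG or TIFF required)")
  }
  if (!bits %in% c(8L, 16L))
    stop("unsupported sample depth: ", bits, "-bit (8 or 16 supported)")
  mx <- if (bits == 8L) 255 else 65535
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc == 2L) {            # gray + alpha
      g <- arr[, , 1]
    } else if (nc %in% c(3L, 4L)) {
      g <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else stop("unsupported channel count: ", nc)
  } else {
    g <- arr
  }
  g <- matrix(as.double(g), dim(arr)[1], dim(arr)[2])
  gray_image(round_half_up(g * mx), depth = if (bits == 8L) "8bit" else "16bit")
}

#' Write a grayscale image to PNG or TIFF
#'
#' Integer-depth images round-trip bit-exactly (8-bit PNG; 8- or 16-bit TIFF).
#' PNG output is 8-bit only; float images must be rescaled to an integer depth
#' first (see [rescale_to_8bit()]).
#'
#' @param img a [gray_image()] of integer depth.
#' @param path destination path ending in `.png`, `.tif` or `.tiff`.
#' @export
write_image <- function(img, path) {
  img <- as_gray_image(img)
  depth <- gray_depth(img)
  if (depth == "float")
    stop("cannot write float-depth image; rescale to an integer depth first")
  mx <- depth_max(depth)
  ext <- tolower(tools::file_ext(path))
  x <- pixels(img) / mx
  if (ext == "png") {
    if (depth == "16bit")
      stop("16-bit PNG output is not supported; write a TIFF instead")
    ok <- try(png::writePNG(x, path), silent = TRUE)
  } else if (ext %in% c("tif", "tiff")) {
    ok <- try(tiff::writeTIFF(x, path, bits.per.sample = if (depth == "8bit") 8L else 16L),
              silent = TRUE)
  } else {
    stop("unsupported image format: .", ext, " (PNG or TIFF required)")
  }
  if (inherits(ok, "try-error"))
    stop("cannot write image to ", path)
  invisible(NULL)
}

#' Rescale intensities linearly onto the 8-bit range
#'
#' Maps `[min(img), max(img)]` linearly onto `[0, 255]` with half-up rounding.
#' A constant image maps to all zeros (documented convention).
#'
#' @param img a [gray_image()] or numeric matrix of any depth.
#' @return an 8-bit [gray_image()].
#' @export
rescale_to_8bit <- function(img) {
  x <- pixels(as_gray_image(img))
  lo <- min(x); hi <- max(x)
  y <- if (hi > lo) round_half_up((x - lo) / (hi - lo) * 255) else x * 0
  gray_image(y, "8bit")
}
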