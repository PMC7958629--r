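#' Preprocessing parameters
#'
#' Defaults are the reference pipeline settings: a 3x3 mean filter before
#' background subtraction (`mean_radius_pre = 1`), rolling-ball radius 100,
#' median radius 4, a second mean filter of radius 3, and a bilateral filter
#' with spatial and range sigmas of 3 (range sigma interpreted on the 0-255
#' scale, since the bilateral step follows the 8-bit rescale).
#'
#' @param median_radius,mean_radius_pre,mean_radius_post window radii in pixels.
#' @param sigma_d,sigma_r bilateral spatial (pixels) / range (intensity) sigmas.
#' @param ball_radius rolling-ball radius in pixels.
#' @param light_background subtract a background estimated above the image
#'   (dark objects on a bright field) rather than below it. The pipeline
#'   default is `TRUE`: erythrocytes are darker than the illuminated field.
#' @param ball_method `"auto"` (exact opening for small radii, block-min
#'   down-sampled estimate for large ones), `"exact"`, or `"downsample"`.
#' @return a list of validated parameters.
#' @export
filter_params <- function(median_radius = 4, mean_radius_pre = 1,
                          mean_radius_post = 3, sigma_d = 3, sigma_r = 3,
                          ball_radius = 100, light_background = TRUE,
                          ball_method = c("auto", "exact", "downsample")) {
  ball_method <- match.arg(ball_method)
  p <- list(median_radius = median_radius, mean_radius_pre = mean_radius_pre,
            mean_radius_post = mean_radius_post, sigma_d = sigma_d,
            sigma_r = sigma_r, ball_radius = ball_radius,
            light_background = isTRUE(light_background),
            ball_method = ball_method)
  for (f in c("median_radius", "mean_radius_pre", "mean_radius_post",
              "sigma_d", "sigma_r", "ball_radius"))
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || p[[f]] <= 0)
      stop("filter parameter ", f, " must be a positive scalar")
  p
}

filtered_like <- function(y, img) {
  depth <- gray_depth(img)
  if (depth != "float") y <- pmin(pmax(y, 0), depth_max(depth))
  gray_image(y, depth)
}

#' Median filter
#'
#' Each output pixel is the median of its `(2 radius + 1)^2` window (odd
#' window, so the median is an observed value); edges replicate. Removes
#' isolated bright or dark spot noise without shifting uniform regions.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param radius window radius in pixels (>= 1).
#' @return filtered image, same depth as the input.
#' @export
median_filter <- function(img, radius) {
  stopifnot(radius >= 1)
  img <- as_gray_image(img)
  filtered_like(cpp_median_filter(pixels(img), as.integer(radius)), img)
}

#' Mean filter
#'
#' Arithmetic mean over the window, rounded half-up for integer depths;
#' edges replicate.
#'
#' @inheritParams median_filter
#' @return filtered image, same depth as the input.
#' @export
mean_filter <- function(img, radius) {
  stopifnot(radius >= 1)
  img <- as_gray_image(img)
  y <- cpp_mean_filter(pixels(img), as.integer(radius), gray_depth(img) != "float")
  filtered_like(y, img)
}

#' Bilateral filter
#'
#' Edge-preserving smoothing: each output pixel is a normalized weighted
#' average of its window, with weights the product of a spatial Gaussian of
#' scale `sigma_d` and a range Gaussian of scale `sigma_r` on the intensity
#' difference. The window is truncated at `ceiling(3 sigma_d)`. Intended for
#' 8-bit input (the pipeline applies it after the 8-bit rescale so that
#' `sigma_r` reads on the 0-255 scale).
#'
#' @inheritParams median_filter
#' @param sigma_d spatial Gaussian scale, pixels.
#' @param sigma_r range Gaussian scale, intensity units.
#' @export
bilateral_filter <- function(img, sigma_d = 3, sigma_r = 3) {
  stopifnot(sigma_d > 0, sigma_r > 0)
  img <- as_gray_image(img)
  y <- cpp_bilateral_filter(pixels(img), sigma_d, sigma_r,
                            gray_depth(img) != "float")
  filtered_like(y, img)
}

#' Gaussian blur
#'
#' Separable Gaussian smoothing, kernel truncated at `ceiling(3 sigma)`,
#' edge replication. Used by the mock-image renderer and as the large-
#' `sigma_r` limit of the bilateral filter.
#'
#' @inheritParams median_filter
#' @param sigma Gaussian scale in pixels.
#' @export
gaussian_blur <- function(img, sigma) {
  img <- as_gray_image(img)
  y <- cpp_gaussian_blur(pixels(img), sigma, gray_depth(img) != "float")
  filtered_like(y, img)
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale morphological opening of the
#' image by a ball-shaped (spherical-cap height profile) structuring element
#' and subtracts it, clamping at zero. The ball cannot enter peaks narrower
#' than its diameter, so narrow structures survive while smooth illumination
#' gradients are removed.
#'
#' With `light_background = TRUE` the roles invert: the image is inverted
#' about the depth maximum, opened, subtracted and re-inverted, so that dark
#' objects on a bright uneven field end up as dark objects on a flat bright
#' field. This is the mode the erythrocyte pipeline uses.
#'
#' `method = "downsample"` estimates the background on a block-minimum
#' shrunken grid (after a light 3x3 mean to de-bias the minimum under noise)
#' with a proportionally reduced ball, then enlarges bilinearly — the
#' standard fast dialect for large radii. `"auto"` picks the exact opening
#' for `ball_radius <= 16` and the down-sampled estimate above that.
#'
#' @inheritParams median_filter
#' @param ball_radius structuring-element radius in pixels (>= 1).
#' @param light_background flatten a bright background under dark objects.
#' @param method `"auto"`, `"exact"` or `"downsample"`.
#' @return image of the same depth with the background removed.
#' @export
subtract_background <- function(img, ball_radius, light_background = FALSE,
                                method = c("auto", "exact", "downsample")) {
  stopifnot(ball_radius >= 1)
  method <- match.arg(method)
  img <- as_gray_image(img)
  x <- pixels(img)
  mx <- if (gray_depth(img) == "float") max(x) else depth_max(gray_depth(img))
  if (light_background) x <- mx - x
  bg <- ball_background(x, ball_radius, method)
  bg <- pmin(bg, x)                       # background never exceeds the image
  y <- x - bg
  if (light_background) y <- mx - y
  if (gray_depth(img) != "float") y <- round_half_up(y)
  filtered_like(y, img)
}

ball_background <- function(x, radius, method = "auto") {
  if (method == "auto")
    method <- if (radius <= 16) "exact" else "downsample"
  if (method == "exact") return(cpp_ball_opening(x, radius))
  s <- if (radius <= 32) 2L else if (radius <= 100) 4L else 8L
  sm <- cpp_mean_filter(x, 1L, FALSE)
  small <- cpp_block_min(sm, s)
  bg_small <- cpp_ball_opening(small, radius / s)
  bg <- EBImage::resize(EBImage::Image(bg_small), w = nrow(x) + 0, h = ncol(x) + 0,
                        filter = "bilinear")
  matrix(EBImage::imageData(bg), nrow(x), ncol(x))
}

#' Full preprocessing chain
#'
#' Applies, in order: mean filter (radius `mean_radius_pre`), rolling-ball
#' background subtraction (`ball_radius`), median filter (`median_radius`),
#' mean filter (`mean_radius_post`), linear rescale to 8-bit, bilateral
#' filter (`sigma_d`, `sigma_r`). With `probability_map_mode = TRUE` (input
#' is an externally produced per-pixel foreground probability rendered as a
#' grayscale image) everything except the 8-bit rescale and the bilateral
#' filter is skipped.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param params a [filter_params()] list.
#' @param probability_map_mode bilateral-only preprocessing.
#' @return an 8-bit [gray_image()].
#' @export
preprocess_image <- function(img, params = filter_params(),
                             probability_map_mode = FALSE) {
  img <- as_gray_image(img)
  if (!probability_map_mode) {
    img <- mean_filter(img, params$mean_radius_pre)
    img <- subtract_background(img, params$ball_radius,
                               light_background = params$light_background,
                               method = params$ball_method)
    img <- median_filter(img, params$median_radius)
    img <- mean_filter(img, params$mean_radius_post)
  }
  img <- rescale_to_8bit(img)
  bilateral_filter(img, params$sigma_d, params$sigma_r)
}
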