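#' Parameters of the artificial erythrocyte image generator
#'
#' The renderer emulates the bright-field appearance the segmentation
#' pipeline targets: dark cells whose inner area is brighter than the rim
#' (a flattened biconcave profile), on a bright background that peaks at
#' the image centre, blurred by Gaussian smoothing and degraded by additive
#' Gaussian noise.
#'
#' Intensity defaults (rim 90, interior 140, background 200, centre-bump
#' amplitude 30 on the 8-bit scale) are fixed, documented conventions: they
#' put the cell/background contrast in the regime real bright-field smears
#' show (cells well below a bright field) while remaining configurable.
#'
#' @param height,width image size in pixels.
#' @param n_objects number of cells.
#' @param radius_range `[r_min, r_max]` semi-major axis range in pixels.
#' @param min_gap minimum edge-to-edge separation in pixels; negative values
#'   permit overlaps up to `|min_gap|` deep (touching pairs).
#' @param border_margin minimum clearance between any cell edge and the
#'   image border (no ground-truth object is border-clipped).
#' @param eccentricity_range `[1, e_max]` ratio of semi-major to semi-minor
#'   axis.
#' @param inner_erosion_radius erosion defining the brighter inner area.
#' @param edge_intensity,inner_intensity,background_base 8-bit paint values.
#' @param background_gauss_amplitude centre-to-corner background modulation.
#' @param background_gauss_sigma scale of the background bump (default
#'   `0.4 * min(height, width)`).
#' @param smoothing_radius Gaussian smoothing radius (sigma = radius / 2).
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed integer seed driving layout and noise.
#' @export
mock_params <- function(height = 1024, width = 1024, n_objects = 124,
                        radius_range = c(14, 22), min_gap = 3,
                        border_margin = 25, eccentricity_range = c(1, 1.3),
                        inner_erosion_radius = 3, edge_intensity = 90,
                        inner_intensity = 140, background_base = 200,
                        background_gauss_amplitude = 30,
                        background_gauss_sigma = NULL,
                        smoothing_radius = 3, noise_sd = 6, seed = 1L) {
  if (is.null(background_gauss_sigma))
    background_gauss_sigma <- 0.4 * min(height, width)
  p <- list(height = height, width = width, n_objects = n_objects,
            radius_range = radius_range, min_gap = min_gap,
            border_margin = border_margin,
            eccentricity_range = eccentricity_range,
            inner_erosion_radius = inner_erosion_radius,
            edge_intensity = edge_intensity,
            inner_intensity = inner_intensity,
            background_base = background_base,
            background_gauss_amplitude = background_gauss_amplitude,
            background_gauss_sigma = background_gauss_sigma,
            smoothing_radius = smoothing_radius, noise_sd = noise_sd,
            seed = as.integer(seed))
  stopifnot(p$radius_range[1] <= p$radius_range[2], p$n_objects >= 0,
            p$eccentricity_range[1] >= 1,
            all(c(p$edge_intensity, p$inner_intensity,
                  p$background_base) >= 0),
            all(c(p$edge_intensity, p$inner_intensity,
                  p$background_base) <= 255))
  p
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# rasterize one ellipse into a logical matrix of the scene size (bbox only)
rasterize_ellipse <- function(h, w, cy, cx, a, b, theta) {
  r <- ceiling(a) + 1L
  rows <- max(1L, floor(cy) - r + 1L):min(h, ceiling(cy) + r + 1L)
  cols <- max(1L, floor(cx) - r + 1L):min(w, ceiling(cx) + r + 1L)
  dy <- outer(rows - 1 - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - 1 - cx)
  xr <- dy * cos(theta) + dx * sin(theta)
  yr <- -dy * sin(theta) + dx * cos(theta)
  inside <- (xr / a)^2 + (yr / b)^2 <= 1
  list(rows = rows, cols = cols, inside = inside)
}

#' Generate a ground-truth cell layout
#'
#' Places `n_objects` ellipses with radii, eccentricity and orientation drawn
#' uniformly from the configured ranges; centres are rejection-sampled
#' (at most 10,000 attempts per object) so that every pair respects
#' `min_gap` and every object edge keeps `border_margin` of clearance from
#' the border. Deterministic given `params$seed`.
#'
#' @param params a [mock_params()] list.
#' @return list with `mask` (logical) and `labels` (integer, 1..n).
#' @export
generate_layout <- function(params = mock_params()) {
  h <- params$height; w <- params$width
  mask <- matrix(FALSE, h, w)
  labels <- matrix(0L, h, w)
  if (params$n_objects == 0L) return(list(mask = mask, labels = labels))
  gap <- params$min_gap
  with_seed(params$seed, {
    for (k in seq_len(params$n_objects)) {
      placed <- FALSE
      for (attempt in seq_len(10000L)) {
        a <- runif(1, params$radius_range[1], params$radius_range[2])
        ecc <- runif(1, params$eccentricity_range[1],
                     params$eccentricity_range[2])
        b <- a / ecc
        theta <- runif(1, 0, pi)
        # border_margin is edge-to-border clearance: keep the whole object
        # (semi-major axis a) at least that far inside
        if (h - 1 < 2 * (params$border_margin + a) ||
            w - 1 < 2 * (params$border_margin + a)) next
        cy <- runif(1, params$border_margin + a, h - 1 - params$border_margin - a)
        cx <- runif(1, params$border_margin + a, w - 1 - params$border_margin - a)
        e <- rasterize_ellipse(h, w, cy, cx, a, b, theta)
        cand <- e$inside
        if (!any(cand)) next
        # separation test on the candidate's neighbourhood
        test <- if (gap >= 1) cpp_binary_dilate(cand, gap)
                else if (gap < 0) cpp_binary_erode(cand, -gap)
                else cand
        occ <- mask[e$rows, e$cols, drop = FALSE]
        if (any(test & occ)) next
        sub <- labels[e$rows, e$cols, drop = FALSE]
        sub[cand] <- k                  # later object wins on rare overlaps
        labels[e$rows, e$cols] <- sub
        msub <- mask[e$rows, e$cols, drop = FALSE]
        mask[e$rows, e$cols] <- msub | cand
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place object ", k, " after 10000 attempts; ",
             "reduce n_objects or radii")
    }
  })
  list(mask = mask, labels = labels)
}

#' Render an artificial erythrocyte image over a ground-truth mask
#'
#' Paints the eroded interior at `inner_intensity` and the remaining rim at
#' `edge_intensity` over a centre-brightened background
#' (`background_base - amplitude + amplitude * exp(-d^2 / (2 sigma^2))`),
#' smooths with a Gaussian (sigma = `smoothing_radius / 2`, truncated at 3
#' sigma), adds zero-mean Gaussian noise of `noise_sd` and clips to the
#' 8-bit range. Deterministic given `params$seed`.
#'
#' @param truth logical ground-truth mask matching `params` dimensions.
#' @param params a [mock_params()] list.
#' @return an 8-bit [gray_image()].
#' @export
render_mock <- function(truth, params = mock_params()) {
  h <- params$height; w <- params$width
  stopifnot(nrow(truth) == h, ncol(truth) == w)
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  d2 <- outer((seq_len(h) - 1 - cy)^2, rep(1, w)) +
        outer(rep(1, h), (seq_len(w) - 1 - cx)^2)
  amp <- params$background_gauss_amplitude
  img <- params$background_base - amp +
    amp * exp(-d2 / (2 * params$background_gauss_sigma^2))
  inner <- erode_mask(truth, params$inner_erosion_radius)
  img[truth] <- params$edge_intensity
  img[inner] <- params$inner_intensity
  if (params$smoothing_radius > 0)
    img <- cpp_gaussian_blur(img, params$smoothing_radius / 2, FALSE)
  if (params$noise_sd > 0)
    img <- img + with_seed(params$seed + 1L,
                           matrix(rnorm(h * w, 0, params$noise_sd), h, w))
  gray_image(pmin(pmax(round_half_up(img), 0), 255), "8bit")
}

#' Generate a complete mock scene
#'
#' @param params a [mock_params()] list.
#' @return a `mock_scene`: list with `image`, `truth_mask`, `truth_labels`,
#'   `params`.
#' @export
mock_scene <- function(params = mock_params()) {
  lay <- generate_layout(params)
  img <- render_mock(lay$mask, params)
  structure(list(image = img, truth_mask = lay$mask,
                 truth_labels = lay$labels, params = params),
            class = "mock_scene")
}

#' @export
print.mock_scene <- function(x, ...) {
  cat(sprintf("<mock_scene %dx%d, %d objects, smoothing %g, noise sd %g>\n",
              x$params$height, x$params$width, count_objects(x$truth_labels),
              x$params$smoothing_radius, x$params$noise_sd))
  invisible(x)
}

resize_matrix <- function(x, h, w, bilinear = TRUE) {
  out <- EBImage::resize(EBImage::Image(x), w = h, h = w,
                         filter = if (bilinear) "bilinear" else "none")
  matrix(EBImage::imageData(out), h, w)
}

crop_scene <- function(scene, r0, c0, hh, ww) {
  rows <- (r0 + 1L):(r0 + hh); cols <- (c0 + 1L):(c0 + ww)
  p <- scene$params
  p$height <- hh; p$width <- ww
  labs <- relabel(scene$truth_labels[rows, cols, drop = FALSE])
  p$n_objects <- count_objects(labs)
  structure(list(image = gray_image(pixels(scene$image)[rows, cols,
                                                        drop = FALSE], "8bit"),
                 truth_mask = labs > 0L, truth_labels = labs, params = p),
            class = "mock_scene")
}

rescale_scene <- function(scene, s) {
  hh <- max(1L, round(scene$params$height * s))
  ww <- max(1L, round(scene$params$width * s))
  img <- resize_matrix(pixels(scene$image), hh, ww, bilinear = TRUE)
  img <- gray_image(pmin(pmax(round_half_up(img), 0), 255), "8bit")
  labs <- resize_matrix(scene$truth_labels + 0.0, hh, ww, bilinear = FALSE)
  labs <- relabel(matrix(as.integer(round(labs)), hh, ww))
  p <- scene$params
  p$height <- hh; p$width <- ww; p$n_objects <- count_objects(labs)
  structure(list(image = img, truth_mask = labs > 0L, truth_labels = labs,
                 params = p), class = "mock_scene")
}

#' Crop/rescale robustness suite
#'
#' Randomly crops the scene `n_crops` times (crop sides drawn uniformly from
#' `crop_frac` of each dimension) and emits each crop at scale 1 plus every
#' listed scaling factor (bilinear for the image, nearest-neighbour for the
#' ground truth): `n_crops * (1 + length(scales))` scenes. With the defaults
#' (5 crops, scales 0.7 and 1.3) this yields the standard 15-image
#' robustness protocol.
#'
#' @param scene a [mock_scene()].
#' @param n_crops number of random crops.
#' @param scales additional scaling factors.
#' @param seed integer seed for crop geometry.
#' @param crop_frac range of crop side length as a fraction of the source.
#' @return list of `mock_scene` objects.
#' @export
crop_rescale_suite <- function(scene, n_crops = 5, scales = c(0.7, 1.3),
                               seed = 1L, crop_frac = c(0.45, 1)) {
  h <- scene$params$height; w <- scene$params$width
  out <- list()
  with_seed(seed, {
    for (k in seq_len(n_crops)) {
      hh <- round(runif(1, crop_frac[1] * h, crop_frac[2] * h))
      ww <- round(runif(1, crop_frac[1] * w, crop_frac[2] * w))
      if (hh > h || ww > w) stop("crop window larger than the image")
      r0 <- floor(runif(1, 0, h - hh + 1)); c0 <- floor(runif(1, 0, w - ww + 1))
      cr <- crop_scene(scene, r0, c0, hh, ww)
      out[[length(out) + 1L]] <- cr
      for (s in scales) out[[length(out) + 1L]] <- rescale_scene(cr, s)
    }
  })
  out
}
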