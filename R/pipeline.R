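#' Pipeline configuration
#'
#' Bundles every stage's parameters at the reference defaults: mean radii
#' 1 (pre) and 3 (post), rolling ball 100, median radius 4, bilateral
#' sigmas 3/3, erosion radius 2, watershed threshold/level 0.004/0.4, size
#' threshold 25, ROI margin 10, mask dilation 6, short-axis pair threshold
#' 4.
#'
#' @param filter a [filter_params()] list.
#' @param watershed a [watershed_params()] list.
#' @param cleanup a [cleanup_params()] list.
#' @param refine a [refine_params()] list.
#' @param mock a [mock_params()] list.
#' @param stage `"initial"` or `"full"`.
#' @param probability_map_mode treat the input as an externally produced
#'   probability map: bilateral-only preprocessing.
#' @param dark_foreground Otsu polarity (cells darker than background).
#' @param seed integer seed for anything stochastic downstream.
#' @export
pipeline_config <- function(filter = filter_params(),
                            watershed = watershed_params(),
                            cleanup = cleanup_params(),
                            refine = refine_params(),
                            mock = mock_params(),
                            stage = c("full", "initial"),
                            probability_map_mode = FALSE,
                            dark_foreground = TRUE, seed = 1L) {
  stage <- match.arg(stage)
  list(filter = filter, watershed = watershed, cleanup = cleanup,
       refine = refine, mock = mock, stage = stage,
       probability_map_mode = isTRUE(probability_map_mode),
       dark_foreground = isTRUE(dark_foreground), seed = as.integer(seed))
}

#' Segment an erythrocyte image end to end
#'
#' Preprocessing, stage-1 segmentation and (unless `config$stage ==
#' "initial"`) per-cell refinement with morphometry.
#'
#' @param img a [gray_image()], numeric matrix, or path to a PNG/TIFF file.
#' @param config a [pipeline_config()] list.
#' @return list with `filtered` (8-bit image), `labels_initial`, `labels`
#'   (refined, or identical to `labels_initial` when stage-1 only),
#'   `measurements` (data frame; `NULL` for stage-1 only) and `cells`.
#' @export
segment_image <- function(img, config = pipeline_config()) {
  if (is.character(img)) img <- read_image(img)
  filtered <- preprocess_image(img, config$filter,
                               probability_map_mode = config$probability_map_mode)
  lab1 <- initial_segment(filtered, config$watershed, config$cleanup,
                          dark_foreground = config$dark_foreground)
  if (config$stage == "initial")
    return(list(filtered = filtered, labels_initial = lab1, labels = lab1,
                measurements = NULL, cells = NULL))
  ref <- process_all_cells(lab1, filtered, config$refine)
  list(filtered = filtered, labels_initial = lab1, labels = ref$labels,
       measurements = ref$measurements, cells = ref$cells)
}

#' Burn contours and axes into an RGB overlay
#'
#' Contours are drawn red, long axes blue and short axes green over the
#' grayscale image.
#'
#' @param img the source [gray_image()] (8-bit).
#' @param cells per-cell records from [process_all_cells()].
#' @return `height x width x 3` array in `[0, 1]`.
#' @export
draw_overlay <- function(img, cells) {
  x <- pixels(as_gray_image(img)) / depth_max(gray_depth(as_gray_image(img)))
  h <- nrow(x); w <- ncol(x)
  rgb <- array(rep(x, 3), dim = c(h, w, 3))
  paint <- function(rgb, pts, col) {
    pts <- pts[pts[, 1] >= 0 & pts[, 1] < h & pts[, 2] >= 0 & pts[, 2] < w,
               , drop = FALSE]
    for (ch in 1:3)
      rgb[cbind(pts[, 1] + 1L, pts[, 2] + 1L, ch)] <- col[ch]
    rgb
  }
  for (cell in cells) {
    if (is.null(cell)) next
    rgb <- paint(rgb, cell$contour, c(1, 0, 0))
    if (!is.null(cell$long_axis))
      rgb <- paint(rgb, bresenham_points(cell$long_axis$p1, cell$long_axis$p2),
                   c(0, 0, 1))
    if (!is.null(cell$short_axis))
      rgb <- paint(rgb, bresenham_points(cell$short_axis$p1,
                                         cell$short_axis$p2), c(0, 1, 0))
  }
  rgb
}
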