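#' Watershed parameters
#'
#' `threshold` and `level` are fractions of the normalized dynamic range of
#' the relief, following the convention of the toolkit these parameter values come
#' from: `threshold` clips shallow micro-minima before flooding and `level`
#' merges adjacent basins whose dynamic (saddle height minus basin minimum)
#' falls below it. Defaults 0.004 and 0.4.
#'
#' @param threshold,level fractions in `[0, 1]`, `threshold <= level`.
#' @export
watershed_params <- function(threshold = 0.004, level = 0.4) {
  stopifnot(threshold >= 0, level <= 1, threshold <= level)
  list(threshold = threshold, level = level)
}

#' Cleanup parameters for the initial segmentation
#'
#' @param size_threshold objects with fewer pixels are removed (default 25).
#' @param erosion_radius disc radius of the pre-distance-map erosion
#'   (default 2).
#' @export
cleanup_params <- function(size_threshold = 25, erosion_radius = 2) {
  stopifnot(size_threshold >= 0, erosion_radius >= 0)
  list(size_threshold = size_threshold, erosion_radius = erosion_radius)
}

#' Otsu threshold
#'
#' Selects the cut maximizing the between-class variance of the 256-bin
#' intensity histogram (values are binned on `[min, max]` for non-8-bit
#' input; for 8-bit input the bins are the 256 intensity levels). Ties are
#' broken towards the lowest qualifying threshold. With
#' `dark_foreground = TRUE` (the default: cells are darker than the
#' illuminated field) the mask holds pixels `<= threshold`, otherwise
#' pixels `> threshold`.
#'
#' @param img a [gray_image()] or numeric matrix with at least two distinct
#'   values.
#' @param dark_foreground select the darker class as foreground.
#' @return list with `threshold` (intensity units) and `mask` (logical
#'   matrix).
#' @export
otsu_threshold <- function(img, dark_foreground = TRUE) {
  x <- pixels(as_gray_image(img))
  thr <- otsu_cut(as.vector(x))
  mask <- if (dark_foreground) x <= thr else x > thr
  list(threshold = thr, mask = mask)
}

# Otsu cut on a numeric vector using a 256-bin histogram; returns the upper
# edge value of the selected bin so that `<= threshold` selects the lower
# class. For whole-number 8-bit data the candidate cuts are the integer
# levels 0..254.
otsu_cut <- function(v) {
  lo <- min(v); hi <- max(v)
  if (hi == lo) stop("degenerate histogram: image is constant")
  integerish <- all(v == floor(v)) && hi - lo <= 255
  if (integerish) {
    levels <- seq(floor(lo), ceiling(hi))
    counts <- tabulate(v - floor(lo) + 1, nbins = length(levels))
  } else {
    levels <- lo + (hi - lo) * (seq_len(256) - 0.5) / 256
    idx <- pmin(pmax(floor((v - lo) / (hi - lo) * 256) + 1, 1), 256)
    counts <- tabulate(idx, nbins = 256)
  }
  n <- length(v)
  w0 <- cumsum(counts) / n
  mu <- cumsum(counts * levels) / n
  mu_t <- mu[length(mu)]
  # between-class variance for cut after bin k (k = 1..K-1)
  k <- seq_len(length(levels) - 1)
  w0k <- w0[k]
  valid <- w0k > 0 & w0k < 1
  sb <- rep(-Inf, length(k))
  sb[valid] <- (mu_t * w0k[valid] - mu[k][valid])^2 /
    (w0k[valid] * (1 - w0k[valid]))
  best <- which.max(sb)  # which.max takes the first (lowest) maximizer
  levels[best]
}

#' Fill holes in a binary mask
#'
#' Background components (4-connectivity) not connected to the image border
#' become foreground; existing foreground is unchanged.
#'
#' @param mask logical matrix.
#' @export
fill_holes <- function(mask) {
  cpp_fill_holes(as_mask(mask))
}

as_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!is.logical(mask)) mask <- mask > 0
  mask
}

#' Binary erosion / dilation with a disc structuring element
#'
#' The disc is the offset set `{(dr, dc): dr^2 + dc^2 <= radius^2}`;
#' radius 0 is the identity. Pixels outside the image count as background.
#'
#' @param mask logical matrix.
#' @param radius disc radius in pixels (>= 0).
#' @export
erode_mask <- function(mask, radius) {
  stopifnot(radius >= 0)
  cpp_binary_erode(as_mask(mask), radius)
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, radius) {
  stopifnot(radius >= 0)
  cpp_binary_dilate(as_mask(mask), radius)
}

#' Inverted Euclidean distance map
#'
#' Computes the exact Euclidean distance `D` from every foreground pixel to
#' the nearest background pixel (`D = 0` on background) and returns
#' `max(D) - D`: background is the bright plateau and deep object interiors
#' are the minima, ready for watershed flooding.
#'
#' @param mask logical matrix with at least one background pixel.
#' @return float [gray_image()] relief.
#' @export
distance_map <- function(mask) {
  mask <- as_mask(mask)
  if (all(mask)) stop("all-foreground mask: no background to measure from")
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1.0),
                                           metric = "euclidean"))
  gray_image(max(d) - matrix(d, nrow(mask), ncol(mask)), "float")
}

#' Watershed segmentation of an inverted-distance relief
#'
#' The relief is normalized to `[0, 1]`; values below
#' `threshold * range` are clipped up to suppress micro-minima; basins are
#' flooded from regional minima (8-connectivity) with dams at basin
#' meetings, and adjacent basins whose dynamic falls below `level` are
#' merged. Only pixels below the background plateau (the original
#' foreground) receive labels, relabelled `1..K`.
#'
#' @param relief float [gray_image()] from [distance_map()].
#' @param params a [watershed_params()] list.
#' @return integer label matrix.
#' @export
watershed_segment <- function(relief, params = watershed_params()) {
  x <- pixels(as_gray_image(relief))
  rng <- max(x) - min(x)
  if (rng == 0) return(matrix(0L, nrow(x), ncol(x)))
  n <- (x - min(x)) / rng
  n[n < params$threshold] <- params$threshold
  surf <- 1 - n                       # basins become peaks; background -> 0
  ws <- EBImage::watershed(EBImage::Image(surf), tolerance = params$level,
                           ext = 1)
  lab <- matrix(as.integer(EBImage::imageData(ws)), nrow(x), ncol(x))
  relabel(lab)
}

# relabel non-zero labels to contiguous 1..K preserving increasing-id order
relabel <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L)
    return(matrix(0L, nrow(lab), ncol(lab)))
  matrix(match(lab, ids, nomatch = 0L), nrow(lab), ncol(lab))
}

#' Remove small objects from a label image
#'
#' Objects with strictly fewer than `size_threshold` pixels are deleted;
#' survivors are relabelled `1..K` preserving their original order.
#'
#' @param labels integer label matrix.
#' @param size_threshold minimum object size in pixels.
#' @export
remove_small <- function(labels, size_threshold) {
  if (max(labels) == 0L) return(labels)
  sizes <- tabulate(labels[labels > 0], nbins = max(labels))
  drop <- which(sizes < size_threshold)
  out <- labels
  out[out %in% drop] <- 0L
  relabel(out)
}

#' Remove objects touching the image border
#'
#' Any object owning at least one pixel in the first/last row or column is
#' deleted; survivors are relabelled `1..K`.
#'
#' @param labels integer label matrix.
#' @export
remove_border_objects <- function(labels) {
  if (max(labels) == 0L) return(labels)
  h <- nrow(labels); w <- ncol(labels)
  touching <- unique(c(labels[1, ], labels[h, ], labels[, 1], labels[, w]))
  touching <- touching[touching != 0]
  out <- labels
  out[out %in% touching] <- 0L
  relabel(out)
}

#' Label connected components
#'
#' 8-connectivity; labels `1..K` in raster-scan discovery order.
#'
#' @param mask logical matrix.
#' @export
label_components <- function(mask) {
  cpp_label(as_mask(mask))
}

#' Stage-1 segmentation
#'
#' Otsu binarization (dark foreground), hole filling, disc erosion, inverted
#' Euclidean distance map, watershed, small-object removal and
#' border-object removal, in that order. Deterministic.
#'
#' @param img preprocessed 8-bit [gray_image()] (see [preprocess_image()]).
#' @param ws a [watershed_params()] list.
#' @param cleanup a [cleanup_params()] list.
#' @param dark_foreground polarity passed to [otsu_threshold()].
#' @return integer label matrix.
#' @export
initial_segment <- function(img, ws = watershed_params(),
                            cleanup = cleanup_params(),
                            dark_foreground = TRUE) {
  x <- pixels(as_gray_image(img))
  if (min(x) == max(x))                  # blank image: nothing to segment
    return(matrix(0L, nrow(x), ncol(x)))
  mask0 <- otsu_threshold(img, dark_foreground = dark_foreground)$mask
  mask0 <- fill_holes(mask0)
  mask <- erode_mask(mask0, cleanup$erosion_radius)
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  relief <- distance_map(mask)
  lab <- watershed_segment(relief, ws)
  # the erosion only shapes the relief: grow labels back over the full
  # hole-filled Otsu foreground so the cell rim is not lost
  lab <- cpp_grow_labels(lab, mask0)
  lab <- remove_small(lab, cleanup$size_threshold)
  remove_border_objects(lab)
}
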