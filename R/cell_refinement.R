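#' Per-cell refinement parameters
#'
#' @param margin ROI margin around each object's bounding box (default 10).
#' @param mask_dilate_radius dilation of the object's own stage-1 mask
#'   (default 6).
#' @param line_distance_threshold max point-to-perpendicular-line distance
#'   for short-axis candidates (fixed `sqrt(2)`).
#' @param pair_distance_threshold minimum mutual distance `t` between the
#'   two candidates seeding the short-axis clusters (default 4).
#' @export
refine_params <- function(margin = 10, mask_dilate_radius = 6,
                          line_distance_threshold = sqrt(2),
                          pair_distance_threshold = 4) {
  p <- list(margin = margin, mask_dilate_radius = mask_dilate_radius,
            line_distance_threshold = line_distance_threshold,
            pair_distance_threshold = pair_distance_threshold)
  if (any(unlist(p) < 0)) stop("refine parameters must be non-negative")
  p
}

#' Rectangular ROI around one labelled object
#'
#' Tight bounding box expanded by `margin` on every side and clipped to the
#' image. Coordinates are 0-based, half-open: rows `[r0, r1)`, cols
#' `[c0, c1)`.
#'
#' @param labels integer label matrix.
#' @param label object id (must be present).
#' @param margin expansion in pixels.
#' @export
select_roi <- function(labels, label, margin = 10) {
  idx <- which(labels == label, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("label ", label, " not present")
  r0 <- max(min(idx[, 1]) - 1L - margin, 0L)
  c0 <- max(min(idx[, 2]) - 1L - margin, 0L)
  r1 <- min(max(idx[, 1]) - 1L + margin + 1L, nrow(labels))
  c1 <- min(max(idx[, 2]) - 1L + margin + 1L, ncol(labels))
  list(r0 = as.integer(r0), c0 = as.integer(c0),
       r1 = as.integer(r1), c1 = as.integer(c1))
}

roi_rows <- function(roi) (roi$r0 + 1L):roi$r1
roi_cols <- function(roi) (roi$c0 + 1L):roi$c1

#' Neighbour-aware mask for one cell
#'
#' The object's own pixels dilated by `dilate_radius`, minus the
#' (un-dilated) pixels of every other object inside the ROI. This keeps the
#' local re-thresholding from leaking into adjacent cells.
#'
#' @inheritParams select_roi
#' @param roi from [select_roi()].
#' @param dilate_radius dilation radius in pixels.
#' @return logical matrix of ROI dimensions.
#' @export
build_cell_mask <- function(labels, label, roi, dilate_radius = 6) {
  sub <- labels[roi_rows(roi), roi_cols(roi), drop = FALSE]
  if (!any(sub == label)) stop("label ", label, " not inside ROI")
  own <- dilate_mask(sub == label, dilate_radius)
  own & !(sub != 0L & sub != label)
}

#' Refine one cell by local Otsu thresholding
#'
#' Otsu's criterion is evaluated on the masked pixels only; the darker class
#' (erythrocyte rim and interior) is kept, holes are filled, and the largest
#' 8-connected component survives. A mask whose intensity histogram is
#' degenerate (fewer than two distinct values) raises an error; callers fall
#' back to the stage-1 shape.
#'
#' @param filtered_roi 8-bit [gray_image()] or matrix, ROI crop of the
#'   preprocessed image.
#' @param mask logical matrix from [build_cell_mask()].
#' @return logical matrix: the refined cell mask.
#' @export
refine_cell <- function(filtered_roi, mask) {
  x <- pixels(as_gray_image(filtered_roi))
  if (!any(mask)) stop("empty mask: nothing to refine")
  vals <- x[mask]
  if (length(unique(vals)) < 2L)
    stop("degenerate masked histogram: refinement failed")
  thr <- otsu_cut(vals)
  keep <- mask & (x <= thr)
  keep <- fill_holes(keep)
  lab <- label_components(keep)
  if (max(lab) == 0L) stop("refinement produced an empty object")
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  lab == which.max(sizes)  # ties: lowest label (raster discovery order)
}

#' Extract the boundary contour of a single object
#'
#' Moore boundary tracing, clockwise, starting from the topmost-then-
#' leftmost boundary pixel; consecutive points are 8-adjacent and form a
#' closed loop. 0-based `(row, col)` coordinates.
#'
#' @param mask logical matrix containing exactly one 8-connected object.
#' @return integer matrix, one `(row, col)` point per row.
#' @export
extract_contour <- function(mask) {
  mask <- as_mask(mask)
  lab <- label_components(mask)
  k <- max(lab)
  if (k == 0L) stop("empty mask: no contour")
  if (k > 1L) stop("mask contains ", k, " objects; exactly one required")
  cpp_moore_contour(mask)
}

seg_len <- function(p1, p2) sqrt(sum((p1 - p2)^2))

axis_segment <- function(p1, p2) {
  list(p1 = as.numeric(p1), p2 = as.numeric(p2), length = seg_len(p1, p2))
}

# lexicographic comparison of (p1, p2) pairs after sorting each pair
pair_key <- function(a, b) {
  pts <- rbind(a, b)
  o <- order(pts[, 1], pts[, 2])
  as.numeric(t(pts[o, ]))
}

#' Long axis of a contour
#'
#' The pair of contour points at maximal Euclidean distance. Ties are broken
#' by lexicographic `(row, col)` order of the sorted pair. Computed on the
#' convex hull (every farthest pair is a pair of hull vertices).
#'
#' @param contour integer matrix of `(row, col)` points.
#' @return an axis segment: list with `p1`, `p2`, `length`.
#' @export
long_axis <- function(contour) {
  contour <- unique(as.matrix(contour))
  n <- nrow(contour)
  if (n < 2L) stop("long axis needs at least two contour points")
  hull <- if (n > 3L) contour[grDevices::chull(contour[, 2], contour[, 1]), ,
                              drop = FALSE] else contour
  m <- nrow(hull)
  d2 <- as.matrix(stats::dist(hull))^2
  best <- max(d2)
  idx <- which(d2 == best, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  keys <- apply(idx, 1, function(k) pair_key(hull[k[1], ], hull[k[2], ]))
  pick <- do.call(order, as.data.frame(t(keys)))[1]
  axis_segment(hull[idx[pick, 1], ], hull[idx[pick, 2], ])
}

# integer Bresenham rasterization of the segment p1 -> p2 (0-based points)
bresenham_points <- function(p1, p2) {
  x0 <- round(p1[2]); y0 <- round(p1[1])
  x1 <- round(p2[2]); y1 <- round(p2[1])
  dx <- abs(x1 - x0); dy <- -abs(y1 - y0)
  sx <- if (x0 < x1) 1 else -1
  sy <- if (y0 < y1) 1 else -1
  err <- dx + dy
  pts <- matrix(0, 0, 2)
  repeat {
    pts <- rbind(pts, c(y0, x0))
    if (x0 == x1 && y0 == y1) break
    e2 <- 2 * err
    if (e2 >= dy) { err <- err + dy; x0 <- x0 + sx }
    if (e2 <= dx) { err <- err + dx; y0 <- y0 + sy }
  }
  pts
}

#' Short axis of a contour
#'
#' For every rasterized point of the long axis, the line perpendicular to
#' the long axis through that point is considered. Contour points within
#' `sqrt(2)` of the line are cross-point candidates; the two mutually
#' farthest candidates (if farther apart than `pair_distance_threshold`)
#' seed two clusters, remaining candidates join the nearer seed, and each
#' cluster contributes its point closest to the line. The best-scoring pair
#' over all long-axis points is the short axis; exact ties go to the pair
#' whose segment crosses the long axis nearest its midpoint. Returns `NULL`
#' when no long-axis point yields a valid pair ("short axis cannot be
#' determined").
#'
#' @param contour integer matrix of `(row, col)` points.
#' @param long the [long_axis()] segment.
#' @param params a [refine_params()] list.
#' @return an axis segment or `NULL`.
#' @export
short_axis <- function(contour, long, params = refine_params()) {
  contour <- unique(as.matrix(contour))
  u <- (long$p2 - long$p1) / long$length       # unit vector along the long axis
  mid <- (long$p1 + long$p2) / 2
  line_pts <- bresenham_points(long$p1, long$p2)
  dmax <- params$line_distance_threshold
  t_thr <- params$pair_distance_threshold
  best <- NULL; best_len <- -Inf; best_mid_d <- Inf
  for (k in seq_len(nrow(line_pts))) {
    q <- line_pts[k, ]
    # distance to the perpendicular line through q = |component along u|
    along <- (contour[, 1] - q[1]) * u[1] + (contour[, 2] - q[2]) * u[2]
    cand <- contour[abs(along) <= dmax, , drop = FALSE]
    if (nrow(cand) < 2L) next
    d2 <- as.matrix(stats::dist(cand))^2
    far <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
    if (sqrt(max(d2)) <= t_thr) next
    s1 <- cand[far[1], ]; s2 <- cand[far[2], ]
    to1 <- (cand[, 1] - s1[1])^2 + (cand[, 2] - s1[2])^2
    to2 <- (cand[, 1] - s2[1])^2 + (cand[, 2] - s2[2])^2
    grp <- ifelse(to1 <= to2, 1L, 2L)
    line_d <- abs((cand[, 1] - q[1]) * u[1] + (cand[, 2] - q[2]) * u[2])
    pick_in <- function(g) {
      i <- which(grp == g)
      i[which.min(line_d[i])]
    }
    a <- cand[pick_in(1L), ]; b <- cand[pick_in(2L), ]
    len <- seg_len(a, b)
    # crossing of segment a-b with the long-axis line, distance to midpoint
    nrm <- c(-u[2], u[1])
    denom <- sum((b - a) * nrm)
    cross <- if (abs(denom) > 1e-12) {
      tt <- sum((long$p1 - a) * nrm) / denom
      a + tt * (b - a)
    } else (a + b) / 2
    mid_d <- seg_len(cross, mid)
    if (len > best_len || (len == best_len && mid_d < best_mid_d)) {
      best <- axis_segment(a, b); best_len <- len; best_mid_d <- mid_d
    }
  }
  best
}

#' Process every stage-1 cell: refine, contour, measure
#'
#' Each object is refined independently ([select_roi()],
#' [build_cell_mask()], [refine_cell()]); refined masks are pasted back at
#' their ROI offsets to form the stage-2 label image (first label wins on
#' the rare overlap of dilated regions). A cell whose refinement fails falls
#' back to its stage-1 shape and is flagged — per-cell failures never abort
#' the batch, and stage 2 never changes the number of objects.
#'
#' @param labels stage-1 label matrix from [initial_segment()].
#' @param filtered preprocessed 8-bit image from [preprocess_image()].
#' @param params a [refine_params()] list.
#' @return list with `cells` (per-cell records: label, contour, axes, status),
#'   `labels` (refined label matrix) and `measurements` (one-row-per-cell
#'   data frame).
#' @export
process_all_cells <- function(labels, filtered, params = refine_params()) {
  k <- max(labels)
  filtered <- as_gray_image(filtered)
  out_labels <- matrix(0L, nrow(labels), ncol(labels))
  cells <- vector("list", k)
  rows <- vector("list", k)
  for (lb in seq_len(k)) {
    roi <- select_roi(labels, lb, params$margin)
    mask <- build_cell_mask(labels, lb, roi, params$mask_dilate_radius)
    sub_img <- pixels(filtered)[roi_rows(roi), roi_cols(roi), drop = FALSE]
    refined <- tryCatch(refine_cell(sub_img, mask), error = function(e) NULL)
    status <- if (is.null(refined)) "fallback" else "refined"
    if (is.null(refined)) {
      refined <- labels[roi_rows(roi), roi_cols(roi), drop = FALSE] == lb
    }
    contour_roi <- cpp_moore_contour(refined)
    contour <- cbind(contour_roi[, 1] + roi$r0, contour_roi[, 2] + roi$c0)
    la <- if (nrow(unique(contour)) >= 2L) long_axis(contour) else NULL
    sa <- if (!is.null(la)) short_axis(contour, la, params) else NULL
    # paste back, first label wins
    sub_out <- out_labels[roi_rows(roi), roi_cols(roi), drop = FALSE]
    put <- refined & sub_out == 0L
    sub_out[put] <- lb
    out_labels[roi_rows(roi), roi_cols(roi)] <- sub_out
    idx <- which(refined, arr.ind = TRUE)
    cells[[lb]] <- list(label = lb, roi = roi, contour = contour,
                        long_axis = la, short_axis = sa,
                        axis_ratio = if (!is.null(la) && !is.null(sa))
                          sa$length / la$length else NA_real_,
                        refine_status = status)
    rows[[lb]] <- data.frame(
      label = lb,
      centroid_row = mean(idx[, 1] - 1L) ,
      centroid_col = mean(idx[, 2] - 1L),
      area_px = nrow(idx),
      long_len = if (is.null(la)) NA_real_ else la$length,
      short_len = if (is.null(sa)) NA_real_ else sa$length,
      axis_ratio = if (!is.null(la) && !is.null(sa)) sa$length / la$length
                   else NA_real_,
      refine_status = status,
      stringsAsFactors = FALSE)
  }
  measurements <- if (k > 0L) do.call(rbind, rows) else
    data.frame(label = integer(), centroid_row = numeric(),
               centroid_col = numeric(), area_px = integer(),
               long_len = numeric(), short_len = numeric(),
               axis_ratio = numeric(), refine_status = character(),
               stringsAsFactors = FALSE)
  list(cells = cells, labels = out_labels, measurements = measurements)
}
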