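# Independent brute-force oracles. These deliberately re-derive each
# quantity by the most literal route available (per-window loops, all-pairs
# searches, exhaustive scans) and stay independent of the package kernels.

clamp_idx <- function(i, n) pmin(pmax(i, 1L), n)

oracle_median <- function(x, r) {
  h <- nrow(x); w <- ncol(x)
  out <- x
  for (i in seq_len(h)) for (j in seq_len(w)) {
    win <- x[clamp_idx((i - r):(i + r), h), clamp_idx((j - r):(j + r), w)]
    s <- sort(as.vector(win))
    out[i, j] <- s[(length(s) + 1) / 2]
  }
  out
}

oracle_mean <- function(x, r, round_int = TRUE) {
  h <- nrow(x); w <- ncol(x)
  out <- x
  for (i in seq_len(h)) for (j in seq_len(w)) {
    win <- x[clamp_idx((i - r):(i + r), h), clamp_idx((j - r):(j + r), w)]
    v <- sum(win) / length(win)
    out[i, j] <- if (round_int) floor(v + 0.5) else v
  }
  out
}

# literal weighted-average bilateral: normalized product of spatial and
# range Gaussians over the truncated window
oracle_bilateral <- function(x, sigma_d, sigma_r) {
  h <- nrow(x); w <- ncol(x)
  r <- ceiling(3 * sigma_d)
  out <- x
  for (i in seq_len(h)) for (j in seq_len(w)) {
    num <- 0; den <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- clamp_idx(i + di, h); jj <- clamp_idx(j + dj, w)
      wgt <- exp(-(di^2 + dj^2) / (2 * sigma_d^2)) *
             exp(-(x[i, j] - x[ii, jj])^2 / (2 * sigma_r^2))
      num <- num + wgt * x[ii, jj]; den <- den + wgt
    }
    out[i, j] <- floor(num / den + 0.5)
  }
  out
}

# exhaustive Otsu scan: every integer cut, literal class statistics
oracle_otsu_cut <- function(v) {
  best_t <- NA; best_sb <- -Inf
  for (t in floor(min(v)):(ceiling(max(v)) - 1)) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    sb <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sb > best_sb + 1e-12) { best_sb <- sb; best_t <- t }
  }
  best_t
}

# all-pairs nearest-background Euclidean distance
oracle_edt <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  bg <- which(!mask, arr.ind = TRUE)
  d <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    if (mask[i, j])
      d[i, j] <- sqrt(min((bg[, 1] - i)^2 + (bg[, 2] - j)^2))
  d
}

oracle_long_axis_len <- function(pts) {
  d2 <- 0
  n <- nrow(pts)
  for (i in seq_len(n - 1)) {
    dd <- (pts[(i + 1):n, 1] - pts[i, 1])^2 + (pts[(i + 1):n, 2] - pts[i, 2])^2
    d2 <- max(d2, dd)
  }
  sqrt(d2)
}

# hole filling by iterative background flood from the border (4-connectivity)
oracle_fill_holes <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  reach <- matrix(FALSE, h, w)
  reach[1, ] <- !mask[1, ]; reach[h, ] <- !mask[h, ]
  reach[, 1] <- reach[, 1] | !mask[, 1]; reach[, w] <- reach[, w] | !mask[, w]
  repeat {
    grown <- reach |
      (rbind(FALSE, reach[-h, ]) & !mask) | (rbind(reach[-1, ], FALSE) & !mask) |
      (cbind(FALSE, reach[, -w]) & !mask) | (cbind(reach[, -1], FALSE) & !mask)
    if (identical(grown, reach)) break
    reach <- grown
  }
  mask | !reach
}

# brute-force grayscale opening by the spherical-cap element: the opening of
# the replicate-extended image, restricted to the core (erosion evaluated on
# a pad ring of width r so the dilation sees consistent values)
oracle_ball_opening <- function(x, radius) {
  h <- nrow(x); w <- ncol(x)
  r <- floor(radius)
  b <- outer((-r):r, (-r):r, function(di, dj) {
    v <- radius^2 - di^2 - dj^2
    ifelse(v >= 0, suppressWarnings(sqrt(v)), NA)
  })
  xe <- function(i, j) x[clamp_idx(i, h), clamp_idx(j, w)]
  ero <- matrix(0, h + 2 * r, w + 2 * r)
  for (i in seq_len(h + 2 * r)) for (j in seq_len(w + 2 * r)) {
    m <- Inf
    for (di in -r:r) for (dj in -r:r) {
      bb <- b[di + r + 1, dj + r + 1]
      if (is.na(bb)) next
      m <- min(m, xe(i - r + di, j - r + dj) - bb)
    }
    ero[i, j] <- m
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    m <- -Inf
    for (di in -r:r) for (dj in -r:r) {
      bb <- b[di + r + 1, dj + r + 1]
      if (is.na(bb)) next
      m <- max(m, ero[i + r + di, j + r + dj] + bb)
    }
    out[i, j] <- m
  }
  out
}

# geometric fixtures
disc_mask <- function(h, w, cy, cx, r) {
  outer(seq_len(h) - cy, seq_len(w) - cx, function(a, b) a^2 + b^2 <= r^2)
}

ellipse_mask <- function(h, w, cy, cx, a, b) {
  outer(seq_len(h) - cy, seq_len(w) - cx,
        function(p, q) (p / b)^2 + (q / a)^2 <= 1)
}

rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]

roi_rows_test <- function(roi) (roi$r0 + 1):roi$r1
roi_cols_test <- function(roi) (roi$c0 + 1):roi$c1
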