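test_that("ROI selection expands the bounding box and clips at the image", {
  lab <- matrix(0L, 100, 100)
  lab[21:31, 41:51] <- 1L                  # rows 20-30, cols 40-50 (0-based)
  roi <- select_roi(lab, 1L, margin = 10)
  expect_equal(roi, list(r0 = 10L, c0 = 30L, r1 = 41L, c1 = 61L))
  roi0 <- select_roi(lab, 1L, margin = 0)
  expect_equal(roi0, list(r0 = 20L, c0 = 40L, r1 = 31L, c1 = 51L))
  corner <- matrix(0L, 30, 30); corner[1:5, 1:5] <- 1L
  roic <- select_roi(corner, 1L, margin = 10)
  expect_equal(c(roic$r0, roic$c0), c(0L, 0L))
  expect_error(select_roi(lab, 9L), "not present")
})

test_that("cell masks dilate the owner and subtract neighbours un-dilated", {
  lab <- matrix(0L, 40, 40)
  own <- disc_mask(40, 40, 20, 14, 5)
  other <- disc_mask(40, 40, 20, 28, 5)
  lab[own] <- 1L; lab[other] <- 2L
  roi <- select_roi(lab, 1L, margin = 10)
  m <- build_cell_mask(lab, 1L, roi, dilate_radius = 6)
  sub_own <- own[roi_rows_test(roi), roi_cols_test(roi)]
  sub_other <- other[roi_rows_test(roi), roi_cols_test(roi)]
  expect_true(all(m[sub_own]))                       # own pixels kept
  expect_true(all(!m[sub_other]))                    # neighbour excluded
  expect_identical(m, dilate_mask(sub_own, 6) & !sub_other)
  # isolated object, radius 0: exactly its own pixels
  lab2 <- matrix(0L, 30, 30); lab2[disc_mask(30, 30, 15, 15, 6)] <- 1L
  roi2 <- select_roi(lab2, 1L, margin = 5)
  m2 <- build_cell_mask(lab2, 1L, roi2, dilate_radius = 0)
  expect_identical(m2, lab2[roi_rows_test(roi2), roi_cols_test(roi2)] == 1L)
})

test_that("per-cell Otsu keeps the darker class, fills it and keeps the biggest", {
  # biconcave-style cell: dark rim 80, brighter centre 140, background
  # excluded by the mask
  cell <- disc_mask(30, 30, 15, 15, 9)
  inner <- disc_mask(30, 30, 15, 15, 5)
  img <- matrix(200, 30, 30)
  img[cell] <- 80; img[inner] <- 140
  refined <- refine_cell(gray_image(img, "8bit"), cell)
  expect_identical(refined, cell)          # rim selected, hole filled
  # uniform dark disc with background in the mask: whole disc kept
  img2 <- matrix(200, 30, 30); img2[cell] <- 80
  refined2 <- refine_cell(gray_image(img2, "8bit"), dilate_mask(cell, 3))
  expect_identical(refined2, cell)
  # two dark fragments: only the bigger survives
  img3 <- matrix(200, 30, 30)
  big <- disc_mask(30, 30, 10, 10, 4)      # 49 px
  small <- disc_mask(30, 30, 22, 22, 2)    # 13 px
  img3[big | small] <- 60
  refined3 <- refine_cell(gray_image(img3, "8bit"), matrix(TRUE, 30, 30))
  expect_identical(refined3, big)
  expect_error(refine_cell(gray_image(matrix(7, 5, 5), "8bit"),
                           matrix(TRUE, 5, 5)), "degenerate")
})

test_that("contours are closed 8-connected boundary loops", {
  sq <- matrix(FALSE, 5, 5); sq[2:4, 2:4] <- TRUE
  ctr <- extract_contour(sq)
  expect_equal(nrow(ctr), 8)
  # consecutive points (and the closing edge) are 8-adjacent
  stepd <- function(p) max(abs(p))
  n <- nrow(ctr)
  for (i in seq_len(n))
    expect_lte(stepd(ctr[i %% n + 1, ] - ctr[i, ]), 1)
  # starts at the topmost-then-leftmost pixel
  expect_equal(ctr[1, ], c(1L, 1L))
  # single pixel: one-point contour
  one <- matrix(FALSE, 3, 3); one[2, 2] <- TRUE
  expect_equal(nrow(extract_contour(one)), 1)
  # disc: contour set equals the boundary predicate (bg 4-neighbour)
  d <- disc_mask(25, 25, 13, 13, 10)
  ctr2 <- extract_contour(d)
  inner4 <- d & rbind(d[-1, ], FALSE) & rbind(FALSE, d[-25, ]) &
    cbind(d[, -1], FALSE) & cbind(FALSE, d[, -25])
  boundary <- which(d & !inner4, arr.ind = TRUE) - 1L
  expect_setequal(paste(ctr2[, 1], ctr2[, 2]),
                  paste(boundary[, 1], boundary[, 2]))
  expect_error(extract_contour(matrix(FALSE, 3, 3)), "empty")
  two <- matrix(FALSE, 9, 9); two[2, 2] <- TRUE; two[7, 7] <- TRUE
  expect_error(extract_contour(two), "2 objects")
})

test_that("long axis equals the all-pairs brute force", {
  # axis-aligned 5x3 rectangle outline: diagonal, length sqrt(20)
  r <- matrix(FALSE, 7, 9); r[2:4, 2:6] <- TRUE
  ctr <- extract_contour(r)
  la <- long_axis(ctr)
  expect_equal(la$length, sqrt(20))
  expect_equal(la$length, oracle_long_axis_len(ctr))
  # two-point contour
  la2 <- long_axis(rbind(c(0, 0), c(3, 4)))
  expect_equal(la2$length, 5)
  # digital circle radius 10: discretized diameter
  d <- disc_mask(25, 25, 13, 13, 10)
  ctr3 <- extract_contour(d)
  la3 <- long_axis(ctr3)
  expect_equal(la3$length, oracle_long_axis_len(ctr3))
  expect_gte(la3$length, 19); expect_lte(la3$length, 21)
  # larger rasterized ellipse contour, still exact vs brute force
  e <- ellipse_mask(61, 101, 31, 51, 45, 25)
  ctr4 <- extract_contour(e)
  expect_equal(long_axis(ctr4)$length, oracle_long_axis_len(ctr4))
  expect_error(long_axis(rbind(c(1, 1))), "at least two")
})

test_that("short axis follows the perpendicular cross-point procedure", {
  d <- disc_mask(25, 25, 13, 13, 10)
  ctr <- extract_contour(d)
  la <- long_axis(ctr)
  sa <- short_axis(ctr, la)
  expect_false(is.null(sa))
  expect_lte(abs(sa$length - la$length), 2)     # circle symmetry
  # 20/10 ellipse: minor diameter recovered, perpendicular to major
  e <- ellipse_mask(51, 91, 26, 46, 20, 10)
  ce <- extract_contour(e)
  lae <- long_axis(ce)
  sae <- short_axis(ce, lae)
  expect_lte(abs(sae$length - 20), 2)
  u <- (lae$p2 - lae$p1) / lae$length
  v <- (sae$p2 - sae$p1) / sae$length
  ang <- acos(min(1, abs(sum(u * v)))) * 180 / pi
  expect_gte(ang, 85)
  # thin line: no candidate pair farther apart than t = 4
  l <- matrix(FALSE, 5, 40); l[3, 4:34] <- TRUE
  cl <- extract_contour(l)
  expect_null(short_axis(cl, long_axis(cl)))
})

test_that("axis measurements are invariant under 90-degree rotation", {
  shapes <- list(disc_mask(25, 25, 13, 13, 10),
                 ellipse_mask(41, 61, 21, 31, 25, 12))
  for (m in shapes) {
    c0 <- extract_contour(m); c1 <- extract_contour(rot90(m))
    l0 <- long_axis(c0); l1 <- long_axis(c1)
    expect_lte(abs(l0$length - l1$length), 1)
    s0 <- short_axis(c0, l0); s1 <- short_axis(c1, l1)
    expect_lte(abs(s0$length - s1$length), 1)
  }
})

test_that("process_all_cells measures every object and respects its mask", {
  img <- matrix(225, 140, 140)
  lab_truth <- matrix(0L, 140, 140)
  centers <- rbind(c(30, 30), c(30, 95), c(80, 50), c(105, 105))
  for (i in seq_len(nrow(centers))) {
    m <- disc_mask(140, 140, centers[i, 1], centers[i, 2], 10)
    img[m] <- 75; lab_truth[m] <- i
  }
  g <- gray_image(img, "8bit")
  lab1 <- initial_segment(g)
  expect_equal(count_objects(lab1), 4)
  res <- process_all_cells(lab1, g)
  expect_equal(nrow(res$measurements), 4)
  expect_equal(count_objects(res$labels), 4)       # stage 2 keeps the count
  expect_true(all(res$measurements$refine_status == "refined"))
  expect_true(all(is.finite(res$measurements$long_len)))
  expect_true(all(is.finite(res$measurements$short_len)))
  # ratio and ordering invariants
  expect_true(all(res$measurements$short_len <= res$measurements$long_len))
  expect_true(all(res$measurements$axis_ratio > 0 &
                  res$measurements$axis_ratio <= 1))
  # refined masks live inside their neighbour-aware dilated region
  for (cell in res$cells) {
    roi <- cell$roi
    allowed <- build_cell_mask(lab1, cell$label, roi, 6)
    refined <- res$labels[(roi$r0 + 1):roi$r1, (roi$c0 + 1):roi$c1] ==
      cell$label
    expect_true(all(!(refined & !allowed)))
  }
  # empty input: empty output
  res0 <- process_all_cells(matrix(0L, 20, 20), gray_image(matrix(10, 20, 20),
                                                           "8bit"))
  expect_equal(nrow(res0$measurements), 0)
  expect_equal(count_objects(res0$labels), 0)
})
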