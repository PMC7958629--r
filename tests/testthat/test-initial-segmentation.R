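test_that("Otsu separates a perfectly bimodal image at the lowest valid cut", {
  x <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  res <- otsu_threshold(gray_image(x, "8bit"))
  expect_equal(res$threshold, 10)          # first maximizer of the criterion
  expect_equal(sum(res$mask), 50)
  expect_true(all(x[res$mask] == 10))
})

test_that("Otsu equals the exhaustive between-class-variance scan", {
  set.seed(21)
  for (k in 1:6) {
    x <- matrix(sample(0:255, 64 * 64, TRUE, prob = runif(256)), 64, 64)
    got <- otsu_threshold(gray_image(x, "8bit"))$threshold
    expect_equal(got, oracle_otsu_cut(as.vector(x)))
  }
})

test_that("inverting image and polarity yields the complementary mask", {
  set.seed(22)
  x <- matrix(sample(0:255, 256, TRUE), 16, 16)
  a <- otsu_threshold(gray_image(x, "8bit"), dark_foreground = TRUE)$mask
  b <- otsu_threshold(gray_image(255 - x, "8bit"), dark_foreground = FALSE)$mask
  expect_identical(a, b)
  expect_error(otsu_threshold(matrix(5, 4, 4)), "constant")
})

test_that("fill_holes closes interior cavities only", {
  ring <- matrix(FALSE, 9, 9)
  ring[3:7, 3:7] <- TRUE; ring[4:6, 4:6] <- FALSE
  expect_true(all(fill_holes(ring)[3:7, 3:7]))
  disc <- disc_mask(15, 15, 8, 8, 5)
  expect_identical(fill_holes(disc), disc)
  set.seed(23)
  for (k in 1:10) {
    m <- matrix(runif(15 * 15) > 0.55, 15, 15)
    expect_identical(fill_holes(m), oracle_fill_holes(m))
  }
})

test_that("disc erosion and dilation behave as adjoint pairs", {
  expect_true(all(!erode_mask(matrix(FALSE, 6, 6), 2)))
  plus <- matrix(FALSE, 5, 5); plus[3, 3] <- TRUE
  d <- dilate_mask(plus, 1)
  expect_equal(sum(d), 5)                      # 5-pixel plus shape
  expect_true(all(d[cbind(c(2, 3, 3, 3, 4), c(3, 2, 3, 4, 3))]))
  set.seed(24)
  for (k in 1:8) {
    m <- matrix(runif(20 * 20) > 0.6, 20, 20)
    r <- sample(1:3, 1)
    expect_true(all(!(m & !erode_mask(dilate_mask(m, r), r))))  # closing >= m
    expect_true(all(!(dilate_mask(erode_mask(m, r), r) & !m)))  # opening <= m
  }
  expect_identical(erode_mask(plus, 0), plus)
})

test_that("distance map matches the all-pairs nearest-background oracle", {
  set.seed(25)
  for (k in 1:8) {
    m <- matrix(runif(24 * 24) > 0.5, 24, 24)
    if (all(m)) m[1, 1] <- FALSE
    rel <- pixels(distance_map(m))
    d <- oracle_edt(m)
    expect_equal(rel, max(d) - d, tolerance = 1e-12)
  }
  # single foreground pixel: relief 0 there, 1 elsewhere
  one <- matrix(FALSE, 7, 7); one[4, 4] <- TRUE
  rel <- pixels(distance_map(one))
  expect_equal(rel[4, 4], 0)
  expect_true(all(rel[!one] == 1))
  # all-background mask: flat zero relief
  expect_true(all(pixels(distance_map(matrix(FALSE, 5, 5))) == 0))
  expect_error(distance_map(matrix(TRUE, 4, 4)), "all-foreground")
})

test_that("watershed splits touching discs and merges everything at level 1", {
  two <- disc_mask(64, 64, 32, 23, 10) | disc_mask(64, 64, 32, 41, 10)
  rel <- distance_map(two)
  expect_equal(count_objects(watershed_segment(rel)), 2)
  expect_equal(count_objects(watershed_segment(rel, watershed_params(level = 1))),
               1)
  # one basin: one label covering the foreground
  one <- disc_mask(40, 40, 20, 20, 12)
  lab <- watershed_segment(distance_map(one))
  expect_equal(count_objects(lab), 1)
  expect_identical(lab > 0, one)
  # labels never extend outside the relief foreground
  lab2 <- watershed_segment(rel)
  expect_true(all(lab2[!two] == 0L))
})

test_that("watershed label count is non-increasing in the merge level", {
  m <- disc_mask(80, 120, 40, 25, 12) | disc_mask(80, 120, 40, 45, 12) |
       disc_mask(80, 120, 40, 85, 9) | disc_mask(80, 120, 46, 100, 9)
  rel <- distance_map(m)
  counts <- vapply(c(0.05, 0.2, 0.4, 0.7, 1.0), function(lv)
    count_objects(watershed_segment(rel, watershed_params(level = lv))),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("small-object removal uses a strict threshold and stable relabel", {
  lab <- matrix(0L, 12, 30)
  lab[2:5, 2:7] <- 1L                       # 24 px
  lab[8:11, 2:21] <- 2L                     # 80 px
  lab[2:6, 10:14] <- 3L                     # 25 px
  out <- remove_small(lab, 25)
  expect_equal(count_objects(out), 2)
  expect_true(all(out[lab == 1L] == 0L))
  expect_equal(unique(out[lab == 2L]), 1L)  # survivors renumbered in order
  expect_equal(unique(out[lab == 3L]), 2L)
  expect_equal(sort(unique(out[out > 0])), c(1L, 2L))
  set.seed(26)
  lab2 <- label_components(matrix(runif(40 * 40) > 0.7, 40, 40))
  sizes <- tabulate(lab2[lab2 > 0])
  out2 <- remove_small(lab2, 5)
  expect_equal(count_objects(out2), sum(sizes >= 5))
})

test_that("border-touching objects are removed entirely", {
  lab <- matrix(0L, 20, 20)
  lab[disc_mask(20, 20, 10, 10, 4)] <- 1L
  clipped <- disc_mask(20, 20, 10, 2, 4)
  lab[clipped] <- 2L
  out <- remove_border_objects(lab)
  expect_equal(count_objects(out), 1)
  expect_true(all(out[clipped] == 0L))
  expect_identical(remove_border_objects(matrix(0L, 5, 5)), matrix(0L, 5, 5))
})

test_that("stage-1 segmentation recovers separated and touching cells", {
  # clean synthetic: dark discs on a bright field
  img <- matrix(230, 160, 160)
  centers <- rbind(c(30, 30), c(30, 100), c(90, 50), c(120, 120), c(130, 30))
  for (i in seq_len(nrow(centers)))
    img[disc_mask(160, 160, centers[i, 1], centers[i, 2], 11)] <- 70
  lab <- initial_segment(gray_image(img, "8bit"))
  expect_equal(count_objects(lab), 5)
  # touching pair is split by the watershed
  img2 <- matrix(230, 80, 80)
  img2[disc_mask(80, 80, 40, 31, 10) | disc_mask(80, 80, 40, 49, 10)] <- 70
  expect_equal(count_objects(initial_segment(gray_image(img2, "8bit"))), 2)
  # blank image segments to nothing
  expect_equal(count_objects(initial_segment(gray_image(matrix(128, 40, 40),
                                                        "8bit"))), 0)
})

test_that("stage-1 labels are confined to the hole-filled Otsu foreground", {
  img <- matrix(230, 100, 100)
  img[disc_mask(100, 100, 50, 50, 15)] <- 70
  img[disc_mask(100, 100, 30, 70, 8)] <- 60
  g <- gray_image(img, "8bit")
  lab <- initial_segment(g)
  fg <- fill_holes(otsu_threshold(g)$mask)
  expect_true(all(lab[!fg] == 0L))
})
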