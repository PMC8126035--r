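disk_mask <- function(h, w, cr, cc, r) {
  m <- matrix(FALSE, h, w)
  m[(row(m) - cr)^2 + (col(m) - cc)^2 <= r^2] <- TRUE
  m
}

test_that("mask cleaning merges near fragments and fills holes", {
  m <- matrix(FALSE, 7, 7); m[4, 3] <- TRUE; m[4, 5] <- TRUE
  expect_identical(clean_mask(m, 0, FALSE), m)
  merged <- clean_mask(m, 1, FALSE)
  expect_identical(max(label_objects(merged)), 1L)

  ring <- disk_mask(15, 15, 8, 8, 5) & !disk_mask(15, 15, 8, 8, 3)
  filled <- clean_mask(ring, 0, TRUE)
  expect_true(all(filled[disk_mask(15, 15, 8, 8, 5)]))
})

test_that("connected components respect connectivity and scan order", {
  expect_identical(max(label_objects(matrix(FALSE, 5, 5))), 0L)

  diag2 <- matrix(FALSE, 4, 4); diag2[2, 2] <- TRUE; diag2[3, 3] <- TRUE
  expect_identical(max(label_objects(diag2, 8)), 1L)
  expect_identical(max(label_objects(diag2, 4)), 2L)

  sq <- matrix(FALSE, 12, 12)
  sq[2:4, 2:4] <- TRUE; sq[2:4, 8:10] <- TRUE; sq[8:10, 2:4] <- TRUE
  lab <- label_objects(sq)
  expect_identical(max(lab), 3L)
  # label conservation
  expect_identical(sum(lab > 0), sum(sq))
})

test_that("labelling agrees with an independent reference implementation", {
  # EBImage::bwlabel uses 4-connectivity
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(runif(40 * 40) < 0.35, 40, 40)
    ours <- label_objects(m, 4)
    ref <- EBImage::bwlabel(matrix(as.integer(m), 40, 40))
    ref <- matrix(as.integer(ref), 40, 40)
    # identical partitions up to label renaming
    expect_identical(ours > 0, ref > 0)
    tab <- table(ours[m], ref[m])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("shape descriptors match closed forms on squares, pixels and disks", {
  sq <- matrix(FALSE, 5, 5); sq[2:4, 2:4] <- TRUE
  d <- shape_descriptors(label_objects(sq))
  expect_identical(d$area, 9L)
  expect_identical(c(d$width, d$height), c(3L, 3L))
  expect_equal(d$solidity, 1)

  px1 <- matrix(FALSE, 3, 3); px1[2, 2] <- TRUE
  d1 <- shape_descriptors(label_objects(px1))
  expect_identical(d1$area, 1L)
  expect_identical(c(d1$width, d1$height), c(1L, 1L))
  expect_equal(d1$solidity, 1)
  expect_gt(d1$circularity, 0)

  dk <- disk_mask(25, 25, 13, 13, 10)
  dd <- shape_descriptors(label_objects(dk))
  expect_gt(dd$circularity, 0.85)
  expect_lt(dd$circularity, 1.15)
  expect_gte(dd$solidity, 0.95)
  expect_equal(dd$centroid_row, 13)
  expect_equal(dd$centroid_col, 13)
})

test_that("area never exceeds the bounding box and solidity stays in (0, 1]", {
  set.seed(6)
  m <- clean_mask(matrix(runif(50 * 50) < 0.4, 50, 50), 1, TRUE)
  d <- shape_descriptors(label_objects(m))
  expect_true(all(d$area >= 1))
  expect_true(all(d$area <= d$width * d$height))
  expect_true(all(d$solidity > 0 & d$solidity <= 1))
  expect_true(all(d$circularity > 0))
  expect_identical(sum(d$area), sum(m))
})

test_that("shape filtering matches a brute-force per-criterion oracle", {
  set.seed(12)
  objs <- data.frame(
    label = 1:20,
    area = sample(1:400, 20), width = sample(1:30, 20),
    height = sample(1:30, 20),
    perimeter = runif(20, 4, 80),
    circularity = runif(20, 0, 1.4),
    convex_area = NA, solidity = runif(20),
    centroid_row = runif(20, 1, 50), centroid_col = runif(20, 1, 50))
  f <- shape_filter(min_area = 50, max_area = 300, min_width = 5,
                    max_width = 25, min_height = 4, max_height = 28,
                    min_circularity = 0.3, min_solidity = 0.4)
  res <- filter_objects(objs, f)

  keep_oracle <- with(objs,
    area >= 50 & area <= 300 & width >= 5 & width <= 25 &
    height >= 4 & height <= 28 & pmin(circularity, 1.15) >= 0.3 &
    solidity >= 0.4)
  expect_identical(res$kept$label, objs$label[keep_oracle])
  expect_identical(res$count, sum(keep_oracle))
  expect_identical(nrow(res$kept) + nrow(res$rejected), 20L)

  # first-failure criterion respects the fixed evaluation order
  one <- filter_objects(data.frame(objs[1, -2], area = 9)[names(objs)],
                        shape_filter(min_area = 10, min_solidity = 0.99))
  expect_identical(one$rejected$criterion, "area")

  all_kept <- filter_objects(objs, shape_filter())
  expect_identical(all_kept$count, 20L)
})

test_that("relaxing any filter bound never decreases the count", {
  set.seed(13)
  objs <- data.frame(
    label = 1:30, area = sample(1:400, 30), width = sample(1:30, 30),
    height = sample(1:30, 30), perimeter = runif(30, 4, 80),
    circularity = runif(30, 0, 1.4), convex_area = NA,
    solidity = runif(30), centroid_row = 0, centroid_col = 0)
  tight <- shape_filter(min_area = 60, max_area = 250, min_width = 6,
                        max_width = 20, min_circularity = 0.5,
                        min_solidity = 0.5)
  loose <- shape_filter(min_area = 30, max_area = 350, min_width = 3,
                        max_width = 28, min_circularity = 0.2,
                        min_solidity = 0.2)
  expect_gte(filter_objects(objs, loose)$count,
             filter_objects(objs, tight)$count)
})

test_that("filter calibration widens observed bounds by the margin", {
  d <- data.frame(area = c(100, 200), width = c(10, 14), height = c(11, 13),
                  circularity = c(0.8, 0.9), solidity = c(0.9, 0.95))
  f <- calibrate_filter(d, margin = 0.5)
  expect_equal(c(f$min_area, f$max_area), c(50, 300))
  expect_equal(c(f$min_width, f$max_width), c(5, 21))
  expect_equal(f$min_circularity, 0.4)
  expect_equal(f$min_solidity, 0.45)

  f0 <- calibrate_filter(d, margin = 0)
  expect_equal(c(f0$min_area, f0$max_area), c(100, 200))
  expect_warning(calibrate_filter(d[1, ]), "one training cell")
  expect_error(calibrate_filter(d[0, ]), "no training-cell")

  # self-consistency: the calibrated filter keeps all calibration objects
  d2 <- cbind(label = 1:2, d[, c("area", "width", "height")],
              perimeter = 1, circularity = d$circularity,
              convex_area = NA, solidity = d$solidity,
              centroid_row = 0, centroid_col = 0)
  expect_identical(filter_objects(d2, f)$count, 2L)
})

test_that("a blank field yields zero hemocytes", {
  m <- get_small_model()
  res <- count_hemocytes(toy_image(64, 64, c(250, 250, 250), id = "blank"), m)
  expect_identical(res$count, 0L)
})

test_that("well-separated planted hemocytes are counted exactly, centroids localized", {
  m <- get_small_model()
  spec <- small_spec(hemocyte_lambda = 5, n_nuclei = 0, n_fibers = 0)
  hits <- 0L
  for (seed in 61:64) {
    fld <- generate_field(spec, seed)
    res <- count_hemocytes(fld$image, m)
    truth <- fld$truth[fld$truth$type == "hemocyte", ]
    expect_identical(res$count, nrow(truth))
    if (nrow(truth)) {
      dmat <- outer(res$kept$centroid_row, truth$center_row, "-")^2 +
              outer(res$kept$centroid_col, truth$center_col, "-")^2
      expect_true(all(sqrt(apply(dmat, 2, min)) <= 5))
      hits <- hits + nrow(truth)
    }
  }
  expect_gt(hits, 0L)
})

test_that("detections map consistently under image transposition", {
  m <- get_small_model()
  fld <- generate_field(small_spec(hemocyte_lambda = 4), 91)
  res <- count_hemocytes(fld$image, m)
  tpx <- aperm(fld$image$pixels, c(2, 1, 3))
  rest <- count_hemocytes(rgb_image(tpx), m)
  expect_identical(rest$count, res$count)
  # the window features permute under transposition, so per-pixel scores can
  # shift marginally at cell rims; objects must still map one-to-one
  expect_lt(max(abs(sort(rest$kept$centroid_row) -
                    sort(res$kept$centroid_col))), 1)
})

test_that("overlays draw boxes without altering geometry", {
  m <- get_small_model()
  fld <- generate_field(small_spec(hemocyte_lambda = 4), 92)
  res <- count_hemocytes(fld$image, m)
  ov <- overlay_detections(fld$image, res)
  expect_identical(dim(ov$pixels), dim(fld$image$pixels))
  if (res$count > 0) expect_false(identical(ov$pixels, fld$image$pixels))
})
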