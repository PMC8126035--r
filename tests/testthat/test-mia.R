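random_image <- function(h, w, seed) {
  set.seed(seed)
  rgb_image(array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3)))
}

test_that("unfolding obeys the feature-dimension law", {
  img <- random_image(5, 5, 1)
  uf <- unfold(img, window_radius = 2)
  expect_identical(dim(uf$X), c(25L, 75L))

  img1 <- random_image(1, 1, 2)
  uf1 <- unfold(img1, window_radius = 0)
  expect_identical(dim(uf1$X), c(1L, 3L))
  expect_equal(as.vector(uf1$X), as.vector(img1$pixels[1, 1, ]))

  cst <- toy_image(6, 7, c(10, 120, 240))
  Xc <- unfold(cst, window_radius = 1)$X
  expect_true(all(apply(Xc, 2, function(v) all(v == v[1]))))
  expect_equal(nrow(unique(Xc)), 1L)
})

test_that("centre columns of the unfolded matrix refold to the original channels", {
  for (r in 0:3) {
    img <- random_image(9, 11, 100 + r)
    uf <- unfold(img, window_radius = r)
    side <- 2L * r + 1L
    centre <- (r) * side + r + 1L
    for (ch in 1:3) {
      col <- (ch - 1L) * side^2 + centre
      refold <- matrix(NA_real_, 9, 11)
      refold[uf$pixel_index] <- uf$X[, col]
      expect_identical(refold, matrix(as.numeric(img$pixels[, , ch]), 9, 11))
    }
  }
})

test_that("degenerate feature matrices produce the expected spectra", {
  Xc <- matrix(57, 40, 12)
  p <- pixel_pca(Xc, 5)
  expect_true(all(p$eigenvalues < 1e-20))

  set.seed(4)
  d <- rnorm(10); d <- d / sqrt(sum(d^2))
  X1 <- outer(rnorm(80), d) + matrix(5, 80, 10)
  p1 <- pixel_pca(X1, 6)
  expect_gt(p1$eigenvalues[1], 1e-6)
  expect_lt(p1$eigenvalues[2] / p1$eigenvalues[1], 1e-12)
  expect_gt(abs(sum(p1$loadings[, 1] * d)), 1 - 1e-10)
})

test_that("fitted loadings satisfy orthonormality, ordering and the trace identity", {
  for (seed in 1:4) {
    set.seed(seed)
    X <- matrix(rnorm(300 * 27, sd = 30), 300, 27)
    p <- pixel_pca(X, 10)
    G <- crossprod(p$loadings)
    expect_lt(max(abs(G - diag(10))), 1e-8)
    expect_true(all(diff(p$eigenvalues) <= 1e-8))
    # eigenvalue sum over all components equals total variance
    pall <- pixel_pca(X, 27)
    expect_equal(sum(pall$eigenvalues),
                 sum(apply(X, 2, var)), tolerance = 1e-6)
  }
})

test_that("score images equal the centred projection, refolded", {
  img <- random_image(12, 10, 42)
  tr_img <- random_image(16, 16, 43)
  uf_tr <- unfold(tr_img, window_radius = 1)
  p <- pixel_pca(uf_tr$X, 6)
  p$window_radius <- 1L
  valid <- matrix(TRUE, 12, 10); valid[1:3, 1:2] <- FALSE
  sc <- score_image(img, valid, p, component = 3)

  uf <- unfold(img, valid, 1)
  oracle <- as.vector(sweep(uf$X, 2, p$mean) %*% p$loadings[, 3])
  expect_lt(max(abs(sc$values[uf$pixel_index] - oracle)), 1e-9)
  expect_true(all(is.na(sc$values[!valid])))
  expect_error(score_image(img, valid, p, component = 7), "out of range")

  # an image whose unfolded rows all equal the model mean scores zero
  cst <- toy_image(8, 8, c(10, 120, 240))
  p0 <- pixel_pca(unfold(cst, window_radius = 1)$X, 3)
  p0$window_radius <- 1L
  sc0 <- score_image(cst, NULL, p0, component = 1)
  expect_lt(max(abs(sc0$values)), 1e-9)
})

test_that("threshold selection keeps the >= side and respects quantiles", {
  vals <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3)
  sc <- structure(list(values = vals, valid = matrix(TRUE, 2, 3),
                       component = 1L), class = "score_image")
  expect_identical(sum(threshold_scores(sc, 2)), 5L)
  expect_identical(sum(threshold_scores(sc, 0)), 6L)
  expect_identical(sum(threshold_scores(sc, 7)), 0L)

  set.seed(10)
  img <- random_image(30, 30, 77)
  tr <- structure(list(mosaic = img, valid = matrix(TRUE, 30, 30),
                       provenance = NULL, window_radius = 1L),
                  class = "training_image")
  p <- fit_pixel_pca(tr, 1, 5)
  tau <- calibrate_threshold(p, tr, 1, 0.5)
  sc <- score_image(img, NULL, p, 1)
  n <- sum(!is.na(sc$values))
  expect_identical(sum(sc$values >= tau, na.rm = TRUE), as.integer(ceiling(n / 2)))
})

test_that("model fitting is deterministic and persists bit-exactly", {
  ts <- training_set(301:304, spec = small_spec(hemocyte_lambda = 4))
  m1 <- hemocyte_model(ts$images, ts$annotations)
  m2 <- hemocyte_model(ts$images, ts$annotations)
  expect_identical(m1$pca$loadings, m2$pca$loadings)
  expect_identical(m1$score_threshold, m2$score_threshold)

  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_hemocyte_model(m1, f1)
  write_hemocyte_model(m2, f2)
  expect_identical(readLines(f1), readLines(f2))

  back <- read_hemocyte_model(f1)
  expect_identical(back$pca$mean, m1$pca$mean)
  expect_identical(back$pca$loadings, m1$pca$loadings)
  expect_identical(back$score_threshold, m1$score_threshold)
  expect_identical(back$selected_pc, m1$selected_pc)
  f3 <- withr::local_tempfile(fileext = ".json")
  write_hemocyte_model(back, f3)
  expect_identical(readLines(f3), readLines(f1))
})

test_that("component ranking finds a component separating hemocytes from tissue", {
  m <- get_small_model()
  expect_s3_class(m$pc_diagnostic, "data.frame")
  expect_identical(which.max(abs(m$pc_diagnostic$contrast)), m$selected_pc)
  expect_gt(m$pc_diagnostic$contrast[m$selected_pc], 1)
  expect_gte(m$pc_diagnostic$hemocyte_mean[m$selected_pc],
             m$pc_diagnostic$other_mean[m$selected_pc])
})
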