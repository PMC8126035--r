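test_that("field generation is bitwise deterministic in (spec, seed)", {
  spec <- small_spec()
  f1 <- generate_field(spec, 123)
  f2 <- generate_field(spec, 123)
  expect_identical(f1$image$pixels, f2$image$pixels)
  expect_identical(f1$truth, f2$truth)
  f3 <- generate_field(spec, 124)
  expect_false(identical(f1$image$pixels, f3$image$pixels))
})

test_that("confounders do not perturb hemocyte placement", {
  sp_with <- small_spec(hemocyte_lambda = 5)
  sp_without <- small_spec(hemocyte_lambda = 5, n_nuclei = 0, n_fibers = 0)
  t1 <- generate_field(sp_with, 55)$truth
  t2 <- generate_field(sp_without, 55)$truth
  h1 <- t1[t1$type == "hemocyte", c("center_row", "center_col", "radius")]
  h2 <- t2[t2$type == "hemocyte", c("center_row", "center_col", "radius")]
  expect_equal(h1, h2)
})

test_that("an empty specification yields an empty field", {
  spec <- small_spec(hemocyte_lambda = 0, n_nuclei = 0, n_fibers = 0,
                     bright_fraction = 0)
  f <- generate_field(spec, 5)
  expect_identical(nrow(f$truth), 0L)
  # plain tissue: nothing brighter than the lacuna rule anywhere
  expect_true(all(background_mask(f$image, background_config())))
})

test_that("planted hemocyte numbers follow the Poisson intensity", {
  spec <- small_spec(size = c(176, 176), hemocyte_lambda = 5,
                     n_nuclei = 0, n_fibers = 0)
  n <- vapply(1:150, function(s)
    sum(generate_field(spec, s)$truth$type == "hemocyte"), integer(1))
  # 99% CI for the mean of 150 Poisson(5) draws
  expect_lt(abs(mean(n) - 5), 2.576 * sqrt(5 / 150))
  expect_true(all(sapply(1:5, function(s) {
    tr <- generate_field(spec, s)$truth
    if (nrow(tr) < 2) return(TRUE)
    d <- as.matrix(dist(tr[, c("center_row", "center_col")]))
    min(d[upper.tri(d)]) >= spec$min_separation
  })))
})

test_that("granule texture contrast dominates the background texture", {
  spec <- synthetic_spec(hemocyte_lambda = 8)
  f <- generate_field(spec, 7)
  tr <- f$truth[f$truth$type == "hemocyte", ]
  g <- f$image$pixels[, , 2]
  sds <- vapply(seq_len(nrow(tr)), function(i) {
    sel <- (row(g) - tr$center_row[i])^2 + (col(g) - tr$center_col[i])^2 <=
      (tr$radius[i] - 1)^2
    sd(g[sel])
  }, numeric(1))
  expect_gte(mean(sds), 3 * spec$bg_texture_amp)

  # nuclei are smooth: their interior variation stays near the noise floor
  nu <- f$truth[f$truth$type == "nucleus", ]
  nsd <- vapply(seq_len(nrow(nu)), function(i) {
    sel <- (row(g) - nu$center_row[i])^2 + (col(g) - nu$center_col[i])^2 <=
      max(nu$radius[i] - 1, 1)^2
    sd(g[sel])
  }, numeric(1))
  expect_lt(mean(nsd, na.rm = TRUE), mean(sds) / 3)
})

test_that("auto-annotation reproduces planted bounding rectangles", {
  spec <- small_spec(hemocyte_lambda = 3)
  f <- generate_field(spec, 31)
  tr <- f$truth[f$truth$type == "hemocyte", ]
  ann <- auto_annotate(f$truth, "img")
  expect_identical(nrow(ann), nrow(tr))
  expect_identical(ann$r0, tr$r0)
  expect_identical(ann$nc, tr$nc)

  nuc_only <- f$truth[f$truth$type != "hemocyte", ]
  expect_error(auto_annotate(nuc_only, "img"), "no hemocytes")

  # assembled mosaic keeps approximately the planted disk areas
  imgs <- setNames(list(f$image), "img")
  mosaic <- assemble_training_image(imgs, ann)
  expect_lt(abs(sum(mosaic$valid) - sum(pi * tr$radius^2)),
            0.2 * sum(pi * tr$radius^2))
})

test_that("the chosen group intensities reproduce the expected fold range", {
  # oracle on the count model: ratio of group means over many replicates
  set.seed(99)
  ratios <- replicate(500, mean(rpois(30, 14)) / mean(rpois(30, 2)))
  expect_gte(mean(ratios >= 5 & ratios <= 9), 0.95)
})

test_that("study generation returns coherent truth, groups and counts", {
  spec <- small_spec()
  st <- generate_study(1, 4, 3, spec = spec, seed = 42)
  expect_identical(length(st$images), 6L)
  expect_identical(nrow(st$counts), 6L)
  expect_identical(st$counts$group, rep(c("control", "regen"), each = 3))
  for (id in st$groups$image_id) {
    tr <- st$truth[st$truth$image_id == id & st$truth$type == "hemocyte", ]
    expect_identical(st$counts$count[st$counts$image_id == id], nrow(tr))
  }
  expect_equal(st$groups$field_area_mm2[1],
               prod(spec$size) * spec$pixel_size_um^2 / 1e6)
})

test_that("study files are byte-identical across reruns with one seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  spec <- small_spec()
  generate_study(1, 3, 2, spec = spec, seed = 9, dir = d1)
  generate_study(1, 3, 2, spec = spec, seed = 9, dir = d2)
  for (f in c("groups.csv", "truth.csv", "spec.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  imgs <- list.files(file.path(d1, "images"))
  expect_identical(imgs, list.files(file.path(d2, "images")))
  for (f in imgs)
    expect_identical(readBin(file.path(d1, "images", f), "raw", 1e6),
                     readBin(file.path(d2, "images", f), "raw", 1e6))
})
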