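test_that("image generation is deterministic given the seed and sensitive to it", {
  a <- generate_real_images(6, seed = 1, style = tiny_style())
  b <- generate_real_images(6, seed = 1, style = tiny_style())
  c <- generate_real_images(6, seed = 2, style = tiny_style())
  expect_identical(a$images, b$images)
  expect_false(identical(a$images, c$images))
  expect_true(all(a$images >= 0 & a$images <= 1))
})

test_that("every generated image has positive pixel variance", {
  ds <- generate_real_images(200, seed = 3, style = tiny_style())
  vars <- apply(ds$images, 4, var)
  expect_true(all(vars > 0))
})

test_that("style parameters are validated", {
  expect_error(generate_real_images(5, 1, style = list(img_size = c(4, 4))), "invalid")
  expect_error(style_params(amplitude = -1), "invalid")
  expect_error(generate_real_images(0, 1), "n > 0")
})

test_that("average images follow the stated weighting rules", {
  const_img <- function(v) array(v, dim = c(4, 4, 3))
  two <- array(c(const_img(0.4), const_img(0.8)), dim = c(4, 4, 3, 2))
  expect_equal(make_average_image(two, 2), const_img(0.6))
  expect_equal(make_average_image(two, 1.25), const_img((0.4 + 0.25 * 0.8) / 1.25))
  one <- array(const_img(0.33), dim = c(4, 4, 3, 1))
  expect_identical(make_average_image(one, 1), const_img(0.33))
  expect_error(make_average_image(two, 3), "expected 3 source images")
  expect_error(make_average_image(two, 0.5), ">= 1")
})

test_that("equal-weight averaging is permutation invariant and pixelwise bounded", {
  src <- generate_real_images(3, seed = 4, style = tiny_style())$images
  avg <- make_average_image(src, 3)
  perm <- src[, , , c(3, 1, 2), drop = FALSE]
  expect_equal(make_average_image(perm, 3), avg, tolerance = 1e-15)
  lo <- pmin(src[, , , 1], src[, , , 2], src[, , , 3])
  hi <- pmax(src[, , , 1], src[, , , 2], src[, , , 3])
  expect_true(all(avg >= lo - 1e-12 & avg <= hi + 1e-12))
})

test_that("difficulty suites are balanced, disjoint, and share real images across levels", {
  suite <- build_difficulty_suite(c(1.25, 3, 20), n_train = 16, n_val = 8,
                                  n_test = 8, seed = 5, style = tiny_style(),
                                  source_pool_size = 32)
  expect_length(suite, 3)
  img_hash <- function(ds) apply(ds$images, 4, rlang::hash)
  for (lv in names(suite)) {
    tr <- suite[[lv]]$train; te <- suite[[lv]]$test
    expect_equal(mean(tr$labels), 0.5)
    expect_equal(mean(te$labels), 0.5)
    expect_length(intersect(img_hash(tr), img_hash(te)), 0)
  }
  # the real class is shared across levels, averages are rebuilt per level
  reals <- lapply(suite, function(tt) {
    sort(img_hash(tt$train)[tt$train$labels == 1])
  })
  expect_identical(reals[[1]], reals[[2]])
  avgs <- lapply(suite, function(tt) {
    sort(img_hash(tt$train)[tt$train$labels == 0])
  })
  expect_length(intersect(avgs[[1]], avgs[[2]]), 0)
})

test_that("suite construction validates sizes and pool capacity", {
  expect_error(build_difficulty_suite(2, n_train = 15, n_val = 8, n_test = 8,
                                      seed = 1, style = tiny_style()), "even")
  expect_error(build_difficulty_suite(40, n_train = 8, n_val = 4, n_test = 4,
                                      seed = 1, style = tiny_style(),
                                      source_pool_size = 10), "pool")
})

test_that("averages drift away from their source scenes as k grows", {
  sims <- vapply(c(1.25, 3, 20), average_source_similarity, numeric(1),
                 n = 25, seed = 6, style = tiny_style())
  expect_true(all(diff(sims) < 0))
})

test_that("class separability in the contrast channel grows with k", {
  suite <- build_difficulty_suite(c(1.25, 40), n_train = 64, n_val = 8,
                                  n_test = 8, seed = 7, style = tiny_style(),
                                  source_pool_size = 64)
  expect_gt(contrast_separation(suite[["40"]]$train),
            contrast_separation(suite[["1.25"]]$train))
})

test_that("category datasets are balanced, deterministic, and linearly decodable", {
  ds1 <- generate_category_dataset(8, 20, seed = 1, style = tiny_style())
  ds2 <- generate_category_dataset(8, 20, seed = 1, style = tiny_style())
  expect_identical(ds1$images, ds2$images)
  expect_equal(n_images(ds1), 160)
  expect_equal(unname(table(ds1$labels)), rep(20L, 8), ignore_attr = TRUE)
  expect_error(generate_category_dataset(1, 5, seed = 1), "n_categories")

  # a linear probe on raw pixels must beat chance by a wide margin
  x <- t(matrix(ds1$images, ncol = 160))
  tr <- seq(1, 160, by = 2); te <- seq(2, 160, by = 2)
  fit <- glmnet::glmnet(x[tr, ], factor(ds1$labels[tr]),
                        family = "multinomial", alpha = 0,
                        lambda = 0.01, standardize = FALSE)
  pred <- predict(fit, x[te, ], s = 0.01, type = "class")
  acc <- mean(pred == as.character(ds1$labels[te]))
  se <- sqrt((1 / 8) * (7 / 8) / length(te))
  expect_gt(acc, 1 / 8 + 3 * se)
})

test_that("datasets round-trip through PNG files and CSV manifests", {
  ds <- generate_real_images(4, seed = 8, style = tiny_style())
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$images, ds$images, tolerance = 1 / 255)
  expect_equal(back$labels, ds$labels)
})

test_that("dataset splits are disjoint and sized as requested", {
  ds <- generate_category_dataset(4, 12, seed = 2, style = tiny_style())
  spl <- split_dataset(ds, 24, 12, 12, seed = 3)
  expect_equal(vapply(spl, n_images, numeric(1)),
               c(train = 24, val = 12, test = 12))
  h <- lapply(spl, function(d) apply(d$images, 4, rlang::hash))
  expect_length(intersect(h$train, h$test), 0)
  expect_length(intersect(h$train, h$val), 0)
})
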