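hist_img <- function(h) {
  # build a gray image realizing histogram h (any spatial arrangement)
  vals <- rep(0:255, h)
  n <- length(vals)
  w <- ceiling(sqrt(n))
  pad <- rep(vals[1], w^2 - n)
  raster_image(matrix(c(vals, pad), w, w))
}

test_that("triangle threshold equals the exhaustive distance oracle", {
  h <- integer(256); h[11] <- 1000; h[201] <- 100
  img <- hist_img(h)
  res <- triangle_auto_threshold(img, object_type = "light")
  expect_identical(res$threshold_value, as.integer(triangle_oracle(histogram256(img))))
  expect_identical(res$histogram, histogram256(img))
  expect_error(triangle_auto_threshold(raster_image(matrix(7, 4, 4))), "constant")
})

test_that("triangle xstep strides the candidate levels", {
  withr::local_seed(31)
  h <- tabulate(pmin(256, pmax(1, round(c(rnorm(3000, 60, 18), rnorm(700, 190, 25))))), 256)
  img <- hist_img(h)
  t1 <- triangle_auto_threshold(img, object_type = "light", xstep = 1)$threshold_value
  t2 <- triangle_auto_threshold(img, object_type = "light", xstep = 2)$threshold_value
  expect_lte(abs(t1 - t2), 2)
  expect_identical(t2, as.integer(triangle_oracle(h, "light", 2)))
})

test_that("otsu threshold equals the exhaustive split-point oracle", {
  img <- raster_image(matrix(c(rep(50, 500), rep(200, 500)), 25, 40))
  res <- otsu_auto_threshold(img)
  expect_gt(res$threshold_value, 50)
  expect_lt(res$threshold_value, 200)
  expect_identical(res$threshold_value, as.integer(otsu_oracle(histogram256(img))))
  expect_error(otsu_auto_threshold(raster_image(matrix(3, 5, 5))), "constant")
})

test_that("otsu and triangle match their oracles on 100 random histograms", {
  withr::local_seed(99)
  for (i in 1:100) {
    h <- random_histogram()
    if (sum(h > 0) < 2) next
    expect_identical(phenokit:::otsu_threshold_value(h), as.integer(otsu_oracle(h)))
    expect_identical(phenokit:::triangle_threshold_value(h, "light"),
                     as.integer(triangle_oracle(h, "light")))
  }
})

test_that("otsu agrees with an independent library implementation", {
  sc <- small_scene(13)
  g <- as_gray(sc$image)
  mine <- otsu_auto_threshold(g)$threshold_value
  ref <- EBImage::otsu(EBImage::Image(t(g$pixels / 255)), range = c(0, 1), levels = 256) * 255
  expect_lte(abs(mine - ref), 2)
})

test_that("binary_threshold obeys the strict comparison rule", {
  withr::local_seed(8)
  img <- raster_image(matrix(sample(0:255, 400, TRUE), 20, 20))
  m <- binary_threshold(img, 127, "light")
  expect_identical(sum(m == 255L), sum(img$pixels > 127))
  expect_identical(sum(binary_threshold(img, 0, "light") == 255L), sum(img$pixels > 0))
  expect_identical(sum(binary_threshold(img, 255, "light") == 255L), 0L)
  # polarity flip complements the mask up to the equality boundary
  d <- binary_threshold(img, 127, "dark")
  expect_identical(sum(m == 255L) + sum(d == 255L) + sum(img$pixels == 127), 400L)
})

test_that("adaptive threshold localizes to intensity boundaries", {
  img <- raster_image(cbind(matrix(50, 20, 10), matrix(200, 20, 10)))
  m <- adaptive_threshold(img, "mean", 3, 0, "light")
  on <- which(unclass(m) == 255L, arr.ind = TRUE)
  expect_true(all(abs(on[, 2] - 10.5) <= 1.5))
  # uniform image with positive offset: nothing passes, either polarity
  u <- raster_image(matrix(90, 15, 15))
  expect_identical(sum(adaptive_threshold(u, "mean", 5, 2, "light") == 255L), 0L)
  expect_identical(sum(adaptive_threshold(u, "gaussian", 5, 2, "dark") == 255L), 0L)
  # constant image yields a constant mask even at offset 0
  expect_length(unique(as.vector(unclass(adaptive_threshold(u, "mean", 5, 0, "light")))), 1)
  expect_error(adaptive_threshold(u, "mean", 4, 0), "odd")
})

test_that("adaptive mean recovers a bright blob on a defeating gradient", {
  # global methods cannot separate this: the ramp spans the blob contrast
  ramp <- matrix(rep(seq(0, 98, by = 2), each = 50), 50, 50)
  blob <- matrix(FALSE, 50, 50); blob[20:30, 20:30] <- TRUE
  g <- ramp + 50 * blob
  m <- adaptive_threshold(raster_image(g), "mean", 15, offset = 10, object_type = "light")
  expect_identical(unclass(m) == 255L, blob)
})
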