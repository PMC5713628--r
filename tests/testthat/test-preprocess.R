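test_that("white_balance scales each channel to its reference maximum", {
  img <- raster_image(matrix(128, 10, 10))
  wb <- white_balance(img, roi(2, 2, 4, 4))
  expect_true(all(wb$pixels == 255))
  # linear-scaling oracle on a color image
  arr <- array(0, c(6, 6, 3))
  arr[, , 1] <- 100; arr[, , 2] <- 200; arr[, , 3] <- 50
  arr[1, 1, ] <- c(120, 240, 60)
  wb2 <- white_balance(raster_image(arr))
  expect_identical(wb2$pixels[3, 3, ],
                   round(pmin(255, c(100 * 255 / 120, 200 * 255 / 240, 50 * 255 / 60))))
  # ROI already containing pure white leaves the image unchanged
  arr[2, 2, ] <- c(255, 255, 255)
  img3 <- raster_image(arr)
  expect_identical(white_balance(img3, roi(0, 0, 3, 3))$pixels, img3$pixels)
  expect_error(white_balance(raster_image(matrix(0, 5, 5))), "reference maximum is 0")
  expect_error(white_balance(img, roi(5, 5, 10, 10)), "outside")
})

test_that("white_balance is idempotent", {
  withr::local_seed(11)
  img <- raster_image(matrix(sample(10:200, 100, TRUE), 10, 10))
  once <- white_balance(img)
  expect_identical(white_balance(once)$pixels, once$pixels)
})

test_that("median_blur removes salt noise and preserves constants", {
  m <- matrix(0, 11, 11); m[6, 6] <- 255
  expect_true(all(median_blur(raster_image(m), 3)$pixels == 0))
  expect_identical(median_blur(raster_image(m), 1)$pixels, m)
  const <- raster_image(matrix(77, 8, 8))
  expect_identical(median_blur(const, 5)$pixels, matrix(77, 8, 8))
  expect_error(median_blur(const, 4), "odd")
})

test_that("gaussian_blur matches a direct convolution oracle", {
  const <- raster_image(matrix(93, 9, 9))
  expect_identical(gaussian_blur(const, 3, 1)$pixels, matrix(93, 9, 9))
  m <- matrix(0, 11, 11); m[6, 6] <- 255
  g3 <- gaussian_blur(raster_image(m), 3, 1, 1)
  x <- exp(-(-1:1)^2 / 2)
  k <- outer(x / sum(x), x / sum(x))
  expect_true(all(abs(g3$pixels[5:7, 5:7] - round(255 * k)) <= 1))
  # larger kernels blur more: the impulse peak strictly decreases
  peaks <- vapply(c(3, 5, 7), function(ks)
    max(gaussian_blur(raster_image(m), ks, ks / 3)$pixels), numeric(1))
  expect_true(all(diff(peaks) < 0))
  expect_error(gaussian_blur(const, 4, 1), "odd")
})

test_that("rotate_img maps coordinates exactly and respects symmetry", {
  m <- matrix(0L, 21, 21); m[3:5, 8:10] <- 255L
  mask <- binary_mask(m)
  expect_identical(unclass(rotate_img(mask, 0)), unclass(mask))
  # full turn: within interpolation tolerance on an intensity image
  withr::local_seed(5)
  img <- raster_image(matrix(sample(0:255, 441, TRUE), 21, 21))
  expect_lt(mean(abs(rotate_img(img, 360)$pixels - img$pixels)), 1)
  # 90 degrees: blob centroid follows the exact coordinate transform
  r90 <- rotate_img(mask, 90)
  idx <- which(unclass(r90) == 255L, arr.ind = TRUE)
  got <- c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)          # (x, y)
  src <- c(8, 3)                                            # blob centroid
  expected <- c(10 + (src[2] - 10), 10 - (src[1] - 10))     # forward 90-degree map
  expect_lt(max(abs(got - expected)), 1)
})

test_that("shift_img translates content and zero-fills", {
  m <- matrix(0L, 30, 30); m[11, 11] <- 255L
  mask <- binary_mask(m)
  expect_identical(unclass(shift_img(mask, 0, 0)), unclass(mask))
  sh <- shift_img(mask, 5, 0)
  expect_identical(which(unclass(sh) == 255L, arr.ind = TRUE)[1, ],
                   c(row = 11L, col = 16L))
  # shift then inverse shift restores everything away from the border
  withr::local_seed(6)
  img <- raster_image(matrix(sample(0:255, 900, TRUE), 30, 30))
  back <- shift_img(shift_img(img, 4, 3), -4, -3)
  expect_equal(back$pixels[1:27, 1:26], img$pixels[1:27, 1:26], ignore_attr = TRUE)
  expect_error(shift_img(mask, 30, 0), "smaller than the image")
})

test_that("resize rescales masks and stays binary", {
  sq <- square_mask(20, 20, 6, 6, 10)
  expect_identical(unclass(resize(sq, 1, 1)), unclass(sq))
  up <- resize(sq, 2, 2)
  expect_identical(dim(unclass(up)), c(40L, 40L))
  expect_setequal(unique(as.vector(unclass(up))), c(0L, 255L))
  expect_lt(abs(sum(up == 255L) / sum(sq == 255L) - 4), 0.4)
  expect_error(resize(sq, 0, 1), "positive")
  # down-then-up round trip keeps at least 90% of the foreground
  sc <- small_scene(9)
  for (f in c(0.5, 1.5, 2)) {
    rt <- resize(resize(sc$mask, f, f), 1 / f, 1 / f)
    both <- sum(unclass(rt) == 255L & unclass(sc$mask) == 255L)
    expect_gte(both / sum(sc$mask == 255L), 0.9)
  }
})

test_that("crop_position_mask anchors, offsets, and matches target dims", {
  nir <- blank_img(20)
  same <- binary_mask(matrix(255L, 20, 20))
  expect_identical(unclass(crop_position_mask(nir, same)), unclass(same))
  blob <- binary_mask(matrix(255L, 5, 5))
  placed <- crop_position_mask(nir, blob, 3, 4, "top", "left")
  idx <- which(unclass(placed) == 255L, arr.ind = TRUE)
  expect_identical(c(min(idx[, 2]) - 1L, min(idx[, 1]) - 1L), c(3L, 4L))
  placed_br <- crop_position_mask(nir, blob, 1, 2, "bottom", "right")
  idx2 <- which(unclass(placed_br) == 255L, arr.ind = TRUE)
  expect_identical(c(max(idx2[, 2]) - 1L, max(idx2[, 1]) - 1L), c(20L - 1L - 1L, 20L - 2L - 1L))
  # oversized masks are cropped to the target frame, still binary
  big <- binary_mask(matrix(255L, 40, 40))
  crop <- crop_position_mask(nir, big)
  expect_identical(dim(unclass(crop)), c(20L, 20L))
  expect_setequal(unique(as.vector(unclass(crop))), 255L)
  sc <- small_scene(2)
  out <- crop_position_mask(blank_img(77, 55), sc$mask, 4, 9)
  expect_identical(dim(unclass(out)), c(77L, 55L))
})

test_that("get_nir finds the sibling by name substitution", {
  d <- withr::local_tempdir()
  file.create(file.path(d, "plant1_VIS.png"), file.path(d, "plant1_NIR.png"))
  expect_identical(basename(get_nir(file.path(d, "plant1_VIS.png"))), "plant1_NIR.png")
  file.create(file.path(d, "lonely_VIS.png"))
  expect_error(get_nir(file.path(d, "lonely_VIS.png")), "not found")
  expect_error(get_nir(file.path(d, "plain.png")), "does not match")
})
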