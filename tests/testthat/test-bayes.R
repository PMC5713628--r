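test_that("two-class training draws 10% of foreground and equal background", {
  pdfs <- train_two_class(list(exact_1000_pair()), seed = 3)
  expect_identical(unname(attr(pdfs, "n_samples")), c(100, 100))
  expect_identical(nrow(attr(pdfs, "samples")$plant), 100L)
  expect_identical(nrow(attr(pdfs, "samples")$background), 100L)
})

test_that("sample counts pool across training pairs", {
  p <- exact_1000_pair()
  pdfs <- train_two_class(list(p, p), seed = 3)
  expect_identical(unname(attr(pdfs, "n_samples")), c(200, 200))
  expect_error(train_two_class(list(list(image = p$image,
                                         mask = binary_mask(matrix(0L, 50, 60))))),
               "no foreground")
})

test_that("every discretized channel density sums to one", {
  sc <- small_scene(41)
  pdfs <- train_two_class(list(list(image = sc$image, mask = sc$mask)), seed = 1)
  for (p in pdfs) {
    expect_identical(dim(p$pdf), c(3L, 256L))
    expect_equal(unname(rowSums(p$pdf)), c(1, 1, 1), tolerance = 1e-6)
    expect_true(all(p$pdf >= 0))
  }
})

test_that("different training seeds classify well-separated scenes identically", {
  sc <- small_scene(42)
  pair <- list(list(image = sc$image, mask = sc$mask))
  p1 <- train_two_class(pair, seed = 1)
  p2 <- train_two_class(pair, seed = 2)
  expect_false(identical(p1$plant$pdf, p2$plant$pdf))
  te <- small_scene(43)
  m1 <- naive_bayes_classifier(te$image, p1)
  m2 <- naive_bayes_classifier(te$image, p2)
  expect_identical(unclass(m1$plant), unclass(m2$plant))
})

test_that("multiclass training reproduces the two-class procedure on the same samples", {
  sc <- small_scene(44)
  two <- train_two_class(list(list(image = sc$image, mask = sc$mask)), seed = 9)
  multi <- train_multiclass(attr(two, "samples"))
  for (cl in c("plant", "background")) {
    expect_equal(multi[[cl]]$pdf, two[[cl]]$pdf, tolerance = 1e-9)
  }
})

test_that("multiclass training validates its inputs", {
  expect_error(train_multiclass(list(a = matrix(100, 40, 3))), "at least 2 classes")
  expect_error(train_multiclass(list(a = matrix(100, 40, 3), b = matrix(100, 10, 3))),
               "at least 30")
  expect_error(train_multiclass(list(a = matrix(100, 40, 3),
                                     b = matrix(300, 40, 3))), "outside")
})

test_that("training tables round-trip and malformed cells carry line numbers", {
  d <- withr::local_tempdir()
  tab <- generate_training_table(palette_rust(), 60, seed = 5)
  path <- file.path(d, "train.tsv")
  write_training_table(tab, path)
  back <- read_training_table(path)
  expect_identical(names(back), names(unclass(tab)))
  for (cl in names(back)) expect_equal(back[[cl]], unname(unclass(tab)[[cl]]))
  pdfs <- train_multiclass(back)
  expect_length(pdfs, 4)
  writeLines(c("a\tb", "256,0,0\t1,2,3"), path)
  expect_error(read_training_table(path), "line 2")
  writeLines("onlyone", path)
  expect_error(read_training_table(path), "at least 2")
})

test_that("PDF files round-trip through the tab-delimited format", {
  d <- withr::local_tempdir()
  sc <- small_scene(45)
  pdfs <- train_two_class(list(list(image = sc$image, mask = sc$mask)), seed = 1)
  path <- file.path(d, "pdfs.tsv")
  write_pdfs(pdfs, path)
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_identical(header[1:3], c("class", "channel", "b0"))
  back <- read_pdfs(path)
  for (cl in names(pdfs)) expect_equal(back[[cl]]$pdf, pdfs[[cl]]$pdf, tolerance = 1e-12)
})

test_that("classification is an exhaustive, exclusive partition", {
  sc <- small_scene(46)
  pdfs <- train_two_class(list(list(image = sc$image, mask = sc$mask)), seed = 1)
  masks <- naive_bayes_classifier(sc$image, pdfs)
  tot <- Reduce(`+`, lapply(masks, function(m) (unclass(m) == 255L) * 1L))
  expect_true(all(tot == 1L))
})

test_that("a pixel in a hue range only one class occupies goes to that class", {
  mk_pdf <- function(cl, lo, hi) {
    pdf <- matrix(1 / 256, 3, 256, dimnames = list(c("h", "s", "v"), NULL))
    hrow <- numeric(256); hrow[(lo:hi) + 1] <- 1 / (hi - lo + 1)
    pdf["h", ] <- hrow
    structure(list(class = cl, pdf = pdf), class = "class_pdf")
  }
  pdfs <- structure(list(A = mk_pdf("A", 0, 100), B = mk_pdf("B", 150, 255)),
                    class = "class_pdfs")
  # a saturated red pixel has hue byte 0 -> only class A has mass there
  img <- raster_image(array(rep(c(200, 10, 10), each = 4), c(2, 2, 3)))
  masks <- naive_bayes_classifier(img, pdfs)
  expect_true(all(masks$A == 255L))
  expect_true(all(masks$B == 0L))
})

test_that("two-class recovery reaches 99% at a 40-byte hue gap", {
  pal <- class_palette(list(plant = c(100, 170, 160),
                            background = c(60, 170, 160)), spread = 8)
  tr <- generate_scene(scene_spec(palette = pal, seed = 61))
  pdfs <- train_two_class(list(list(image = tr$image, mask = tr$mask)), seed = 62)
  te <- generate_scene(scene_spec(palette = pal, seed = 63))
  masks <- naive_bayes_classifier(te$image, pdfs)
  acc <- mean((unclass(masks$plant) == 255L) == (unclass(te$mask) == 255L))
  expect_gte(acc, 0.99)
})

test_that("four-class recovery reaches 95% on the leaf-disease palette", {
  tab <- generate_training_table(palette_rust(), 300, seed = 71)
  pdfs <- train_multiclass(tab)
  sc <- generate_scene(scene_spec(palette = palette_rust(), seed = 72))
  masks <- naive_bayes_classifier(sc$image, pdfs)
  agree <- 0
  for (cl in names(masks)) {
    agree <- agree + sum(unclass(masks[[cl]]) == 255L &
                           unclass(sc$class_masks[[cl]]) == 255L)
  }
  expect_gte(agree / prod(dim(unclass(sc$mask))), 0.95)
})
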