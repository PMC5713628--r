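square_contour <- function(side = 20, canvas = 40, at = 10) {
  mask <- square_mask(canvas, canvas, at, at, side)
  list(mask = mask, contour = find_objects(blank_img(canvas), mask)[[1]])
}

test_that("angle profile matches the law-of-cosines oracle on a square", {
  sq <- square_contour()
  ap <- angle_profile(sq$contour, 5)
  pts <- sq$contour$points
  n <- nrow(pts)
  ora <- vapply(seq_len(n), function(i) {
    a <- pts[((i - 1 - 5) %% n) + 1, ] - pts[i, ]
    b <- pts[((i - 1 + 5) %% n) + 1, ] - pts[i, ]
    acos(max(-1, min(1, sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
  }, numeric(1))
  expect_equal(ap, ora)
  expect_equal(min(ap), 90)   # corners
  expect_equal(max(ap), 180)  # straight edges
})

test_that("angle profile is invariant to ring rotation and reversal", {
  st <- star_mask()
  ct <- find_objects(NULL, st$mask)[[1]]
  ap <- angle_profile(ct, 8)
  rot <- ct; k <- 37
  rot$points <- rbind(ct$points[(k + 1):nrow(ct$points), ], ct$points[1:k, ])
  expect_equal(angle_profile(rot, 8), c(ap[(k + 1):length(ap)], ap[1:k]))
  rev_ct <- ct; rev_ct$points <- ct$points[nrow(ct$points):1, ]
  expect_equal(angle_profile(rev_ct, 8), rev(ap))
})

test_that("acute finds exactly the square's four corners at ~90 degrees", {
  sq <- square_contour()
  lm <- acute(blank_img(40), sq$mask, sq$contour, window = 5, angle_threshold = 120)
  expect_identical(nrow(lm), 4L)
  expect_setequal(lm$x, c(9, 28))
  expect_setequal(lm$y, c(9, 28))
  ap <- angle_profile(sq$contour, 5)
  corner_idx <- vapply(seq_len(nrow(lm)), function(i)
    which(sq$contour$points[, 1] == lm$x[i] & sq$contour$points[, 2] == lm$y[i])[1],
    numeric(1))
  expect_true(all(abs(ap[corner_idx] - 90) <= 2))
})

test_that("a smooth contour yields no acute landmarks", {
  dk <- disk_mask(90, 90, 44, 44, 35)
  ct <- find_objects(NULL, dk)[[1]]
  lm <- acute(NULL, dk, ct, window = 4, angle_threshold = 120)
  expect_identical(nrow(lm), 0L)
})

test_that("star tips and notches separate by pt_val", {
  st <- star_mask()
  ct <- find_objects(NULL, st$mask)[[1]]
  lm <- acute(NULL, st$mask, ct, window = 15, angle_threshold = 120)
  expect_identical(nrow(lm), 10L)
  expect_identical(sum(lm$pt_val > 200), 5L)  # convex tips
  expect_identical(sum(lm$pt_val < 50), 5L)   # concave notches
  # landmarks sit near the analytic star vertices
  verts <- rbind(st$tips, st$notches)
  for (i in seq_len(nrow(lm))) {
    d <- sqrt((verts[, 1] - lm$x[i])^2 + (verts[, 2] - lm$y[i])^2)
    expect_lt(min(d), 4)
  }
})

test_that("acute_vertex at stride 1 reproduces acute exactly", {
  sq <- square_contour()
  a <- acute(blank_img(40), sq$mask, sq$contour, 5, 120)
  v <- acute_vertex(blank_img(40), sq$contour, 5, 120, 1, mask = sq$mask)
  expect_identical(v$x, a$x)
  expect_identical(v$y, a$y)
  expect_identical(v$pt_val, a$pt_val)
})

test_that("strided acute_vertex keeps the runs within a stride of acute", {
  st <- star_mask()
  ct <- find_objects(NULL, st$mask)[[1]]
  a <- acute(NULL, st$mask, ct, 15, 120)
  v <- acute_vertex(NULL, ct, 15, 120, 5, mask = st$mask)
  expect_identical(nrow(v), nrow(a))
  for (i in seq_len(nrow(v))) {
    d <- sqrt((a$x - v$x[i])^2 + (a$y - v$y[i])^2)
    expect_lte(min(d), 5)
  }
  expect_error(acute_vertex(NULL, ct, 15, 120, nrow(ct$points) + 1), "search_stride")
})

test_that("axis pseudolandmarks produce 60 points in three 20-point roles", {
  sc <- small_scene(31)
  for (fun in c(x_axis_pseudolandmarks, y_axis_pseudolandmarks)) {
    lm <- fun(sc$image, sc$mask)
    expect_identical(nrow(lm), 60L)
    expect_true(all(table(lm$role) == 20))
  }
  expect_setequal(unique(x_axis_pseudolandmarks(sc$image, sc$mask)$role),
                  c("x_top", "x_bottom", "x_center"))
  expect_setequal(unique(y_axis_pseudolandmarks(sc$image, sc$mask)$role),
                  c("y_left", "y_right", "y_center"))
})

test_that("rectangle pseudolandmarks sit on its edges and midline", {
  mask <- square_mask(60, 80, 11, 21, 40)  # rows 11:50, cols 21:60
  lm <- x_axis_pseudolandmarks(blank_img(60, 80), mask)
  expect_true(all(lm$y[lm$role == "x_top"] == 10))
  expect_true(all(lm$y[lm$role == "x_bottom"] == 49))
  expect_true(all(lm$y[lm$role == "x_center"] == 29.5))
})

test_that("right-triangle pseudolandmarks match a per-bin slab oracle", {
  h <- 60; w <- 60
  gx <- rep(0:(w - 1), each = h); gy <- rep(0:(h - 1), times = w)
  tri <- binary_mask(matrix(gx >= 10 & gy >= 10 & (gy - 10) >= (gx - 10), h, w))
  lm <- x_axis_pseudolandmarks(blank_img(h, w), tri)
  fg <- which(unclass(tri) == 255L)
  x <- (fg - 1) %/% h; y <- (fg - 1) %% h
  lo <- min(x); hi <- max(x)
  edges <- lo + (hi - lo + 1) * (0:20) / 20
  bin <- pmin(20, findInterval(x, edges, rightmost.closed = TRUE))
  for (b in 1:20) {
    expect_identical(lm$y[lm$role == "x_top"][b], min(y[bin == b]))
    expect_identical(lm$y[lm$role == "x_bottom"][b], max(y[bin == b]))
    expect_equal(lm$x[lm$role == "x_center"][b], mean(x[bin == b]))
    expect_equal(lm$y[lm$role == "x_center"][b], mean(y[bin == b]))
  }
})

test_that("narrow objects are rejected for axis scans", {
  m <- matrix(0L, 40, 40)
  m[5:30, 8:12] <- 255L  # 5 columns wide
  expect_error(x_axis_pseudolandmarks(blank_img(40), binary_mask(m)), "fewer than 20")
})

test_that("scale_features maps the bounding box to the unit square", {
  sc <- small_scene(32)
  lm <- x_axis_pseudolandmarks(sc$image, sc$mask)
  sf <- scale_features(lm, sc$mask)
  expect_gte(min(sf$points$x), 0); expect_lte(max(sf$points$x), 1)
  expect_gte(min(sf$points$y), 0); expect_lte(max(sf$points$y), 1)
  expect_equal(range(sf$points$x), c(0, 1), tolerance = 0.08)
  # distance ratios along an axis are preserved
  p <- new_set <- lm[lm$role == "x_center", ]
  r_before <- (p$x[10] - p$x[1]) / (p$x[20] - p$x[1])
  q <- sf$points[sf$points$role == "x_center", ]
  r_after <- (q$x[10] - q$x[1]) / (q$x[20] - q$x[1])
  expect_equal(r_before, r_after)
  expect_error(scale_features(lm, square_mask(30, 30, 5, 5, 1)), "degenerate")
})

test_that("reference distances follow plane geometry", {
  lm <- phenokit:::new_landmark_set(role = c("acute", "acute"),
                                    x = c(0.5, 0.8), y = c(0.5, 0.9))
  ft <- landmark_reference_pt_dist(lm, centroid = c(0.5, 0.5), baseline = c(0.5, 1))
  expect_equal(ft$dx_centroid, c(0, 0.3))
  expect_equal(ft$dy_centroid, c(0, 0.4))
  expect_equal(ft$dist_centroid, c(0, 0.5))  # 3-4-5 triangle
  expect_equal(ft$dist_baseline[1], 0.5)
  empty <- phenokit:::new_landmark_set()
  expect_identical(nrow(landmark_reference_pt_dist(empty, c(0, 0), c(0, 0))), 0L)
})

test_that("scaled features are invariant to mask scaling and translation", {
  base <- square_mask(60, 60, 6, 10, 40)
  big <- square_mask(120, 120, 12, 20, 80)  # same shape, doubled
  f <- function(mask, canvas) {
    lm <- x_axis_pseudolandmarks(blank_img(canvas), mask)
    sf <- scale_features(lm, mask)
    landmark_reference_pt_dist(sf$points, sf$centroid, sf$baseline)
  }
  fa <- f(base, 60); fb <- f(big, 120)
  num <- vapply(fa, is.numeric, logical(1))
  for (cn in names(fa)[num]) {
    if (grepl("angle", cn)) {
      # angles are ill-conditioned for landmarks near the reference point
      ref <- sub("angle_", "dist_", cn)
      far <- fa[[ref]] >= 0.2
      expect_lte(max(abs(fa[[cn]][far] - fb[[cn]][far])), 2)
    } else {
      expect_lte(max(abs(fa[[cn]] - fb[[cn]])), 0.02)  # unit-frame 2%
    }
  }
})
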