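# Fixtures and independent oracles, all built in code at test time.

blank_img <- function(h, w = h) raster_image(matrix(0, h, w))

disk_mask <- function(h, w, cx, cy, r) {
  gx <- rep(0:(w - 1), each = h)
  gy <- rep(0:(h - 1), times = w)
  binary_mask(matrix((gx - cx)^2 + (gy - cy)^2 <= r^2, h, w))
}

square_mask <- function(h, w, row0, col0, side) {
  m <- matrix(0L, h, w)
  m[row0:(row0 + side - 1), col0:(col0 + side - 1)] <- 255L
  binary_mask(m)
}

# 5-point star, vertices on alternating radii; returns the mask and the
# analytic vertex coordinates (tips then notches).
star_mask <- function(outer = 40, inner = 13, canvas = 90) {
  ang <- seq(-90, 234, by = 36) * pi / 180
  r <- ifelse(seq_along(ang) %% 2 == 1, outer, inner)
  px <- round(canvas / 2 + r * cos(ang))
  py <- round(canvas / 2 + r * sin(ang))
  gx <- rep(0:(canvas - 1), each = canvas)
  gy <- rep(0:(canvas - 1), times = canvas)
  inside <- phenokit:::points_in_polygon(gx, gy, cbind(px, py))
  list(mask = binary_mask(matrix(inside, canvas, canvas)),
       tips = cbind(px, py)[seq(1, 9, 2), ],
       notches = cbind(px, py)[seq(2, 10, 2), ])
}

# Independent connected-component counter: iterative minimum-label
# propagation until fixpoint (a different algorithm from the package's
# breadth-first labeling).
cc_count_oracle <- function(mask, connectivity = 8) {
  fg <- unclass(mask) == 255L
  h <- nrow(fg); w <- ncol(fg)
  lab <- matrix(0L, h, w)
  lab[fg] <- seq_len(sum(fg))
  pad <- function(m) rbind(0L, cbind(0L, m, 0L), 0L)
  repeat {
    p <- pad(lab)
    cand <- list(p[1:h, 2:(w + 1)], p[3:(h + 2), 2:(w + 1)],
                 p[2:(h + 1), 1:w], p[2:(h + 1), 3:(w + 2)])
    if (connectivity == 8) {
      cand <- c(cand, list(p[1:h, 1:w], p[1:h, 3:(w + 2)],
                           p[3:(h + 2), 1:w], p[3:(h + 2), 3:(w + 2)]))
    }
    m <- lab
    for (cc in cand) {
      cc[cc == 0L | !fg] <- .Machine$integer.max
      m <- pmin(m, matrix(cc, h, w))
    }
    m[!fg] <- 0L
    if (identical(m, lab)) break
    lab <- m
  }
  length(unique(lab[fg]))
}

# Exhaustive Otsu oracle: direct per-split class statistics from the raw
# level vector, same flat-valley midpoint rule as the package documents.
otsu_oracle <- function(h) {
  n <- sum(h)
  lev <- 0:255
  wcv <- rep(Inf, 256)
  for (t in 0:254) {
    lo <- h[1:(t + 1)]; hi <- h[(t + 2):256]
    nlo <- sum(lo); nhi <- sum(hi)
    if (nlo == 0 || nhi == 0) next
    llo <- lev[1:(t + 1)]; lhi <- lev[(t + 2):256]
    mlo <- sum(lo * llo) / nlo; mhi <- sum(hi * lhi) / nhi
    vlo <- sum(lo * (llo - mlo)^2) / nlo
    vhi <- sum(hi * (lhi - mhi)^2) / nhi
    wcv[t + 1] <- (nlo / n) * vlo + (nhi / n) * vhi
  }
  ties <- which(wcv <= min(wcv) + 1e-12)
  floor((min(ties) + max(ties)) / 2) - 1
}

# Exhaustive triangle oracle: explicit per-level distances via the exact
# (unnormalized) cross product, so ties resolve deterministically.
triangle_oracle <- function(h, object_type = "light", xstep = 1) {
  occ <- which(h > 0)
  peak <- which.max(h)
  end <- if (object_type == "light") max(occ) else min(occ)
  if (end == peak) end <- if (object_type == "light") min(occ) else max(occ)
  cand <- seq(min(peak, end), max(peak, end), by = xstep)
  cand <- cand[cand != peak]
  if (length(cand) == 0) cand <- setdiff(c(min(peak, end), max(peak, end)), peak)
  d <- abs((h[end] - h[peak]) * (cand - peak) - (end - peak) * (h[cand] - h[peak]))
  cand[which.max(d)] - 1
}

random_histogram <- function() {
  h <- integer(256)
  modes <- sample(2:4, 1)
  for (m in seq_len(modes)) {
    mu <- sample(0:255, 1)
    sd <- runif(1, 3, 40)
    x <- pmin(255, pmax(0, round(stats::rnorm(sample(50:500, 1), mu, sd))))
    h <- h + tabulate(x + 1L, 256)
  }
  h
}

# A small synthetic rosette convenient for landmark/threshold tests.
small_scene <- function(seed = 1, leaf_count = 6) {
  generate_scene(scene_spec(canvas = c(120, 120), leaf_count = leaf_count,
                            leaf_length = 38, leaf_width = 12,
                            seed = seed))
}

# A training pair whose mask holds exactly 1,000 foreground pixels.
exact_1000_pair <- function() {
  # a mask with exactly 1,000 foreground pixels over a colored scene
  m <- matrix(0L, 50, 60)
  m[11:30, 11:60] <- 255L  # 20 x 50 = 1000
  sc <- generate_scene(scene_spec(canvas = c(50, 60), leaf_count = 3,
                                  leaf_length = 16, leaf_width = 6,
                                  petiole_length = 3, petiole_width = 2,
                                  separable = FALSE, seed = 2))
  list(image = sc$image, mask = binary_mask(m))
}
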