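# Global and adaptive automatic thresholding.
#
# All methods operate on a single-channel image and produce strictly binary
# masks. The comparison rule is strict: light objects pass where
# gray > threshold, dark objects where gray < threshold, so masks are
# bit-reproducible.

#' Gray-level histogram of a single-channel image
#'
#' @param img a GRAY `raster_image`
#' @return integer vector of 256 counts indexed by gray level 0..255
#' @export
histogram256 <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  if (n_channels(img) != 1L) stop("histogram256 requires a single-channel image")
  tabulate(as.integer(img$pixels) + 1L, nbins = 256L)
}

check_gray <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  if (n_channels(img) != 1L) stop("thresholding requires a single-channel image")
  img
}

apply_global_threshold <- function(img, value, object_type, max_value = 255) {
  g <- img$pixels
  m <- if (object_type == "light") g > value else g < value
  binary_mask(m * as.integer(max_value))
}

new_threshold_result <- function(mask, value, histogram = NULL, method = "") {
  structure(list(mask = mask, threshold_value = value,
                 histogram = histogram, method = method),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result (%s): value %s, %d foreground px>\n",
              x$method, format(x$threshold_value), sum(x$mask == 255L)))
  invisible(x)
}

#' Fixed-value binary threshold
#'
#' The baseline the automatic methods replace: light objects pass where
#' gray > value, dark objects where gray < value.
#'
#' @param img a GRAY `raster_image`
#' @param value gray level in \[0, 255\]
#' @param object_type `"light"` (object brighter than background) or
#'   `"dark"`
#' @return a `binary_mask`
#' @export
binary_threshold <- function(img, value, object_type = c("light", "dark")) {
  check_gray(img)
  object_type <- match.arg(object_type)
  stopifnot(value >= 0, value <= 255)
  apply_global_threshold(img, value, object_type)
}

#' Triangle (Zack) automatic threshold
#'
#' Draws a line on the gray-level histogram from the peak bin to the last
#' occupied bin on the object-side tail and selects the level that
#' maximizes the perpendicular distance from the histogram to that line.
#' `xstep > 1` evaluates candidate levels at that stride along the x-axis,
#' shifting where the distance is computed.
#'
#' @param img a GRAY `raster_image`
#' @param max_value output foreground value (255)
#' @param object_type `"light"` or `"dark"`; selects the histogram tail the
#'   object occupies
#' @param xstep candidate-level stride (>= 1)
#' @return a `threshold_result` carrying the mask, the threshold value and
#'   the histogram
#' @export
triangle_auto_threshold <- function(img, max_value = 255,
                                    object_type = c("light", "dark"), xstep = 1) {
  check_gray(img)
  object_type <- match.arg(object_type)
  if (xstep < 1) stop("xstep must be >= 1")
  h <- histogram256(img)
  thr <- triangle_threshold_value(h, object_type, xstep)
  res <- new_threshold_result(
    apply_global_threshold(img, thr, object_type, max_value),
    thr, h, "triangle")
  debug_emit(res$mask, "triangle_auto_threshold")
  res
}

# Threshold from a 256-bin histogram by the triangle geometry. Exported for
# the histogram-level API; the image-level wrapper applies the polarity.
triangle_threshold_value <- function(h, object_type = "light", xstep = 1) {
  occ <- which(h > 0)
  if (length(occ) < 2) stop("constant image: triangle threshold undefined")
  peak <- which.max(h)  # lowest level on ties
  # tail end: last occupied bin on the object side of the peak
  if (object_type == "light") {
    end <- max(occ)
    if (end == peak) end <- min(occ)  # object tail empty; use the other tail
  } else {
    end <- min(occ)
    if (end == peak) end <- max(occ)
  }
  lo <- min(peak, end); hi <- max(peak, end)
  cand <- seq(lo, hi, by = as.integer(xstep))
  cand <- setdiff(cand, c(peak))
  if (length(cand) == 0) cand <- setdiff(c(lo, hi), peak)
  # perpendicular distance from (x, h[x]) to the peak->end line, up to the
  # constant line length: the unnormalized cross product is exact in
  # integer arithmetic, so ties resolve deterministically
  x1 <- peak; y1 <- h[peak]; x2 <- end; y2 <- h[end]
  dist <- abs((y2 - y1) * (cand - x1) - (x2 - x1) * (h[cand] - y1))
  best <- cand[which.max(dist)]  # lowest level on ties
  best - 1L  # histogram index 1..256 -> gray level 0..255
}

#' Otsu automatic threshold
#'
#' Selects the gray level that minimizes the weighted within-class variance
#' of the two classes it induces (equivalently, maximizes between-class
#' variance). When a run of levels ties (a flat valley between two modes),
#' the midpoint of the run is chosen, placing the threshold between the
#' peaks.
#'
#' @inheritParams triangle_auto_threshold
#' @return a `threshold_result`
#' @export
otsu_auto_threshold <- function(img, max_value = 255, object_type = c("light", "dark")) {
  check_gray(img)
  object_type <- match.arg(object_type)
  h <- histogram256(img)
  thr <- otsu_threshold_value(h)
  res <- new_threshold_result(
    apply_global_threshold(img, thr, object_type, max_value),
    thr, h, "otsu")
  debug_emit(res$mask, "otsu_auto_threshold")
  res
}

# Minimum weighted within-class variance over all split points t, where the
# low class is {0..t} and the high class is {t+1..255}.
otsu_threshold_value <- function(h) {
  if (sum(h > 0) < 2) stop("constant image: Otsu threshold undefined")
  n <- sum(h)
  lev <- 0:255
  w0 <- cumsum(h)                 # mass of low class up to t
  m0 <- cumsum(h * lev)           # first moment
  s0 <- cumsum(h * lev^2)         # second moment
  wt <- w0[256]; mt <- m0[256]; st <- s0[256]
  w1 <- wt - w0; m1 <- mt - m0; s1 <- st - s0
  mu0 <- ifelse(w0 > 0, m0 / w0, 0)
  mu1 <- ifelse(w1 > 0, m1 / w1, 0)
  var0 <- ifelse(w0 > 0, s0 / w0 - mu0^2, 0)
  var1 <- ifelse(w1 > 0, s1 / w1 - mu1^2, 0)
  wcv <- (w0 / n) * var0 + (w1 / n) * var1
  wcv[w0 == 0 | w1 == 0] <- Inf   # degenerate splits excluded
  # all minimizers tie on flat valleys (e.g. two delta peaks); the midpoint
  # of the tied run puts the threshold between the peaks
  ties <- which(wcv <= min(wcv) + 1e-12)
  as.integer(floor((min(ties) + max(ties)) / 2)) - 1L
}

#' Mean or Gaussian adaptive threshold
#'
#' Each pixel is compared against a local reference computed over its
#' `block_size` x `block_size` neighborhood: the plain mean or a
#' Gaussian-weighted mean. Light objects pass where
#' `gray > reference + offset`; dark objects where
#' `gray < reference - offset`, so a positive offset suppresses flat-field
#' noise in either polarity.
#'
#' @param img a GRAY `raster_image`
#' @param method `"mean"` or `"gaussian"`
#' @param block_size odd neighborhood size >= 3 (scale-dependent; no
#'   default)
#' @param offset bias subtracted from the evidence (default 0)
#' @param object_type `"light"` or `"dark"`
#' @return a `binary_mask`
#' @export
adaptive_threshold <- function(img, method = c("mean", "gaussian"), block_size,
                               offset = 0, object_type = c("light", "dark")) {
  check_gray(img)
  method <- match.arg(method)
  object_type <- match.arg(object_type)
  if (!is_odd(block_size) || block_size < 3) stop("block_size must be an odd integer >= 3")
  kern <- if (method == "mean") {
    matrix(1 / block_size^2, block_size, block_size)
  } else {
    gaussian_kernel_2d(c(block_size, block_size), 0, 0)
  }
  ref <- conv2_replicate(img$pixels, kern)
  g <- img$pixels
  m <- if (object_type == "light") g > ref + offset else g < ref - offset
  res <- binary_mask(m * 255L)
  debug_emit(res, "adaptive_threshold")
  res
}
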