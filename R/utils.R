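# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporarily seeded RNG
#'
#' Saves and restores `.Random.seed` so package internals never perturb the
#' caller's random stream. All stochastic operations in phenokit route their
#' seed through this helper.
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

is_odd <- function(x) x %% 2 == 1

# Replicate-pad a matrix by (ry, rx) on each side.
pad_replicate <- function(m, ry, rx) {
  h <- nrow(m); w <- ncol(m)
  ri <- c(rep(1L, ry), seq_len(h), rep(h, ry))
  ci <- c(rep(1L, rx), seq_len(w), rep(w, rx))
  m[ri, ci, drop = FALSE]
}

# Dense 2-D correlation with replicate borders via shift-and-accumulate.
# kernel dims must be odd. Exactly equals the direct sliding-window sum.
conv2_replicate <- function(m, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  stopifnot(is_odd(kh), is_odd(kw))
  ry <- (kh - 1L) %/% 2L; rx <- (kw - 1L) %/% 2L
  p <- pad_replicate(m, ry, rx)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      kv <- kernel[i, j]
      if (kv == 0) next
      out <- out + kv * p[i:(i + h - 1L), j:(j + w - 1L), drop = FALSE]
    }
  }
  out
}

# Sliding-window maximum over a Euclidean disk of radius r (replicate
# borders). The disk footprint makes peak suppression isotropic, matching
# the Euclidean separation rule used when thinning peaks.
window_max <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  r <- as.integer(r)
  p <- pad_replicate(m, r, r)
  out <- m
  for (dy in -r:r) {
    dxmax <- as.integer(floor(sqrt(r^2 - dy^2)))
    rows <- (r + 1L + dy):(r + dy + h)
    for (dx in -dxmax:dxmax) {
      if (dy == 0L && dx == 0L) next
      out <- pmax(out, p[rows, (r + 1L + dx):(r + dx + w), drop = FALSE])
    }
  }
  out
}

# 1-D sampled, normalized Gaussian (OpenCV-style default sigma when <= 0).
gaussian_kernel_1d <- function(ksize, sigma) {
  stopifnot(is_odd(ksize), ksize >= 1)
  if (sigma <= 0) sigma <- 0.3 * ((ksize - 1) * 0.5 - 1) + 0.8
  r <- (ksize - 1) / 2
  x <- seq(-r, r)
  k <- exp(-(x^2) / (2 * sigma^2))
  k / sum(k)
}

gaussian_kernel_2d <- function(ksize, sigma_x, sigma_y) {
  kx <- gaussian_kernel_1d(ksize[2], sigma_x)
  ky <- gaussian_kernel_1d(ksize[1], sigma_y)
  outer(ky, kx)
}

# RGB bytes (n x 3) -> HSV bytes (n x 3), full-byte hue scaling [0, 255].
rgb_to_hsv_bytes <- function(rgb) {
  stopifnot(ncol(rgb) == 3)
  hsv <- grDevices::rgb2hsv(t(rgb), maxColorValue = 255)
  t(round(hsv * 255))
}

# HSV bytes (n x 3) -> RGB bytes (n x 3).
hsv_to_rgb_bytes <- function(hsv) {
  stopifnot(ncol(hsv) == 3)
  cols <- grDevices::hsv(hsv[, 1] / 255, hsv[, 2] / 255, hsv[, 3] / 255)
  t(grDevices::col2rgb(cols))
}

# Fixed qualitative palette (RGB bytes) cycled by label index for overlays.
label_palette <- function(n) {
  base <- c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00",
            "#FFFF33", "#A65628", "#F781BF", "#66C2A5", "#FC8D62",
            "#8DA0CB", "#E78AC3")
  cols <- rep_len(base, n)
  t(grDevices::col2rgb(cols))
}

# Shared debug-image emission. Off unless a debug directory is set via
# options(phenokit.debug = "<dir>"). Every operation calls this with its
# annotated intermediate; emission cost is zero when disabled.
debug_emit <- function(img, name) {
  dir <- getOption("phenokit.debug", NULL)
  if (is.null(dir)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0(name, ".png"))
  write_image(img, path)
  invisible(path)
}
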