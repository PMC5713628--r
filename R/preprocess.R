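# Illumination normalization, smoothing, geometric adjustment, and
# VIS -> NIR mask transfer.

#' Construct a rectangular region of interest
#'
#' @param x,y 0-based pixel coordinates of the top-left corner
#' @param w,h width and height in pixels (both >= 1)
#' @return an `roi` object
#' @export
roi <- function(x, y, w, h) {
  stopifnot(w >= 1, h >= 1, x >= 0, y >= 0)
  structure(list(kind = "rectangle", x = as.integer(x), y = as.integer(y),
                 w = as.integer(w), h = as.integer(h)), class = "roi")
}

check_roi <- function(r, img) {
  d <- img_dim(img)
  if (r$x + r$w > d[2] || r$y + r$h > d[1])
    stop("ROI extends outside the image")
  invisible(r)
}

roi_rows <- function(r) (r$y + 1L):(r$y + r$h)
roi_cols <- function(r) (r$x + 1L):(r$x + r$w)

#' White-balance an image against a reference region
#'
#' Each channel is scaled so the reference maximum in the ROI maps to 255
#' (values are clipped at 255). With no ROI the whole image is the
#' reference. The reference statistic is an upper percentile of the ROI
#' (default 100, the literal maximum); lowering it slightly guards against
#' isolated hot pixels.
#'
#' @param img a 1- or 3-channel `raster_image`
#' @param roi optional `roi` containing the white standard
#' @param percentile reference percentile of the ROI per channel (default
#'   100 = channel maximum)
#' @return the rebalanced `raster_image`
#' @export
white_balance <- function(img, roi = NULL, percentile = 100) {
  stopifnot(inherits(img, "raster_image"))
  if (!is.null(roi)) check_roi(roi, img)
  scale_channel <- function(ch) {
    ref <- if (is.null(roi)) ch else ch[roi_rows(roi), roi_cols(roi)]
    m <- as.numeric(stats::quantile(ref, percentile / 100, names = FALSE))
    if (m <= 0) stop("white balance reference maximum is 0; channel cannot be scaled")
    round(clamp255(ch * (255 / m)))
  }
  p <- img$pixels
  if (is.matrix(p)) {
    out <- scale_channel(p)
  } else {
    out <- p
    for (c in 1:3) out[, , c] <- scale_channel(p[, , c])
  }
  res <- raster_image(out, img$colorspace)
  debug_emit(res, "white_balance")
  res
}

apply_channels <- function(img, f) {
  p <- img$pixels
  if (is.matrix(p)) {
    out <- f(p)
  } else {
    out <- p
    for (c in 1:3) out[, , c] <- f(p[, , c])
  }
  raster_image(out, img$colorspace)
}

#' Median blur
#'
#' Replaces each pixel with the median of its `ksize` x `ksize`
#' neighborhood (borders replicate-extended). Applied per channel.
#'
#' @param img a `raster_image`
#' @param ksize odd window size >= 1
#' @return the smoothed `raster_image`
#' @export
median_blur <- function(img, ksize) {
  stopifnot(inherits(img, "raster_image"))
  if (!is_odd(ksize) || ksize < 1) stop("ksize must be an odd integer >= 1")
  if (ksize == 1) return(img)
  r <- (ksize - 1L) %/% 2L
  med <- function(ch) {
    h <- nrow(ch); w <- ncol(ch)
    p <- pad_replicate(ch, r, r)
    stack <- matrix(0, h * w, ksize^2)
    k <- 0L
    for (i in seq_len(ksize)) for (j in seq_len(ksize)) {
      k <- k + 1L
      stack[, k] <- as.vector(p[i:(i + h - 1L), j:(j + w - 1L)])
    }
    matrix(apply(stack, 1L, stats::median), h, w)
  }
  res <- apply_channels(img, med)
  debug_emit(res, "median_blur")
  res
}

#' Gaussian blur
#'
#' Convolution with a normalized sampled Gaussian kernel (borders
#' replicate-extended), per channel. Sigma values of 0 select the
#' conventional kernel-size-derived default.
#'
#' @param img a `raster_image`
#' @param ksize odd kernel size, scalar or `c(ky, kx)`
#' @param sigma_x,sigma_y Gaussian standard deviations in pixels
#' @return the smoothed `raster_image`
#' @export
gaussian_blur <- function(img, ksize, sigma_x = 0, sigma_y = sigma_x) {
  stopifnot(inherits(img, "raster_image"))
  if (length(ksize) == 1) ksize <- c(ksize, ksize)
  if (!all(is_odd(ksize)) || any(ksize < 1)) stop("kernel dimensions must be odd integers >= 1")
  kern <- gaussian_kernel_2d(ksize, sigma_x, sigma_y)
  res <- apply_channels(img, function(ch) round(conv2_replicate(ch, kern)))
  debug_emit(res, "gaussian_blur")
  res
}

# Inverse-mapped affine resampling about the image center.
# interp: "bilinear" or "nearest". Out-of-frame source pixels give fill.
affine_sample <- function(ch, inv_map, interp, fill = 0) {
  h <- nrow(ch); w <- ncol(ch)
  gx <- rep(0:(w - 1L), each = h)
  gy <- rep(0:(h - 1L), times = w)
  src <- inv_map(gx, gy)
  sx <- src[[1]]; sy <- src[[2]]
  if (interp == "nearest") {
    rx <- round(sx); ry <- round(sy)
    ok <- rx >= 0 & rx < w & ry >= 0 & ry < h
    out <- rep(fill, h * w)
    out[ok] <- ch[cbind(ry[ok] + 1L, rx[ok] + 1L)]
  } else {
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    out <- rep(as.numeric(fill), h * w)
    ok <- x0 >= -1 & x0 < w & y0 >= -1 & y0 < h
    getpx <- function(xx, yy) {
      v <- rep(as.numeric(fill), length(xx))
      in_r <- xx >= 0 & xx < w & yy >= 0 & yy < h
      v[in_r] <- ch[cbind(yy[in_r] + 1L, xx[in_r] + 1L)]
      v
    }
    v00 <- getpx(x0, y0); v10 <- getpx(x0 + 1, y0)
    v01 <- getpx(x0, y0 + 1); v11 <- getpx(x0 + 1, y0 + 1)
    val <- (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
      (1 - fx) * fy * v01 + fx * fy * v11
    out[ok] <- val[ok]
  }
  matrix(out, h, w)
}

#' Rotate an image about its center
#'
#' The canvas size is preserved; regions rotated out of frame are lost and
#' vacated regions are filled with 0. Intensity images are resampled
#' bilinearly; binary masks use nearest-neighbor so they stay binary.
#'
#' @param img a `raster_image` or `binary_mask`
#' @param angle rotation in degrees (positive = counterclockwise in
#'   standard orientation, i.e. clockwise on screen with y down)
#' @return rotated image of the same class and size
#' @export
rotate_img <- function(img, angle) {
  is_mask <- inherits(img, "binary_mask")
  if (is_mask) img <- raster_image(unclass(img), "GRAY")
  stopifnot(inherits(img, "raster_image"))
  d <- img_dim(img)
  cx <- (d[2] - 1) / 2; cy <- (d[1] - 1) / 2
  th <- angle * pi / 180
  co <- cos(th); si <- sin(th)
  inv_map <- function(gx, gy) {
    xr <- gx - cx; yr <- gy - cy
    list(co * xr - si * yr + cx, si * xr + co * yr + cy)
  }
  interp <- if (is_mask) "nearest" else "bilinear"
  out <- apply_channels(img, function(ch) round(affine_sample(ch, inv_map, interp)))
  debug_emit(out, "rotate_img")
  if (is_mask) binary_mask(out$pixels) else out
}

#' Shift (translate) an image
#'
#' Content moves by `(dx, dy)`; the vacated region is filled with 0 and the
#' canvas size is preserved.
#'
#' @param img a `raster_image` or `binary_mask`
#' @param dx,dy integer shift in pixels (positive = right/down); both must
#'   be smaller than the image size in magnitude
#' @return shifted image of the same class and size
#' @export
shift_img <- function(img, dx, dy) {
  is_mask <- inherits(img, "binary_mask")
  if (is_mask) img <- raster_image(unclass(img), "GRAY")
  stopifnot(inherits(img, "raster_image"))
  d <- img_dim(img)
  dx <- as.integer(round(dx)); dy <- as.integer(round(dy))
  if (abs(dx) >= d[2] || abs(dy) >= d[1]) stop("shift magnitude must be smaller than the image size")
  shift_ch <- function(ch) {
    out <- matrix(0, d[1], d[2])
    src_rows <- seq_len(d[1]) - dy
    src_cols <- seq_len(d[2]) - dx
    ok_r <- src_rows >= 1 & src_rows <= d[1]
    ok_c <- src_cols >= 1 & src_cols <= d[2]
    out[ok_r, ok_c] <- ch[src_rows[ok_r], src_cols[ok_c]]
    out
  }
  out <- apply_channels(img, shift_ch)
  debug_emit(out, "shift_img")
  if (is_mask) binary_mask(out$pixels) else out
}

#' Resize a binary mask
#'
#' Nearest-neighbor scaling by independent x and y factors; the output is
#' still strictly binary. Used to match a VIS-derived plant mask to the NIR
#' camera's resolution.
#'
#' @param mask a `binary_mask`
#' @param fx,fy positive scale factors
#' @return the resized `binary_mask`
#' @export
resize <- function(mask, fx, fy = fx) {
  stopifnot(inherits(mask, "binary_mask"))
  if (fx <= 0 || fy <= 0) stop("scale factors must be positive")
  h <- nrow(mask); w <- ncol(mask)
  nh <- max(1L, as.integer(round(h * fy)))
  nw <- max(1L, as.integer(round(w * fx)))
  src_r <- pmin(h, pmax(1L, floor((seq_len(nh) - 0.5) * h / nh) + 1L))
  src_c <- pmin(w, pmax(1L, floor((seq_len(nw) - 0.5) * w / nw) + 1L))
  binary_mask(unclass(mask)[src_r, src_c, drop = FALSE])
}

#' Position a VIS mask over an NIR frame
#'
#' Anchors the mask to the stated corner of the target frame, offsets it by
#' `(x_offset, y_offset)`, and crops/pads so the output has exactly the NIR
#' image's dimensions.
#'
#' @param nir_img the target `raster_image` (defines the output size)
#' @param mask the (already resized) `binary_mask`
#' @param x_offset,y_offset nonnegative offsets from the anchored corner
#' @param v_pos `"top"` or `"bottom"` vertical anchor
#' @param h_pos `"left"` or `"right"` horizontal anchor
#' @return a `binary_mask` with the NIR image's dimensions
#' @export
crop_position_mask <- function(nir_img, mask, x_offset = 0, y_offset = 0,
                               v_pos = c("top", "bottom"), h_pos = c("left", "right")) {
  stopifnot(inherits(nir_img, "raster_image"), inherits(mask, "binary_mask"))
  v_pos <- match.arg(v_pos); h_pos <- match.arg(h_pos)
  if (x_offset < 0 || y_offset < 0) stop("offsets must be nonnegative")
  d <- img_dim(nir_img)
  mh <- nrow(mask); mw <- ncol(mask)
  top <- if (v_pos == "top") y_offset else d[1] - mh - y_offset
  left <- if (h_pos == "left") x_offset else d[2] - mw - x_offset
  out <- matrix(0L, d[1], d[2])
  rows <- (top + 1L):(top + mh)
  cols <- (left + 1L):(left + mw)
  keep_r <- rows >= 1L & rows <= d[1]
  keep_c <- cols >= 1L & cols <= d[2]
  if (!any(keep_r) || !any(keep_c)) stop("mask placed entirely outside the target frame")
  out[rows[keep_r], cols[keep_c]] <- unclass(mask)[keep_r, keep_c]
  res <- binary_mask(out)
  debug_emit(res, "crop_position_mask")
  res
}

#' Locate the NIR sibling of a VIS image
#'
#' Derives the matching NIR filename by substring substitution in the same
#' directory. Requires a consistent naming scheme.
#'
#' @param vis_path path of the VIS image
#' @param naming_rule length-2 character vector `c(from, to)`, e.g.
#'   `c("VIS", "NIR")`
#' @return the existing NIR sibling path
#' @export
get_nir <- function(vis_path, naming_rule = c("VIS", "NIR")) {
  stopifnot(length(naming_rule) == 2)
  base <- basename(vis_path)
  if (!grepl(naming_rule[1], base, fixed = TRUE))
    stop("naming rule '", naming_rule[1], "' does not match filename: ", base)
  sib <- file.path(dirname(vis_path), sub(naming_rule[1], naming_rule[2], base, fixed = TRUE))
  if (!file.exists(sib)) stop("matching NIR image not found: ", sib)
  sib
}
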