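# Size-marker detection and area reporting for cross-image scale
# normalization.

#' Extract a named channel as a grayscale image
#'
#' RGB channels are taken directly; `h`, `s`, `v` come from an HSV
#' conversion with full-byte scaling; `gray` is the Rec. 601 luma.
#'
#' @param img a `raster_image`
#' @param channel one of `"gray"`, `"r"`, `"g"`, `"b"`, `"h"`, `"s"`, `"v"`
#' @return a single-channel GRAY `raster_image`
#' @export
extract_channel <- function(img, channel = c("gray", "r", "g", "b", "h", "s", "v")) {
  channel <- match.arg(channel)
  if (n_channels(img) == 1L) {
    if (!channel %in% c("gray", "v")) stop("channel '", channel, "' requires a color image")
    return(img)
  }
  p <- img$pixels
  ch <- switch(channel,
    gray = return(as_gray(img)),
    r = p[, , 1], g = p[, , 2], b = p[, , 3],
    h = , s = , v = {
      d <- dim(p)
      hsv <- rgb_to_hsv_bytes(cbind(as.vector(p[, , 1]), as.vector(p[, , 2]),
                                    as.vector(p[, , 3])))
      k <- match(channel, c("h", "s", "v"))
      matrix(hsv[, k], d[1], d[2])
    })
  raster_image(ch, "GRAY")
}

#' Report the pixel area of a size marker
#'
#' In `"define"` mode the ROI itself is the marker and its pixel count is
#' reported. In `"detect"` mode the chosen channel is thresholded inside
#' the ROI and the largest detected object is reported, which tolerates
#' marker movement within the ROI. The reported area normalizes
#' measurements across images taken at different zoom or distance; dividing
#' plant area by marker area is left to the caller's analysis.
#'
#' @param img a `raster_image`
#' @param roi an `roi` containing (or defining) the marker
#' @param mode `"detect"` or `"define"`
#' @param channel channel used for detection: one of `"h"`, `"s"`, `"v"`,
#'   `"r"`, `"g"`, `"b"`, `"gray"`
#' @param threshold_method `"binary"`, `"otsu"`, or `"triangle"`
#' @param threshold_value gray level for `threshold_method = "binary"`
#' @param object_type `"light"` or `"dark"` marker polarity
#' @return a `marker_report` list with `area`, `centroid` (image
#'   coordinates), and `mode`
#' @export
report_size_marker_area <- function(img, roi, mode = c("detect", "define"),
                                    channel = "gray",
                                    threshold_method = c("binary", "otsu", "triangle"),
                                    threshold_value = NULL,
                                    object_type = c("light", "dark")) {
  stopifnot(inherits(img, "raster_image"), inherits(roi, "roi"))
  mode <- match.arg(mode)
  threshold_method <- match.arg(threshold_method)
  object_type <- match.arg(object_type)
  check_roi(roi, img)
  if (mode == "define") {
    rep <- list(area = roi$w * roi$h,
                centroid = c(x = roi$x + (roi$w - 1) / 2, y = roi$y + (roi$h - 1) / 2),
                mode = mode)
    return(structure(rep, class = "marker_report"))
  }
  ch <- extract_channel(img, channel)
  sub <- raster_image(ch$pixels[roi_rows(roi), roi_cols(roi), drop = FALSE], "GRAY")
  mask <- switch(threshold_method,
    binary = {
      if (is.null(threshold_value)) stop("threshold_value is required for the binary method")
      binary_threshold(sub, threshold_value, object_type)
    },
    otsu = otsu_auto_threshold(sub, object_type = object_type)$mask,
    triangle = triangle_auto_threshold(sub, object_type = object_type)$mask)
  objs <- find_objects(sub, mask)
  if (length(objs) == 0) stop("no marker object detected inside the ROI")
  areas <- vapply(objs, function(o) length(o$pixels), numeric(1))
  best <- objs[[which.max(areas)]]
  hsub <- nrow(mask)
  pix <- best$pixels
  x <- (pix - 1L) %/% hsub + roi$x
  y <- (pix - 1L) %% hsub + roi$y
  structure(list(area = length(pix),
                 centroid = c(x = mean(x), y = mean(y)),
                 mode = mode),
            class = "marker_report")
}

#' @export
print.marker_report <- function(x, ...) {
  cat(sprintf("<marker_report (%s): area %d px, centroid (%.1f, %.1f)>\n",
              x$mode, x$area, x$centroid[1], x$centroid[2]))
  invisible(x)
}
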