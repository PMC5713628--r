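# Distance-transform watershed segmentation: split a plant mask into
# organs (leaves) and count them.

# Marker peaks of a Euclidean distance map. All local maxima (Chebyshev
# window of radius min_distance) are candidates; candidate plateaus
# contribute one marker at the plateau pixel nearest the plateau centroid
# (topmost-leftmost on exact ties). Peaks are then thinned greedily per
# connected component, in order of decreasing height (scan order on ties),
# enforcing pairwise Euclidean separation >= min_distance. Per-component
# selection guarantees every foreground component keeps at least one
# marker.
distance_peaks <- function(dist, fg, min_distance, peak_tolerance = 1e-6) {
  h <- nrow(dist); w <- ncol(dist)
  r <- as.integer(min_distance)
  wmax <- window_max(dist, r)
  cand <- fg & dist > 0 & dist >= wmax - peak_tolerance
  if (!any(cand)) return(matrix(numeric(0), 0, 2))
  plab <- label_components(cand, 8L)
  markers <- matrix(0, 0, 3)  # x, y, height
  for (l in seq_len(max(plab))) {
    pix <- which(plab == l)
    x <- (pix - 1L) %/% h; y <- (pix - 1L) %% h
    cx <- mean(x); cy <- mean(y)
    d2 <- (x - cx)^2 + (y - cy)^2
    best <- which(d2 == min(d2))
    # exact symmetry: topmost then leftmost
    best <- best[order(y[best], x[best])][1]
    markers <- rbind(markers, c(x[best], y[best], dist[y[best] + 1L, x[best] + 1L]))
  }
  comp <- label_components(fg, 8L)
  comp_of <- comp[cbind(markers[, 2] + 1L, markers[, 1] + 1L)]
  kept <- matrix(numeric(0), 0, 2)
  for (cl in sort(unique(comp_of))) {
    mk <- markers[comp_of == cl, , drop = FALSE]
    ord <- order(-mk[, 3], mk[, 2], mk[, 1])
    mk <- mk[ord, , drop = FALSE]
    sel <- matrix(numeric(0), 0, 2)
    for (i in seq_len(nrow(mk))) {
      p <- mk[i, 1:2]
      if (nrow(sel) == 0 ||
          all((sel[, 1] - p[1])^2 + (sel[, 2] - p[2])^2 >= min_distance^2)) {
        sel <- rbind(sel, p)
      }
    }
    kept <- rbind(kept, sel)
  }
  kept
}

#' Watershed segmentation of a plant mask
#'
#' Computes the Euclidean distance map of the mask, places marker peaks at
#' distance-map maxima separated by at least `min_distance`, and floods the
#' mask from those markers so that every foreground pixel receives exactly
#' one segment label. Designed for plants whose organs are locally thick
#' and joined by thin necks (e.g. rosette leaves on thin petioles), where
#' distance-map peaks sit one per organ.
#'
#' @param img the source `raster_image` (used for the overlay)
#' @param mask a nonempty `binary_mask`
#' @param min_distance minimum peak separation in pixels (>= 1); larger
#'   values merge nearby peaks and can only reduce the count
#' @param peak_tolerance plateau tolerance in distance units:
#'   pixels within this margin of their window maximum still count as
#'   peaks; the default keeps detection strict up to floating-point noise,
#'   while larger values admit near-flat plateau shoulders as one peak
#' @return a `watershed_result`: `labels` (H x W integer grid, 0 =
#'   background), `object_count`, `markers` (k x 2 matrix of peak
#'   coordinates), and `overlay` (segments in distinct colors)
#' @export
watershed_segmentation <- function(img, mask, min_distance, peak_tolerance = 1e-6) {
  stopifnot(inherits(mask, "binary_mask"))
  if (min_distance < 1) stop("min_distance must be >= 1")
  fg <- mask_logical(mask)
  if (!any(fg)) stop("empty mask: nothing to segment")
  if (!is.null(img)) stopifnot(all(img_dim(img) == dim(mask)))
  dist <- t(EBImage::distmap(EBImage::Image(t(fg)), metric = "euclidean")@.Data)
  pk <- distance_peaks(dist, fg, min_distance, peak_tolerance)
  h <- nrow(fg); w <- ncol(fg)
  seeds <- matrix(0L, h, w)
  seeds[cbind(pk[, 2] + 1L, pk[, 1] + 1L)] <- seq_len(nrow(pk))
  labels <- t(EBImage::propagate(EBImage::Image(t(dist)),
                                 seeds = EBImage::Image(t(seeds)),
                                 mask = EBImage::Image(t(fg)))@.Data)
  labels <- matrix(as.integer(labels), h, w)
  count <- length(setdiff(unique(as.vector(labels)), 0L))
  overlay <- watershed_overlay(img, labels)
  res <- structure(list(labels = labels, object_count = count,
                        markers = pk, overlay = overlay),
                   class = "watershed_result")
  debug_emit(overlay, "watershed_segmentation")
  res
}

#' @export
print.watershed_result <- function(x, ...) {
  cat(sprintf("<watershed_result: %d segment(s)>\n", x$object_count))
  invisible(x)
}

# Segments painted in distinct colors (fixed qualitative palette cycled by
# label) over the source image.
watershed_overlay <- function(img, labels) {
  h <- nrow(labels); w <- ncol(labels)
  canvas <- if (!is.null(img) && n_channels(img) == 3L) img$pixels
            else if (!is.null(img)) array(rep(img$pixels, 3), dim = c(h, w, 3))
            else array(0, dim = c(h, w, 3))
  k <- max(labels)
  if (k > 0) {
    pal <- label_palette(k)
    for (l in seq_len(k)) {
      sel <- labels == l
      for (ch in 1:3) {
        pc <- canvas[, , ch]; pc[sel] <- pal[l, ch]; canvas[, , ch] <- pc
      }
    }
  }
  raster_image(canvas, "RGB")
}
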