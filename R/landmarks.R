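# Acute-region (Type II) and axis pseudo-landmark (Type III) morphometrics:
# landmark identification, unit-square rescaling, and centroid-referenced
# distance features.
#
# A landmark set is a data.frame with columns (role, x, y, pt_val) so it can
# be written straight to tab-delimited text for external morphometric
# analysis.

new_landmark_set <- function(role = character(), x = numeric(), y = numeric(),
                             pt_val = NA_real_) {
  if (length(role) == 0) pt_val <- numeric(0)
  else if (length(pt_val) == 1) pt_val <- rep(pt_val, length(role))
  structure(data.frame(role = role, x = x, y = y, pt_val = pt_val,
                       stringsAsFactors = FALSE),
            class = c("landmark_set", "data.frame"))
}

#' Angle profile of a closed contour
#'
#' For every contour position `i`, the angle at point `i` between the two
#' chord vectors to points `i - window` and `i + window` (ring indices
#' wrap). Computed by the law of cosines and clamped to \[0, 180\] degrees;
#' coincident chord endpoints yield 180 (flat), so duplicated points never
#' spawn spurious corners.
#'
#' @param contour a `contour`
#' @param window chord half-span in contour positions
#'   (1 <= window < length/2)
#' @return numeric vector of angles in degrees, one per contour point
#' @export
angle_profile <- function(contour, window) {
  stopifnot(inherits(contour, "contour"))
  pts <- contour$points
  n <- nrow(pts)
  if (window < 1 || window >= n / 2) stop("window must satisfy 1 <= window < contour length / 2")
  im <- ((seq_len(n) - 1 - window) %% n) + 1
  ip <- ((seq_len(n) - 1 + window) %% n) + 1
  a <- pts[im, , drop = FALSE] - pts
  b <- pts[ip, , drop = FALSE] - pts
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  cosang <- rowSums(a * b) / (na * nb)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  ang[na == 0 | nb == 0] <- 180
  ang
}

# Consecutive runs of TRUE on a ring, merged across the start/end seam.
# Returns a list of integer index vectors in traversal order.
ring_runs <- function(flag) {
  n <- length(flag)
  if (!any(flag)) return(list())
  if (all(flag)) return(list(seq_len(n)))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- Map(seq, starts[r$values], ends[r$values])
  # wrap: if both the first and last positions are TRUE, join those runs
  if (flag[1] && flag[n] && length(runs) > 1) {
    runs[[1]] <- c(runs[[length(runs)]], runs[[1]])
    runs[[length(runs)]] <- NULL
  }
  runs
}

# Mean mask value inside the convex hull of a point run (tips sit over
# foreground -> high values; axils span background -> low values).
hull_mean_value <- function(pts, mask) {
  if (nrow(pts) < 3) {
    vals <- unclass(mask)[cbind(pts[, 2] + 1L, pts[, 1] + 1L)]
    return(mean(vals))
  }
  hull <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
  xmin <- min(hull[, 1]); xmax <- max(hull[, 1])
  ymin <- min(hull[, 2]); ymax <- max(hull[, 2])
  gx <- rep(xmin:xmax, each = ymax - ymin + 1)
  gy <- rep(ymin:ymax, times = xmax - xmin + 1)
  inside <- points_in_polygon(gx, gy, hull)
  if (!any(inside)) inside <- rep(TRUE, length(gx))
  vals <- unclass(mask)[cbind(gy[inside] + 1L, gx[inside] + 1L)]
  mean(vals)
}

# Even-odd rule point-in-polygon test, vectorized over query points.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

acute_from_indices <- function(contour, mask, idx, window, angle_threshold) {
  pts <- contour$points
  sub <- pts[idx, , drop = FALSE]
  nidx <- length(idx)
  # angles evaluated on the full ring at the sampled positions
  full <- angle_profile(contour, window)
  ang <- full[idx]
  runs <- ring_runs(ang < angle_threshold)
  if (length(runs) == 0) return(new_landmark_set())
  mid <- vapply(runs, function(r) r[floor(length(r) / 2) + 1], numeric(1))
  pt_val <- if (!is.null(mask)) {
    # the acute region spans the run plus one chord arm on each side, so the
    # hull covers the full tip (foreground) or the full notch (background)
    n_full <- nrow(pts)
    vapply(runs, function(r) {
      ext <- unique(((idx[c(r, rep(r[1], window), rep(r[length(r)], window))] - 1 +
                        c(rep(0L, length(r)), -(1:window), 1:window)) %% n_full) + 1)
      hull_mean_value(pts[ext, , drop = FALSE], mask)
    }, numeric(1))
  } else NA_real_
  new_landmark_set(role = "acute",
                   x = sub[mid, 1], y = sub[mid, 2],
                   pt_val = pt_val)
}

#' Acute-region landmarks (Type II)
#'
#' Scores every contour point by the angle between chords to its
#' `window`-distant neighbors, segments consecutive runs of points whose
#' angle falls below `angle_threshold`, and emits the middle point of each
#' run as one landmark. Runs wrap across the ring seam. The `pt_val`
#' column — the mean mask value inside the convex hull of each run —
#' separates convex tips (high) from concave axils (low).
#'
#' @param img the source `raster_image` (unused by the geometry; kept for
#'   pipeline uniformity)
#' @param mask the object's `binary_mask`, sampled for `pt_val`
#' @param contour the object's closed `contour`
#' @param window chord half-span along the contour; larger windows respond
#'   to coarser structures (lobes), smaller ones to fine serrations
#' @param angle_threshold degrees; contour points scoring below it are
#'   acute
#' @return a `landmark_set` data.frame (role `"acute"`)
#' @export
acute <- function(img, mask, contour, window, angle_threshold) {
  stopifnot(inherits(contour, "contour"))
  n <- nrow(contour$points)
  acute_from_indices(contour, mask, seq_len(n), window, angle_threshold)
}

#' Acute-region landmarks with strided search
#'
#' Identical landmark definition to [acute()], but the angle runs are
#' evaluated only at every `search_stride`-th contour position, trading
#' positional resolution for fewer angle evaluations. Stride 1 reproduces
#' [acute()] exactly.
#'
#' @inheritParams acute
#' @param search_stride evaluate every k-th contour point (>= 1, at most
#'   the contour length)
#' @return a `landmark_set`
#' @export
acute_vertex <- function(img, contour, window, angle_threshold, search_stride = 1,
                         mask = NULL) {
  stopifnot(inherits(contour, "contour"))
  n <- nrow(contour$points)
  if (search_stride < 1 || search_stride > n) stop("search_stride must be in [1, contour length]")
  idx <- seq(1L, n, by = as.integer(search_stride))
  acute_from_indices(contour, mask, idx, window, angle_threshold)
}

axis_pseudolandmarks <- function(mask, axis = c("x", "y"), n_bins = 20L) {
  axis <- match.arg(axis)
  fg <- mask_logical(mask)
  if (!any(fg)) stop("empty mask: no object to landmark")
  idx <- which(fg)
  h <- nrow(fg)
  x <- (idx - 1L) %/% h
  y <- (idx - 1L) %% h
  along <- if (axis == "x") x else y
  across <- if (axis == "x") y else x
  lo <- min(along); hi <- max(along)
  if (hi - lo + 1L < n_bins)
    stop("object spans fewer than ", n_bins, " pixels along the ", axis, " axis")
  # half-open bins [left, right) except the last, which is closed
  edges <- lo + (hi - lo + 1) * (0:n_bins) / n_bins
  bin <- pmin(n_bins, findInterval(along, edges, rightmost.closed = TRUE))
  roles <- if (axis == "x") c("x_top", "x_bottom", "x_center")
           else c("y_left", "y_right", "y_center")
  res <- new_landmark_set()
  for (b in seq_len(n_bins)) {
    sel <- bin == b
    al <- along[sel]; ac <- across[sel]
    i_min <- which(ac == min(ac)); i_min <- i_min[which.min(al[i_min])]
    i_max <- which(ac == max(ac)); i_max <- i_max[which.min(al[i_max])]
    pts <- rbind(c(al[i_min], ac[i_min]),
                 c(al[i_max], ac[i_max]),
                 c(mean(al), mean(ac)))
    if (axis == "y") pts <- pts[, 2:1]
    res <- rbind(res, new_landmark_set(role = roles, x = pts[, 1], y = pts[, 2]))
  }
  class(res) <- c("landmark_set", "data.frame")
  res
}

#' Axis pseudo-landmarks (Type III)
#'
#' Divides the object's extent along the scanned axis into 20 equal-width
#' bins and records, per bin, the minimum extent, maximum extent, and
#' centroid of the bin's foreground pixels — 60 semi-landmark points per
#' axis that approximate the object's contour without requiring true
#' homology.
#'
#' @param img the source `raster_image` (kept for pipeline uniformity)
#' @param mask the object's `binary_mask`
#' @param contour optional `contour` (unused; the mask defines the object)
#' @return a `landmark_set` with 60 rows: roles `x_top`/`x_bottom`/
#'   `x_center` (20 each)
#' @export
x_axis_pseudolandmarks <- function(img, mask, contour = NULL) {
  axis_pseudolandmarks(mask, "x")
}

#' @rdname x_axis_pseudolandmarks
#' @return for the y-axis scan: roles `y_left`/`y_right`/`y_center`
#' @export
y_axis_pseudolandmarks <- function(img, mask, contour = NULL) {
  axis_pseudolandmarks(mask, "y")
}

#' Centroid of the base of the plant
#'
#' The reference point "localized to the base": the centroid of the
#' foreground pixels in the bottom fraction of the object's row span
#' (default bottom 5%).
#'
#' @param mask the object's `binary_mask`
#' @param fraction bottom fraction of the object's height (default 0.05)
#' @return numeric `(x, y)`
#' @export
plant_base_point <- function(mask, fraction = 0.05) {
  fg <- mask_logical(mask)
  if (!any(fg)) stop("empty mask")
  idx <- which(fg)
  h <- nrow(fg)
  x <- (idx - 1L) %/% h
  y <- (idx - 1L) %% h
  cut <- max(y) - fraction * (max(y) - min(y))
  sel <- y >= cut
  c(x = mean(x[sel]), y = mean(y[sel]))
}

#' Rescale landmarks to the unit square
#'
#' Applies the affine map sending the object's bounding box to
#' \[0, 1\] x \[0, 1\] to every landmark point, the object centroid, and
#' the plant-base point, preserving relative geometry so that objects of
#' different sizes and positions become directly comparable.
#'
#' @param points a `landmark_set`
#' @param mask the object's `binary_mask` (defines the bounding box)
#' @param centroid optional `(x, y)` object centroid; computed from the
#'   mask when missing
#' @param baseline optional `(x, y)` plant-base point; computed via
#'   [plant_base_point()] when missing
#' @return list with `points` (rescaled `landmark_set`), `centroid`, and
#'   `baseline` in the unit frame
#' @export
scale_features <- function(points, mask, centroid = NULL, baseline = NULL) {
  stopifnot(inherits(points, "landmark_set"))
  fg <- mask_logical(mask)
  if (!any(fg)) stop("empty mask")
  idx <- which(fg)
  h <- nrow(fg)
  x <- (idx - 1L) %/% h
  y <- (idx - 1L) %% h
  if (is.null(centroid)) centroid <- c(mean(x), mean(y))
  if (is.null(baseline)) baseline <- plant_base_point(mask)
  xr <- range(x); yr <- range(y)
  if (diff(xr) == 0 || diff(yr) == 0) stop("degenerate bounding box: zero width or height")
  sc <- function(p) c((p[1] - xr[1]) / diff(xr), (p[2] - yr[1]) / diff(yr))
  out <- points
  out$x <- (points$x - xr[1]) / diff(xr)
  out$y <- (points$y - yr[1]) / diff(yr)
  list(points = out, centroid = sc(centroid), baseline = sc(baseline))
}

#' Landmark distances from reference points
#'
#' For every landmark, the signed horizontal and vertical offsets,
#' Euclidean distance, and angle (degrees, `atan2(dy, dx)`) to each of the
#' two references — the object centroid and the plant-base point — in the
#' rescaled unit frame. Per-feature means over the set are attached as the
#' `"summary"` attribute.
#'
#' @param points rescaled `landmark_set`
#' @param centroid rescaled `(x, y)` centroid
#' @param baseline rescaled `(x, y)` plant-base point
#' @return data.frame with eight feature columns per landmark; empty input
#'   yields an empty table
#' @export
landmark_reference_pt_dist <- function(points, centroid, baseline) {
  stopifnot(inherits(points, "landmark_set"))
  feat <- function(px, py, ref, tag) {
    dx <- px - ref[1]; dy <- py - ref[2]
    out <- data.frame(dx, dy, sqrt(dx^2 + dy^2), atan2(dy, dx) * 180 / pi)
    names(out) <- paste0(c("dx_", "dy_", "dist_", "angle_"), tag)
    out
  }
  tab <- cbind(points[, c("role", "x", "y")],
               feat(points$x, points$y, centroid, "centroid"),
               feat(points$x, points$y, baseline, "baseline"))
  num <- tab[, setdiff(names(tab), c("role", "x", "y")), drop = FALSE]
  attr(tab, "summary") <- if (nrow(tab)) colMeans(num) else NULL
  tab
}

#' Write a landmark set to tab-delimited text
#'
#' Columns `(role, x, y, pt_val)`, directly loadable by external
#' morphometrics software.
#'
#' @param points a `landmark_set`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_landmarks <- function(points, path) {
  utils::write.table(points, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
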