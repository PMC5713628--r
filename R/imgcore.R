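# Core raster/mask/contour types and image I/O.
#
# Conventions shared by every module:
#   * pixel grids are numeric/integer arrays indexed [row, col(, channel)]
#   * public coordinates are 0-based (x, y) = (column, row), origin top-left
#   * foreground connectivity is 8, background connectivity is 4

#' Construct a raster image
#'
#' The universal pixel carrier: an H x W (grayscale) or H x W x 3 array of
#' 8-bit values with a colorspace tag. Images read from disk are always
#' delivered in RGB channel order regardless of on-disk layout.
#'
#' @param pixels numeric matrix (H x W) or array (H x W x 3) with values in
#'   \[0, 255\]
#' @param colorspace one of `"RGB"`, `"GRAY"`, `"HSV"`; defaults to `"GRAY"`
#'   for matrices and `"RGB"` for 3-channel arrays
#' @return a `raster_image` object
#' @export
raster_image <- function(pixels, colorspace = NULL) {
  if (is.matrix(pixels)) {
    colorspace <- colorspace %||% "GRAY"
    if (colorspace != "GRAY") stop("single-channel images must be GRAY")
  } else if (is.array(pixels) && length(dim(pixels)) == 3 && dim(pixels)[3] == 3) {
    colorspace <- colorspace %||% "RGB"
    if (!colorspace %in% c("RGB", "HSV")) stop("3-channel colorspace must be RGB or HSV")
  } else {
    stop("pixels must be an H x W matrix or H x W x 3 array")
  }
  if (any(pixels < 0) || any(pixels > 255)) stop("pixel values must lie in [0, 255]")
  structure(list(pixels = pixels, colorspace = colorspace), class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_image %dx%d %s>\n", d[1], d[2], x$colorspace))
  invisible(x)
}

img_dim <- function(img) dim(img$pixels)[1:2]

n_channels <- function(img) if (is.matrix(img$pixels)) 1L else dim(img$pixels)[3]

#' Construct a binary mask
#'
#' A single-channel image with background 0 and foreground 255.
#'
#' @param pixels matrix containing only the values 0 and 255 (or a logical
#'   matrix, mapped to 0/255)
#' @return a `binary_mask` object (an integer matrix with class attribute)
#' @export
binary_mask <- function(pixels) {
  if (is.logical(pixels)) pixels <- pixels * 255L
  pixels <- as.matrix(pixels)
  if (!all(pixels %in% c(0, 255))) stop("a binary mask may contain only 0 and 255")
  structure(matrix(as.integer(pixels), nrow(pixels), ncol(pixels)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %dx%d, %d foreground px>\n",
              nrow(x), ncol(x), sum(x == 255L)))
  invisible(x)
}

mask_logical <- function(mask) unclass(mask) == 255L

#' Convert an RGB image to grayscale
#'
#' Rec. 601 luma weights (0.299, 0.587, 0.114), rounded to 8 bits.
#'
#' @param img a `raster_image`
#' @return a single-channel GRAY `raster_image`
#' @export
as_gray <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  if (n_channels(img) == 1L) return(img)
  p <- img$pixels
  g <- round(0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3])
  raster_image(g, "GRAY")
}

#' Read an image file
#'
#' Decodes PNG, TIFF, or JPEG. Color images are returned in RGB channel
#' order; grayscale files yield a single-channel image. Any alpha channel is
#' dropped.
#'
#' @param path file path
#' @return a `raster_image`
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image, file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = , tiff = tiff::readTIFF(path),
      jpg = , jpeg = jpeg::readJPEG(path),
      stop("unsupported image format: ", path)
    ),
    error = function(e) stop("failed to decode image ", path, ": ", conditionMessage(e))
  )
  if (length(dim(arr)) == 3 && dim(arr)[3] >= 3) {
    arr <- arr[, , 1:3, drop = FALSE]
    raster_image(round(arr * 255), "RGB")
  } else {
    if (length(dim(arr)) == 3) arr <- arr[, , 1]
    raster_image(round(arr * 255), "GRAY")
  }
}

#' Write an image file
#'
#' PNG and TIFF writes are lossless: a write/read round trip reproduces the
#' pixel grid bit-exactly. JPEG is lossy and provided for interoperability
#' only. Binary masks are written as single-channel images.
#'
#' @param img a `raster_image` or `binary_mask`
#' @param path output path (extension selects the format)
#' @return `path`, invisibly
#' @export
write_image <- function(img, path) {
  if (inherits(img, "binary_mask")) img <- raster_image(unclass(img), "GRAY")
  stopifnot(inherits(img, "raster_image"))
  if (!dir.exists(dirname(path))) stop("cannot write image, no such directory: ", dirname(path))
  arr <- img$pixels / 255
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    switch(ext,
      png = png::writePNG(arr, path),
      tif = , tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8),
      jpg = , jpeg = jpeg::writeJPEG(arr, path, quality = 0.95),
      stop("unsupported image format: ", path)
    )
    TRUE
  }, error = function(e) stop("failed to write image ", path, ": ", conditionMessage(e)))
  invisible(path)
}

# ---- connected components ----------------------------------------------

# 8-connected labeling of a logical matrix by vectorized breadth-first
# frontier expansion. Returns an integer matrix of labels (0 = background).
label_components <- function(fg, connectivity = 8L) {
  h <- nrow(fg); w <- ncol(fg)
  lab <- matrix(0L, h, w)
  offs_row <- if (connectivity == 8L) c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L) else c(-1L, 1L, 0L, 0L)
  offs_col <- if (connectivity == 8L) c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L) else c(0L, 0L, -1L, 1L)
  idx_all <- which(fg)
  if (length(idx_all) == 0L) return(lab)
  cur_label <- 0L
  for (seed in idx_all) {
    if (lab[seed] != 0L) next
    cur_label <- cur_label + 1L
    lab[seed] <- cur_label
    frontier <- seed
    while (length(frontier)) {
      fr_row <- ((frontier - 1L) %% h) + 1L
      fr_col <- ((frontier - 1L) %/% h) + 1L
      nxt <- integer(0)
      for (k in seq_along(offs_row)) {
        r <- fr_row + offs_row[k]; c <- fr_col + offs_col[k]
        keep <- r >= 1L & r <= h & c >= 1L & c <= w
        if (!any(keep)) next
        cand <- (c[keep] - 1L) * h + r[keep]
        cand <- cand[fg[cand] & lab[cand] == 0L]
        if (length(cand)) {
          lab[cand] <- cur_label
          nxt <- c(nxt, cand)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

# ---- contour tracing ----------------------------------------------------

# Moore-neighbor boundary tracing (clockwise in image coordinates, y down)
# of the component of `fg` containing linear index `start` (which must be
# its topmost-leftmost pixel in column-major (x, y) scan order). Returns an
# n x 2 matrix of 0-based (x, y) coordinates forming a closed 8-connected
# ring.
trace_contour <- function(fg, start) {
  h <- nrow(fg); w <- ncol(fg)
  # clockwise neighbor order starting west, as (dx, dy)
  dx <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dy <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  sx <- (start - 1L) %/% h   # 0-based col
  sy <- (start - 1L) %% h    # 0-based row
  at <- function(x, y) x >= 0L && x < w && y >= 0L && y < h && fg[y + 1L, x + 1L]
  pts <- matrix(c(sx, sy), ncol = 2)
  # entry direction: came from the west (scan order guarantees west is bg)
  cx <- sx; cy <- sy; bdir <- 1L  # index into dx/dy of the backtrack neighbor
  second <- NULL
  nstep <- 0L
  repeat {
    found <- FALSE
    for (step in 0:7) {
      d <- ((bdir - 1L + step) %% 8L) + 1L
      nx <- cx + dx[d]; ny <- cy + dy[d]
      if (at(nx, ny)) {
        nstep <- nstep + 1L
        # stop when the first directed boundary edge start->second repeats
        if (nstep > 1L && cx == sx && cy == sy &&
            nx == second[1] && ny == second[2]) {
          # drop a trailing duplicate of the start pixel, if present
          n <- nrow(pts)
          if (n > 1L && pts[n, 1] == sx && pts[n, 2] == sy) pts <- pts[-n, , drop = FALSE]
          return(pts)
        }
        if (nstep == 1L) second <- c(nx, ny)
        # backtrack for next pixel: neighbor just before d, relative to new pixel
        prev <- ((d - 2L) %% 8L) + 1L
        px <- cx + dx[prev]; py <- cy + dy[prev]
        # direction from new pixel to that background pixel
        ddx <- px - nx; ddy <- py - ny
        bdir <- which(dx == ddx & dy == ddy)
        cx <- nx; cy <- ny
        pts <- rbind(pts, c(cx, cy))
        found <- TRUE
        break
      }
    }
    if (!found) return(pts)  # isolated pixel
    if (nrow(pts) > 4L * (sum(fg) + 8L)) stop("contour tracing failed to terminate")
  }
}

new_contour <- function(points, is_hole = FALSE, pixels = NULL, label = NA_integer_) {
  structure(list(points = points, orientation = "clockwise",
                 is_hole = is_hole, label = label,
                 pixels = pixels, children = list()),
            class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour: %d points%s, %d child(ren)>\n", nrow(x$points),
              if (x$is_hole) " (hole)" else "", length(x$children)))
  invisible(x)
}

#' Find object contours in a binary mask
#'
#' Labels 8-connected foreground components and traces one closed external
#' contour per component (Moore-neighbor tracing, clockwise). Holes —
#' 4-connected background components that do not touch the image border —
#' are traced as child contours of the enclosing object.
#'
#' @param img the source `raster_image` (dimension check only)
#' @param mask a `binary_mask` of the same size
#' @return a list of `contour` objects; each carries the linear pixel
#'   indices of its component in `$pixels` and hole contours in `$children`.
#'   An empty mask yields an empty list.
#' @export
find_objects <- function(img, mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.null(img)) {
    stopifnot(inherits(img, "raster_image"))
    if (!all(img_dim(img) == dim(mask))) stop("mask and image dimensions differ")
  }
  fg <- mask_logical(mask)
  h <- nrow(fg); w <- ncol(fg)
  lab <- label_components(fg, 8L)
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  contours <- vector("list", nlab)
  for (l in seq_len(nlab)) {
    pix <- which(lab == l)
    attr(pix, "h") <- h
    # topmost-leftmost in (x, y) order = smallest column, then smallest row
    cols <- (pix - 1L) %/% h; rows <- (pix - 1L) %% h
    o <- order(cols, rows)[1]
    start <- pix[o]
    pts <- trace_contour(lab == l, start)
    contours[[l]] <- new_contour(pts, FALSE, pix, l)
  }
  # holes: background 4-connected components not touching the border
  bglab <- label_components(!fg, 4L)
  if (max(bglab) > 0L) {
    border <- unique(c(bglab[1, ], bglab[h, ], bglab[, 1], bglab[, w]))
    for (bl in setdiff(seq_len(max(bglab)), border[border > 0L])) {
      pix <- which(bglab == bl)
      rows <- ((pix - 1L) %% h) + 1L
      cols <- ((pix - 1L) %/% h) + 1L
      # parent = label of a foreground pixel directly above the hole's top pixel
      top <- which.min(rows)
      parent <- lab[rows[top] - 1L, cols[top]]
      c0 <- (pix - 1L) %/% h; r0 <- (pix - 1L) %% h
      o <- order(c0, r0)[1]
      pts <- trace_contour(bglab == bl, pix[o])
      hole <- new_contour(pts, TRUE, pix, parent)
      contours[[parent]]$children <- c(contours[[parent]]$children, list(hole))
    }
  }
  contours
}

# Integer line rasterization (DDA) between two 0-based points, endpoints
# included; used to densify sparse vertex rings (e.g. convex hulls).
raster_segment <- function(p, q) {
  n <- max(abs(q - p))
  if (n == 0) return(matrix(p, 1, 2))
  t <- 0:n
  cbind(round(p[1] + t * (q[1] - p[1]) / n),
        round(p[2] + t * (q[2] - p[2]) / n))
}

# Pixels enclosed by a closed ring (ring itself included), as a logical
# matrix over the ring's bounding box, by flood-filling the complement from
# outside. `points` are 0-based (x, y); consecutive points need not be
# adjacent — segments between them are rasterized.
ring_fill <- function(points) {
  points <- round(points)
  n <- nrow(points)
  if (n > 1) {
    segs <- lapply(seq_len(n), function(i)
      raster_segment(points[i, ], points[(i %% n) + 1, ]))
    points <- unique(do.call(rbind, segs))
  }
  xmin <- min(points[, 1]); xmax <- max(points[, 1])
  ymin <- min(points[, 2]); ymax <- max(points[, 2])
  h <- ymax - ymin + 3L; w <- xmax - xmin + 3L  # one-pixel border all round
  ring <- matrix(FALSE, h, w)
  ring[cbind(points[, 2] - ymin + 2L, points[, 1] - xmin + 2L)] <- TRUE
  outside <- matrix(FALSE, h, w)
  frontier <- 1L  # top-left border pixel
  outside[1L] <- TRUE
  offs <- c(-1L, 1L, -h, h)
  while (length(frontier)) {
    nxt <- integer(0)
    fr_row <- ((frontier - 1L) %% h) + 1L
    fr_col <- ((frontier - 1L) %/% h) + 1L
    for (k in 1:4) {
      if (k == 1L) { r <- fr_row - 1L; c <- fr_col }
      else if (k == 2L) { r <- fr_row + 1L; c <- fr_col }
      else if (k == 3L) { r <- fr_row; c <- fr_col - 1L }
      else { r <- fr_row; c <- fr_col + 1L }
      keep <- r >= 1L & r <= h & c >= 1L & c <= w
      if (!any(keep)) next
      cand <- (c[keep] - 1L) * h + r[keep]
      cand <- cand[!outside[cand] & !ring[cand]]
      if (length(cand)) {
        outside[cand] <- TRUE
        nxt <- c(nxt, cand)
      }
    }
    frontier <- unique(nxt)
  }
  list(inside = !outside, x0 = xmin - 1L, y0 = ymin - 1L)  # offsets of grid origin
}

contour_enclosed_pixels <- function(contour) {
  f <- ring_fill(contour$points)
  idx <- which(f$inside)
  h <- nrow(f$inside)
  x <- ((idx - 1L) %/% h) + f$x0
  y <- ((idx - 1L) %% h) + f$y0
  cbind(x = x, y = y)
}

#' Summarize the shape of one contour
#'
#' Area is the enclosed-pixel count (ring plus interior, holes included);
#' the centroid is the mean coordinate of the enclosed pixels. The convex
#' hull is returned as a vertex contour.
#'
#' @param contour a `contour` (closed ring of at least 3 points)
#' @return a `shape_summary` list with `area`, `centroid`, `bbox`
#'   (`x_min`, `y_min`, `x_max`, `y_max`) and `hull`
#' @export
shape_summary <- function(contour) {
  stopifnot(inherits(contour, "contour"))
  pts <- unique(contour$points)
  if (nrow(pts) < 3L) stop("degenerate contour: fewer than 3 distinct points")
  # collinearity check via cross products against the first edge
  v <- sweep(pts[-1, , drop = FALSE], 2, pts[1, ])
  cross <- v[1, 1] * v[, 2] - v[1, 2] * v[, 1]
  if (all(abs(cross) < 1e-9)) stop("degenerate contour: all points are collinear")
  enc <- contour_enclosed_pixels(contour)
  hull_idx <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- new_contour(pts[hull_idx, , drop = FALSE])
  structure(list(
    area = nrow(enc),
    centroid = c(x = mean(enc[, 1]), y = mean(enc[, 2])),
    bbox = c(x_min = min(pts[, 1]), y_min = min(pts[, 2]),
             x_max = max(pts[, 1]), y_max = max(pts[, 2])),
    hull = hull
  ), class = "shape_summary")
}

#' @export
print.shape_summary <- function(x, ...) {
  cat(sprintf("<shape_summary: area %d px, centroid (%.2f, %.2f)>\n",
              x$area, x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Write a paired training example (image plus mask)
#'
#' Saves the original image and its binary mask side by side with matched
#' basenames, the on-disk layout consumed by two-class classifier training.
#'
#' @param img a `raster_image`
#' @param mask a size-matched `binary_mask`
#' @param out_dir output directory (created if missing)
#' @param basename file stem; defaults to `"sample"`
#' @return character vector of the two written paths (image, mask)
#' @export
output_mask <- function(img, mask, out_dir, basename = "sample") {
  stopifnot(inherits(img, "raster_image"), inherits(mask, "binary_mask"))
  if (!all(img_dim(img) == dim(mask))) stop("image and mask dimensions differ")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  img_path <- file.path(out_dir, paste0(basename, ".png"))
  mask_path <- file.path(out_dir, paste0(basename, "_mask.png"))
  write_image(img, img_path)
  write_image(mask, mask_path)
  c(image = img_path, mask = mask_path)
}
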