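# Multi-plant detection: cluster contours on an approximate grid and split
# trays into single-plant images.

contour_centroid <- function(contour) {
  pix <- contour$pixels
  h <- attr(pix, "h")
  if (!is.null(pix) && !is.null(h)) {
    # pixels are linear indices into the source mask; height travels with them
    x <- (pix - 1L) %/% h
    y <- (pix - 1L) %% h
    return(c(mean(x), mean(y)))
  }
  enc <- contour_enclosed_pixels(contour)
  c(mean(enc[, 1]), mean(enc[, 2]))
}

#' Cluster contours on an approximate grid
#'
#' The image is divided into `nrow` x `ncol` equal cells that act as
#' approximate regions of interest; each contour is assigned to the cell
#' containing its centroid, so fragments of one plant (leaves detected as
#' separate contours) regroup and leaves overhanging a neighboring cell do
#' not split a plant. Cells may be empty.
#'
#' @param img the source `raster_image` (its size defines the grid)
#' @param contours list of `contour` objects (typically from
#'   [find_objects()])
#' @param nrow,ncol grid dimensions (>= 1)
#' @return a `contour_clusters` object: `groups` (named list of contour
#'   indices in row-major cell order), `grid`, `row_edges`/`col_edges`
#'   (pixel boundaries), and the inputs needed for splitting
#' @export
cluster_contours <- function(img, contours, nrow, ncol) {
  stopifnot(inherits(img, "raster_image"), nrow >= 1, ncol >= 1)
  d <- img_dim(img)
  row_edges <- seq(0, d[1], length.out = nrow + 1)
  col_edges <- seq(0, d[2], length.out = ncol + 1)
  groups <- list()
  if (length(contours)) {
    cent <- t(vapply(contours, contour_centroid, numeric(2)))
    cell_r <- pmin(nrow, findInterval(cent[, 2], row_edges, rightmost.closed = TRUE))
    cell_c <- pmin(ncol, findInterval(cent[, 1], col_edges, rightmost.closed = TRUE))
    key <- paste0(cell_r, "_", cell_c)
    # row-major order over nonempty cells
    all_keys <- as.vector(t(outer(seq_len(nrow), seq_len(ncol), paste, sep = "_")))
    for (k in all_keys) {
      idx <- which(key == k)
      if (length(idx)) groups[[k]] <- idx
    }
  }
  res <- structure(list(groups = groups, grid = c(nrow = nrow, ncol = ncol),
                        row_edges = row_edges, col_edges = col_edges,
                        contours = contours, img_dim = d),
                   class = "contour_clusters")
  debug_emit(cluster_debug_image(img, res), "cluster_contours")
  res
}

#' @export
print.contour_clusters <- function(x, ...) {
  cat(sprintf("<contour_clusters: %d group(s) on a %dx%d grid, %d contour(s)>\n",
              length(x$groups), x$grid[1], x$grid[2], length(x$contours)))
  invisible(x)
}

# Debug rendering: each cluster group painted in a unique color drawn from
# a sequential palette.
cluster_debug_image <- function(img, clusters) {
  d <- clusters$img_dim
  canvas <- if (n_channels(img) == 3L) img$pixels else {
    g <- img$pixels
    array(rep(g, 3), dim = c(d, 3))
  }
  ng <- length(clusters$groups)
  if (ng) {
    pal <- label_palette(ng)
    for (gi in seq_len(ng)) {
      for (ci in clusters$groups[[gi]]) {
        pix <- clusters$contours[[ci]]$pixels
        if (is.null(pix)) next
        rows <- ((pix - 1L) %% d[1]) + 1L
        cols <- ((pix - 1L) %/% d[1]) + 1L
        for (ch in 1:3) canvas[cbind(rows, cols, ch)] <- pal[gi, ch]
      }
    }
  }
  raster_image(canvas, "RGB")
}

group_mask <- function(clusters, gi) {
  d <- clusters$img_dim
  m <- matrix(0L, d[1], d[2])
  for (ci in clusters$groups[[gi]]) {
    pix <- clusters$contours[[ci]]$pixels
    if (is.null(pix)) {
      enc <- contour_enclosed_pixels(clusters$contours[[ci]])
      pix <- (enc[, 1]) * d[1] + enc[, 2] + 1L
    }
    m[pix] <- 255L
  }
  binary_mask(m)
}

#' Split a clustered multi-plant image into single-plant images
#'
#' Produces one image per nonempty cluster group, keeping the full original
#' canvas with all pixels outside the group blanked to 0 so every split
#' image shares the tray's coordinate frame. Labels come from a genotype
#' names file (one name per line, row-major grid order) or default to the
#' positional label `"row_col"`. A name-count mismatch triggers a warning:
#' names are consumed in row-major order, surplus groups fall back to
#' positional labels, surplus names are dropped.
#'
#' @param img the original `raster_image`
#' @param clusters a `contour_clusters` from [cluster_contours()]
#' @param names_file optional path to a plain-text genotype names file
#' @param crop if `TRUE`, crop each output to the bounding box of its group
#' @return list with one element per nonempty group: `image`, `label`,
#'   `mask` (the group's foreground)
#' @export
cluster_contour_split_img <- function(img, clusters, names_file = NULL, crop = FALSE) {
  stopifnot(inherits(img, "raster_image"), inherits(clusters, "contour_clusters"))
  ng <- length(clusters$groups)
  labels <- names(clusters$groups)
  if (!is.null(names_file)) {
    if (!file.exists(names_file)) stop("cannot read names file: ", names_file)
    nm <- readLines(names_file, warn = FALSE)
    nm <- nm[nzchar(nm)]
    if (length(nm) != ng) {
      warning(sprintf(paste0("names file has %d name(s) for %d object group(s); ",
                             "consuming names in row-major order and labeling ",
                             "the remainder by position"), length(nm), ng))
    }
    take <- min(length(nm), ng)
    if (take > 0) labels[seq_len(take)] <- nm[seq_len(take)]
  }
  out <- vector("list", ng)
  for (gi in seq_len(ng)) {
    gm <- group_mask(clusters, gi)
    keep <- mask_logical(gm)
    p <- img$pixels
    if (is.matrix(p)) {
      p[!keep] <- 0
    } else {
      for (ch in 1:3) {
        pc <- p[, , ch]; pc[!keep] <- 0; p[, , ch] <- pc
      }
    }
    if (crop) {
      idx <- which(keep, arr.ind = TRUE)
      rr <- range(idx[, 1]); cc <- range(idx[, 2])
      p <- if (is.matrix(p)) p[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
           else p[rr[1]:rr[2], cc[1]:cc[2], , drop = FALSE]
      gm <- binary_mask(unclass(gm)[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE])
    }
    out[[gi]] <- list(image = raster_image(p, img$colorspace),
                      label = labels[gi], mask = gm)
  }
  out
}
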