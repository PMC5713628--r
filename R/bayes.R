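# Trainable two-class and multiclass naive Bayes pixel classifier.
#
# Per class and per HSV channel, a kernel density estimate over the
# channel's byte values is discretized to 256 bins. Classification is the
# per-pixel argmax of the product of the three channel densities under a
# uniform prior. Hue uses full-byte [0, 255] scaling and is treated as
# linear; the circular wrap-around at red is a documented limitation that
# does not affect green-centered plant hues.

PDF_FLOOR <- 1e-10  # zero-density floor so finite samples never hard-zero a class

# Gaussian KDE over byte samples, evaluated at the 256 integer bin centers
# and renormalized to sum to 1. Scott's-rule bandwidth, floored so
# degenerate (constant) samples still yield a usable density.
channel_pdf <- function(samples) {
  stopifnot(length(samples) >= 1)
  bw <- tryCatch(stats::bw.nrd(samples), error = function(e) NA_real_)
  if (!is.finite(bw) || bw <= 0) bw <- 1
  d <- stats::density(samples, bw = bw, from = 0, to = 255, n = 256)
  y <- d$y
  y / sum(y)
}

# Build one class PDF set (h, s, v rows) from an n x 3 matrix of RGB bytes.
class_pdf_from_rgb <- function(rgb, class_name) {
  hsv <- rgb_to_hsv_bytes(rgb)
  pdf <- rbind(h = channel_pdf(hsv[, 1]),
               s = channel_pdf(hsv[, 2]),
               v = channel_pdf(hsv[, 3]))
  structure(list(class = class_name, pdf = pdf), class = "class_pdf")
}

#' @export
print.class_pdf <- function(x, ...) {
  cat(sprintf("<class_pdf '%s': 3 channels x 256 bins>\n", x$class))
  invisible(x)
}

new_class_pdfs <- function(pdfs) {
  names(pdfs) <- vapply(pdfs, `[[`, character(1), "class")
  structure(pdfs, class = "class_pdfs")
}

#' @export
print.class_pdfs <- function(x, ...) {
  cat(sprintf("<class_pdfs: %s>\n", paste(names(x), collapse = ", ")))
  invisible(x)
}

image_rgb_matrix <- function(img) {
  p <- img$pixels
  if (is.matrix(p)) cbind(as.vector(p), as.vector(p), as.vector(p))
  else cbind(as.vector(p[, , 1]), as.vector(p[, , 2]), as.vector(p[, , 3]))
}

#' Train a two-class (plant / background) pixel classifier
#'
#' Pools the pixels of all image/mask pairs, draws a seeded random sample
#' of 10% of the foreground pixels and an equal number of background
#' pixels, converts both samples to HSV, and fits one kernel density per
#' channel per class. Equal sample counts make the uniform class prior
#' consistent with the training data.
#'
#' @param pairs list of `list(image =, mask =)` pairs (size-matched); the
#'   masks are white over the target object
#' @param seed integer seed for the pixel sampling
#' @param fraction foreground sampling fraction (default 0.1)
#' @return a `class_pdfs` object with classes `"plant"` and
#'   `"background"`
#' @export
train_two_class <- function(pairs, seed = 1, fraction = 0.1) {
  stopifnot(length(pairs) >= 1)
  fg_rgb <- list(); bg_rgb <- list()
  for (p in pairs) {
    img <- p$image; mask <- p$mask
    stopifnot(inherits(img, "raster_image"), inherits(mask, "binary_mask"))
    if (!all(img_dim(img) == dim(mask))) stop("training image and mask dimensions differ")
    rgb <- image_rgb_matrix(img)
    keep <- as.vector(mask_logical(mask))
    fg_rgb[[length(fg_rgb) + 1L]] <- rgb[keep, , drop = FALSE]
    bg_rgb[[length(bg_rgb) + 1L]] <- rgb[!keep, , drop = FALSE]
  }
  fg <- do.call(rbind, fg_rgb)
  bg <- do.call(rbind, bg_rgb)
  if (nrow(fg) == 0) stop("no foreground pixels across the training pairs")
  n_samp <- max(1L, round(fraction * nrow(fg)))
  n_bg <- min(n_samp, nrow(bg))
  sel <- with_seed(seed, {
    list(fg = sample.int(nrow(fg), n_samp),
         bg = sample.int(nrow(bg), n_bg))
  })
  samples <- list(plant = fg[sel$fg, , drop = FALSE],
                  background = bg[sel$bg, , drop = FALSE])
  pdfs <- new_class_pdfs(list(
    class_pdf_from_rgb(samples$plant, "plant"),
    class_pdf_from_rgb(samples$background, "background")))
  attr(pdfs, "n_samples") <- c(plant = n_samp, background = n_bg)
  attr(pdfs, "samples") <- samples
  pdfs
}

#' Train a multiclass pixel classifier from a sample table
#'
#' One class per table column; every sample is used (no subsampling). The
#' same HSV kernel-density procedure as two-class training is applied per
#' class.
#'
#' @param table a `training_sample_table` (see [read_training_table()]) or
#'   a named list of n x 3 RGB byte matrices, one per class
#' @param min_samples minimum samples per class for a stable density
#'   estimate (default 30)
#' @return a `class_pdfs` object, one entry per class
#' @export
train_multiclass <- function(table, min_samples = 30) {
  if (inherits(table, "training_sample_table")) table <- unclass(table)
  stopifnot(is.list(table), !is.null(names(table)))
  if (length(table) < 2) stop("multiclass training requires at least 2 classes")
  for (cl in names(table)) {
    m <- table[[cl]]
    if (!is.matrix(m) || ncol(m) != 3) stop("class '", cl, "' is not an n x 3 RGB matrix")
    if (nrow(m) < min_samples)
      stop("class '", cl, "' has ", nrow(m), " samples; at least ", min_samples, " required")
    if (any(m < 0 | m > 255)) stop("class '", cl, "' has RGB values outside [0, 255]")
  }
  new_class_pdfs(lapply(names(table), function(cl)
    class_pdf_from_rgb(table[[cl]], cl)))
}

#' Read a multiclass training table
#'
#' Tab-delimited text, one class per column (header row holds the class
#' names), each cell a comma-separated `"R,G,B"` byte triple. Columns may
#' have different lengths; short columns leave trailing cells empty.
#'
#' @param path file path
#' @return a `training_sample_table`: named list of n x 3 RGB matrices
#' @export
read_training_table <- function(path) {
  if (!file.exists(path)) stop("training table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1) stop("training table is empty")
  classes <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(classes) < 2) stop("training table must have at least 2 class columns")
  if (length(lines) < 2) stop("training table has no sample rows")
  out <- lapply(classes, function(x) list())
  names(out) <- classes
  for (li in seq(2, length(lines))) {
    cells <- strsplit(lines[li], "\t", fixed = TRUE)[[1]]
    for (ci in seq_along(cells)) {
      cell <- trimws(cells[ci])
      if (!nzchar(cell)) next
      vals <- suppressWarnings(as.numeric(strsplit(cell, ",", fixed = TRUE)[[1]]))
      if (length(vals) != 3 || anyNA(vals) || any(vals < 0 | vals > 255))
        stop("malformed RGB cell '", cell, "' at line ", li, " of ", path)
      out[[ci]][[length(out[[ci]]) + 1L]] <- vals
    }
  }
  out <- lapply(out, function(l) do.call(rbind, l))
  structure(out, class = "training_sample_table")
}

#' Write a multiclass training table
#'
#' @param table a `training_sample_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_training_table <- function(table, path) {
  tab <- unclass(table)
  nmax <- max(vapply(tab, nrow, integer(1)))
  cols <- lapply(tab, function(m) {
    cells <- apply(m, 1, paste, collapse = ",")
    c(cells, rep("", nmax - length(cells)))
  })
  lines <- c(paste(names(tab), collapse = "\t"),
             do.call(paste, c(cols, sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read class PDFs as tab-delimited text
#'
#' Format: header `class channel b0 ... b255`, one row per class-channel
#' pair — directly plottable to inspect per-channel class separation.
#'
#' @param pdfs a `class_pdfs`
#' @param path file path
#' @return `path` (write) or a `class_pdfs` (read)
#' @export
write_pdfs <- function(pdfs, path) {
  stopifnot(inherits(pdfs, "class_pdfs"))
  rows <- character(0)
  for (p in pdfs) {
    for (ch in c("h", "s", "v")) {
      rows <- c(rows, paste(c(p$class, ch,
                              format(p$pdf[ch, ], digits = 17)), collapse = "\t"))
    }
  }
  writeLines(c(paste(c("class", "channel", paste0("b", 0:255)), collapse = "\t"), rows),
             path)
  invisible(path)
}

#' @rdname write_pdfs
#' @export
read_pdfs <- function(path) {
  if (!file.exists(path)) stop("PDF file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) != 258) stop("malformed PDF file: expected 258 columns")
  classes <- unique(tab$class)
  new_class_pdfs(lapply(classes, function(cl) {
    sub <- tab[tab$class == cl, ]
    pdf <- as.matrix(sub[match(c("h", "s", "v"), sub$channel), -(1:2)])
    dimnames(pdf) <- list(c("h", "s", "v"), NULL)
    structure(list(class = cl, pdf = pdf), class = "class_pdf")
  }))
}

#' Classify every pixel by naive Bayes
#'
#' Converts the image to HSV and scores each pixel under every class as
#' the product of the three per-channel densities at the pixel's bin
#' values (uniform prior; densities floored at 1e-10). Each pixel is
#' assigned to the argmax class; ties break toward the first class in the
#' PDF set and are reported via a warning when they occur. The returned
#' per-class masks are mutually exclusive and jointly exhaustive.
#'
#' @param img a `raster_image`
#' @param pdfs a `class_pdfs` (at least 2 classes)
#' @return named list of `binary_mask`, one per class
#' @export
naive_bayes_classifier <- function(img, pdfs) {
  stopifnot(inherits(img, "raster_image"), inherits(pdfs, "class_pdfs"))
  if (length(pdfs) < 2) stop("classification requires at least 2 class PDFs")
  for (p in pdfs) if (!all(dim(p$pdf) == c(3, 256)))
    stop("class '", p$class, "' PDF does not have 3 x 256 bins")
  d <- img_dim(img)
  hsv <- rgb_to_hsv_bytes(image_rgb_matrix(img))
  bins <- hsv + 1L
  scores <- vapply(pdfs, function(p) {
    log(pmax(p$pdf["h", bins[, 1]], PDF_FLOOR)) +
      log(pmax(p$pdf["s", bins[, 2]], PDF_FLOOR)) +
      log(pmax(p$pdf["v", bins[, 3]], PDF_FLOOR))
  }, numeric(nrow(bins)))
  best <- max.col(scores, ties.method = "first")
  rowmax <- do.call(pmax, lapply(seq_len(ncol(scores)), function(k) scores[, k]))
  n_tied <- sum(rowSums(scores == rowmax) > 1L)
  if (n_tied > 0)
    warning(n_tied, " pixel(s) had tied class scores; first class wins")
  masks <- lapply(seq_along(pdfs), function(k)
    binary_mask(matrix((best == k) * 255L, d[1], d[2])))
  names(masks) <- names(pdfs)
  for (nm in names(masks)) debug_emit(masks[[nm]], paste0("naive_bayes_", nm))
  masks
}
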