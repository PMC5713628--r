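# Deterministic, seeded generator of synthetic plant scenes and training
# data. Every other module is exercised against the ground truth this
# module constructs: rosette plants built from elliptical leaves on thin
# petioles radiating from a center, single or grid (tray) layouts,
# per-class HSV color palettes, flat or gradient backgrounds, and an
# optional disk size marker.

#' Define a class color palette
#'
#' Per class: mean HSV (bytes) and a shared Gaussian spread. Pixel colors
#' are drawn as independent Gaussians per channel, clipped to \[0, 255\] —
#' the noise model the classifier recovery tests assume.
#'
#' @param means named list of length-3 HSV byte vectors, one per class
#' @param spread Gaussian sigma (bytes) applied to every channel
#' @return a `class_palette`
#' @export
class_palette <- function(means, spread = 8) {
  stopifnot(is.list(means), !is.null(names(means)))
  for (m in means) stopifnot(length(m) == 3, all(m >= 0), all(m <= 255))
  structure(list(means = means, spread = spread), class = "class_palette")
}

#' Default palettes
#'
#' `palette_plant_background()`: a green plant on brown soil, hue gap
#' about 60 bytes. `palette_rust()`: the four-class leaf-disease styling —
#' background, unaffected (green) tissue, chlorotic (yellow) tissue, and
#' orange pustules.
#'
#' @param spread Gaussian sigma in bytes
#' @return a `class_palette`
#' @export
palette_plant_background <- function(spread = 8) {
  class_palette(list(
    plant = c(100, 180, 170),
    background = c(30, 90, 90)
  ), spread)
}

#' @rdname palette_plant_background
#' @export
palette_rust <- function(spread = 7) {
  class_palette(list(
    background = c(160, 40, 60),
    unaffected = c(95, 170, 150),
    chlorotic = c(45, 190, 200),
    pustule = c(12, 200, 180)
  ), spread)
}

#' Specify a synthetic scene
#'
#' @param canvas `c(height, width)` in pixels
#' @param layout `"single"` or `"grid"`
#' @param nrow,ncol grid dimensions (grid layout)
#' @param jitter positional jitter in pixels applied to plant centers
#' @param leaf_count leaves per plant (>= 1)
#' @param leaf_length,leaf_width full blade-ellipse length/width in pixels;
#'   `leaf_width = NULL` (default) narrows the blades as `leaf_count`
#'   grows, the way crowded rosettes grow narrower leaves
#' @param petiole_length radial offset of the blade bases from the plant
#'   center; the central area inside it is open, so the plant core adds no
#'   spurious distance-map peak
#' @param petiole_width thickness of the thin central ring that joins the
#'   blade bases into one connected plant
#' @param palette a `class_palette`; the first class colors the plant (or,
#'   with more than 2 classes, foreground classes are cycled over leaves)
#' @param background `"flat"` or `"gradient"` (horizontal value ramp)
#' @param marker optional `list(radius =, x =, y =)` white disk size marker
#' @param separable if `TRUE` (default), reject geometry whose leaves can
#'   collide or whose distance-map peaks are not one-per-leaf
#' @param seed integer seed; a fixed seed gives byte-identical scenes
#' @return a `scene_spec`
#' @export
scene_spec <- function(canvas = c(160, 160),
                       layout = c("single", "grid"),
                       nrow = 1, ncol = 1, jitter = 2,
                       leaf_count = 8,
                       leaf_length = 52, leaf_width = NULL,
                       petiole_length = 7, petiole_width = 2,
                       palette = palette_plant_background(),
                       background = c("flat", "gradient"),
                       marker = NULL,
                       separable = TRUE,
                       seed = 1) {
  layout <- match.arg(layout)
  background <- match.arg(background)
  stopifnot(leaf_count >= 1, inherits(palette, "class_palette"))
  if (is.null(leaf_width)) leaf_width <- default_leaf_width(leaf_count)
  spec <- structure(list(canvas = canvas, layout = layout,
                         nrow = nrow, ncol = ncol, jitter = jitter,
                         leaf_count = leaf_count,
                         leaf_length = leaf_length, leaf_width = leaf_width,
                         petiole_length = petiole_length, petiole_width = petiole_width,
                         palette = palette, background = background,
                         marker = marker, separable = separable,
                         seed = as.integer(seed)),
                    class = "scene_spec")
  if (separable) check_separable(spec)
  spec
}

# Default blade half-width by leaf count: crowded rosettes get narrower
# blades so neighboring distance-map peaks stay distinct.
default_leaf_width <- function(leaf_count) {
  if (leaf_count <= 5) 18 else if (leaf_count <= 8) 14
  else if (leaf_count <= 10) 12 else 10
}

# Analytic separability constraints, all under worst-case angular jitter:
# adjacent blade peaks must clear each other laterally and stand far
# enough apart for peak thinning, the bare ring arcs between blades must
# stay inside the suppression window of taller blade pixels, and the
# rosette must fit its cell.
check_separable <- function(spec) {
  b <- spec$leaf_width / 2
  k <- spec$leaf_count
  rho_peak <- spec$petiole_length - 1 + spec$leaf_length -
    min(spec$leaf_width, 0.4 * spec$leaf_length)
  if (k > 1) {
    gam <- (pi / k) * (1 - 2 * ANGLE_JITTER)  # worst-case half-gap angle
    if (rho_peak * sin(gam) - b < 0.75)
      stop("leaves overlap beyond separability: increase leaf length, ",
           "or reduce leaf count or width")
    if (2 * rho_peak * sin(gam) < 10)
      stop("blade peaks too close for watershed separation: ",
           "reduce leaf count or lengthen leaves")
    if (spec$petiole_length * pi / k > 12)
      stop("ring arcs between blades too long: reduce petiole_length ",
           "or increase leaf count")
  }
  reach <- spec$petiole_length - 1 + spec$leaf_length + spec$jitter + 2
  cell <- cell_size(spec)
  if (2 * reach > min(cell))
    stop("rosette does not fit its cell: reduce leaf dimensions or enlarge the canvas")
  invisible(spec)
}

# Per-leaf angular jitter, as a fraction of the inter-leaf spacing.
ANGLE_JITTER <- 0.1

cell_size <- function(spec) {
  if (spec$layout == "single") spec$canvas
  else c(spec$canvas[1] / spec$nrow, spec$canvas[2] / spec$ncol)
}

# Rasterize one rosette into a logical mask; returns per-leaf tip
# coordinates as an attribute. Each blade is spatulate: a trapezoidal base
# widening linearly from the attachment ring to an elliptical outer cap,
# so its distance-map ridge rises monotonically to a single peak near the
# cap. Blade bases sit on a thin central ring that joins the plant into
# one 8-connected component while the open center keeps the distance map
# free of a central peak; the separable lobes are exactly the blades.
draw_rosette <- function(h, w, cx, cy, angles, len, b, attach_r, ring_w) {
  gx <- rep(0:(w - 1L), each = h)
  gy <- rep(0:(h - 1L), times = w)
  fg <- rep(FALSE, h * w)
  tips <- matrix(0, length(angles), 2)
  # connecting ring: annulus just inside the blade bases
  rho2 <- (gx - cx)^2 + (gy - cy)^2
  fg <- fg | (rho2 <= attach_r^2 & rho2 >= (attach_r - ring_w)^2)
  # cap center: a rounded cap (semi-major 2b, capped at 0.4 len) keeps the
  # ridge maximum compact, so distance-map value ties cannot spread far
  t_cap <- len - min(2 * b, 0.4 * len)
  b0 <- min(1, b)           # half-width where the blade meets the ring
  for (i in seq_along(angles)) {
    th <- angles[i]
    co <- cos(th); si <- sin(th)
    # blade frame: u along the axis from the base, v across
    bx <- cx + (attach_r - 1) * co
    by <- cy + (attach_r - 1) * si
    u <- (gx - bx) * co + (gy - by) * si
    v <- -(gx - bx) * si + (gy - by) * co
    half <- b0 + (b - b0) * pmin(pmax(u, 0), t_cap) / t_cap
    blade <- (u >= 0 & u <= t_cap & abs(v) <= half) |
      ((u - t_cap)^2 / (len - t_cap)^2 + v^2 / b^2 <= 1)
    fg <- fg | blade
    tips[i, ] <- c(bx + len * co, by + len * si)
  }
  out <- matrix(fg, h, w)
  attr(out, "tips") <- tips
  out
}

# Draw byte colors for a set of pixels from a palette class.
sample_class_colors <- function(palette, class_name, n) {
  m <- palette$means[[class_name]]
  hsv <- cbind(
    clamp255(round(stats::rnorm(n, m[1], palette$spread))),
    clamp255(round(stats::rnorm(n, m[2], palette$spread))),
    clamp255(round(stats::rnorm(n, m[3], palette$spread))))
  hsv_to_rgb_bytes(hsv)
}

#' Generate a synthetic scene with full ground truth
#'
#' Rasterizes the scene described by a [scene_spec()]: one rosette (or an
#' `nrow` x `ncol` grid of them), colored per the palette with per-pixel
#' Gaussian HSV noise, over a flat or horizontally graded background, plus
#' an optional white disk marker. All randomness flows through the spec's
#' seed; the caller's RNG state is untouched.
#'
#' @param spec a `scene_spec`
#' @return list: `image` (RGB `raster_image`), `mask` (all-plant
#'   `binary_mask`), `class_masks` (named list, one `binary_mask` per
#'   palette class), `plant_masks` (per-plant), `leaf_count` (per plant),
#'   `landmarks` (per-plant matrix of leaf-tip coordinates), and
#'   `marker_mask` when a marker was requested
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  h <- spec$canvas[1]; w <- spec$canvas[2]
  b <- spec$leaf_width / 2
  classes <- names(spec$palette$means)
  fg_classes <- setdiff(classes, "background")
  centers <- if (spec$layout == "single") {
    matrix(c((w - 1) / 2, (h - 1) / 2), 1)
  } else {
    ch <- h / spec$nrow; cw <- w / spec$ncol
    as.matrix(expand.grid(
      x = (seq_len(spec$ncol) - 0.5) * cw,
      y = (seq_len(spec$nrow) - 0.5) * ch))[, 1:2, drop = FALSE]
  }
  n_plants <- nrow(centers)
  plant_masks <- vector("list", n_plants)
  tips <- vector("list", n_plants)
  leaf_id <- matrix(0L, h, w)   # which leaf (global index) claimed a pixel
  fg_all <- matrix(FALSE, h, w)
  leaf_counter <- 0L
  for (p_i in seq_len(n_plants)) {
    cx <- centers[p_i, 1] + stats::runif(1, -spec$jitter, spec$jitter)
    cy <- centers[p_i, 2] + stats::runif(1, -spec$jitter, spec$jitter)
    base <- stats::runif(1, 0, 2 * pi)
    k <- spec$leaf_count
    angles <- base + 2 * pi * (seq_len(k) - 1) / k +
      stats::runif(k, -ANGLE_JITTER, ANGLE_JITTER) * (pi / k)
    pm <- draw_rosette(h, w, cx, cy, angles, spec$leaf_length, b,
                       spec$petiole_length, spec$petiole_width)
    plant_masks[[p_i]] <- binary_mask(pm)
    tips[[p_i]] <- attr(pm, "tips")
    fg_all <- fg_all | pm
    # assign pixels to their nearest leaf axis (for multi-class coloring)
    idx <- which(pm)
    px <- (idx - 1L) %/% h; py <- (idx - 1L) %% h
    ang_px <- atan2(py - cy, px - cx)
    dif <- outer(ang_px, angles, function(p, q) abs(atan2(sin(p - q), cos(p - q))))
    leaf_id[idx] <- leaf_counter + max.col(-dif)
    leaf_counter <- leaf_counter + k
  }
  # background
  bg_rgb <- sample_class_colors(spec$palette, "background", h * w)
  if (spec$background == "gradient") {
    ramp <- matrix(rep(seq(-40, 40, length.out = w), each = h), h, w)
    hsvb <- rgb_to_hsv_bytes(bg_rgb)
    hsvb[, 3] <- clamp255(hsvb[, 3] + as.vector(ramp))
    bg_rgb <- hsv_to_rgb_bytes(hsvb)
  }
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- matrix(bg_rgb[, ch], h, w)
  # foreground coloring: cycle the non-background classes over leaves
  class_masks <- lapply(classes, function(cl) matrix(FALSE, h, w))
  names(class_masks) <- classes
  class_masks$background <- !fg_all
  idx_fg <- which(fg_all)
  cls_of_leaf <- rep_len(fg_classes, max(1L, leaf_counter))
  pix_cls <- cls_of_leaf[leaf_id[idx_fg]]
  for (cl in fg_classes) {
    sel <- idx_fg[pix_cls == cl]
    if (!length(sel)) next
    class_masks[[cl]][sel] <- TRUE
    rgb <- sample_class_colors(spec$palette, cl, length(sel))
    for (ch in 1:3) {
      plane <- img[, , ch]; plane[sel] <- rgb[, ch]; img[, , ch] <- plane
    }
  }
  out <- list(image = NULL, mask = binary_mask(fg_all),
              class_masks = lapply(class_masks, binary_mask),
              plant_masks = plant_masks,
              leaf_count = rep(spec$leaf_count, n_plants),
              landmarks = tips)
  # marker
  if (!is.null(spec$marker)) {
    mk <- spec$marker
    gx <- rep(0:(w - 1L), each = h); gy <- rep(0:(h - 1L), times = w)
    disk <- matrix((gx - mk$x)^2 + (gy - mk$y)^2 <= mk$radius^2, h, w)
    disk <- disk & !fg_all
    for (ch in 1:3) {
      plane <- img[, , ch]; plane[disk] <- 245; img[, , ch] <- plane
    }
    out$marker_mask <- binary_mask(disk)
  }
  out$image <- raster_image(img, "RGB")
  out
}

#' Generate a multiclass training table from a palette
#'
#' Draws `n_per_class` HSV samples per class from the palette's Gaussian
#' model, converts them to RGB bytes, and returns them in the multiclass
#' training-table structure.
#'
#' @param palette a `class_palette`
#' @param n_per_class samples per class (>= 30)
#' @param seed integer seed
#' @return a `training_sample_table`
#' @export
generate_training_table <- function(palette, n_per_class = 200, seed = 1) {
  stopifnot(inherits(palette, "class_palette"))
  if (n_per_class < 30) stop("n_per_class must be at least 30 for a stable density estimate")
  means <- do.call(rbind, palette$means)
  if (nrow(means) > 1) {
    d <- as.matrix(stats::dist(means[, 1, drop = FALSE]))
    diag(d) <- Inf
    if (min(d) < 3 * palette$spread)
      warning("class hue means closer than 3 sigma; classes may not be separable")
  }
  with_seed(seed, {
    tab <- lapply(names(palette$means), function(cl)
      sample_class_colors(palette, cl, n_per_class))
    names(tab) <- names(palette$means)
    structure(tab, class = "training_sample_table")
  })
}
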