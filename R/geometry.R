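#' Axis-aligned bounding boxes
#'
#' Boxes are the geometric atom of the package: candidate proposals,
#' reference annotations and detections are all axis-aligned rectangles in
#' pixel space. The convention is 0-based, half-open pixel intervals
#' \code{[x_min, x_max) x [y_min, y_max)}, so the area of a box is
#' \code{(x_max - x_min) * (y_max - y_min)} and an integer box of side s
#' contains exactly s^2 pixels. Empty and inverted boxes are rejected at
#' construction.
#'
#' @param x_min,y_min,x_max,y_max Numeric vectors of corner coordinates in
#'   pixels; recycled to a common length. All must be finite and
#'   non-negative, with \code{x_min < x_max} and \code{y_min < y_max}.
#' @return A numeric matrix of class \code{"bbox"} with one row per box and
#'   columns \code{x_min, y_min, x_max, y_max}.
#' @examples
#' b <- bbox(0, 0, 10, 10)
#' box_area(b)
#' @export
bbox <- function(x_min, y_min, x_max, y_max) {
  m <- cbind(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
             x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  if (!all(is.finite(m))) {
    stop("box coordinates must be finite numbers")
  }
  if (any(m < 0)) {
    stop("box coordinates must be non-negative")
  }
  if (any(m[, "x_min"] >= m[, "x_max"]) || any(m[, "y_min"] >= m[, "y_max"])) {
    stop("empty box: need x_min < x_max and y_min < y_max")
  }
  class(m) <- c("bbox", class(m))
  m
}

#' @rdname bbox
#' @param b A \code{bbox} matrix.
#' @export
box_area <- function(b) {
  b <- as_bbox(b)
  unname((b[, "x_max"] - b[, "x_min"]) * (b[, "y_max"] - b[, "y_min"]))
}

#' Coerce to a bbox matrix
#'
#' Accepts a \code{bbox}, a plain 4-column matrix (corner order), or a
#' length-4 numeric vector, and revalidates through \code{\link{bbox}}.
#'
#' @param x Object to coerce.
#' @return A \code{bbox} matrix.
#' @export
as_bbox <- function(x) {
  if (inherits(x, "bbox")) return(x)
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 4L) {
    x <- matrix(x, nrow = 1L)
  }
  if (!is.matrix(x) || ncol(x) != 4L) {
    stop("cannot interpret object as boxes: need a 4-column matrix or length-4 vector")
  }
  bbox(x[, 1L], x[, 2L], x[, 3L], x[, 4L])
}

#' Jaccard index (intersection over union) between boxes
#'
#' The overlap measure used throughout the toolkit: for cascade sample
#' selection, non-maximum suppression, augmentation gating and detection
#' evaluation. Computed on continuous box geometry under the half-open
#' convention, so for integer boxes it agrees exactly with counting member
#' pixels of each set.
#'
#' \code{jaccard()} pairs rows elementwise (with recycling of a single row);
#' \code{jaccard_matrix()} returns the full cross matrix, rows of \code{a}
#' against rows of \code{b}.
#'
#' @param a,b Boxes coercible via \code{\link{as_bbox}}.
#' @return \code{jaccard()}: numeric vector in [0, 1]. \code{jaccard_matrix()}:
#'   an \code{nrow(a)} by \code{nrow(b)} matrix.
#' @examples
#' jaccard(bbox(0, 0, 10, 10), bbox(5, 5, 15, 15)) # 25 / 175
#' @export
jaccard <- function(a, b) {
  a <- as_bbox(a); b <- as_bbox(b)
  na <- nrow(a); nb <- nrow(b)
  if (na != nb) {
    if (na == 1L) a <- a[rep(1L, nb), , drop = FALSE]
    else if (nb == 1L) b <- b[rep(1L, na), , drop = FALSE]
    else stop("jaccard: incompatible numbers of boxes (", na, " vs ", nb, ")")
  }
  iw <- pmin(a[, "x_max"], b[, "x_max"]) - pmax(a[, "x_min"], b[, "x_min"])
  ih <- pmin(a[, "y_max"], b[, "y_max"]) - pmax(a[, "y_min"], b[, "y_min"])
  inter <- pmax(iw, 0) * pmax(ih, 0)
  uni <- box_area(a) + box_area(b) - inter
  unname(inter / uni)
}

#' @rdname jaccard
#' @export
jaccard_matrix <- function(a, b) {
  a <- as_bbox(a); b <- as_bbox(b)
  na <- nrow(a); nb <- nrow(b)
  ix_min <- outer(a[, "x_min"], b[, "x_min"], pmax)
  iy_min <- outer(a[, "y_min"], b[, "y_min"], pmax)
  ix_max <- outer(a[, "x_max"], b[, "x_max"], pmin)
  iy_max <- outer(a[, "y_max"], b[, "y_max"], pmin)
  inter <- pmax(ix_max - ix_min, 0) * pmax(iy_max - iy_min, 0)
  uni <- outer(box_area(a), box_area(b), `+`) - inter
  m <- inter / uni
  dim(m) <- c(na, nb)
  m
}

#' Magnification-level coordinate mapping
#'
#' Slide analysis runs at two pyramid levels: regions of interest are located
#' at low magnification and then analysed at high magnification. A level map
#' records the linear scale between the two levels so boxes can be carried
#' across. ROI polygons from an upstream localizer are expected to arrive
#' already bounding-boxed at the low level.
#'
#' @param scale_x,scale_y High-magnification pixels per low-magnification
#'   pixel along each axis; both must be >= 1.
#' @param level_low,level_high Pyramid level indices (bookkeeping only).
#' @return An object of class \code{"level_map"}.
#' @export
level_map <- function(scale_x, scale_y = scale_x, level_low = 0L, level_high = 1L) {
  if (!is.finite(scale_x) || !is.finite(scale_y) || scale_x < 1 || scale_y < 1) {
    stop("level_map scales must be finite and >= 1")
  }
  structure(list(scale_x = scale_x, scale_y = scale_y,
                 level_low = as.integer(level_low),
                 level_high = as.integer(level_high)),
            class = "level_map")
}

#' Map boxes between magnification levels
#'
#' Multiplies (low to high) or divides (high to low) corner coordinates by
#' the level-map scale factors. With integer scales the round trip
#' low -> high -> low is exact; in general it returns the original box to
#' within one pixel per coordinate. No margin is added around mapped regions.
#'
#' @param box Boxes coercible via \code{\link{as_bbox}}, in source-level
#'   coordinates.
#' @param map A \code{\link{level_map}}.
#' @param direction \code{"low_to_high"} or \code{"high_to_low"}.
#' @return A \code{bbox} matrix in target-level coordinates.
#' @export
map_box <- function(box, map, direction = c("low_to_high", "high_to_low")) {
  direction <- match.arg(direction)
  stopifnot(inherits(map, "level_map"))
  b <- as_bbox(box)
  sx <- map$scale_x; sy <- map$scale_y
  if (direction == "high_to_low") { sx <- 1 / sx; sy <- 1 / sy }
  bbox(b[, "x_min"] * sx, b[, "y_min"] * sy, b[, "x_max"] * sx, b[, "y_max"] * sy)
}

#' Tile an image into unit patches
#'
#' Partitions a w x h image into q x q patches; edge tiles are clipped to the
#' image bounds so the tiles cover the image exactly once and their areas sum
#' to the image area. The same grid feeds augmentation-patch selection and
#' the patch count of the adaptive learning-rate schedule.
#'
#' @param image_width,image_height Image size in pixels.
#' @param tile_side Patch side q in pixels; must satisfy
#'   \code{1 <= q <= min(w, h)}.
#' @return An object of class \code{"tile_grid"}: a list with the grid
#'   dimensions and a \code{tiles} \code{bbox} matrix in row-major order.
#' @examples
#' g <- tile_grid(2000, 2000, 500)
#' nrow(g$tiles) # 16
#' @export
tile_grid <- function(image_width, image_height, tile_side) {
  w <- image_width; h <- image_height; q <- tile_side
  if (q < 1) stop("tile_side must be >= 1")
  if (q > w || q > h) {
    stop("degenerate grid: tile_side exceeds the image (", q, " > ", min(w, h), ")")
  }
  nx <- ceiling(w / q); ny <- ceiling(h / q)
  x0 <- rep((seq_len(nx) - 1L) * q, times = ny)
  y0 <- rep((seq_len(ny) - 1L) * q, each = nx)
  tiles <- bbox(x0, y0, pmin(x0 + q, w), pmin(y0 + q, h))
  structure(list(image_width = w, image_height = h, tile_side = q,
                 n_x = nx, n_y = ny, tiles = tiles),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("tile grid: %d x %d image, %d px tiles, %d x %d = %d tiles\n",
              x$image_width, x$image_height, x$tile_side,
              x$n_x, x$n_y, nrow(x$tiles)))
  invisible(x)
}

#' Convert between corner boxes and COCO-style [x, y, width, height]
#'
#' COCO-style JSON stores boxes as top-left corner plus size; internally the
#' package works in corner form.
#'
#' @param b A \code{bbox} matrix (for \code{bbox_to_coco}) or a numeric
#'   matrix / length-4 vector of \code{[x, y, w, h]} rows (for
#'   \code{coco_to_bbox}).
#' @return The converted representation.
#' @export
bbox_to_coco <- function(b) {
  b <- as_bbox(b)
  cbind(x = b[, "x_min"], y = b[, "y_min"],
        width = b[, "x_max"] - b[, "x_min"],
        height = b[, "y_max"] - b[, "y_min"])
}

#' @rdname bbox_to_coco
#' @export
coco_to_bbox <- function(b) {
  if (is.numeric(b) && is.null(dim(b)) && length(b) == 4L) b <- matrix(b, nrow = 1L)
  bbox(b[, 1L], b[, 2L], b[, 1L] + b[, 3L], b[, 2L] + b[, 4L])
}
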