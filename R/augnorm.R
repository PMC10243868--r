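# Union area of a set of boxes clipped to a window, by coordinate
# compression: the clipped rectangles induce a grid of disjoint cells; a
# cell is covered iff any rectangle covers it. Exact for continuous boxes.
clipped_union_area <- function(boxes, window) {
  b <- as_bbox(boxes); w <- as_bbox(window)
  x0 <- pmax(b[, "x_min"], w[1L, "x_min"]); x1 <- pmin(b[, "x_max"], w[1L, "x_max"])
  y0 <- pmax(b[, "y_min"], w[1L, "y_min"]); y1 <- pmin(b[, "y_max"], w[1L, "y_max"])
  keep <- x0 < x1 & y0 < y1
  if (!any(keep)) return(0)
  x0 <- x0[keep]; x1 <- x1[keep]; y0 <- y0[keep]; y1 <- y1[keep]
  xs <- sort(unique(c(x0, x1))); ys <- sort(unique(c(y0, y1)))
  cw <- diff(xs); ch <- diff(ys)
  covered <- matrix(FALSE, length(cw), length(ch))
  for (i in seq_along(x0)) {
    ix <- which(xs >= x0[i] & xs < x1[i])
    iy <- which(ys >= y0[i] & ys < y1[i])
    covered[ix, iy] <- TRUE
  }
  sum(outer(cw, ch)[covered])
}

#' Positive-area fraction of a patch
#'
#' The augmentation gate: the fraction of a patch's area covered by the
#' union of reference annotation boxes, |h intersect z| / |z|. Patches with
#' a strictly positive fraction contain (part of) at least one labeled cell
#' and are the ones worth augmenting. Annotation boxes (not pixel masks)
#' define the positive region h.
#'
#' @param patch A single box (the patch z), coercible via \code{\link{as_bbox}}.
#' @param annotations Annotation boxes; may be empty (\code{NULL}).
#' @return A ratio in [0, 1]; 0 when there are no annotations.
#' @export
positive_fraction <- function(patch, annotations) {
  p <- as_bbox(patch)
  if (nrow(p) != 1L) stop("positive_fraction expects a single patch box")
  if (is.null(annotations) || (is.matrix(annotations) && nrow(annotations) == 0L)) {
    return(0)
  }
  clipped_union_area(annotations, p) / box_area(p)
}

#' Select tiles for augmentation
#'
#' Evaluates \code{\link{positive_fraction}} on every tile of a grid and
#' marks as selected exactly the tiles whose fraction is > 0.
#'
#' @param grid A \code{\link{tile_grid}} sharing the annotations' frame.
#' @param annotations Annotation boxes (or \code{NULL}).
#' @return A data frame with one row per tile: the tile corners,
#'   \code{positive_fraction} and logical \code{selected}.
#' @export
select_for_augmentation <- function(grid, annotations) {
  stopifnot(inherits(grid, "tile_grid"))
  tiles <- grid$tiles
  pf <- vapply(seq_len(nrow(tiles)), function(i) {
    positive_fraction(tiles[i, , drop = FALSE], annotations)
  }, numeric(1))
  data.frame(tiles[, , drop = FALSE], positive_fraction = pf, selected = pf > 0)
}

#' Augmentation operation set
#'
#' The training-time augmentation recipe: rotated copies at five small 5-degree
#' steps plus the right-angle rotations, horizontal and vertical mirror
#' copies, and photometric jitter with contrast and saturation varied
#' multiplicatively by up to +/-20\% and brightness additively by up to
#' +/-12.5\% on a [0, 1] intensity scale.
#'
#' @param rotation_angles Rotation angles in degrees.
#' @param flips Subset of \code{c("horizontal", "vertical")}.
#' @param contrast_range,saturation_range Half-width of the multiplicative
#'   jitter range (factor drawn uniformly from \code{1 +/- range}); at most 0.2.
#' @param brightness_range Half-width of the additive jitter range; at most
#'   0.125.
#' @param n_jitter Number of photometric-jitter copies to emit (default 3).
#' @param seed Integer seed driving the jitter draws.
#' @return An object of class \code{"augmentation_spec"}.
#' @export
augmentation_spec <- function(rotation_angles = c(5, 10, 15, 20, 25, 90, 180, 270),
                              flips = c("horizontal", "vertical"),
                              contrast_range = 0.2,
                              saturation_range = 0.2,
                              brightness_range = 0.125,
                              n_jitter = 3L,
                              seed = 1L) {
  if (contrast_range < 0 || contrast_range > 0.2) {
    stop("contrast_range must lie in [0, 0.2]")
  }
  if (saturation_range < 0 || saturation_range > 0.2) {
    stop("saturation_range must lie in [0, 0.2]")
  }
  if (brightness_range < 0 || brightness_range > 0.125) {
    stop("brightness_range must lie in [0, 0.125]")
  }
  if (length(flips)) flips <- match.arg(flips, c("horizontal", "vertical"),
                                        several.ok = TRUE)
  structure(list(rotation_angles = rotation_angles, flips = flips,
                 contrast_range = contrast_range,
                 saturation_range = saturation_range,
                 brightness_range = brightness_range,
                 n_jitter = as.integer(n_jitter), seed = as.integer(seed)),
            class = "augmentation_spec")
}

# Run code under a private RNG stream without disturbing global state.
with_private_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

as_image_array <- function(image) {
  if (is.null(dim(image))) stop("image must be a matrix or h x w x c array")
  if (length(dim(image)) == 2L) dim(image) <- c(dim(image), 1L)
  if (any(image < 0 | image > 1)) stop("image channels must lie in [0, 1]")
  image
}

rotate_image <- function(img, angle, bg) {
  out <- lapply(seq_len(dim(img)[3L]), function(k) {
    # EBImage indexes [x, y]; our arrays are [row = y, col = x]
    ch <- EBImage::rotate(t(img[, , k]), angle, bg.col = bg[k])
    t(EBImage::imageData(ch))
  })
  arr <- array(unlist(out), dim = c(dim(out[[1L]]), length(out)))
  pmin(pmax(arr, 0), 1)
}

photometric_jitter <- function(img, fc, fs, db) {
  nc <- dim(img)[3L]
  out <- img
  if (nc == 3L) {
    gray <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    for (k in 1:3) out[, , k] <- gray + fs * (img[, , k] - gray)
  }
  m <- mean(out)
  out <- m + fc * (out - m)
  pmin(pmax(out + db, 0), 1)
}

#' Generate augmented copies of a patch image
#'
#' Emits, independently per operation: one rotated copy per configured
#' angle (corners exposed by non-right-angle rotations are filled with the
#' patch's per-channel median), one copy per configured mirror flip, and
#' \code{n_jitter} photometrically jittered copies with factors drawn
#' uniformly from the spec ranges. All outputs are clipped to [0, 1] and the
#' whole emission is deterministic given the spec seed. With
#' \code{compose = TRUE} the jitter is instead applied on top of every
#' geometric copy (product set).
#'
#' @param image Numeric array \code{h x w x channels} (or matrix) with
#'   values in [0, 1].
#' @param spec An \code{\link{augmentation_spec}}.
#' @param compose Compose photometric jitter with each geometric copy
#'   instead of emitting them independently (default FALSE).
#' @return A named list of image arrays; an identity spec (no angles, no
#'   flips, no jitter) yields a single unchanged copy named
#'   \code{"identity"}.
#' @export
augment <- function(image, spec = augmentation_spec(), compose = FALSE) {
  stopifnot(inherits(spec, "augmentation_spec"))
  img <- as_image_array(image)
  if (length(img) == 0L) stop("empty image")
  bg <- apply(img, 3L, stats::median)
  geo <- list()
  for (a in spec$rotation_angles) {
    geo[[sprintf("rot%03d", as.integer(a))]] <- rotate_image(img, a, bg)
  }
  if ("horizontal" %in% spec$flips) geo[["flip_horizontal"]] <- img[, rev(seq_len(dim(img)[2L])), , drop = FALSE]
  if ("vertical" %in% spec$flips) geo[["flip_vertical"]] <- img[rev(seq_len(dim(img)[1L])), , , drop = FALSE]
  with_private_rng(spec$seed, {
    draw <- function() list(
      fc = stats::runif(1, 1 - spec$contrast_range, 1 + spec$contrast_range),
      fs = stats::runif(1, 1 - spec$saturation_range, 1 + spec$saturation_range),
      db = stats::runif(1, -spec$brightness_range, spec$brightness_range))
    out <- geo
    if (compose) {
      base <- c(list(identity = img), geo)
      out <- list()
      for (nm in names(base)) {
        out[[nm]] <- base[[nm]]
        for (j in seq_len(spec$n_jitter)) {
          d <- draw()
          out[[paste0(nm, "_jitter", j)]] <- photometric_jitter(base[[nm]], d$fc, d$fs, d$db)
        }
      }
    } else {
      for (j in seq_len(spec$n_jitter)) {
        d <- draw()
        out[[paste0("jitter", j)]] <- photometric_jitter(img, d$fc, d$fs, d$db)
      }
    }
    if (!length(out)) out <- list(identity = img)
    out
  })
}

#' Map box corners through an augmentation geometry
#'
#' Applies the same rotation/flip map that \code{\link{augment}} applies to
#' pixels to annotation box corners, so augmented patches keep consistent
#' annotations. Rotation is about the patch centre with the output canvas
#' enlarged to contain the rotated patch (matching the image operation);
#' the transformed box is the axis-aligned hull of the four mapped corners.
#'
#' @param boxes Boxes coercible via \code{\link{as_bbox}}, in patch
#'   coordinates.
#' @param width,height Patch size in pixels.
#' @param op Operation name as emitted by \code{augment()}:
#'   \code{"rotNNN"}, \code{"flip_horizontal"}, \code{"flip_vertical"},
#'   \code{"identity"} or a jitter name (photometric ops leave geometry
#'   unchanged).
#' @return A \code{bbox} matrix in output-canvas coordinates.
#' @export
map_augmented_boxes <- function(boxes, width, height, op) {
  b <- as_bbox(boxes)
  if (op == "flip_horizontal") {
    return(bbox(width - b[, "x_max"], b[, "y_min"], width - b[, "x_min"], b[, "y_max"]))
  }
  if (op == "flip_vertical") {
    return(bbox(b[, "x_min"], height - b[, "y_max"], b[, "x_max"], height - b[, "y_min"]))
  }
  if (grepl("^rot[0-9]+$", op)) {
    theta <- as.numeric(sub("rot", "", op)) * pi / 180
    # clockwise rotation in image coordinates (y down), as the pixel op
    rot <- function(x, y) {
      cbind(x * cos(theta) - y * sin(theta), x * sin(theta) + y * cos(theta))
    }
    cx <- width / 2; cy <- height / 2
    # output canvas: hull of the rotated patch corners
    pc <- rot(c(0, width, width, 0) - cx, c(0, 0, height, height) - cy)
    ox <- -min(pc[, 1]); oy <- -min(pc[, 2])
    out <- t(vapply(seq_len(nrow(b)), function(i) {
      xs <- c(b[i, "x_min"], b[i, "x_max"], b[i, "x_max"], b[i, "x_min"]) - cx
      ys <- c(b[i, "y_min"], b[i, "y_min"], b[i, "y_max"], b[i, "y_max"]) - cy
      p <- rot(xs, ys)
      c(min(p[, 1]) + ox, min(p[, 2]) + oy, max(p[, 1]) + ox, max(p[, 2]) + oy)
    }, numeric(4)))
    return(bbox(pmax(out[, 1], 0), pmax(out[, 2], 0), out[, 3], out[, 4]))
  }
  b  # identity / photometric ops
}

#' Reference intensity distribution for histogram specification
#'
#' A per-channel cumulative distribution over a fixed grid of intensity
#' levels in [0, 1]. \code{fit_reference_histogram()} pools the pixels of
#' one or more images; \code{default_reference_histogram()} loads the
#' packaged synthetic reference, a smooth natural-image-like RGB
#' distribution shipped as a plain-text table (no external image corpus is
#' required or downloaded).
#'
#' @param images A list of image arrays (or a single array), channels in
#'   [0, 1].
#' @param n_levels Number of intensity levels in the grid (default 256).
#' @return An object of class \code{"ref_hist"}: \code{levels} (numeric
#'   vector) and \code{cdf} (levels x channels matrix, non-decreasing,
#'   ending at 1).
#' @export
fit_reference_histogram <- function(images, n_levels = 256L) {
  if (is.array(images) || is.matrix(images)) images <- list(images)
  if (!length(images)) stop("need at least one image")
  images <- lapply(images, as_image_array)
  nc <- dim(images[[1L]])[3L]
  levels <- seq(0, 1, length.out = n_levels)
  cdf <- matrix(0, n_levels, nc)
  for (k in seq_len(nc)) {
    px <- unlist(lapply(images, function(im) as.numeric(im[, , k])))
    # level i collects pixels with value <= levels[i] (bin by nearest level above)
    idx <- findInterval(px, levels, left.open = TRUE) + 1L
    counts <- tabulate(pmin(idx, n_levels), nbins = n_levels)
    cdf[, k] <- cumsum(counts) / length(px)
  }
  structure(list(levels = levels, cdf = cdf, n_channels = nc), class = "ref_hist")
}

#' @rdname fit_reference_histogram
#' @export
default_reference_histogram <- function() {
  path <- system.file("extdata", "reference_cdf_synthetic.csv",
                      package = "cellsieve", mustWork = TRUE)
  read_reference_cdf(path)
}

inv_cdf <- function(u, levels, cdf) {
  # smallest level whose cumulative probability reaches u
  idx <- findInterval(u, cdf, left.open = TRUE) + 1L
  levels[pmin(idx, length(levels))]
}

#' Histogram specification (quantile matching) of an image
#'
#' Color normalization by matching the input's per-channel intensity
#' distribution to a reference distribution: each pixel value x is mapped to
#' the reference quantile at the input's empirical CDF, Q_R(F_S(x)). For a
#' source with many distinct values the output's empirical CDF tracks the
#' reference closely; specifying an image against its own fitted histogram
#' returns it unchanged up to level quantization. A constant channel has no
#' usable CDF and is mapped to the reference median.
#'
#' @param image Image array, channels in [0, 1], channel count matching the
#'   reference.
#' @param ref A \code{"ref_hist"}; defaults to the packaged synthetic
#'   reference.
#' @return The normalized image array, values on the reference level grid.
#' @export
histogram_specify <- function(image, ref = default_reference_histogram()) {
  stopifnot(inherits(ref, "ref_hist"))
  img <- as_image_array(image)
  if (length(img) == 0L) stop("empty image")
  nc <- dim(img)[3L]
  if (nc != ncol(ref$cdf)) stop("channel count mismatch with reference")
  out <- img
  for (k in seq_len(nc)) {
    px <- as.numeric(img[, , k])
    if (max(px) == min(px)) {
      out[, , k] <- inv_cdf(0.5, ref$levels, ref$cdf[, k])
      next
    }
    u <- rank(px, ties.method = "max") / length(px)
    out[, , k] <- inv_cdf(u, ref$levels, ref$cdf[, k])
  }
  out
}

#' Read / write a reference CDF as structured text
#'
#' Serialization of a \code{"ref_hist"} as a plain-text table with columns
#' \code{channel, level, cum}.
#'
#' @param path File path.
#' @param ref A \code{"ref_hist"} object (for writing).
#' @return \code{read_reference_cdf()}: a \code{"ref_hist"};
#'   \code{write_reference_cdf()}: \code{path}, invisibly.
#' @export
read_reference_cdf <- function(path) {
  tab <- utils::read.csv(path)
  stopifnot(all(c("channel", "level", "cum") %in% names(tab)))
  chans <- sort(unique(tab$channel))
  levels <- sort(unique(tab$level))
  cdf <- matrix(0, length(levels), length(chans))
  for (k in seq_along(chans)) {
    sub <- tab[tab$channel == chans[k], ]
    sub <- sub[order(sub$level), ]
    if (!isTRUE(all.equal(sub$level, levels))) stop("channels disagree on level grid")
    if (is.unsorted(sub$cum) || abs(sub$cum[length(levels)] - 1) > 1e-6) {
      stop("invalid reference CDF: must be non-decreasing and end at 1")
    }
    cdf[, k] <- sub$cum
  }
  structure(list(levels = levels, cdf = cdf, n_channels = length(chans)),
            class = "ref_hist")
}

#' @rdname read_reference_cdf
#' @export
write_reference_cdf <- function(ref, path) {
  stopifnot(inherits(ref, "ref_hist"))
  nc <- ncol(ref$cdf)
  tab <- data.frame(channel = rep(seq_len(nc), each = length(ref$levels)),
                    level = rep(ref$levels, nc),
                    cum = as.numeric(ref$cdf))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
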