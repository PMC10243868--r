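#' Specification of a synthetic multi-class cell field
#'
#' The simulator emulates the partially annotated slide setting that the
#' sampling machinery is built for: a textured background carrying K classes
#' of elliptical cells, of which only a fraction 1 - u carries a reference
#' annotation — the remaining u masquerade as background, exactly the
#' contamination that dual-layer negative filtering addresses. Candidate
#' proposals are jittered copies of the true boxes (plus pure-background
#' boxes) with scores correlated to their true overlap, and detections carry
#' class-probability vectors peaked on the true class.
#'
#' @param field_size Side of the square field in pixels (default 512).
#' @param n_classes Number of cell classes K (default 4).
#' @param n_cells Number of true cells (default 40).
#' @param cell_radius_range Min/max cell semi-axis in pixels.
#' @param unlabeled_fraction Fraction u of true cells left unannotated.
#' @param class_mixture Class probabilities (length K, sums to 1).
#' @param max_true_overlap Maximum pairwise Jaccard allowed between true
#'   boxes at placement (default 0.3).
#' @param n_proposals_per_cell Jittered proposals per true cell (default 4).
#' @param n_background_proposals Pure-background proposals (default 20).
#' @param jitter_sd Translation/scale jitter of proposals, as a fraction of
#'   box size (default 0.15).
#' @param score_noise_sd Noise on proposal scores around the overlap
#'   (default 0.1).
#' @param confusion_noise Mass spread off the true class in detection
#'   probability vectors (default 0.1).
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class \code{"field_spec"}.
#' @export
field_spec <- function(field_size = 512L, n_classes = 4L, n_cells = 40L,
                       cell_radius_range = c(8, 20), unlabeled_fraction = 0,
                       class_mixture = NULL, max_true_overlap = 0.3,
                       n_proposals_per_cell = 4L, n_background_proposals = 20L,
                       jitter_sd = 0.15, score_noise_sd = 0.1,
                       confusion_noise = 0.1, seed = 1L) {
  if (is.null(class_mixture)) class_mixture <- rep(1 / n_classes, n_classes)
  if (length(class_mixture) != n_classes ||
      abs(sum(class_mixture) - 1) > 1e-8 || any(class_mixture < 0)) {
    stop("class_mixture must be a length-K probability vector summing to 1")
  }
  if (unlabeled_fraction < 0 || unlabeled_fraction > 1) {
    stop("unlabeled_fraction must lie in [0, 1]")
  }
  if (length(cell_radius_range) != 2L || cell_radius_range[1] > cell_radius_range[2] ||
      cell_radius_range[1] <= 0) {
    stop("cell_radius_range must be an increasing positive pair")
  }
  structure(list(field_size = as.integer(field_size),
                 n_classes = as.integer(n_classes),
                 n_cells = as.integer(n_cells),
                 cell_radius_range = cell_radius_range,
                 unlabeled_fraction = unlabeled_fraction,
                 class_mixture = class_mixture,
                 max_true_overlap = max_true_overlap,
                 n_proposals_per_cell = as.integer(n_proposals_per_cell),
                 n_background_proposals = as.integer(n_background_proposals),
                 jitter_sd = jitter_sd, score_noise_sd = score_noise_sd,
                 confusion_noise = confusion_noise, seed = as.integer(seed)),
            class = "field_spec")
}

# Rejection-sample true cell boxes with bounded pairwise overlap.
place_cells <- function(spec) {
  n <- spec$n_cells
  if (n == 0L) {
    return(list(boxes = NULL, rx = numeric(0), ry = numeric(0),
                class_id = integer(0)))
  }
  fs <- spec$field_size
  rmin <- spec$cell_radius_range[1]; rmax <- spec$cell_radius_range[2]
  out <- matrix(NA_real_, n, 4L)
  rx <- ry <- numeric(n)
  placed <- 0L
  tries <- 0L
  max_tries <- 200L * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("infeasible placement: could not fit ", n, " cells in a ",
           fs, "px field within ", max_tries, " tries")
    }
    a <- stats::runif(1, rmin, rmax); b <- stats::runif(1, rmin, rmax)
    cx <- stats::runif(1, a, fs - a); cy <- stats::runif(1, b, fs - b)
    cand <- c(cx - a, cy - b, cx + a, cy + b)
    if (placed > 0L) {
      ov <- jaccard(matrix(cand, 1L), out[seq_len(placed), , drop = FALSE])
      if (max(ov) >= spec$max_true_overlap) next
    }
    placed <- placed + 1L
    out[placed, ] <- cand
    rx[placed] <- a; ry[placed] <- b
  }
  class_id <- sample.int(spec$n_classes, n, replace = TRUE,
                         prob = spec$class_mixture)
  list(boxes = bbox(out[, 1], out[, 2], out[, 3], out[, 4]),
       rx = rx, ry = ry, class_id = class_id)
}

# Filled-ellipse rendering over a smooth textured background; class sets hue.
render_field <- function(spec, cells) {
  fs <- spec$field_size
  xs <- matrix(rep(seq_len(fs) - 0.5, each = fs), fs)   # column = x
  ys <- matrix(rep(seq_len(fs) - 0.5, times = fs), fs)  # row = y
  base <- 0.82 + 0.06 * sin(xs / 37) * cos(ys / 53) +
    matrix(stats::rnorm(fs * fs, 0, 0.015), fs)
  img <- array(0, dim = c(fs, fs, 3L))
  img[, , 1] <- base; img[, , 2] <- base * 0.96; img[, , 3] <- base * 1.02
  if (spec$n_cells > 0L) {
    hues <- (seq_len(spec$n_classes) - 1) / spec$n_classes
    for (i in seq_len(spec$n_cells)) {
      b <- cells$boxes[i, ]
      cx <- (b["x_min"] + b["x_max"]) / 2; cy <- (b["y_min"] + b["y_max"]) / 2
      inside <- ((xs - cx) / cells$rx[i])^2 + ((ys - cy) / cells$ry[i])^2 <= 1
      col <- grDevices::hsv(hues[cells$class_id[i]], 0.55, 0.65)
      rgbv <- grDevices::col2rgb(col) / 255
      for (k in 1:3) {
        ch <- img[, , k]
        ch[inside] <- rgbv[k]
        img[, , k] <- ch
      }
    }
  }
  pmin(pmax(img, 0), 1)
}

# Jittered proposals around true boxes plus pure-background boxes.
make_proposals <- function(spec, cells) {
  fs <- spec$field_size
  boxes <- list(); src <- integer(0)
  if (spec$n_cells > 0L) {
    for (i in seq_len(spec$n_cells)) {
      b <- cells$boxes[i, ]
      w <- b["x_max"] - b["x_min"]; h <- b["y_max"] - b["y_min"]
      for (j in seq_len(spec$n_proposals_per_cell)) {
        dx <- stats::rnorm(1, 0, spec$jitter_sd * w)
        dy <- stats::rnorm(1, 0, spec$jitter_sd * h)
        sw <- w * exp(stats::rnorm(1, 0, spec$jitter_sd))
        sh <- h * exp(stats::rnorm(1, 0, spec$jitter_sd))
        cx <- (b["x_min"] + b["x_max"]) / 2 + dx
        cy <- (b["y_min"] + b["y_max"]) / 2 + dy
        x0 <- max(0, cx - sw / 2); y0 <- max(0, cy - sh / 2)
        x1 <- min(fs, cx + sw / 2); y1 <- min(fs, cy + sh / 2)
        if (x1 - x0 < 1 || y1 - y0 < 1) next
        boxes[[length(boxes) + 1L]] <- c(x0, y0, x1, y1)
        src <- c(src, i)
      }
    }
  }
  for (j in seq_len(spec$n_background_proposals)) {
    w <- stats::runif(1, spec$cell_radius_range[1], 2 * spec$cell_radius_range[2])
    h <- stats::runif(1, spec$cell_radius_range[1], 2 * spec$cell_radius_range[2])
    x0 <- stats::runif(1, 0, fs - w); y0 <- stats::runif(1, 0, fs - h)
    boxes[[length(boxes) + 1L]] <- c(x0, y0, x0 + w, y0 + h)
    src <- c(src, NA_integer_)
  }
  m <- do.call(rbind, boxes)
  pb <- bbox(m[, 1], m[, 2], m[, 3], m[, 4])
  # ground-truth overlap: against the source true box for jittered
  # proposals, against the best-matching true box for background ones
  true_ov <- if (spec$n_cells > 0L) {
    best <- apply(jaccard_matrix(pb, cells$boxes), 1L, max)
    sourced <- !is.na(src)
    if (any(sourced)) {
      best[sourced] <- jaccard(pb[sourced, , drop = FALSE],
                               cells$boxes[src[sourced], , drop = FALSE])
    }
    best
  } else rep(0, nrow(pb))
  score <- pmin(1, pmax(0, true_ov + stats::rnorm(nrow(pb), 0, spec$score_noise_sd)))
  list(boxes = pb, source = src, score = score, true_overlap = true_ov)
}

make_detections <- function(spec, cells) {
  if (spec$n_cells == 0L) {
    return(detections(matrix(numeric(0), 0, 4), matrix(numeric(0), 0, spec$n_classes)))
  }
  fs <- spec$field_size
  b <- cells$boxes
  n <- nrow(b)
  w <- b[, "x_max"] - b[, "x_min"]; h <- b[, "y_max"] - b[, "y_min"]
  dx <- stats::rnorm(n, 0, 0.05 * w); dy <- stats::rnorm(n, 0, 0.05 * h)
  db <- bbox(pmax(0, b[, "x_min"] + dx), pmax(0, b[, "y_min"] + dy),
             pmin(fs, b[, "x_max"] + dx), pmin(fs, b[, "y_max"] + dy))
  probs <- matrix(0, n, spec$n_classes)
  for (i in seq_len(n)) {
    p <- rep(spec$confusion_noise / max(1L, spec$n_classes - 1L), spec$n_classes)
    p[cells$class_id[i]] <- 1 - spec$confusion_noise
    p <- p + abs(stats::rnorm(spec$n_classes, 0, 0.02))
    probs[i, ] <- p / sum(p) * stats::runif(1, 0.85, 1)
  }
  detections(db, probs)
}

#' Simulate a partially annotated cell field
#'
#' Deterministic given the spec seed. Returns the full ground truth
#' (\code{true_objects}), the observed annotation subset (a fraction
#' 1 - u of the true cells, chosen at random), jittered candidate
#' \code{proposals} whose \code{overlap} column is the Jaccard against the
#' annotated reference only (what a sampler can see) alongside
#' \code{true_overlap} against all true objects, and plausible
#' \code{detections} near the true boxes.
#'
#' @param spec A \code{\link{field_spec}}.
#' @param render Rasterize the field image (default TRUE); the geometric
#'   bookkeeping is independent of rendering.
#' @return An object of class \code{"simulated_field"}: \code{image} (or
#'   NULL), \code{true_objects}, \code{annotations} (an
#'   \code{\link{annotation_set}}), \code{proposals} (a
#'   \code{\link{candidate_set}} with extra columns \code{true_overlap},
#'   \code{source}, \code{matches_unlabeled}), \code{detections} and the
#'   spec itself.
#' @export
simulate_field <- function(spec = field_spec(), render = TRUE) {
  stopifnot(inherits(spec, "field_spec"))
  with_private_rng(spec$seed, {
    cells <- place_cells(spec)
    n <- spec$n_cells
    n_lab <- round((1 - spec$unlabeled_fraction) * n)
    labeled <- if (n > 0L) sort(sample.int(n, n_lab)) else integer(0)
    true_objects <- if (n > 0L) {
      data.frame(cells$boxes[, , drop = FALSE], class_id = cells$class_id,
                 labeled = seq_len(n) %in% labeled)
    } else {
      data.frame(x_min = numeric(0), y_min = numeric(0), x_max = numeric(0),
                 y_max = numeric(0), class_id = integer(0), labeled = logical(0))
    }
    ann <- if (length(labeled)) {
      annotation_set(cells$boxes[labeled, , drop = FALSE],
                     cells$class_id[labeled])
    } else {
      annotation_set(matrix(numeric(0), 0, 4), integer(0))
    }
    pr <- make_proposals(spec, cells)
    ann_boxes <- if (length(labeled)) cells$boxes[labeled, , drop = FALSE] else NULL
    cand <- candidate_set(pr$boxes, pr$score, annotations = ann_boxes)
    cand$true_overlap <- pr$true_overlap
    cand$source <- pr$source
    # does this proposal sit on a true-but-unlabeled object?
    unl <- which(n > 0L & !(seq_len(n) %in% labeled))
    cand$matches_unlabeled <- if (length(unl)) {
      apply(jaccard_matrix(as_bbox(as.matrix(cand[, c("x_min", "y_min", "x_max", "y_max")])),
                           cells$boxes[unl, , drop = FALSE]), 1L, max) >= 0.5
    } else rep(FALSE, nrow(cand))
    dets <- make_detections(spec, cells)
    img <- if (render) render_field(spec, cells) else NULL
    structure(list(image = img, true_objects = true_objects, annotations = ann,
                   proposals = cand, detections = dets, spec = spec),
              class = "simulated_field")
  })
}

#' @export
print.simulated_field <- function(x, ...) {
  cat(sprintf("simulated field: %d px, %d cells (%d annotated), %d proposals, %d detections\n",
              x$spec$field_size, nrow(x$true_objects),
              nrow(x$annotations), nrow(x$proposals),
              n_detections(x$detections)))
  invisible(x)
}

#' Simulate a two-level (low/high magnification) fixture
#'
#' Builds a low-magnification frame containing region-of-interest boxes and,
#' for each ROI, a high-magnification cell field whose frame is the ROI
#' scaled by the level map. Annotations generated at high magnification map
#' back inside their ROI by construction, which is the contract the
#' coordinate-mapping plumbing has to satisfy.
#'
#' @param spec A \code{\link{field_spec}} for each high-magnification crop;
#'   its \code{field_size} is taken as the ROI side at low magnification
#'   times \code{scale}.
#' @param roi_layout ROI boxes at low magnification, coercible via
#'   \code{\link{as_bbox}}; overlapping ROIs are permitted with a warning.
#' @param scale Linear scale factor between levels (default 4).
#' @return An object of class \code{"two_level_fixture"}: \code{map} (a
#'   \code{\link{level_map}}), \code{rois}, and per-ROI \code{crops}, each a
#'   \code{\link{simulate_field}} result plus the ROI it belongs to.
#' @export
simulate_two_level <- function(spec = field_spec(), roi_layout, scale = 4) {
  rois <- as_bbox(roi_layout)
  if (nrow(rois) > 1L) {
    jm <- jaccard_matrix(rois, rois)
    diag(jm) <- 0
    if (any(jm > 0)) warning("overlapping ROIs in layout")
  }
  m <- level_map(scale)
  crops <- vector("list", nrow(rois))
  for (r in seq_len(nrow(rois))) {
    side_hi <- round(min(rois[r, "x_max"] - rois[r, "x_min"],
                         rois[r, "y_max"] - rois[r, "y_min"]) * scale)
    sp <- spec
    sp$field_size <- as.integer(side_hi)
    sp$seed <- spec$seed + r - 1L
    crops[[r]] <- list(roi = rois[r, , drop = FALSE],
                       field = simulate_field(sp, render = FALSE))
  }
  structure(list(map = m, rois = rois, crops = crops),
            class = "two_level_fixture")
}
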