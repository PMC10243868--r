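#' Reference annotation set
#'
#' Annotations couple a reference-standard box with a single class label
#' (and optionally the annotator who produced it).
#'
#' @param boxes Annotation boxes, coercible via \code{\link{as_bbox}}.
#' @param class_id Integer class labels, one per box.
#' @param annotator Optional annotator identifiers.
#' @return A data frame of class \code{"annotation_set"} with the box
#'   corners, \code{class_id} and \code{annotator}.
#' @export
annotation_set <- function(boxes, class_id, annotator = NA_character_) {
  b <- as_bbox(boxes)
  class_id <- rep_len(as.integer(class_id), nrow(b))
  out <- data.frame(b[, , drop = FALSE], class_id = class_id,
                    annotator = rep_len(annotator, nrow(b)))
  class(out) <- c("annotation_set", class(out))
  out
}

# Greedy one-to-one matching in descending detection-score order. Each
# detection claims the unmatched annotation of maximal Jaccard >= thr
# (optionally restricted to its own predicted class).
greedy_match <- function(dets, ann, iou_threshold, class_required) {
  nd <- n_detections(dets); na <- nrow(ann)
  pairs <- data.frame(detection = integer(0), annotation = integer(0),
                      iou = numeric(0), ref_class = integer(0),
                      pred_class = integer(0))
  if (nd == 0L || na == 0L) return(pairs)
  jm <- jaccard_matrix(dets$boxes, as_bbox(as.matrix(ann[, c("x_min", "y_min", "x_max", "y_max")])))
  taken <- rep(FALSE, na)
  ord <- order(-dets$score, seq_len(nd))
  for (i in ord) {
    ov <- jm[i, ]
    ov[taken] <- -1
    if (class_required) ov[ann$class_id != dets$class_id[i]] <- -1
    j <- which.max(ov)
    if (ov[j] >= iou_threshold) {
      taken[j] <- TRUE
      pairs <- rbind(pairs, data.frame(detection = i, annotation = j,
                                       iou = jm[i, j],
                                       ref_class = ann$class_id[j],
                                       pred_class = dets$class_id[i]))
    }
  }
  pairs
}

match_counts <- function(pairs, dets, ann, classes, mode) {
  tp <- fp <- fn <- integer(length(classes))
  names(tp) <- names(fp) <- names(fn) <- classes
  for (k in seq_along(classes)) {
    cl <- classes[k]
    if (mode == "classification") {
      # a hit counts for class cl only when reference and prediction agree on cl
      tp[k] <- sum(pairs$ref_class == cl & pairs$pred_class == cl)
    } else {
      tp[k] <- sum(pairs$ref_class == cl)
    }
    fn[k] <- sum(ann$class_id == cl) - tp[k]
    pred_cl <- sum(dets$class_id == cl)
    matched_pred_cl <- if (mode == "classification") {
      sum(pairs$pred_class == cl & pairs$ref_class == cl)
    } else {
      sum(pairs$pred_class == cl)
    }
    fp[k] <- pred_cl - matched_pred_cl
  }
  data.frame(class_id = classes, tp = tp, fp = fp, fn = fn, row.names = NULL)
}

#' Match detections against reference annotations
#'
#' Greedy one-to-one matching by descending detection score at a Jaccard
#' threshold: each detection claims the unmatched annotation it overlaps
#' best, provided the overlap reaches the threshold; later (lower-scoring)
#' detections on an already-claimed annotation become false positives. Two
#' matching regimes are evaluated side by side: class-agnostic ("detection"
#' metrics — was the cell found at all) and class-required ("classification"
#' metrics — was it found and given the right type).
#'
#' @param dets A \code{\link{detections}} object (typically post-suppression).
#' @param annotations An \code{\link{annotation_set}}.
#' @param iou_threshold Matching threshold in (0, 1]; default 0.5.
#' @return An object of class \code{"match_result"}: \code{pairs}
#'   (class-agnostic matched pairs with reference and predicted class),
#'   \code{detection} and \code{classification} per-class TP/FP/FN tables,
#'   plus the inputs' class universe.
#' @export
match_detections <- function(dets, annotations, iou_threshold = 0.5) {
  stopifnot(inherits(dets, "detections"))
  if (iou_threshold <= 0 || iou_threshold > 1) {
    stop("iou_threshold must lie in (0, 1]")
  }
  ann <- annotations
  classes <- sort(unique(c(ann$class_id, dets$class_id)))
  pairs_any <- greedy_match(dets, ann, iou_threshold, class_required = FALSE)
  pairs_cls <- greedy_match(dets, ann, iou_threshold, class_required = TRUE)
  structure(list(pairs = pairs_any,
                 pairs_class_required = pairs_cls,
                 detection = match_counts(pairs_any, dets, ann, classes, "detection"),
                 classification = match_counts(pairs_cls, dets, ann, classes, "classification"),
                 classes = classes,
                 n_annotations = nrow(ann),
                 n_detections = n_detections(dets),
                 iou_threshold = iou_threshold),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match at IoU >= %.2f: %d detections vs %d annotations, %d matched\n",
              x$iou_threshold, x$n_detections, x$n_annotations, nrow(x$pairs)))
  invisible(x)
}

#' Recall, precision, F1 and accuracy from a match result
#'
#' Per class: recall = TP/(TP+FN), precision = TP/(TP+FP), F1 their harmonic
#' mean. Accuracy is (TP+TN)/total under a one-vs-rest reading over the
#' candidate universe of all resolved instances (matched pairs, missed
#' annotations and unmatched detections); the universe convention is a
#' documented interpretation, since detection benchmarks do not define a true
#' negative. Zero-denominator cells are NA and excluded from the macro
#' averages.
#'
#' @param match A \code{\link{match_detections}} result.
#' @param mode \code{"detection"} (class-agnostic matching) or
#'   \code{"classification"} (class-required).
#' @return A data frame with one row per class plus an \code{"average"} row:
#'   columns \code{class_id, tp, fp, fn, recall, precision, f1, accuracy}.
#' @export
detection_metrics <- function(match, mode = c("detection", "classification")) {
  mode <- match.arg(mode)
  stopifnot(inherits(match, "match_result"))
  tab <- match[[mode]]
  total <- match$n_annotations +
    (match$n_detections - nrow(if (mode == "detection") match$pairs else match$pairs_class_required))
  rec <- ifelse(tab$tp + tab$fn > 0, tab$tp / (tab$tp + tab$fn), NA_real_)
  prec <- ifelse(tab$tp + tab$fp > 0, tab$tp / (tab$tp + tab$fp), NA_real_)
  f1 <- ifelse(!is.na(rec) & !is.na(prec) & (rec + prec) > 0,
               2 * rec * prec / (rec + prec), NA_real_)
  tn <- total - tab$tp - tab$fp - tab$fn
  acc <- ifelse(total > 0, (tab$tp + tn) / total, NA_real_)
  out <- data.frame(class_id = as.character(tab$class_id), tp = tab$tp,
                    fp = tab$fp, fn = tab$fn, recall = rec,
                    precision = prec, f1 = f1, accuracy = acc)
  avg <- data.frame(class_id = "average", tp = sum(tab$tp), fp = sum(tab$fp),
                    fn = sum(tab$fn),
                    recall = mean(rec, na.rm = TRUE),
                    precision = mean(prec, na.rm = TRUE),
                    f1 = mean(f1, na.rm = TRUE),
                    accuracy = mean(acc, na.rm = TRUE))
  rbind(out, avg)
}

#' Confusion matrix over matched pairs
#'
#' Cross-tabulates reference class (rows) against predicted class (columns)
#' over the class-agnostic matched pairs — agnostic matching is what lets a
#' cell found under the wrong type land off the diagonal. Rows are
#' normalized to percentages by default.
#'
#' @param match A \code{\link{match_detections}} result.
#' @param normalize \code{"row"} (percentages per reference class),
#'   \code{"none"} (raw counts).
#' @return A numeric matrix, reference classes x predicted classes; empty
#'   (0 x 0) when there are no matched pairs.
#' @export
confusion_matrix <- function(match, normalize = c("row", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(match, "match_result"))
  pairs <- match$pairs
  if (!nrow(pairs)) return(matrix(numeric(0), 0, 0))
  lev <- match$classes
  m <- table(factor(pairs$ref_class, levels = lev),
             factor(pairs$pred_class, levels = lev))
  m <- unclass(m)
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  if (normalize == "row") m <- 100 * m / rowSums(m)
  m
}

#' Cohen's kappa with conventional interpretation bands
#'
#' Chance-corrected agreement between two raters over the same items:
#' kappa = (p_o - p_e) / (1 - p_e), with observed agreement p_o and expected
#' agreement p_e from the raters' marginal products. The value is mapped to
#' the conventional bands: below 0.20 poor, 0.21-0.40 fair, 0.41-0.60
#' moderate, 0.61-0.80 good and 0.81-1.00 excellent. When both raters are
#' constant and identical p_e = 1 and kappa is returned as 1 with a warning.
#'
#' @param labels_a,labels_b Paired categorical sequences of equal length
#'   (>= 1).
#' @return An object of class \code{"cohen_kappa"}: \code{kappa},
#'   \code{p_observed}, \code{p_expected}, \code{band} and \code{n}.
#' @examples
#' cohen_kappa(rep(c("x", "y"), c(25, 25)),
#'             rep(c("x", "y", "x", "y"), c(20, 5, 10, 15)))
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("label sequences must have equal length")
  n <- length(labels_a)
  if (n < 1) stop("need at least one paired label")
  lev <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  tab <- table(factor(labels_a, levels = lev), factor(labels_b, levels = lev))
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (isTRUE(all.equal(p_e, 1))) {
    warning("both raters constant and identical: expected agreement is 1; kappa defined as 1")
    k <- 1
  } else {
    k <- (p_o - p_e) / (1 - p_e)
  }
  structure(list(kappa = k, p_observed = p_o, p_expected = p_e,
                 band = kappa_band(k), n = n, table = tab),
            class = "cohen_kappa")
}

#' @rdname cohen_kappa
#' @param kappa A kappa value in [-1, 1].
#' @return \code{kappa_band()}: one of \code{"poor"}, \code{"fair"},
#'   \code{"moderate"}, \code{"good"}, \code{"excellent"}.
#' @export
kappa_band <- function(kappa) {
  stopifnot(is.finite(kappa))
  if (kappa <= 0.20) "poor"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "good"
  else "excellent"
}

#' @export
print.cohen_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (%s agreement), p_o = %.3f, p_e = %.3f, n = %d\n",
              x$kappa, x$band, x$p_observed, x$p_expected, x$n))
  invisible(x)
}

#' Nucleated differential cell count report
#'
#' Turns classified detections (typically the kept set after multi-class
#' suppression) into the diagnostic readout of a marrow smear: per-type
#' counts and percentages among counted cells. Following the standard
#' adequacy rule, a differential is flagged adequate only when at least 500
#' cells were counted. Non-countable categories (e.g. megakaryocytes) can be
#' excluded before percentages are formed.
#'
#' @param x A \code{\link{detections}} object, or a named vector / table of
#'   per-class counts.
#' @param categories Optional names for the class indices.
#' @param exclude Class labels to drop before counting.
#' @param min_cells Adequacy threshold (default 500 cells).
#' @return An object of class \code{"ndc_report"}: \code{counts},
#'   \code{percentages} (summing to 100 when any cell was counted),
#'   \code{total} and \code{adequate}.
#' @export
ndc_report <- function(x, categories = NULL, exclude = NULL, min_cells = 500L) {
  counts <- if (inherits(x, "detections")) {
    tab <- table(x$class_id)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(as.integer(x), names(x))
  }
  if (!is.null(categories)) {
    names(counts) <- categories[as.integer(names(counts))]
  }
  if (!is.null(exclude)) counts <- counts[!(names(counts) %in% exclude)]
  total <- sum(counts)
  pct <- if (total > 0) 100 * counts / total else stats::setNames(numeric(0), character(0))
  structure(list(counts = counts, percentages = pct, total = total,
                 adequate = total >= min_cells, min_cells = min_cells),
            class = "ndc_report")
}

#' @export
print.ndc_report <- function(x, ...) {
  cat(sprintf("differential count: %d cells (%s; rule: >= %d)\n", x$total,
              if (x$adequate) "adequate" else "INADEQUATE", x$min_cells))
  if (length(x$percentages)) {
    for (nm in names(x$percentages)) {
      cat(sprintf("  %-24s %6d  %6.2f%%\n", nm, x$counts[[nm]], x$percentages[[nm]]))
    }
  }
  invisible(x)
}

#' Precision-recall curve and its area
#'
#' Ranks detections by score, matches them greedily (class-agnostic) at the
#' IoU threshold, and accumulates precision and recall along the ranking.
#' The area is computed under the interpolated curve (precision replaced by
#' its running maximum from the right), the usual detection-benchmark
#' convention; the averaging scheme is a documented convention of this
#' package.
#'
#' @inheritParams match_detections
#' @return A list with \code{curve} (data frame: score, recall, precision)
#'   and \code{auc}.
#' @export
pr_auc <- function(dets, annotations, iou_threshold = 0.5) {
  stopifnot(inherits(dets, "detections"))
  ann <- annotations
  nd <- n_detections(dets)
  if (nd == 0L || nrow(ann) == 0L) {
    return(list(curve = data.frame(score = numeric(0), recall = numeric(0),
                                   precision = numeric(0)), auc = 0))
  }
  jm <- jaccard_matrix(dets$boxes, as_bbox(as.matrix(ann[, c("x_min", "y_min", "x_max", "y_max")])))
  ord <- order(-dets$score, seq_len(nd))
  taken <- rep(FALSE, nrow(ann))
  is_tp <- logical(nd)
  for (r in seq_along(ord)) {
    i <- ord[r]
    ov <- jm[i, ]; ov[taken] <- -1
    j <- which.max(ov)
    if (ov[j] >= iou_threshold) { taken[j] <- TRUE; is_tp[r] <- TRUE }
  }
  cum_tp <- cumsum(is_tp)
  rec <- cum_tp / nrow(ann)
  prec <- cum_tp / seq_len(nd)
  interp <- rev(cummax(rev(prec)))
  auc <- sum(diff(c(0, rec)) * interp)
  list(curve = data.frame(score = dets$score[ord], recall = rec, precision = prec),
       auc = auc)
}
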