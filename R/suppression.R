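#' Detection set with per-class probability vectors
#'
#' A detection couples a box with a probability vector over the K cell
#' classes; its predicted class is the argmax and its score the argmax
#' probability. Suppression works on the argmax class and score only, while
#' the full probability vectors are carried through for downstream
#' reporting.
#'
#' @param boxes Detection boxes, coercible via \code{\link{as_bbox}}.
#' @param probs Numeric matrix, one row per detection, one column per class;
#'   entries in [0, 1]. A numeric vector is taken as single-class scores.
#' @return An object of class \code{"detections"}: a list with \code{boxes}
#'   (bbox matrix), \code{probs}, \code{class_id} (argmax, lowest index on
#'   ties) and \code{score}.
#' @export
detections <- function(boxes, probs) {
  b <- as_bbox(boxes)
  if (is.null(dim(probs))) probs <- matrix(as.numeric(probs), ncol = 1L)
  probs <- as.matrix(probs)
  if (nrow(probs) != nrow(b)) stop("need one probability row per box")
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1)) {
    stop("class probabilities must lie in [0, 1]")
  }
  structure(list(boxes = b, probs = probs,
                 class_id = if (nrow(probs)) max.col(probs, ties.method = "first") else integer(0),
                 score = if (nrow(probs)) apply(probs, 1L, max) else numeric(0)),
            class = "detections")
}

#' @export
print.detections <- function(x, ...) {
  cat(sprintf("%d detections over %d classes (scores %.3f..%.3f)\n",
              n_detections(x), ncol(x$probs),
              if (n_detections(x)) min(x$score) else NA,
              if (n_detections(x)) max(x$score) else NA))
  invisible(x)
}

#' @rdname detections
#' @param x A \code{detections} object.
#' @export
n_detections <- function(x) nrow(x$boxes)

subset_detections <- function(x, i) {
  structure(list(boxes = x$boxes[i, , drop = FALSE],
                 probs = x$probs[i, , drop = FALSE],
                 class_id = x$class_id[i], score = x$score[i]),
            class = "detections")
}

#' Classification-confidence thresholding
#'
#' Keeps the detections whose argmax-class probability meets the
#' classification threshold (score >= varrho, boundary inclusive). This is
#' the per-class initial output pooled over classes; it precedes either form
#' of non-maximum suppression.
#'
#' @param dets A \code{\link{detections}} object.
#' @param varrho Classification threshold in [0, 1]; default 0.5.
#' @return A \code{detections} object with the surviving subset, carrying an
#'   attribute \code{"kept_index"} with the original row indices.
#' @export
threshold_detections <- function(dets, varrho = 0.5) {
  stopifnot(inherits(dets, "detections"))
  if (varrho < 0 || varrho > 1) stop("varrho must lie in [0, 1]")
  keep <- which(dets$score >= varrho)
  out <- subset_detections(dets, keep)
  attr(out, "kept_index") <- keep
  out
}

# Greedy NMS core: process in descending score (ties by input index), keep a
# detection unless it overlaps an already-kept member of its conflict group
# at Jaccard >= eta. `group` defines conflicts: per-class for SCNMS,
# a single group for MCNMS.
greedy_nms <- function(dets, eta, group) {
  n <- n_detections(dets)
  ord <- order(-dets$score, seq_len(n))
  kept <- integer(0)
  suppressor <- rep(NA_integer_, n)
  for (i in ord) {
    rivals <- kept[group[kept] == group[i]]
    if (length(rivals)) {
      ov <- jaccard(dets$boxes[rep(i, length(rivals)), , drop = FALSE],
                    dets$boxes[rivals, , drop = FALSE])
      hit <- which(ov >= eta)
      if (length(hit)) {
        suppressor[i] <- rivals[hit[1L]]
        next
      }
    }
    kept <- c(kept, i)
  }
  kept <- sort(kept)
  structure(list(kept = subset_detections(dets, kept),
                 kept_index = kept,
                 suppressed = data.frame(index = which(!is.na(suppressor)),
                                         suppressor = suppressor[!is.na(suppressor)])),
            class = "suppression_result")
}

#' @export
print.suppression_result <- function(x, ...) {
  cat(sprintf("suppression: kept %d, suppressed %d\n",
              length(x$kept_index), nrow(x$suppressed)))
  invisible(x)
}

#' Single-class non-maximum suppression (SCNMS)
#'
#' Suppresses detections within each class independently: greedy selection
#' in descending score order, pruning any detection whose Jaccard overlap
#' with an already-kept detection of the same class reaches eta. Detections
#' of different classes never suppress each other, so a single cell can
#' survive with several contradictory class labels — the failure mode that
#' \code{\link{mcnms}} removes.
#'
#' @param dets A \code{\link{detections}} object, already thresholded.
#' @param eta Overlap-suppression threshold in [0, 1]; default 0.3.
#' @return An object of class \code{"suppression_result"}: \code{kept}
#'   (a \code{detections} subset), \code{kept_index} (original indices) and
#'   \code{suppressed} (a data frame of suppressed index / suppressor index
#'   pairs).
#' @export
scnms <- function(dets, eta = 0.3) {
  stopifnot(inherits(dets, "detections"))
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]")
  greedy_nms(dets, eta, group = dets$class_id)
}

#' Multi-class non-maximum suppression (MCNMS)
#'
#' A single greedy pass over all classes jointly: detections are visited in
#' descending score order and pruned if they overlap any already-kept
#' detection at Jaccard >= eta, regardless of class. Consequently no two
#' kept boxes overlap at eta or more, so no cell can carry two contradictory
#' class predictions. The kept set is always a subset of the SCNMS kept set
#' at the same eta.
#'
#' @inheritParams scnms
#' @return A \code{"suppression_result"}; see \code{\link{scnms}}.
#' @export
mcnms <- function(dets, eta = 0.3) {
  stopifnot(inherits(dets, "detections"))
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]")
  greedy_nms(dets, eta, group = rep(1L, n_detections(dets)))
}

#' Brute-force suppression oracle
#'
#' Independent reference implementation used to validate the greedy
#' suppressors in tests: repeatedly extracts the highest-scoring remaining
#' detection (globally for multi-class mode, within the surviving pool with
#' same-class conflicts for single-class mode), keeps it, and deletes every
#' remaining detection that conflicts with it. Ties on score are resolved
#' toward the lower input index, matching the stable ordering of the greedy
#' implementations. Guarded to small instances.
#'
#' @inheritParams scnms
#' @param mode \code{"single_class"} (per-class conflicts) or
#'   \code{"multi_class"} (all classes conflict).
#' @param max_n Combinatorial guard on instance size (default 12).
#' @return A \code{"suppression_result"}; see \code{\link{scnms}}.
#' @export
brute_force_suppression <- function(dets, eta = 0.3,
                                    mode = c("single_class", "multi_class"),
                                    max_n = 12L) {
  mode <- match.arg(mode)
  stopifnot(inherits(dets, "detections"))
  n <- n_detections(dets)
  if (n > max_n) stop("brute-force oracle refused: ", n, " > ", max_n, " detections")
  alive <- rep(TRUE, n)
  kept <- integer(0)
  suppressor <- rep(NA_integer_, n)
  while (any(alive)) {
    pool <- which(alive)
    best <- pool[order(-dets$score[pool], pool)[1L]]
    kept <- c(kept, best)
    alive[best] <- FALSE
    others <- which(alive)
    if (length(others)) {
      conflict <- if (mode == "single_class") {
        dets$class_id[others] == dets$class_id[best]
      } else rep(TRUE, length(others))
      if (any(conflict)) {
        cand <- others[conflict]
        ov <- jaccard(dets$boxes[rep(best, length(cand)), , drop = FALSE],
                      dets$boxes[cand, , drop = FALSE])
        gone <- cand[ov >= eta]
        alive[gone] <- FALSE
        suppressor[gone] <- best
      }
    }
  }
  kept <- sort(kept)
  structure(list(kept = subset_detections(dets, kept),
                 kept_index = kept,
                 suppressed = data.frame(index = which(!is.na(suppressor)),
                                         suppressor = suppressor[!is.na(suppressor)])),
            class = "suppression_result")
}
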