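#' Cascade stage plan
#'
#' A multi-stage detector trains one sample classifier per stage against an
#' increasing overlap threshold: stage z uses phi_z = phi_1 + (z - 1) * rho.
#' The plan also carries the ignored-instance threshold phi_i of the
#' dual-layer negative filter. Defaults are the operating point used
#' throughout the package: phi_1 = 0.5, rho = 0.1, three stages, phi_i = 0.1.
#'
#' @param phi1 First-stage overlap threshold, in (0, 1).
#' @param rho Per-stage threshold increment (>= 0).
#' @param n_stages Number of cascade stages Z (>= 1).
#' @param phi_ignore Ignored-class threshold phi_i, in [0, phi1).
#' @return An object of class \code{"stage_plan"}.
#' @examples
#' stage_thresholds(stage_plan()) # 0.5 0.6 0.7
#' @export
stage_plan <- function(phi1 = 0.5, rho = 0.1, n_stages = 3L, phi_ignore = 0.1) {
  if (phi1 <= 0 || phi1 >= 1) stop("phi1 must lie in (0, 1)")
  if (rho < 0) stop("rho must be >= 0")
  if (n_stages < 1) stop("need at least one stage")
  if (phi_ignore < 0 || phi_ignore >= phi1) stop("phi_ignore must lie in [0, phi1)")
  thr <- phi1 + (seq_len(n_stages) - 1) * rho
  if (any(thr >= 1)) {
    stop(sprintf("derived stage threshold %.3f >= 1; reduce rho or n_stages", max(thr)))
  }
  structure(list(phi1 = phi1, rho = rho, n_stages = as.integer(n_stages),
                 phi_ignore = phi_ignore),
            class = "stage_plan")
}

#' @export
print.stage_plan <- function(x, ...) {
  cat(sprintf("cascade plan: %d stages, thresholds %s, ignore below %.3g\n",
              x$n_stages, paste(format(stage_thresholds(x)), collapse = ", "),
              x$phi_ignore))
  invisible(x)
}

#' @rdname stage_plan
#' @param plan A \code{stage_plan}.
#' @return \code{stage_thresholds()}: the numeric vector
#'   \code{phi_1, phi_1 + rho, ..., phi_1 + (Z-1) rho}.
#' @export
stage_thresholds <- function(plan) {
  stopifnot(inherits(plan, "stage_plan"))
  plan$phi1 + (seq_len(plan$n_stages) - 1) * plan$rho
}

#' Candidate proposals with reference overlaps
#'
#' A candidate is a proposal box plus an objectness score and its Jaccard
#' overlap against the best-matching reference annotation. When annotation
#' boxes are supplied the overlap is computed here: each candidate takes its
#' maximum Jaccard over all annotations regardless of class (ties broken by
#' the lowest annotation index); with no annotations at all the overlap is 0,
#' which is exactly the failure mode of partial labeling that the dual-layer
#' filter addresses.
#'
#' @param boxes Candidate boxes, coercible via \code{\link{as_bbox}}.
#' @param scores Objectness/class scores in [0, 1], one per box.
#' @param annotations Optional annotation boxes used to compute overlaps.
#' @param overlaps Optional precomputed overlaps (used as-is when
#'   \code{annotations} is NULL).
#' @return A data frame of class \code{"candidate_set"} with columns
#'   \code{x_min, y_min, x_max, y_max, score, overlap, matched_annotation}.
#' @export
candidate_set <- function(boxes, scores, annotations = NULL, overlaps = NULL) {
  b <- as_bbox(boxes)
  n <- nrow(b)
  scores <- rep_len(as.numeric(scores), n)
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  matched <- rep(NA_integer_, n)
  if (!is.null(annotations)) {
    ann <- as_bbox(annotations)
    jm <- jaccard_matrix(b, ann)
    overlaps <- apply(jm, 1L, max)
    matched <- apply(jm, 1L, which.max)  # which.max takes the lowest index on ties
    matched[overlaps == 0] <- NA_integer_
  } else if (is.null(overlaps)) {
    overlaps <- rep(0, n)
  }
  overlaps <- rep_len(as.numeric(overlaps), n)
  if (any(overlaps < 0 | overlaps > 1)) stop("overlaps must lie in [0, 1]")
  out <- data.frame(b[, , drop = FALSE], score = scores, overlap = overlaps,
                    matched_annotation = matched)
  class(out) <- c("candidate_set", class(out))
  out
}

#' Stage-wise positive/negative partition
#'
#' At stage z a candidate is positive iff its reference overlap meets the
#' stage threshold (overlap >= phi_z, boundary inclusive); everything else is
#' negative. The partition is exhaustive and disjoint, and because the
#' thresholds increase with z, the positive set can only shrink from one
#' stage to the next.
#'
#' @param candidates A \code{\link{candidate_set}} (or compatible data frame
#'   with an \code{overlap} column).
#' @param plan A \code{\link{stage_plan}}.
#' @param stage Stage index z in \code{1..n_stages}.
#' @return A list with data frames \code{positives} and \code{negatives}.
#' @export
partition_stage <- function(candidates, plan, stage) {
  stopifnot(inherits(plan, "stage_plan"))
  if (stage < 1 || stage > plan$n_stages) {
    stop("stage must lie in 1..", plan$n_stages)
  }
  phi_z <- stage_thresholds(plan)[stage]
  pos <- candidates$overlap >= phi_z
  list(positives = candidates[pos, , drop = FALSE],
       negatives = candidates[!pos, , drop = FALSE])
}

#' Dual-layer negative refinement (final-stage ignored class)
#'
#' Under partial annotation, unlabeled true cells sit among the negatives
#' with near-zero recorded overlap and would poison training as false
#' background. The second filtering layer splits the final-stage negatives:
#' those with overlap >= phi_i are kept as refined negatives (genuinely hard
#' background near a labeled cell), while those below phi_i are moved to an
#' ignored class that contributes nothing to training. By construction this
#' is applied to the last cascade stage only; \code{stage} exists for
#' ablation studies.
#'
#' @param negatives Data frame of candidates already labeled negative at the
#'   final stage (from \code{\link{partition_stage}}).
#' @param plan A \code{\link{stage_plan}}.
#' @return A list with data frames \code{refined_negatives} and
#'   \code{ignored}; together they partition the input.
#' @export
refine_negatives <- function(negatives, plan) {
  stopifnot(inherits(plan, "stage_plan"))
  keep <- negatives$overlap >= plan$phi_ignore
  list(refined_negatives = negatives[keep, , drop = FALSE],
       ignored = negatives[!keep, , drop = FALSE])
}

#' Soft-sampling attention weights
#'
#' Rather than discarding background proposals, soft sampling lets every
#' candidate contribute to the loss with an attention weight that reflects
#' its reliability: positives (overlap >= phi_1) get weight 1; everything
#' else gets a weight in (0, 1] from a pluggable function of (overlap,
#' score). The default ramps linearly from a floor \code{w_min} at zero
#' overlap up to 1 at phi_1,
#' \code{w = min(1, w_min + (1 - w_min) * overlap / phi_1)},
#' which is monotone in overlap and keeps even pure background contributing
#' weakly. Weights are emitted for consumption by an external trainer.
#'
#' @param candidates A \code{\link{candidate_set}}.
#' @param plan A \code{\link{stage_plan}} (supplies phi_1).
#' @param weight_fn Optional \code{function(overlap, score)} returning
#'   weights in (0, 1]; vectorized over its arguments.
#' @param w_min Floor weight of the default ramp, in (0, 1].
#' @return Numeric vector of weights, one per candidate.
#' @export
soft_weights <- function(candidates, plan, weight_fn = NULL, w_min = 0.1) {
  stopifnot(inherits(plan, "stage_plan"))
  if (is.null(weight_fn)) {
    if (w_min <= 0 || w_min > 1) stop("w_min must lie in (0, 1]")
    weight_fn <- function(overlap, score) {
      pmin(1, w_min + (1 - w_min) * overlap / plan$phi1)
    }
  }
  w <- rep(1, nrow(candidates))
  bg <- candidates$overlap < plan$phi1
  if (any(bg)) {
    wf <- weight_fn(candidates$overlap[bg], candidates$score[bg])
    wf <- rep_len(as.numeric(wf), sum(bg))
    if (any(!is.finite(wf) | wf <= 0 | wf > 1)) {
      stop("weight_fn must return weights in (0, 1] for every non-ignored sample")
    }
    w[bg] <- wf
  }
  w
}

#' Full cascade sample assignment
#'
#' Runs the stage partition at every stage, the dual-layer negative
#' refinement at the final stage (or, for ablation, at all stages), and the
#' soft-sampling weights, returning one long assignment table. Labels are
#' \code{positive}, \code{negative}, \code{refined_negative} and
#' \code{ignored}; ignored samples carry weight 0, every other label a
#' positive weight.
#'
#' @inheritParams soft_weights
#' @param refine_all_stages Apply the ignored-class filter at every stage
#'   instead of only the last (ablation switch; default FALSE).
#' @return A data frame of class \code{"sample_assignment"}: the candidate
#'   columns plus \code{candidate} (input row index), \code{stage},
#'   \code{label} (factor) and \code{weight}.
#' @export
assign_samples <- function(candidates, plan, weight_fn = NULL, w_min = 0.1,
                           refine_all_stages = FALSE) {
  stopifnot(inherits(plan, "stage_plan"))
  n <- nrow(candidates)
  base_w <- soft_weights(candidates, plan, weight_fn, w_min)
  thr <- stage_thresholds(plan)
  lv <- c("positive", "negative", "refined_negative", "ignored")
  out <- vector("list", plan$n_stages)
  for (z in seq_len(plan$n_stages)) {
    lab <- ifelse(candidates$overlap >= thr[z], "positive", "negative")
    if (refine_all_stages || z == plan$n_stages) {
      neg <- lab == "negative"
      lab[neg & candidates$overlap >= plan$phi_ignore] <- "refined_negative"
      lab[neg & candidates$overlap < plan$phi_ignore] <- "ignored"
    }
    w <- base_w
    w[lab == "positive"] <- 1
    w[lab == "ignored"] <- 0
    df <- candidates
    df$candidate <- seq_len(n)
    df$stage <- z
    df$label <- factor(lab, levels = lv)
    df$weight <- w
    out[[z]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("sample_assignment", "data.frame")
  res
}
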