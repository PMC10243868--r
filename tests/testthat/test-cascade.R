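test_that("stage thresholds follow the arithmetic progression and bound check", {
  expect_equal(stage_thresholds(stage_plan(0.5, 0.1, 3)), c(0.5, 0.6, 0.7))
  expect_equal(stage_thresholds(stage_plan(0.5, 0, 3)), c(0.5, 0.5, 0.5))
  expect_error(stage_plan(0.7, 0.2, 3), ">= 1")
  expect_error(stage_plan(phi_ignore = 0.6), "phi_ignore")
})

test_that("stage partition is threshold-inclusive, exhaustive and disjoint", {
  plan <- stage_plan()
  cand <- candidate_set(bbox(c(0, 20, 40), c(0, 0, 0), c(10, 30, 50), c(10, 10, 10)),
                        scores = c(0.9, 0.8, 0.7),
                        overlaps = c(0.65, 0.5, 0.3))
  p1 <- partition_stage(cand, plan, 1)
  expect_equal(p1$positives$overlap, c(0.65, 0.5))  # 0.5 boundary is positive
  p2 <- partition_stage(cand, plan, 2)
  expect_equal(p2$positives$overlap, 0.65)
  p3 <- partition_stage(cand, plan, 3)
  expect_equal(nrow(p3$positives), 0)
  expect_equal(nrow(p3$negatives), 3)
  empty <- candidate_set(matrix(numeric(0), 0, 4), numeric(0))
  pe <- partition_stage(empty, plan, 1)
  expect_equal(nrow(pe$positives) + nrow(pe$negatives), 0)
  expect_error(partition_stage(cand, plan, 4), "stage")
})

test_that("negative refinement keeps the phi_i boundary and splits exactly", {
  plan <- stage_plan()
  neg <- candidate_set(bbox(c(0, 20, 40), c(0, 0, 0), c(10, 30, 50), c(10, 10, 10)),
                       scores = 0.5, overlaps = c(0.15, 0.05, 0.1))
  r <- refine_negatives(neg, plan)
  expect_equal(sort(r$refined_negatives$overlap), c(0.1, 0.15))
  expect_equal(r$ignored$overlap, 0.05)
  expect_equal(nrow(r$refined_negatives) + nrow(r$ignored), nrow(neg))
})

test_that("soft weights give positives 1, a floor at zero overlap, and reject bad fns", {
  plan <- stage_plan()
  cand <- candidate_set(bbox(c(0, 20, 40), c(0, 0, 0), c(10, 30, 50), c(10, 10, 10)),
                        scores = 0.5, overlaps = c(0.7, 0.25, 0))
  w <- soft_weights(cand, plan)
  expect_equal(w[1], 1)
  expect_equal(w[3], 0.1)                      # configured floor at zero overlap
  expect_equal(w[2], 0.1 + 0.9 * 0.25 / 0.5)   # linear ramp toward phi1
  allpos <- candidate_set(bbox(0, 0, 10, 10), 0.9, overlaps = 0.8)
  expect_equal(soft_weights(allpos, plan), 1)
  expect_error(soft_weights(cand, plan, weight_fn = function(o, s) o * 0),
               "weight_fn")
  # default is monotone non-decreasing in overlap
  ov <- seq(0, 0.49, by = 0.01)
  cmon <- candidate_set(bbox(ov * 0 + 1, 1, ov * 0 + 11, 11), 0.5, overlaps = ov)
  expect_true(all(diff(soft_weights(cmon, plan)) >= 0))
})

test_that("partition and refinement laws hold on randomized candidate sets", {
  plan <- stage_plan()
  set.seed(99)
  for (i in 1:30) {
    n <- sample(1:60, 1)
    cand <- candidate_set(bbox(runif(n, 0, 50), runif(n, 0, 50),
                               runif(n, 51, 100), runif(n, 51, 100)),
                          scores = runif(n), overlaps = round(runif(n), 2))
    prev_pos <- NULL
    for (z in 1:3) {
      p <- partition_stage(cand, plan, z)
      # exhaustive and disjoint
      expect_equal(nrow(p$positives) + nrow(p$negatives), n)
      expect_length(intersect(rownames(p$positives), rownames(p$negatives)), 0)
      # positives shrink monotonically across stages
      if (!is.null(prev_pos)) {
        expect_true(all(rownames(p$positives) %in% prev_pos))
      }
      prev_pos <- rownames(p$positives)
    }
    r <- refine_negatives(partition_stage(cand, plan, 3)$negatives, plan)
    expect_equal(nrow(r$refined_negatives) + nrow(r$ignored),
                 nrow(partition_stage(cand, plan, 3)$negatives))
  }
})

test_that("assign_samples emits consistent labels and weights per stage", {
  plan <- stage_plan()
  set.seed(21)
  f <- simulate_field(field_spec(seed = 21, unlabeled_fraction = 0.2), render = FALSE)
  a <- assign_samples(f$proposals, plan)
  expect_equal(nrow(a), 3 * nrow(f$proposals))
  expect_true(all(a$weight[a$label == "positive"] == 1))
  expect_true(all(a$weight[a$label == "ignored"] == 0))
  expect_true(all(a$weight[a$label %in% c("negative", "refined_negative")] > 0))
  # ignored only exists at the final stage by default
  expect_true(all(a$stage[a$label == "ignored"] == 3))
  expect_true(all(a$overlap[a$label == "ignored"] < plan$phi_ignore))
  # labels agree with the threshold rule at each stage
  thr <- stage_thresholds(plan)
  for (z in 1:3) {
    sz <- a[a$stage == z, ]
    expect_identical(sz$label == "positive", sz$overlap >= thr[z])
  }
})

test_that("with full annotation the ignored pool is true background", {
  f <- simulate_field(field_spec(seed = 5, unlabeled_fraction = 0), render = FALSE)
  plan <- stage_plan()
  neg <- partition_stage(f$proposals, plan, 3)$negatives
  ig <- refine_negatives(neg, plan)$ignored
  expect_gt(nrow(ig), 0)
  expect_false(any(ig$matches_unlabeled))
  # none of the ignored candidates sits on any true object
  tru <- as_bbox(as.matrix(f$true_objects[, c("x_min", "y_min", "x_max", "y_max")]))
  igb <- as_bbox(as.matrix(ig[, c("x_min", "y_min", "x_max", "y_max")]))
  expect_lt(max(jaccard_matrix(igb, tru)), 0.5)
})

test_that("dual-layer filtering reduces unlabeled-object contamination", {
  plan <- stage_plan()
  for (u in c(0.2, 0.5)) {
    naive_hits <- naive_tot <- refined_hits <- refined_tot <- 0
    for (s in 1:50) {
      f <- simulate_field(field_spec(seed = 1000 + s, unlabeled_fraction = u),
                          render = FALSE)
      neg <- partition_stage(f$proposals, plan, 3)$negatives
      ref <- refine_negatives(neg, plan)$refined_negatives
      naive_hits <- naive_hits + sum(neg$matches_unlabeled)
      naive_tot <- naive_tot + nrow(neg)
      refined_hits <- refined_hits + sum(ref$matches_unlabeled)
      refined_tot <- refined_tot + nrow(ref)
    }
    expect_lt(refined_hits / refined_tot, naive_hits / naive_tot)
  }
})
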