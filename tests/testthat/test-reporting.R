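test_that("matching covers the exact-hit, false-positive and one-to-one cases", {
  ann <- annotation_set(bbox(0, 0, 10, 10), 1L)
  hit <- detections(bbox(0, 0, 10, 10), matrix(0.9, 1, 1))
  m <- match_detections(hit, ann)
  expect_equal(m$detection$tp, 1)
  met <- detection_metrics(m)
  expect_equal(met$recall[met$class_id == "1"], 1)
  expect_equal(met$precision[met$class_id == "1"], 1)

  miss <- detections(bbox(50, 50, 60, 60), matrix(0.9, 1, 1))
  m2 <- match_detections(miss, ann)
  expect_equal(m2$detection$fp, 1)
  expect_equal(m2$detection$fn, 1)

  # two detections on one annotation: the higher score claims it, 1 TP + 1 FP
  double <- detections(bbox(c(0, 1), c(0, 1), c(10, 11), c(10, 11)),
                       matrix(c(0.9, 0.8), 2, 1))
  m3 <- match_detections(double, ann)
  expect_equal(m3$detection$tp, 1)
  expect_equal(m3$detection$fp, 1)
  expect_equal(m3$pairs$detection, 1L)
  expect_error(match_detections(hit, ann, iou_threshold = 0), "iou_threshold")
})

test_that("metric arithmetic and degenerate columns", {
  ann <- annotation_set(bbox(seq(0, 160, by = 40), 0, seq(10, 170, by = 40), 10), 1L)
  # 3 TP (on annotations 1..3), 1 FP (far away), 2 FN (annotations 4..5 unmatched)
  d <- detections(bbox(c(0, 40, 80, 300), c(0, 0, 0, 300),
                       c(10, 50, 90, 310), c(10, 10, 10, 310)),
                  matrix(0.9, 4, 1))
  m <- match_detections(d, ann)
  met <- detection_metrics(m)
  r1 <- met[met$class_id == "1", ]
  expect_equal(r1$recall, 0.6)
  expect_equal(r1$precision, 0.75)
  expect_equal(r1$f1, 2 / 3)

  # no detections at all: recall 0, precision undefined (NA)
  none <- detections(matrix(numeric(0), 0, 4), matrix(numeric(0), 0, 1))
  m0 <- match_detections(none, ann)
  met0 <- detection_metrics(m0)
  expect_equal(met0$recall[met0$class_id == "1"], 0)
  expect_true(is.na(met0$precision[met0$class_id == "1"]))
})

test_that("self-match metrics are exactly one", {
  f <- simulate_field(field_spec(seed = 4), render = FALSE)
  ann <- f$annotations
  self <- detections(as_bbox(as.matrix(ann[, c("x_min", "y_min", "x_max", "y_max")])),
                     {
                       k <- max(ann$class_id)
                       p <- matrix(0.05, nrow(ann), k)
                       p[cbind(seq_len(nrow(ann)), ann$class_id)] <- 0.95
                       p
                     })
  met <- detection_metrics(match_detections(self, ann), mode = "classification")
  avg <- met[met$class_id == "average", ]
  expect_equal(avg$recall, 1)
  expect_equal(avg$precision, 1)
  expect_equal(avg$f1, 1)
  expect_equal(avg$accuracy, 1)
})

test_that("confusion matrices are row-normalized over matched pairs", {
  ann <- annotation_set(bbox(c(0, 40, 80), c(0, 0, 0), c(10, 50, 90), c(10, 10, 10)),
                        c(1L, 1L, 1L))
  # predictions: A, A, B on the three reference-A cells
  probs <- rbind(c(0.9, 0.1), c(0.9, 0.1), c(0.1, 0.9))
  d <- detections(bbox(c(0, 40, 80), c(0, 0, 0), c(10, 50, 90), c(10, 10, 10)), probs)
  cm <- confusion_matrix(match_detections(d, ann))
  expect_equal(as.numeric(cm["1", ]), c(200 / 3, 100 / 3))

  # perfect agreement: 100 on the diagonal
  dp <- detections(bbox(c(0, 40), c(0, 0), c(10, 50), c(10, 10)),
                   rbind(c(0.9, 0.1), c(0.1, 0.9)))
  annp <- annotation_set(bbox(c(0, 40), c(0, 0), c(10, 50), c(10, 10)), c(1L, 2L))
  cmp <- confusion_matrix(match_detections(dp, annp))
  expect_equal(unname(diag(cmp)), c(100, 100))

  # a single cross-class pair lands fully off-diagonal
  d1 <- detections(bbox(0, 0, 10, 10), matrix(c(0.1, 0.9), 1, 2))
  a1 <- annotation_set(bbox(0, 0, 10, 10), 1L)
  cm1 <- confusion_matrix(match_detections(d1, a1))
  expect_equal(cm1["1", "2"], 100)
  expect_equal(cm1["1", "1"], 0)

  empty <- confusion_matrix(match_detections(
    detections(matrix(numeric(0), 0, 4), matrix(numeric(0), 0, 1)), a1))
  expect_equal(dim(empty), c(0L, 0L))
})

test_that("kappa reproduces the hand-computed 2x2 table and the printed bands", {
  a <- rep(c("x", "y"), c(25, 25))
  b <- rep(c("x", "y", "x", "y"), c(20, 5, 10, 15))  # table [[20,5],[10,15]]
  k <- cohen_kappa(a, b)
  expect_equal(k$p_observed, 0.7)
  expect_equal(k$p_expected, 0.5)
  expect_equal(k$kappa, 0.4)
  expect_equal(k$band, "fair")
  expect_equal(kappa_band(0.8), "good")
  expect_equal(kappa_band(0.81), "excellent")
  expect_equal(kappa_band(0.15), "poor")
  expect_equal(kappa_band(0.5), "moderate")
  ident <- cohen_kappa(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(ident$kappa, 1)
  expect_equal(ident$band, "excellent")
  expect_warning(kc <- cohen_kappa(rep("a", 5), rep("a", 5)), "constant")
  expect_equal(kc$kappa, 1)
  expect_error(cohen_kappa(1:3, 1:4), "equal length")
})

test_that("kappa agrees with an independent implementation and is label-invariant", {
  skip_if_not_installed("e1071")
  set.seed(123)
  a <- sample(1:4, 400, replace = TRUE)
  b <- ifelse(runif(400) < 0.6, a, sample(1:4, 400, replace = TRUE))
  k <- cohen_kappa(a, b)
  ext <- e1071::classAgreement(table(a, b))$kappa
  expect_equal(k$kappa, ext, tolerance = 1e-12)
  # invariance under category relabeling
  perm <- c(3L, 1L, 4L, 2L)
  k2 <- cohen_kappa(perm[a], perm[b])
  expect_equal(k2$kappa, k$kappa)
})

test_that("kappa of independently shuffled labels is near zero", {
  set.seed(99)
  a <- sample(1:5, 10000, replace = TRUE)
  b <- sample(1:5, 10000, replace = TRUE)
  expect_lt(abs(cohen_kappa(a, b)$kappa), 0.05)
})

test_that("differential count percentages, adequacy rule and exclusions", {
  r <- ndc_report(c(A = 300, B = 200))
  expect_equal(unname(r$percentages), c(60, 40))
  expect_true(r$adequate)  # 500 cells is the inclusive boundary
  expect_equal(sum(r$percentages), 100)

  r499 <- ndc_report(c(A = 499))
  expect_false(r499$adequate)

  r0 <- ndc_report(integer(0))
  expect_false(r0$adequate)
  expect_length(r0$percentages, 0)

  rex <- ndc_report(c(blast = 400, megakaryocyte = 50, lymphocyte = 200),
                    exclude = "megakaryocyte")
  expect_equal(rex$total, 600)
  expect_equal(sum(rex$percentages), 100)
  expect_false("megakaryocyte" %in% names(rex$percentages))
})

test_that("ndc_report consumes classified detections", {
  f <- simulate_field(field_spec(seed = 2, n_cells = 30), render = FALSE)
  kept <- mcnms(threshold_detections(f$detections, 0.5), 0.3)$kept
  r <- ndc_report(kept, categories = paste0("type", 1:4))
  expect_equal(r$total, n_detections(kept))
  expect_equal(sum(r$percentages), 100)
  expect_false(r$adequate)  # far fewer than 500 cells in one field
})

test_that("precision-recall area is 1 for perfect ranking and 0 for misses", {
  ann <- annotation_set(bbox(c(0, 40), c(0, 0), c(10, 50), c(10, 10)), c(1L, 1L))
  perfect <- detections(bbox(c(0, 40), c(0, 0), c(10, 50), c(10, 10)),
                        matrix(c(0.9, 0.8), 2, 1))
  expect_equal(pr_auc(perfect, ann)$auc, 1)
  off <- detections(bbox(100, 100, 110, 110), matrix(0.9, 1, 1))
  expect_equal(pr_auc(off, ann)$auc, 0)
  # a false positive ranked above a true positive halves the interpolated area
  mixed <- detections(bbox(c(100, 0), c(100, 0), c(110, 10), c(110, 10)),
                      matrix(c(0.9, 0.8), 2, 1))
  expect_equal(pr_auc(mixed, ann)$auc, 0.25)
})
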