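test_that("positive fraction covers containment, disjoint and partial cases", {
  patch <- bbox(0, 0, 100, 100)
  expect_equal(positive_fraction(patch, bbox(0, 0, 100, 100)), 1)
  expect_equal(positive_fraction(patch, NULL), 0)
  expect_equal(positive_fraction(patch, bbox(200, 200, 250, 250)), 0)
  expect_equal(positive_fraction(patch, bbox(0, 0, 50, 100)), 0.5)
  # overlapping annotations are a union, not a sum
  expect_equal(positive_fraction(patch, bbox(c(0, 25), c(0, 0), c(50, 75), c(100, 100))),
               0.75)
  # annotation spilling out of the patch is clipped
  expect_equal(positive_fraction(bbox(0, 0, 10, 10), bbox(5, 0, 50, 50)), 0.5)
})

test_that("positive fraction is monotone under annotation growth", {
  set.seed(13)
  patch <- bbox(0, 0, 64, 64)
  anns <- NULL
  prev <- 0
  for (i in 1:10) {
    nb <- random_int_box(max_side = 30, origin_max = 50)
    anns <- rbind(anns, nb)
    cur <- positive_fraction(patch, bbox(anns[, 1], anns[, 2], anns[, 3], anns[, 4]))
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("tiles are selected exactly when they contain annotated area", {
  g <- tile_grid(100, 100, 50)
  none <- select_for_augmentation(g, NULL)
  expect_false(any(none$selected))
  # one annotation straddling the two left tiles
  sel <- select_for_augmentation(g, bbox(10, 30, 20, 70))
  expect_equal(sel$selected, c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(sel$selected, sel$positive_fraction > 0)
})

test_that("augment emits the configured operation set deterministically", {
  set.seed(1)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  spec <- augmentation_spec(seed = 9)
  out <- augment(img, spec)
  expect_named(out, c("rot005", "rot010", "rot015", "rot020", "rot025",
                      "rot090", "rot180", "rot270",
                      "flip_horizontal", "flip_vertical",
                      "jitter1", "jitter2", "jitter3"))
  out2 <- augment(img, spec)
  expect_identical(out, out2)  # bit-identical under the same seed
  expect_true(all(vapply(out, function(x) all(x >= 0 & x <= 1), logical(1))))
  # flips are exact coordinate reversals
  expect_identical(out$flip_horizontal, img[, 32:1, , drop = FALSE])
  expect_identical(out$flip_vertical, img[32:1, , , drop = FALSE])
  # right-angle rotation preserves content (two quarter turns = 180)
  expect_equal(dim(out$rot090), c(32, 32, 3))
})

test_that("identity augmentation spec yields one unchanged copy", {
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  spec <- augmentation_spec(rotation_angles = numeric(0), flips = character(0),
                            contrast_range = 0, saturation_range = 0,
                            brightness_range = 0, n_jitter = 0L)
  out <- augment(img, spec)
  expect_named(out, "identity")
  expect_identical(out$identity, img)
  expect_error(augmentation_spec(contrast_range = 0.5), "contrast_range")
  expect_error(augmentation_spec(brightness_range = 0.2), "brightness_range")
})

test_that("box corners follow the augmentation geometry and stay in bounds", {
  w <- 40; h <- 40
  b <- bbox(c(5, 20), c(8, 25), c(15, 30), c(18, 38))
  fh <- map_augmented_boxes(b, w, h, "flip_horizontal")
  expect_equal(unclass(fh)[1, ], c(x_min = 25, y_min = 8, x_max = 35, y_max = 18))
  fv <- map_augmented_boxes(b, w, h, "flip_vertical")
  expect_equal(unclass(fv)[1, ], c(x_min = 5, y_min = 22, x_max = 15, y_max = 32))
  r180 <- map_augmented_boxes(b, w, h, "rot180")
  expect_equal(unclass(r180)[1, ], c(x_min = 25, y_min = 22, x_max = 35, y_max = 32))
  for (op in c("rot005", "rot025", "rot090", "rot270")) {
    mb <- map_augmented_boxes(b, w, h, op)
    theta <- as.numeric(sub("rot", "", op)) * pi / 180
    canvas <- w * abs(cos(theta)) + h * abs(sin(theta))
    expect_true(all(mb[, c("x_min", "x_max")] >= -1e-9 &
                    mb[, c("x_min", "x_max")] <= canvas + 1e-9))
    expect_true(all(mb[, c("y_min", "y_max")] >= -1e-9 &
                    mb[, c("y_min", "y_max")] <= canvas + 1e-9))
  }
  # photometric ops leave geometry untouched
  expect_identical(map_augmented_boxes(b, w, h, "jitter1"), b)
})

test_that("reference histograms pool pixels into a valid CDF", {
  gray <- array(0.5, c(4, 4, 1))
  ref <- fit_reference_histogram(gray)
  expect_equal(max(ref$cdf), 1)
  expect_true(all(diff(ref$cdf[, 1]) >= 0))
  # step CDF: zero below the gray level, one at and above it
  expect_equal(ref$cdf[ref$levels < 0.5 - 1e-9, 1], rep(0, sum(ref$levels < 0.5 - 1e-9)))
  expect_equal(ref$cdf[ref$levels >= 0.5, 1], rep(1, sum(ref$levels >= 0.5)))
  # two images with disjoint ranges: two rises with a flat plateau between
  lo <- array(c(0.1, 0.15, 0.2, 0.12), c(2, 2, 1))
  hi <- array(c(0.8, 0.85, 0.9, 0.82), c(2, 2, 1))
  ref2 <- fit_reference_histogram(list(lo, hi))
  mid <- ref2$levels > 0.2 & ref2$levels < 0.8
  expect_equal(unique(ref2$cdf[mid, 1]), 0.5)
  expect_equal(ref2$cdf[length(ref2$levels), 1], 1)
  expect_error(fit_reference_histogram(list()), "at least one image")
})

test_that("histogram specification matches the reference distribution", {
  set.seed(8)
  img <- array(runif(128 * 128 * 3), c(128, 128, 3))
  ref <- default_reference_histogram()
  out <- histogram_specify(img, ref)
  for (k in 1:3) {
    ks <- max(abs(ecdf(out[, , k])(ref$levels) - ref$cdf[, k]))
    expect_lte(ks, 0.02)
  }
})

test_that("self-specification is the identity up to quantization", {
  set.seed(9)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  ref <- fit_reference_histogram(img)
  out <- histogram_specify(img, ref)
  expect_lt(max(abs(out - img)), 1 / 255 + 1e-9)
})

test_that("degenerate inputs: constant image maps to the reference median", {
  ref <- default_reference_histogram()
  const <- array(0.3, c(8, 8, 3))
  out <- histogram_specify(const, ref)
  for (k in 1:3) {
    med <- ref$levels[min(which(ref$cdf[, k] >= 0.5))]
    expect_true(all(out[, , k] == med))
  }
})

test_that("a uniform ramp specified to a uniform reference is preserved", {
  ramp <- array(rep(seq(0, 1, length.out = 256), 4), c(256, 4, 1))
  uniform_ref <- structure(list(levels = seq(0, 1, length.out = 256),
                                cdf = matrix(seq(0, 1, length.out = 256), 256, 1),
                                n_channels = 1L),
                           class = "ref_hist")
  out <- histogram_specify(ramp, uniform_ref)
  expect_lt(max(abs(out - ramp)), 1 / 100)
})
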