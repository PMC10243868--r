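# Independent pixel-enumeration Jaccard oracle for integer boxes: under the
# half-open convention a box contains the integer pixel centres
# {x_min..x_max-1} x {y_min..y_max-1}; membership is counted by explicit
# set enumeration, independent of the continuous-geometry implementation.
pixel_jaccard <- function(a, b) {
  keys <- function(bx) {
    g <- expand.grid(x = seq(bx[1], bx[3] - 1), y = seq(bx[2], bx[4] - 1))
    paste(g$x, g$y)
  }
  ka <- keys(a); kb <- keys(b)
  length(intersect(ka, kb)) / length(unique(c(ka, kb)))
}

random_int_box <- function(max_side = 50, origin_max = 60) {
  x0 <- sample(0:origin_max, 1); y0 <- sample(0:origin_max, 1)
  c(x0, y0, x0 + sample(1:max_side, 1), y0 + sample(1:max_side, 1))
}

# Random detection instances for suppression tests: coarse probability
# grids make score ties common, exercising the stable tie-break.
random_detections <- function(n, n_classes = 3, extent = 60, side = 5:20,
                              coarse = TRUE) {
  boxes <- t(replicate(n, {
    x0 <- runif(1, 0, extent); y0 <- runif(1, 0, extent)
    c(x0, y0, x0 + sample(side, 1), y0 + sample(side, 1))
  }))
  probs <- matrix(runif(n * n_classes), n, n_classes)
  if (coarse) probs <- round(probs, 1)
  detections(bbox(boxes[, 1], boxes[, 2], boxes[, 3], boxes[, 4]), probs)
}

expect_same_suppression <- function(fast, oracle) {
  expect_identical(fast$kept_index, oracle$kept_index)
}
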