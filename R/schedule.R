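#' Adaptive, data-oriented learning-rate schedule
#'
#' Instead of dropping the learning rate at fixed iteration milestones, the
#' adaptive schedule ties the step length to the amount of training data:
#' with I images of size w x h tiled into q x q unit patches, the training
#' set holds N = I * ceil(w/q) * ceil(h/q) patches (data augmentation
#' excluded), and the multiplier decreases by alpha after every
#' \code{step_size} iterations, where by default
#' \code{step_size = N / alpha}. With alpha = 0.1 the schedule thus spends
#' ten passes-worth of patches at each of the ten multiplier plateaus
#' before reaching zero. The rendered form of the step-size formula is
#' ambiguous between dividing and multiplying by alpha; the division reading
#' (long, data-proportional decay) is the default and the other is available
#' via \code{interpretation = "times_alpha"}.
#'
#' @param n_images Number of training images I.
#' @param image_width,image_height Image size w, h in pixels.
#' @param patch_side Unit patch side q in pixels; non-divisible sizes use
#'   ceiling division, consistent with \code{\link{tile_grid}}.
#' @param alpha Step fraction in (0, 1]; default 0.1.
#' @param interpretation \code{"inverse_alpha"} (default,
#'   \code{step = N / alpha}) or \code{"times_alpha"}
#'   (\code{step = N * alpha}).
#' @return An object of class \code{"schedule_plan"} with \code{n_patches}
#'   and derived \code{step_size}.
#' @examples
#' p <- schedule_plan(10, 2000, 2000, 500)
#' p$n_patches                 # 160
#' lr_multiplier(1600, p)      # 0.9
#' @export
schedule_plan <- function(n_images, image_width, image_height, patch_side,
                          alpha = 0.1,
                          interpretation = c("inverse_alpha", "times_alpha")) {
  interpretation <- match.arg(interpretation)
  vals <- c(n_images, image_width, image_height, patch_side)
  if (any(!is.finite(vals) | vals <= 0)) stop("all schedule inputs must be positive")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  n_patches <- n_images * ceiling(image_width / patch_side) *
    ceiling(image_height / patch_side)
  step <- if (interpretation == "inverse_alpha") n_patches / alpha else n_patches * alpha
  if (step <= 0) stop("derived step size must be positive")
  structure(list(n_images = n_images, image_width = image_width,
                 image_height = image_height, patch_side = patch_side,
                 alpha = alpha, interpretation = interpretation,
                 n_patches = n_patches, step_size = step),
            class = "schedule_plan")
}

#' @export
print.schedule_plan <- function(x, ...) {
  cat(sprintf("adaptive schedule: %g patches (%g images), alpha = %g, step = %g iterations\n",
              x$n_patches, x$n_images, x$alpha, x$step_size))
  invisible(x)
}

#' Learning-rate multiplier at an iteration
#'
#' The multiplier is \code{max(0, 1 - floor(iteration / step) * alpha)}:
#' piecewise constant, starting at 1, dropping by exactly alpha at each
#' multiple of the step size, and clamped at 0 once the (finitely many)
#' plateaus are exhausted.
#'
#' @param iteration Iteration count(s) Lambda, >= 0; vectorized.
#' @param plan A \code{\link{schedule_plan}}, or a numeric step size (in
#'   which case supply \code{alpha}).
#' @param alpha Step fraction, only used when \code{plan} is numeric.
#' @return Multiplier(s) in [0, 1].
#' @export
lr_multiplier <- function(iteration, plan, alpha = 0.1) {
  if (inherits(plan, "schedule_plan")) {
    step <- plan$step_size; alpha <- plan$alpha
  } else {
    step <- plan
  }
  if (any(iteration < 0)) stop("iteration must be >= 0")
  pmax(0, 1 - floor(iteration / step) * alpha)
}

#' Tabulate a schedule
#'
#' @param plan A \code{\link{schedule_plan}} or a fixed-step baseline from
#'   \code{\link{fixed_step_schedule}}.
#' @param iterations Iterations at which to evaluate; defaults to one point
#'   per plateau boundary up to exhaustion for adaptive plans.
#' @return A data frame with columns \code{iteration} and \code{multiplier}.
#' @export
schedule_table <- function(plan, iterations = NULL) {
  if (inherits(plan, "schedule_plan")) {
    if (is.null(iterations)) {
      n_steps <- ceiling(1 / plan$alpha)
      iterations <- round(seq(0, plan$step_size * (n_steps + 1), by = plan$step_size))
    }
    data.frame(iteration = iterations, multiplier = lr_multiplier(iterations, plan))
  } else if (inherits(plan, "fixed_step_schedule")) {
    if (is.null(iterations)) iterations <- sort(c(0, plan$milestones, plan$milestones + 1))
    data.frame(iteration = iterations,
               multiplier = vapply(iterations, function(it) {
                 plan$factor ^ sum(it >= plan$milestones)
               }, numeric(1)))
  } else stop("unknown schedule plan")
}

#' Fixed-milestone baseline schedule
#'
#' The conventional cascade-detector schedule used as a contrast fixture:
#' the learning rate is reduced by a fixed fraction at preset iteration
#' milestones (by default 10\% at 160k and 240k iterations), regardless of
#' dataset size.
#'
#' @param milestones Iterations at which the rate is reduced.
#' @param reduction Fractional reduction applied at each milestone
#'   (multiplier scales by \code{1 - reduction}).
#' @return An object of class \code{"fixed_step_schedule"}.
#' @export
fixed_step_schedule <- function(milestones = c(160000, 240000), reduction = 0.1) {
  if (reduction <= 0 || reduction >= 1) stop("reduction must lie in (0, 1)")
  structure(list(milestones = sort(milestones), factor = 1 - reduction),
            class = "fixed_step_schedule")
}
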