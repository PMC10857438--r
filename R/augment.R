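#' Specify a stochastic augmentation for contrastive view generation
#'
#' Five single-transform augmentations are supported: `scaling`
#' (channel-wise multiplicative factors ~ Normal(1, sigma)), `inverting`
#' (sign flip with probability 0.5 per window), `reversing` (time-axis
#' reversal), `random_noise` (elementwise additive Normal(0, sigma)
#' jitter) and `time_warp` (smooth monotone re-timing of the time axis
#' through a random warp curve with linear interpolation back onto the
#' original grid). The default, scaling with sigma 0.1, is the transform
#' that performs best for ambient-sensor windows in both linear-probe and
#' fine-tuning evaluations.
#'
#' @param name One of `"scaling"`, `"inverting"`, `"reversing"`,
#'   `"random_noise"`, `"time_warp"`.
#' @param magnitude Transform strength: sigma for scaling/noise, warp
#'   strength for time_warp; ignored by inverting/reversing.
#' @param n_knots Interior knots of the time-warp curve.
#' @return An `augmentation_spec` object.
#' @export
augmentation_spec <- function(name = c("scaling", "inverting", "reversing",
                                       "random_noise", "time_warp"),
                              magnitude = 0.1, n_knots = 4L) {
  name <- match.arg(name)
  stopifnot(magnitude >= 0)
  structure(list(name = name, magnitude = magnitude, n_knots = as.integer(n_knots)),
            class = "augmentation_spec")
}

#' Apply an augmentation to a batch of windows
#'
#' @param x Array `(batch, timesteps, features)`.
#' @param spec An [augmentation_spec()].
#' @return Transformed array of identical shape.
#' @export
apply_augmentation <- function(x, spec) {
  stopifnot(inherits(spec, "augmentation_spec"), length(dim(x)) == 3L)
  switch(spec$name,
    scaling = augment_scaling(x, spec$magnitude),
    inverting = augment_inverting(x),
    reversing = augment_reversing(x),
    random_noise = augment_random_noise(x, spec$magnitude),
    time_warp = augment_time_warp(x, spec$magnitude, spec$n_knots)
  )
}

#' @rdname apply_augmentation
#' @param sigma Standard deviation of the multiplicative factors
#'   (mean 1); one factor per window and feature channel, shared across
#'   timesteps.
#' @export
augment_scaling <- function(x, sigma) {
  d <- dim(x)
  if (sigma == 0) return(x)
  factors <- matrix(stats::rnorm(d[1] * d[3], mean = 1, sd = sigma), d[1], d[3])
  x * aperm(array(factors, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
}

#' @rdname apply_augmentation
#' @export
augment_inverting <- function(x) {
  d <- dim(x)
  flip <- stats::runif(d[1]) < 0.5
  sign <- ifelse(flip, -1, 1)
  x * array(sign, dim = d)
}

#' @rdname apply_augmentation
#' @export
augment_reversing <- function(x) {
  x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
}

#' @rdname apply_augmentation
#' @export
augment_random_noise <- function(x, sigma) {
  if (sigma == 0) return(x)
  x + array(stats::rnorm(length(x), sd = sigma), dim = dim(x))
}

#' @rdname apply_augmentation
#' @param strength Scale of the random perturbation of knot spacing; 0
#'   gives the identity warp.
#' @param n_knots Interior knots of the warp curve.
#' @export
augment_time_warp <- function(x, strength, n_knots = 4L) {
  d <- dim(x)
  T <- d[2]
  out <- x
  grid <- seq(0, 1, length.out = T)
  knots <- seq(0, 1, length.out = n_knots + 2L)
  for (b in seq_len(d[1])) {
    # random monotone warp: perturb knot increments, renormalize, then
    # evaluate the piecewise-linear inverse mapping on the original grid
    inc <- diff(knots) * exp(stats::rnorm(n_knots + 1L, sd = strength))
    warped_knots <- c(0, cumsum(inc) / sum(inc))
    warp <- stats::approx(knots, warped_knots, xout = grid)$y
    src <- stats::approx(warp, grid, xout = grid, rule = 2)$y
    pos <- 1 + src * (T - 1)
    lo <- pmin(floor(pos), T - 1)
    w <- pos - lo
    out[b, , ] <- (1 - w) * x[b, lo, , drop = FALSE] +
      w * x[b, lo + 1, , drop = FALSE]
  }
  out
}

#' Generate two contrastive views of a batch
#'
#' Every window is independently transformed twice; the two transforms of
#' the same window form the positive pair and all other windows in the
#' batch act as negatives. Both views are augmented (neither is the clean
#' sample).
#'
#' @param batch Array `(batch, timesteps, features)`.
#' @param spec An [augmentation_spec()].
#' @return List with arrays `view_i` and `view_j` of the batch's shape.
#' @export
make_views <- function(batch, spec = augmentation_spec()) {
  list(view_i = apply_augmentation(batch, spec),
       view_j = apply_augmentation(batch, spec))
}
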