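# Seeded synthetic vertebra phantoms: an axial-slice caricature of a lumbar
# vertebra - a bright elliptical cortical ring (outer ellipse minus a
# concentric inner ellipse at 60% axes) with a rectangular posterior
# (spinous) process - over a darker soft-tissue background, optionally
# degraded by a smooth multiplicative bias field ("gray unevenness"),
# additive Gaussian noise, and bright salt impulses. Ground truth comes for
# free, so every segmentation property is testable without real CT data.

#' Phantom specification
#'
#' @param height,width image shape in pixels (default 128 x 128: large
#'   enough for realistic geometry, small enough that a level-set evolution
#'   converges in seconds).
#' @param body_axes ellipse semi-axes `c(col, row)` of the vertebral body in
#'   pixels (default 30 x 22).
#' @param process_length spinous-process length in pixels (default 18).
#' @param process_halfwidth spinous-process half-width in pixels (default 3).
#' @param bone_intensity mean cortical-bone gray (default 200; bone is
#'   bright on CT).
#' @param background_intensity mean soft-tissue gray (default 60); must be
#'   below `bone_intensity`.
#' @param bias_amplitude relative amplitude `a` in `[0, 1]` of a smooth
#'   multiplicative field rescaled to `[1 - a, 1 + a]` (default 0).
#' @param noise_sigma additive Gaussian noise standard deviation in
#'   intensity units (default 0).
#' @param salt_fraction fraction in `[0, 1]` of pixels replaced by bright
#'   (255) impulses (default 0).
#' @param seed non-negative RNG seed; phantom generation is a pure function
#'   of the spec including the seed.
#' @param center body center `c(row, col)`; defaults to the image center.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 128L, width = 128L, body_axes = c(30, 22),
                         process_length = 18, process_halfwidth = 3,
                         bone_intensity = 200, background_intensity = 60,
                         bias_amplitude = 0, noise_sigma = 0,
                         salt_fraction = 0, seed = 0L,
                         center = c((height + 1) / 2, (width + 1) / 2)) {
  if (bone_intensity <= background_intensity)
    stop("bone_intensity must exceed background_intensity")
  if (bias_amplitude < 0 || bias_amplitude > 1)
    stop("bias_amplitude must lie in [0, 1]")
  if (salt_fraction < 0 || salt_fraction > 1)
    stop("salt_fraction must lie in [0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  spec <- structure(list(height = as.integer(height),
                         width = as.integer(width),
                         body_axes = body_axes,
                         process_length = process_length,
                         process_halfwidth = process_halfwidth,
                         bone_intensity = bone_intensity,
                         background_intensity = background_intensity,
                         bias_amplitude = bias_amplitude,
                         noise_sigma = noise_sigma,
                         salt_fraction = salt_fraction,
                         seed = as.integer(seed),
                         center = center),
                    class = "phantom_spec")
  check_phantom_fit(spec)
  spec
}

check_phantom_fit <- function(spec) {
  cr <- spec$center[1]; cc <- spec$center[2]
  if (cr - spec$body_axes[2] < 1 || cc - spec$body_axes[1] < 1 ||
      cc + spec$body_axes[1] > spec$width ||
      cr + spec$body_axes[2] + spec$process_length > spec$height)
    stop("phantom does not fit")
  invisible(TRUE)
}

phantom_truth <- function(spec) {
  cr <- spec$center[1]; cc <- spec$center[2]
  a <- spec$body_axes[1]; b <- spec$body_axes[2]
  r <- matrix(seq_len(spec$height), spec$height, spec$width)
  c <- matrix(seq_len(spec$width), spec$height, spec$width, byrow = TRUE)
  ell <- ((c - cc) / a)^2 + ((r - cr) / b)^2
  ring <- (ell <= 1) & (((c - cc) / (0.6 * a))^2 + ((r - cr) / (0.6 * b))^2 > 1)
  proc <- abs(c - cc) <= spec$process_halfwidth &
    r >= cr + b & r <= cr + b + spec$process_length
  (ring | proc) * 1
}

# Smooth multiplicative bias: a sum of seeded Gaussian bumps rescaled onto
# [1 - a, 1 + a]. The simplest field matching "strong gray unevenness".
phantom_bias <- function(spec) {
  if (spec$bias_amplitude == 0)
    return(matrix(1, spec$height, spec$width))
  n_bumps <- 4L
  cx <- stats::runif(n_bumps, 1, spec$width)
  cy <- stats::runif(n_bumps, 1, spec$height)
  amp <- stats::runif(n_bumps, 0.5, 1)
  w <- min(spec$height, spec$width) / 2.5
  r <- matrix(seq_len(spec$height), spec$height, spec$width)
  c <- matrix(seq_len(spec$width), spec$height, spec$width, byrow = TRUE)
  f <- matrix(0, spec$height, spec$width)
  for (k in seq_len(n_bumps))
    f <- f + amp[k] * exp(-((r - cy[k])^2 + (c - cx[k])^2) / (2 * w^2))
  rng <- range(f)
  if (rng[2] - rng[1] < 1e-12) return(matrix(1, spec$height, spec$width))
  1 - spec$bias_amplitude +
    2 * spec$bias_amplitude * (f - rng[1]) / (rng[2] - rng[1])
}

#' Generate a vertebra phantom
#'
#' Builds the ground-truth mask (cortical ring plus posterior process), then
#' `image = clamp(bias * (bone * truth + background * (1 - truth)) +
#' Gaussian noise)`, followed by salt impulses. Identical specs (seed
#' included) give identical output.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (gray matrix) and `truth` (binary mask).
#' @export
generate_vertebra_phantom <- function(spec = phantom_spec()) {
  check_phantom_fit(spec)
  truth <- phantom_truth(spec)
  with_seed(spec$seed, {
    base <- spec$bone_intensity * truth +
      spec$background_intensity * (1 - truth)
    img <- phantom_bias(spec) * base
    if (spec$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sigma),
                          nrow(img), ncol(img))
    img <- clamp255(img)
    if (spec$salt_fraction > 0) {
      n_salt <- floor(spec$salt_fraction * length(img))
      if (n_salt > 0) img[sample.int(length(img), n_salt)] <- 255
    }
    list(image = img, truth = truth)
  })
}

#' Generate a drifting slice stack
#'
#' `n` phantoms whose body center translates by `drift` pixels per frame
#' along the column axis, with fresh noise per frame (frame `i` uses seed
#' `seed + i - 1`).
#'
#' @param spec a [phantom_spec()] for the first frame.
#' @param n number of frames (>= 1).
#' @param drift pixels of center translation per frame.
#' @return list with `frames` (list of gray matrices) and `truths` (list of
#'   binary masks).
#' @export
generate_slice_stack <- function(spec = phantom_spec(), n = 5L, drift = 0) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  frames <- truths <- vector("list", n)
  for (i in seq_len(n)) {
    spec_i <- spec
    spec_i$center <- spec$center + c(0, drift * (i - 1))
    spec_i$seed <- spec$seed + i - 1L
    check_phantom_fit(spec_i)
    ph <- generate_vertebra_phantom(spec_i)
    frames[[i]] <- ph$image
    truths[[i]] <- ph$truth
  }
  list(frames = frames, truths = truths)
}

#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks have Dice 1.
#'
#' @param a,b binary masks of the same shape.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- as_binary_mask(a); b <- as_binary_mask(b)
  check_same_shape(a, b, "mask shape mismatch")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a * b) / denom
}
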