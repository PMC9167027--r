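# Contrast enhancement by a neighborhood-fused exponential gray adjustment:
# each pixel f0 maps to f0 * exp(alpha - 0.45), where alpha is the 3x3
# neighborhood intensity sum normalized by 255 * 9. Neighborhood means above
# 114.75 (= 0.45 * 255) brighten the pixel, below darken it, so bone regions
# gain contrast against soft tissue while near-mean noise is damped over
# repeated passes.

ALPHA_NORM <- 255 * 9

# Per-pixel alpha over the whole image: 3x3 box sum with edge replication.
alpha_map <- function(image) {
  s <- matrix(0, nrow(image), ncol(image))
  for (dr in -1:1) for (dc in -1:1) s <- s + shift_mat(image, dr, dc)
  s / ALPHA_NORM
}

#' Neighborhood brightness coefficient
#'
#' The coefficient alpha at one pixel: the sum of the nine intensities in
#' the 3 x 3 neighborhood centered there (center included), divided by
#' 255 * 9, so alpha is the neighborhood mean on a 0-1 scale. Border
#' neighborhoods are completed by edge replication.
#'
#' @param image gray image matrix.
#' @param row,col 1-based pixel indices.
#' @return scalar in `[0, 1]`.
#' @export
neighborhood_alpha <- function(image, row, col) {
  image <- as_gray_image(image)
  if (row < 1L || row > nrow(image) || col < 1L || col > ncol(image))
    stop("index outside image")
  ri <- pmin(pmax(row + (-1:1), 1L), nrow(image))
  ci <- pmin(pmax(col + (-1:1), 1L), ncol(image))
  sum(image[ri, ci]) / ALPHA_NORM
}

#' Enhancement parameters
#'
#' @param iterations number of enhancement passes (>= 1). Default 3: a few
#'   passes reduce near-mean noise without saturating bone.
#' @param clip_output clamp each pass's output to `[0, 255]` (default TRUE).
#' @return list of class `enhancement_params`.
#' @export
enhancement_params <- function(iterations = 3L, clip_output = TRUE) {
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L) stop("iterations must be >= 1")
  structure(list(iterations = iterations, clip_output = isTRUE(clip_output)),
            class = "enhancement_params")
}

#' Exponential neighborhood contrast enhancement
#'
#' Applies `f0' = f0 * exp(alpha - 0.45)` pixelwise, with alpha the
#' neighborhood coefficient of [neighborhood_alpha()]. Within each pass alpha
#' is computed from that pass's input snapshot, so the update is
#' order-independent across pixels; passes are then iterated. A uniform image
#' at 114.75 is a fixed point; brighter neighborhoods brighten, darker ones
#' darken.
#'
#' @param image gray image matrix.
#' @param params an [enhancement_params()] bundle.
#' @return enhanced gray image matrix.
#' @export
enhance_contrast <- function(image, params = enhancement_params()) {
  image <- as_gray_image(image)
  if (!inherits(params, "enhancement_params")) params <- do.call(enhancement_params, params)
  out <- image
  for (k in seq_len(params$iterations)) {
    out <- out * exp(alpha_map(out) - 0.45)
    if (params$clip_output) out <- clamp255(out)
  }
  out
}
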