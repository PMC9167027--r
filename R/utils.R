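# Internal helpers shared across modules: shifted-matrix stencils, seeded
# evaluation, and small validators. All images are plain numeric matrices on
# the 0-255 scale, row-major, pixel centers at integer (row, col) coordinates.

#' Validate a gray image matrix
#'
#' Checks that `image` is a finite numeric matrix of at least 3 x 3 pixels
#' (the smallest size on which a 3 x 3 neighborhood exists). Intensities live
#' on the 0-255 scale but are kept as reals; quantization happens only when a
#' file is written.
#'
#' @param image numeric matrix of intensities.
#' @return the validated matrix, invisibly usable in pipelines.
#' @export
as_gray_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix")
  if (nrow(image) < 3L || ncol(image) < 3L)
    stop("image must be at least 3 x 3")
  if (!all(is.finite(image)))
    stop("image intensities must all be finite")
  image
}

#' Validate a binary mask
#'
#' A mask is a matrix whose entries are exactly 0 or 1, with the same shape
#' as the image it segments.
#'
#' @param mask numeric matrix with values in {0, 1}.
#' @return the validated mask.
#' @export
as_binary_mask <- function(mask) {
  if (!is.matrix(mask) || !is.numeric(mask))
    stop("mask must be a numeric matrix")
  if (!all(mask == 0 | mask == 1))
    stop("mask values must be exactly 0 or 1")
  mask
}

check_same_shape <- function(a, b, msg) {
  if (nrow(a) != nrow(b) || ncol(a) != ncol(b)) stop(msg)
  invisible(TRUE)
}

# Shift a matrix by (dr, dc) with edge replication: out[i, j] = m[clamp(i+dr),
# clamp(j+dc)]. This single primitive gives Neumann boundary conditions for
# finite differences and replicated borders for neighborhood sums.
shift_mat <- function(m, dr, dc) {
  ri <- pmin(pmax(seq_len(nrow(m)) + dr, 1L), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m)) + dc, 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

# Central differences with replicated edges; unit pixel spacing.
grad_col <- function(m) (shift_mat(m, 0L, 1L) - shift_mat(m, 0L, -1L)) / 2
grad_row <- function(m) (shift_mat(m, 1L, 0L) - shift_mat(m, -1L, 0L)) / 2

laplacian <- function(m) {
  shift_mat(m, 1L, 0L) + shift_mat(m, -1L, 0L) +
    shift_mat(m, 0L, 1L) + shift_mat(m, 0L, -1L) - 4 * m
}

# 3x3 binary morphology via shifted maxima/minima (Chebyshev unit ball).
dilate3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1)
    if (dr != 0L || dc != 0L) out <- pmax(out, shift_mat(m, dr, dc))
  out
}

erode3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1)
    if (dr != 0L || dc != 0L) out <- pmin(out, shift_mat(m, dr, dc))
  out
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

clamp255 <- function(m) pmin(pmax(m, 0), 255)
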