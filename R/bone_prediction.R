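# Iterative bone-region prediction over sequential slices. Each frame is
# contrast-enhanced, fused with the previous frame's binarized segmentation
# (a convex pixelwise mix, the mask lifted to the 0-255 scale), and then
# noise-suppressed in the "suture" band around the previous contour before
# being segmented itself. The suppression damps pixels that the fusion
# brightened but that are dark in the raw incoming frame - i.e. soft tissue
# leaking bone intensity from the previous mask.

#' Frame-fusion parameters
#'
#' @param weight_prev weight on the previous binarized mask (lifted to
#'   0-255); default 0.3.
#' @param weight_next weight on the incoming enhanced frame; default 0.7.
#'   The two weights must sum to 1 so fused intensities stay on the 0-255
#'   scale.
#' @param mu1 multiplier in `(0, 1]` applied inside the contour band
#'   (default 0.5).
#' @param mu2 multiplier in `(0, 1]` applied outside the contour band
#'   (default 0.5).
#' @param threshold raw-intensity threshold `th`; suppression applies only
#'   where the raw incoming frame is darker than `th` (default
#'   `0.3 * 255 = 76.5`).
#' @param band_radius suture band half-width in pixels (Chebyshev distance
#'   from the previous mask boundary); default 2.
#' @return list of class `fusion_params`.
#' @export
fusion_params <- function(weight_prev = 0.3, weight_next = 0.7,
                          mu1 = 0.5, mu2 = 0.5, threshold = 0.3 * 255,
                          band_radius = 2L) {
  if (weight_prev < 0 || weight_prev > 1 || weight_next < 0 || weight_next > 1)
    stop("fusion weights must lie in [0, 1]")
  if (abs(weight_prev + weight_next - 1) > 1e-9)
    stop("fusion weights must sum to 1")
  if (mu1 <= 0 || mu1 > 1 || mu2 <= 0 || mu2 > 1)
    stop("mu1 and mu2 must lie in (0, 1]")
  if (threshold < 0 || threshold > 255)
    stop("threshold must lie in [0, 255]")
  band_radius <- as.integer(band_radius)
  if (is.na(band_radius) || band_radius < 0L)
    stop("band_radius must be a non-negative integer")
  structure(list(weight_prev = weight_prev, weight_next = weight_next,
                 mu1 = mu1, mu2 = mu2, threshold = threshold,
                 band_radius = band_radius),
            class = "fusion_params")
}

#' Fuse a mask with the next enhanced frame
#'
#' Pixelwise convex mix `weight_prev * (255 * prev_mask) +
#' weight_next * next_enhanced`: the previous segmentation acts as a bone
#' prior for the incoming slice.
#'
#' @param prev_mask binary mask of the previous frame.
#' @param next_enhanced enhanced gray image of the next frame.
#' @param params a [fusion_params()] bundle.
#' @return fused gray image matrix.
#' @export
fuse_frames <- function(prev_mask, next_enhanced, params = fusion_params()) {
  prev_mask <- as_binary_mask(prev_mask)
  check_same_shape(prev_mask, next_enhanced, "frame shape mismatch")
  params$weight_prev * (255 * prev_mask) + params$weight_next * next_enhanced
}

#' Extract the suture band around a mask boundary
#'
#' The suture area is the band of pixels within `band_radius` (Chebyshev
#' metric, realized by iterated 3x3 dilation/erosion) of the previous mask's
#' boundary; `q1` is its inside part (mask pixels not surviving
#' `band_radius` erosions), `q2` its outside part (non-mask pixels reached
#' by `band_radius` dilations). The two are disjoint by construction.
#'
#' @param prev_mask binary mask containing both a 0 and a 1.
#' @param band_radius non-negative integer half-width; 0 gives empty bands.
#' @return list with binary masks `q1` (inner band), `q2` (outer band).
#' @export
extract_suture_regions <- function(prev_mask, band_radius = 2L) {
  prev_mask <- as_binary_mask(prev_mask)
  if (all(prev_mask == 1) || all(prev_mask == 0))
    stop("no boundary: suture undefined")
  band_radius <- as.integer(band_radius)
  er <- di <- prev_mask
  for (k in seq_len(band_radius)) {
    er <- erode3(er)
    di <- dilate3(di)
  }
  list(q1 = prev_mask * (1 - er), q2 = di * (1 - prev_mask))
}

#' Suppress fusion noise in the suture band
#'
#' Pixels of the fused image lying in `q1` (resp. `q2`) whose raw incoming
#' intensity is below `threshold` are multiplied by `mu1` (resp. `mu2`);
#' every other pixel passes through unchanged.
#'
#' @param fused fused gray image (output of [fuse_frames()]).
#' @param original_next the raw (pre-enhancement) incoming frame.
#' @param regions suture bands from [extract_suture_regions()].
#' @param params a [fusion_params()] bundle.
#' @return gray image matrix.
#' @export
suture_noise_suppress <- function(fused, original_next, regions,
                                  params = fusion_params()) {
  check_same_shape(fused, original_next, "frame shape mismatch")
  check_same_shape(fused, regions$q1, "frame shape mismatch")
  out <- fused
  dark <- original_next < params$threshold
  s1 <- regions$q1 == 1 & dark
  s2 <- regions$q2 == 1 & dark
  out[s1] <- out[s1] * params$mu1
  out[s2] <- out[s2] * params$mu2
  out
}

#' Predict bone regions over a slice sequence
#'
#' The full iterative pipeline: frame 1 is enhanced, segmented by the chosen
#' active-contour model and binarized. Each later frame is enhanced, fused
#' with the previous frame's mask, suppressed in the previous mask's suture
#' band (using the raw incoming frame as the reference intensity), then
#' segmented and binarized. After the last frame the final bone region is
#' the segmentation of the last modified image; every segmentation starts
#' from the same deterministic initialization, so this equals the last
#' per-frame mask and is returned as `final` without a redundant
#' recomputation.
#'
#' @param frames list of gray image matrices, all the same shape.
#' @param fusion a [fusion_params()] bundle.
#' @param contour_method `"cv"` or `"lbf"`.
#' @param contour_params parameter bundle for the chosen method (defaults
#'   when NULL).
#' @param enh an [enhancement_params()] bundle.
#' @return list with `masks` (per-frame binary masks, in order), `final`
#'   (the final bone mask), and `diagnostics` (data.frame: frame, energy at
#'   convergence, iterations, foreground area in pixels).
#' @export
predict_segment_sequence <- function(frames, fusion = fusion_params(),
                                     contour_method = c("cv", "lbf"),
                                     contour_params = NULL,
                                     enh = enhancement_params()) {
  if (!is.list(frames) || length(frames) == 0L) stop("no frames")
  contour_method <- match.arg(contour_method)
  shape0 <- dim(frames[[1]])
  n <- length(frames)
  masks <- vector("list", n)
  diag <- data.frame(frame = integer(0), energy = numeric(0),
                     iterations = integer(0), area = numeric(0))
  prev_mask <- NULL
  for (i in seq_len(n)) {
    res <- tryCatch({
      frame <- as_gray_image(frames[[i]])
      if (!identical(dim(frame), shape0)) stop("frame shape mismatch")
      work <- enhance_contrast(frame, enh)
      if (i > 1L) {
        work <- fuse_frames(prev_mask, work, fusion)
        if (any(prev_mask == 1) && any(prev_mask == 0) &&
            fusion$band_radius > 0L) {
          regions <- extract_suture_regions(prev_mask, fusion$band_radius)
          work <- suture_noise_suppress(work, frame, regions, fusion)
        }
      }
      segment_image(work, contour_method, contour_params)
    }, error = function(e) {
      stop("frame ", i, ": ", conditionMessage(e), call. = FALSE)
    })
    masks[[i]] <- res$mask
    ev <- res$evolution
    diag <- rbind(diag, data.frame(frame = i,
                                   energy = ev$history[ev$iterations],
                                   iterations = ev$iterations,
                                   area = sum(res$mask)))
    prev_mask <- res$mask
  }
  list(masks = masks, final = masks[[n]], diagnostics = diag)
}
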