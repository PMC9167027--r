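# Downstream spinal morphometry and clinical-efficacy computations:
# protrusion/spinal-canal area ratio, disc height (DH), vertebral slippage
# from near-parallel endplate lines, four-level efficacy grading, the total
# effective rate, and the group-comparison statistics (chi-square on
# responder counts; paired and two-sample t tests on scores).

#' Pixel spacing
#'
#' Physical size of a pixel in millimetres, possibly anisotropic.
#'
#' @param mm_per_pixel_row,mm_per_pixel_col positive reals.
#' @return list of class `pixel_spacing`.
#' @export
pixel_spacing <- function(mm_per_pixel_row = 1, mm_per_pixel_col = mm_per_pixel_row) {
  if (mm_per_pixel_row <= 0 || mm_per_pixel_col <= 0)
    stop("pixel spacing must be > 0")
  structure(list(mm_per_pixel_row = mm_per_pixel_row,
                 mm_per_pixel_col = mm_per_pixel_col),
            class = "pixel_spacing")
}

#' Protrusion-to-canal area ratio
#'
#' Areas are foreground pixel counts scaled by the pixel area in mm^2; the
#' ratio is protrusion area over spinal-canal area.
#'
#' @param protrusion binary mask of the herniated protrusion.
#' @param canal binary mask of the spinal canal (>= 1 foreground pixel).
#' @param spacing a [pixel_spacing()].
#' @return data.frame with `protrusion_area_mm2`, `canal_area_mm2`,
#'   `protrusion_ratio`.
#' @export
protrusion_ratio <- function(protrusion, canal, spacing = pixel_spacing()) {
  protrusion <- as_binary_mask(protrusion)
  canal <- as_binary_mask(canal)
  if (sum(canal) == 0) stop("canal area zero")
  px_area <- spacing$mm_per_pixel_row * spacing$mm_per_pixel_col
  pa <- sum(protrusion) * px_area
  ca <- sum(canal) * px_area
  data.frame(protrusion_area_mm2 = pa, canal_area_mm2 = ca,
             protrusion_ratio = pa / ca)
}

#' Disc height
#'
#' Euclidean distance in mm between the midpoint of the upper vertebra's
#' lower endplate and the midpoint of the lower vertebra's upper endplate,
#' with anisotropic pixel spacing.
#'
#' @param upper_mid,lower_mid points `c(row, col)` in pixel coordinates.
#' @param spacing a [pixel_spacing()].
#' @return distance in mm.
#' @export
disc_height <- function(upper_mid, lower_mid, spacing = pixel_spacing()) {
  dr <- (upper_mid[1] - lower_mid[1]) * spacing$mm_per_pixel_row
  dc <- (upper_mid[2] - lower_mid[2]) * spacing$mm_per_pixel_col
  sqrt(dr^2 + dc^2)
}

#' Endplate line
#'
#' A line segment along a vertebral endplate, in pixel coordinates.
#'
#' @param p_start,p_end distinct points `c(row, col)`.
#' @return list of class `endplate_line`.
#' @export
endplate_line <- function(p_start, p_end) {
  if (isTRUE(all.equal(p_start, p_end, tolerance = 0)))
    stop("endplate endpoints must be distinct")
  structure(list(p_start = p_start, p_end = p_end), class = "endplate_line")
}

#' Vertebral slippage
#'
#' Anteroposterior offset between adjacent vertebral bodies. A midline
#' parallel to both endplates (direction: the average of the two
#' sign-aligned unit directions, through the midpoint between the two
#' endplate midpoints) is constructed; each endplate midpoint is dropped
#' perpendicularly onto it, and the slippage is the distance in mm between
#' the two foot points. Exactly aligned vertebrae give 0; a purely
#' perpendicular separation (disc space only, no shear) also gives 0. The
#' construction assumes near-parallel endplates and refuses lines more than
#' 30 degrees apart.
#'
#' @param upper_edge lower endplate line of the upper vertebral body
#'   ([endplate_line()]).
#' @param lower_edge upper endplate line of the lower vertebral body.
#' @param spacing a [pixel_spacing()]; geometry is done in mm coordinates.
#' @param percent if TRUE, return the slippage as a percentage of the mean
#'   endplate length instead of mm.
#' @return slippage in mm (or percent).
#' @export
vertebral_slippage <- function(upper_edge, lower_edge,
                               spacing = pixel_spacing(), percent = FALSE) {
  to_mm <- function(p) c(p[1] * spacing$mm_per_pixel_row,
                         p[2] * spacing$mm_per_pixel_col)
  a1 <- to_mm(upper_edge$p_start); a2 <- to_mm(upper_edge$p_end)
  b1 <- to_mm(lower_edge$p_start); b2 <- to_mm(lower_edge$p_end)
  d1 <- (a2 - a1); d1 <- d1 / sqrt(sum(d1^2))
  d2 <- (b2 - b1); d2 <- d2 / sqrt(sum(d2^2))
  if (sum(d1 * d2) < 0) d2 <- -d2
  cosang <- min(max(sum(d1 * d2), -1), 1)
  if (acos(cosang) > 30 * pi / 180) stop("endplates not near-parallel")
  d <- d1 + d2
  d <- d / sqrt(sum(d^2))
  m1 <- (a1 + a2) / 2
  m2 <- (b1 + b2) / 2
  slip <- abs(sum((m1 - m2) * d))
  if (percent) {
    len <- (sqrt(sum((a2 - a1)^2)) + sqrt(sum((b2 - b1)^2))) / 2
    slip <- 100 * slip / len
  }
  slip
}

#' Grade a symptom-improvement rate
#'
#' Four-level scale on the improvement percentage: `>= 80` cured, `>= 60`
#' markedly effective, `>= 25` effective, below 25 ineffective. Intervals
#' are closed on the left of the better category.
#'
#' @param rate improvement percentage in `[0, 100]` (vectorized).
#' @return character vector of grades.
#' @export
grade_improvement <- function(rate) {
  if (any(!is.finite(rate)) || any(rate < 0) || any(rate > 100))
    stop("invalid improvement rate")
  ifelse(rate >= 80, "cured",
         ifelse(rate >= 60, "markedly_effective",
                ifelse(rate >= 25, "effective", "ineffective")))
}

#' Efficacy counts
#'
#' Per-group patient counts on the four-level scale.
#'
#' @param cured,markedly,effective,ineffective non-negative integers.
#' @return list of class `efficacy_counts` with a `total` field.
#' @export
efficacy_counts <- function(cured, markedly, effective, ineffective) {
  v <- c(cured, markedly, effective, ineffective)
  if (any(v < 0) || any(v != floor(v))) stop("counts must be non-negative integers")
  total <- sum(v)
  if (total <= 0) stop("empty group")
  structure(list(cured = cured, markedly = markedly, effective = effective,
                 ineffective = ineffective, total = total),
            class = "efficacy_counts")
}

#' Total effective rate
#'
#' Percentage of patients graded cured, markedly effective or effective,
#' reported to two decimals: `100 (cured + markedly + effective) / total`.
#'
#' @param counts an [efficacy_counts()].
#' @return percentage rounded to two decimals.
#' @export
total_effective_rate <- function(counts) {
  if (!inherits(counts, "efficacy_counts")) counts <- do.call(efficacy_counts, as.list(counts))
  round(100 * (counts$cured + counts$markedly + counts$effective) / counts$total, 2)
}

#' Compare efficacy rates between two groups
#'
#' Pearson chi-square on the 2 x 2 table of responders (cured + markedly +
#' effective) versus ineffective, 1 degree of freedom, no continuity
#' correction by default. Efficacy tables routinely have few ineffective
#' patients, so the small-expected-count caution `stats::chisq.test` emits
#' is suppressed; the statistic itself is exact, and the Yates flag is
#' available when the approximation is a concern.
#'
#' @param a,b [efficacy_counts()] for the two groups.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return data.frame with `statistic`, `df`, `p_value`.
#' @export
compare_rates <- function(a, b, correct = FALSE) {
  if (!inherits(a, "efficacy_counts")) a <- do.call(efficacy_counts, as.list(a))
  if (!inherits(b, "efficacy_counts")) b <- do.call(efficacy_counts, as.list(b))
  tab <- rbind(c(a$cured + a$markedly + a$effective, a$ineffective),
               c(b$cured + b$markedly + b$effective, b$ineffective))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  data.frame(statistic = unname(ct$statistic), df = unname(ct$parameter),
             p_value = ct$p.value)
}

#' Compare scores within and between groups
#'
#' Paired t tests before vs. after within each group, and a two-sample t
#' test (pooled variance by default, the classic independent t test) on the
#' after-treatment scores between groups.
#'
#' @param before_a,after_a scores of group A before/after treatment (equal
#'   length).
#' @param before_b,after_b scores of group B before/after treatment.
#' @param var_equal pooled-variance two-sample t (default TRUE); FALSE gives
#'   Welch.
#' @return data.frame with one row per comparison: `comparison`, group
#'   means and SDs, `t`, `df`, `p_value`.
#' @export
compare_scores <- function(before_a, after_a, before_b, after_b,
                           var_equal = TRUE) {
  if (length(before_a) != length(after_a) || length(before_b) != length(after_b))
    stop("unpaired observations")
  if (length(before_a) == 0 || length(before_b) == 0)
    stop("scores must be nonempty")
  row_of <- function(name, x, y, test) {
    data.frame(comparison = name,
               mean_1 = mean(x), sd_1 = stats::sd(x),
               mean_2 = mean(y), sd_2 = stats::sd(y),
               t = unname(test$statistic), df = unname(test$parameter),
               p_value = test$p.value)
  }
  # stats::t.test refuses all-zero paired differences; no change is a valid
  # clinical outcome, reported as t = 0, p = 1.
  paired_t <- function(x, y) {
    if (all(x == y))
      return(list(statistic = c(t = 0), parameter = c(df = length(x) - 1),
                  p.value = 1))
    stats::t.test(x, y, paired = TRUE)
  }
  rbind(
    row_of("within_a_before_after", before_a, after_a,
           paired_t(before_a, after_a)),
    row_of("within_b_before_after", before_b, after_b,
           paired_t(before_b, after_b)),
    row_of("between_groups_after", after_a, after_b,
           if (stats::sd(after_a) == 0 && stats::sd(after_b) == 0 &&
               mean(after_a) == mean(after_b))
             list(statistic = c(t = 0),
                  parameter = c(df = length(after_a) + length(after_b) - 2),
                  p.value = 1)
           else stats::t.test(after_a, after_b, var.equal = var_equal))
  )
}
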