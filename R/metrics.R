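# Spatiotemporal synergy metrics: full width at half maximum, circular
# centre of activity, primitive overlaps, joint coactivation index.

#' Full width at half maximum of a motor primitive
#'
#' After subtracting the cycle's minimum, counts the points strictly
#' exceeding half the (shifted) maximum. Non-contiguous supra-threshold
#' lobes all contribute, so a bimodal primitive's FWHM is the sum of its
#' lobe widths. Invariant to positive affine transforms and to circular
#' shifts.
#'
#' @param primitive numeric series over the normalized cycle
#' @return number of supra-half-maximum points (0 for a constant series,
#'   with a warning)
#' @export
fwhm <- function(primitive) {
  shifted <- primitive - min(primitive)
  if (max(shifted) == 0) {
    warning("constant primitive; FWHM undefined, returning 0")
    return(0L)
  }
  sum(shifted > max(shifted) / 2)
}

# half-maximum mask under the same minimum-subtracted rule as fwhm()
half_max_mask <- function(primitive) {
  shifted <- primitive - min(primitive)
  if (max(shifted) == 0) return(rep(FALSE, length(primitive)))
  shifted > max(shifted) / 2
}

#' Circular centre of activity of a motor primitive
#'
#' The cycle is wrapped onto the unit circle (point `t` at angle
#' `2*pi*(t-1)/n`) and the primitive treated as a mass distribution; the
#' CoA is the angle of its centre of mass, mapped back to cycle points in
#' `[0, n)`. Raw values are used as weights (no minimum subtraction).
#' Equivariant under circular shifts.
#'
#' @param primitive nonnegative series over the cycle
#' @return CoA in cycle points, `NA` (with a warning) for a zero-sum series
#' @export
coa <- function(primitive) {
  n <- length(primitive)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  a <- sum(primitive * sin(theta))
  b <- sum(primitive * cos(theta))
  if (a == 0 && b == 0) {
    warning("zero or uniform circular mass; CoA undefined")
    return(NA_real_)
  }
  ang <- atan2(a, b) %% (2 * pi)
  (ang * n / (2 * pi) + 1) %% n
}

#' Overlap profile of a set of motor primitives
#'
#' A cycle point is an overlap when at least two primitives simultaneously
#' exceed their own half maximum (same minimum-subtracted rule as
#' [fwhm()]).
#'
#' @param primitives matrix, synergies x cycle points
#' @return list with integer `overlap_count` and logical
#'   `overlap_indicator`, both of cycle length
#' @export
overlaps <- function(primitives) {
  primitives <- as.matrix(primitives)
  masks <- t(apply(primitives, 1L, half_max_mask))
  if (nrow(primitives) == 1L) masks <- matrix(masks, nrow = 1L)
  count <- colSums(masks)
  list(overlap_count = as.integer(count), overlap_indicator = count >= 2)
}

#' Joint coactivation index of a motor module
#'
#' Ratio of the mean flexor to the summed mean flexor and extensor module
#' weights at a joint, `CaI = Flex / (Flex + Ext)`: 0 when only extensors
#' contribute, 1 when only flexors do, 0.5 at full coactivation. Muscle
#' groups per joint are those of [muscle_groups()].
#'
#' @param module named nonnegative weight vector over [landing_muscles]
#' @param joint `"hip"`, `"knee"` or `"ankle"`
#' @return list with `joint`, `cai`, and the pairwise-normalized
#'   `flexor_mean` and `extensor_mean` (forced to sum to 1)
#' @export
coactivation_index <- function(module, joint = c("hip", "knee", "ankle")) {
  joint <- match.arg(joint)
  if (is.null(names(module))) names(module) <- landing_muscles
  if (any(module < 0)) stop("module weights must be nonnegative")
  grp <- muscle_groups()[[joint]]
  fl <- mean(module[grp$flexors])
  ex <- mean(module[grp$extensors])
  tot <- fl + ex
  if (tot == 0) {
    warning("flexor and extensor means both zero; CaI undefined")
    return(list(joint = joint, cai = NA_real_,
                flexor_mean = NA_real_, extensor_mean = NA_real_))
  }
  list(joint = joint, cai = fl / tot,
       flexor_mean = fl / tot, extensor_mean = ex / tot)
}
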