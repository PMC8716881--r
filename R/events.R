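# GRF-based landing segmentation, 100+200-point time normalization, CoP
# sway ellipse and joint-moment scalar metrics.

#' Detect touchdown from the vertical GRF
#'
#' Touchdown is the first sample strictly exceeding the 20 N threshold.
#'
#' @param vgrf vertical ground reaction force series, in N
#' @param rate sampling rate in Hz (unused by the rule; kept for interface
#'   symmetry)
#' @param threshold force threshold in N (default 20)
#' @return the touchdown sample index
#' @export
detect_touchdown <- function(vgrf, rate = 1000, threshold = 20) {
  above <- which(vgrf > threshold)
  if (!length(above) || above[1L] == 1L)
    stop("no flight-to-stance threshold crossing found")
  above[1L]
}

#' Detect the end of the stance phase
#'
#' Finds the first strict local minimum of the vertical GRF after the impact
#' peak, then returns the first subsequent sample whose value enters the
#' body-weight +-`band` tolerance band. Trials whose force never re-enters
#' the band are rejected with an error, mirroring failed-landing exclusion.
#'
#' @param vgrf vertical GRF series, N
#' @param touchdown touchdown sample index
#' @param bodyweight body weight in N
#' @param band half-width of the body-weight band as a fraction (default
#'   0.025)
#' @return stance-end sample index
#' @export
detect_stance_end <- function(vgrf, touchdown, bodyweight, band = 0.025) {
  n <- length(vgrf)
  stopifnot(touchdown >= 1L, touchdown < n, bodyweight > 0)
  peak <- touchdown - 1L + which.max(vgrf[touchdown:n])
  i <- peak + 1L
  min_idx <- NA_integer_
  while (i < n) {
    if (vgrf[i] < vgrf[i - 1L] && vgrf[i] < vgrf[i + 1L]) {
      min_idx <- i
      break
    }
    i <- i + 1L
  }
  if (is.na(min_idx))
    stop("no vertical-GRF minimum found after the impact peak")
  lo <- (1 - band) * bodyweight
  hi <- (1 + band) * bodyweight
  in_band <- which(vgrf >= lo & vgrf <= hi)
  in_band <- in_band[in_band >= min_idx]
  if (!length(in_band))
    stop("vertical GRF never enters the body-weight band; trial rejected")
  in_band[1L]
}

#' Segment one landing
#'
#' @param vgrf vertical GRF series, N
#' @param bodyweight body weight, N
#' @param rate sampling rate, Hz
#' @return object of class `landing_segmentation`: touchdown, interval
#'   start (300 ms pre-touchdown), stance end and stance duration in s
#' @export
segment_landing <- function(vgrf, bodyweight, rate = 1000) {
  touchdown <- detect_touchdown(vgrf, rate)
  interval_start <- touchdown - as.integer(floor(rate * 0.3))
  if (interval_start < 1L)
    stop("fewer than 300 ms of flight recorded before touchdown")
  stance_end <- detect_stance_end(vgrf, touchdown, bodyweight)
  structure(list(touchdown_index = touchdown,
                 interval_start_index = interval_start,
                 stance_end_index = stance_end,
                 stance_duration = (stance_end - touchdown + 1L) / rate,
                 rate = rate),
            class = "landing_segmentation")
}

# Linearly resample the columns of a phase onto n points, endpoints fixed.
resample_phase <- function(x, n) {
  L <- ncol(x)
  if (L < 2L) stop("fewer than 2 samples in a phase; cannot resample")
  xout <- seq(1, L, length.out = n)
  t(apply(x, 1L, function(row) approx(seq_len(L), row, xout)$y))
}

#' Time-normalize channels onto the fixed 300-point landing cycle
#'
#' The flight phase (interval start to the sample before touchdown) is
#' linearly resampled to 100 points and the stance phase (touchdown to
#' stance end) to 200 points; the two are concatenated so point 101 is the
#' touchdown. The 1:2 split mirrors the typical flight:stance duration
#' ratio of a 30 cm single-leg landing.
#'
#' @param x numeric matrix (channels x samples) or vector sharing the
#'   trial's time base
#' @param seg a `landing_segmentation`
#' @param flight_points,stance_points cycle allocation (defaults 100, 200)
#' @return matrix channels x (flight_points + stance_points)
#' @export
time_normalize <- function(x, seg, flight_points = 100L, stance_points = 200L) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  flight <- x[, seg$interval_start_index:(seg$touchdown_index - 1L),
              drop = FALSE]
  stance <- x[, seg$touchdown_index:seg$stance_end_index, drop = FALSE]
  out <- cbind(resample_phase(flight, flight_points),
               resample_phase(stance, stance_points))
  rownames(out) <- rownames(x)
  out
}

#' Build the fully time-normalized trial
#'
#' Applies [time_normalize()] to the conditioned EMG, the Euclidean norm of
#' the 3-D GRF, and any joint-angle/moment series of the trial.
#'
#' @param emg conditioned (and amplitude-normalized) envelope matrix,
#'   muscles x samples
#' @param grf n x 3 GRF matrix, N
#' @param seg a `landing_segmentation`
#' @param angles,moments optional joints x samples matrices
#' @param condition condition label carried through
#' @return object of class `normalized_trial` with elements `emg`
#'   (muscles x 300), `grf_norm` (length 300), optional `angles`/`moments`,
#'   `condition`, `flight_points`, `stance_points`
#' @export
normalize_trial <- function(emg, grf, seg, angles = NULL, moments = NULL,
                            condition = NA_character_) {
  grf_norm <- sqrt(rowSums(grf^2))
  out <- list(emg = time_normalize(emg, seg),
              grf_norm = drop(time_normalize(grf_norm, seg)),
              condition = condition,
              flight_points = 100L, stance_points = 200L)
  if (!is.null(angles)) out$angles <- time_normalize(angles, seg)
  if (!is.null(moments)) out$moments <- time_normalize(moments, seg)
  class(out) <- "normalized_trial"
  out
}

#' Area of the CoP 95 % confidence ellipse
#'
#' Area of the smallest ellipse expected to contain `coverage` of the CoP
#' points under a bivariate normal model:
#' `pi * qchisq(coverage, 2) * sqrt(lambda1 * lambda2)` with the lambdas the
#' eigenvalues of the 2 x 2 sample covariance (`qchisq(0.95, 2) = 5.991`).
#'
#' @param cop n x 2 matrix of CoP coordinates in m (stance phase)
#' @param coverage ellipse coverage probability (default 0.95)
#' @return area in m^2
#' @export
cop_ellipse_area <- function(cop, coverage = 0.95) {
  cop <- as.matrix(cop)
  if (nrow(cop) < 3L) stop("need at least 3 CoP points")
  d <- det(cov(cop))
  if (!is.finite(d) || d <= 0) {
    warning("degenerate CoP covariance; returning zero area")
    return(0)
  }
  pi * qchisq(coverage, df = 2) * sqrt(d)
}

#' Scalar joint-moment (and joint-angle) landing metrics
#'
#' The moment maximum over stance, the time from touchdown to that maximum,
#' the rate of moment development (maximum / time-to-peak), and, when an
#' angle series is given, the joint range of motion (angle at touchdown
#' minus the stance-phase minimum).
#'
#' @param moment joint-moment series, Nm, on the trial's raw time base
#' @param seg a `landing_segmentation`
#' @param angle optional joint-angle series, deg, same time base
#' @return list with `max` (Nm), `time_to_peak` (s), `rate` (Nm/s, `NA`
#'   when the peak coincides with touchdown), `rate_defined` flag, and
#'   `range_of_motion` (deg, `NA` when no angle given)
#' @export
moment_scalars <- function(moment, seg, angle = NULL) {
  td <- seg$touchdown_index
  if (td < 1L || td > length(moment)) stop("touchdown outside series")
  stance <- td:seg$stance_end_index
  mx <- max(moment[stance])
  ipk <- stance[which.max(moment[stance])]
  ttp <- (ipk - td) / seg$rate
  rate_defined <- ttp > 0
  if (!rate_defined) warning("moment peak at touchdown; rate undefined")
  rom <- NA_real_
  if (!is.null(angle)) rom <- angle[td] - min(angle[stance])
  list(max = mx, time_to_peak = ttp,
       rate = if (rate_defined) mx / ttp else NA_real_,
       rate_defined = rate_defined, range_of_motion = rom)
}
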