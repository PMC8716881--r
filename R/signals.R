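# EMG conditioning: 4th-order zero-phase Butterworth high-pass at 50 Hz,
# full-wave rectification, 4th-order zero-phase low-pass at 20 Hz, then
# amplitude normalization to the per-muscle maximum of the stable-ground
# reference series.

#' Condition raw EMG into linear envelopes
#'
#' Applies, per muscle, a fourth-order Butterworth high-pass (50 Hz cut-off)
#' forward and backward (zero phase), full-wave rectifies, and low-pass
#' filters (fourth-order Butterworth, 20 Hz cut-off, also zero phase). The
#' stated orders are the single-pass design orders; forward-backward
#' application doubles the effective attenuation. Tiny negative excursions
#' introduced by the zero-phase low-pass are clipped to zero so the envelope
#' is valid input for non-negative factorization.
#'
#' @param raw numeric matrix, muscles x samples; row names carry the muscle
#'   labels
#' @param rate sampling rate in Hz (must exceed twice the high-pass cut-off)
#' @param high_cutoff,low_cutoff filter cut-offs in Hz
#' @param order Butterworth design order of each single pass
#' @return nonnegative envelope matrix of the same shape, with attribute
#'   `rate`
#' @export
condition_emg <- function(raw, rate, high_cutoff = 50, low_cutoff = 20,
                          order = 4L) {
  if (is.vector(raw)) raw <- matrix(raw, nrow = 1L)
  if (!is.matrix(raw) || !is.numeric(raw) || nrow(raw) < 1L)
    stop("'raw' must be a numeric matrix with at least one muscle row")
  if (!all(is.finite(raw))) stop("non-finite samples in EMG input")
  if (rate <= 2 * high_cutoff)
    stop("sampling rate must exceed twice the high-pass cut-off")

  hp <- signal::butter(order, high_cutoff / (rate / 2), type = "high")
  lp <- signal::butter(order, low_cutoff / (rate / 2), type = "low")
  env <- t(apply(raw, 1L, function(x) {
    if (all(x == 0)) return(x)
    y <- abs(signal::filtfilt(hp, x))
    pmax(signal::filtfilt(lp, y), 0)
  }))
  dimnames(env) <- dimnames(raw)
  attr(env, "rate") <- rate
  env
}

#' Normalize envelope amplitude to the stable-ground reference maxima
#'
#' Divides each muscle's envelope by that muscle's maximum over all samples
#' of the supplied reference envelopes (the participant's stable-ground
#' series). Reference trials therefore map to a per-muscle maximum of 1;
#' trials exceeding the reference may exceed 1.
#'
#' @param env envelope matrix (muscles x samples), rows named by muscle
#' @param reference a single envelope matrix or a list of them, same muscle
#'   rows, pooled to compute the per-muscle maxima
#' @return normalized envelope matrix of the same shape
#' @export
normalize_amplitude <- function(env, reference) {
  if (is.matrix(reference)) reference <- list(reference)
  if (!length(reference)) stop("reference collection is empty")
  labels <- rownames(env)
  ref_max <- Reduce(pmax, lapply(reference, function(r) {
    if (!is.null(labels)) {
      if (is.null(rownames(r)) || !all(labels %in% rownames(r)))
        stop("reference trials must carry the same muscle labels")
      r <- r[labels, , drop = FALSE]
    }
    apply(r, 1L, max)
  }))
  zero <- ref_max <= 0
  if (any(zero))
    stop("all-zero reference for muscle(s): ",
         paste(if (is.null(labels)) which(zero) else labels[zero],
               collapse = ", "))
  out <- env / ref_max
  attr(out, "rate") <- attr(env, "rate")
  out
}
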