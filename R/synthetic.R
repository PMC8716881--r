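# Synthetic landing trials with known ground-truth synergy structure.
# The generator inverts the analysis model: envelopes are built as M %*% P,
# mapped from the 300-point cycle back to real time, and modulated onto
# band-limited zero-mean carriers so the raw signal survives the 50 Hz
# high-pass of the conditioning chain.

#' Gaussian motor-primitive template
#'
#' A truncated Gaussian bump on the normalized landing cycle, scaled to unit
#' maximum at the sample nearest `center`. The width parameter is the full
#' width at half maximum, so `fwhm(generate_primitive(c, w))` recovers `w`
#' to within a point for interior bumps.
#'
#' @param center bump center, in cycle points (1..`n_points`)
#' @param width full width at half maximum, in cycle points (> 0)
#' @param n_points cycle length (default 300)
#' @return nonnegative numeric vector of length `n_points` with maximum 1
#' @export
generate_primitive <- function(center, width, n_points = 300L) {
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop("'width' must be a single positive number")
  if (!is.numeric(center) || length(center) != 1L ||
      center < 1 || center > n_points)
    stop("'center' must lie in [1, n_points]")
  sigma <- width / (2 * sqrt(2 * log(2)))   # FWHM = 2.355 sigma
  t <- seq_len(n_points)
  v <- exp(-((t - center)^2) / (2 * sigma^2))
  v / max(v)
}

#' Ground-truth synergy structure for a synthetic trial
#'
#' Builds the time-invariant module weights and primitive parameters of a
#' three-synergy landing: a touchdown synergy dominated by plantar flexors,
#' a weight-acceptance synergy dominated by knee extensors, and a
#' stabilization synergy dominated by hamstrings and the muscles spanning
#' the ankle. Defaults place the primitive centers at cycle points 90, 120
#' and 210 (late flight, early stance, mid stance).
#'
#' @param condition `"SG"` (stable) or `"UG"` (unstable ground)
#' @param p_true number of synergies (default 3; must satisfy
#'   `1 <= p_true < n_muscles`)
#' @param centers,widths,amplitudes per-synergy primitive parameters, in
#'   cycle points (centers, widths) and arbitrary units (amplitudes);
#'   recycled defaults exist only for `p_true = 3`
#' @param noise_snr envelope signal-to-noise ratio in dB (`Inf` = noiseless)
#' @param seed integer seed reserved for trial synthesis
#' @return object of class `ground_truth`
#' @export
default_ground_truth <- function(condition = c("SG", "UG"), p_true = 3L,
                                 centers = c(90, 120, 210),
                                 widths = c(50, 55, 70),
                                 amplitudes = c(1, 1, 1),
                                 noise_snr = 20, seed = 1L) {
  condition <- match.arg(condition)
  m <- length(landing_muscles)
  stopifnot(p_true >= 1L, p_true < m,
            length(centers) == p_true, length(widths) == p_true,
            length(amplitudes) == p_true, all(widths > 0))

  modules <- matrix(0.05, nrow = m, ncol = p_true,
                    dimnames = list(landing_muscles, NULL))
  if (p_true == 3L) {
    # touchdown: plantar flexors; weight acceptance: knee extensors;
    # stabilization: hamstrings + ankle dorsiflexor/everter
    modules[c("SO", "GM", "GL", "PL", "TA"), 1] <- c(0.9, 0.85, 0.8, 0.7, 0.3)
    modules[c("VM", "RF", "VL", "ME", "MA"), 2] <- c(0.9, 0.85, 0.85, 0.3, 0.3)
    modules[c("TA", "ST", "BF", "PL", "ME"), 3] <- c(0.8, 0.75, 0.7, 0.7, 0.4)
  } else {
    # generic distinct muscle emphasis per synergy
    for (j in seq_len(p_true)) {
      idx <- ((j - 1L) * (m %/% p_true)) + seq_len(m %/% p_true)
      modules[idx, j] <- 0.85
    }
  }
  structure(
    list(modules_true = modules,
         primitive_params = data.frame(center = centers, width = widths,
                                       amplitude = amplitudes),
         noise_snr = noise_snr, n_muscles = m, p_true = as.integer(p_true),
         condition = condition, seed = as.integer(seed)),
    class = "ground_truth")
}

#' True envelope matrix of a ground truth on the normalized cycle
#'
#' @param gt a `ground_truth` object
#' @param n_points cycle length
#' @return nonnegative matrix muscles x `n_points`
#' @export
true_envelopes <- function(gt, n_points = 300L) {
  P <- t(vapply(seq_len(gt$p_true), function(j) {
    gt$primitive_params$amplitude[j] *
      generate_primitive(gt$primitive_params$center[j],
                         gt$primitive_params$width[j], n_points)
  }, numeric(n_points)))
  gt$modules_true %*% P
}

# Smooth landing-shaped vertical GRF in units of body weight.
# Piecewise raised-cosine segments: flight, impact rise, peak-to-dip,
# dip-to-band rise, exponential settle inside the +-2.5% band. Strictly one
# 20 N crossing (at `touchdown`), strictly one local minimum after the peak.
vgrf_shape <- function(n_flight, s_peak, peak_rel, s_dip, dip_rel,
                       s_band, n_tail, bodyweight) {
  f0 <- 25 / bodyweight                 # first stance sample sits above 20 N
  band_edge <- 0.9755                   # just inside the lower band edge
  rise <- f0 + (peak_rel - f0) * sin(pi / 2 * (0:s_peak) / s_peak)^2
  fall <- dip_rel + (peak_rel - dip_rel) *
    cos(pi / 2 * seq_len(s_dip - s_peak) / (s_dip - s_peak))^2
  climb <- dip_rel + (band_edge - dip_rel) *
    sin(pi / 2 * seq_len(s_band - s_dip) / (s_band - s_dip))^2
  tail <- 1 - (1 - band_edge) * exp(-seq_len(n_tail) / 40)
  stance <- c(rise, fall, climb, tail) * bodyweight
  flight <- pmin(8 + 6 * sin(2 * pi * 3 * seq_len(n_flight) / 1000), 19)
  c(flight, stance)
}

#' Synthesize landing mechanics (GRF and CoP) for one trial
#'
#' Vertical GRF follows the canonical flight / impact-transient / dip /
#' settling shape, with the first 20 N crossing placed exactly at the true
#' touchdown sample and the series ending inside the body-weight +-2.5 %
#' band. The unstable condition has a slower post-impact force development
#' and a longer stance, and its CoP random walk has a smaller step size
#' (smaller sway ellipse). CoP is a mean-reverting AR(1) walk in 2-D.
#'
#' @param condition `"SG"` or `"UG"`
#' @param bodyweight body weight in N (> 0)
#' @param seed integer seed
#' @param rate sampling rate in Hz (default 1000)
#' @param lead extra flight samples before the 300 ms interval of interest
#' @return list with `grf` (n x 3 matrix, N; column 3 vertical), `cop`
#'   (n x 2 matrix, m), `touchdown_sample`, `stance_end_sample`, `rate`
#' @export
synthesize_mechanics <- function(condition = c("SG", "UG"), bodyweight,
                                 seed = 1L, rate = 1000, lead = 50L) {
  condition <- match.arg(condition)
  stopifnot(bodyweight > 0)
  set.seed(seed)
  n_flight <- lead + as.integer(round(rate * 0.3))
  if (condition == "SG") {
    s_peak <- round(runif(1, 30, 50)); peak_rel <- runif(1, 2.6, 3.4)
    dip_rel <- runif(1, 0.50, 0.70)
    s_band <- round(max(350, min(650, rnorm(1, 491, 62))))
    cop_step <- 6e-4
  } else {
    s_peak <- round(runif(1, 55, 85)); peak_rel <- runif(1, 2.3, 3.1)
    dip_rel <- runif(1, 0.55, 0.75)
    s_band <- round(max(480, min(850, rnorm(1, 629, 85))))
    cop_step <- 3.6e-4
  }
  s_dip <- s_peak + round(runif(1, 60, 100))
  n_tail <- 150L
  vz <- vgrf_shape(n_flight, s_peak, peak_rel, s_dip, dip_rel,
                   s_band, n_tail, bodyweight)
  n <- length(vz)
  touchdown <- n_flight + 1L

  # small smooth horizontal forces during stance only
  hx <- hy <- numeric(n)
  s <- seq_len(n - n_flight)
  hx[touchdown:n] <- 0.05 * bodyweight * exp(-s / 120) * sin(2 * pi * s / 180)
  hy[touchdown:n] <- 0.04 * bodyweight * exp(-s / 150) * cos(2 * pi * s / 220)
  grf <- cbind(x = hx, y = hy, z = vz)

  # mean-reverting CoP walk, condition-scaled dispersion
  cop <- matrix(0, n, 2, dimnames = list(NULL, c("x", "y")))
  rho <- 0.98
  for (i in (touchdown + 1L):n)
    cop[i, ] <- rho * cop[i - 1L, ] + rnorm(2, sd = cop_step)

  stance_end <- detect_stance_end(vz, touchdown, bodyweight)
  list(grf = grf, cop = cop, touchdown_sample = touchdown,
       stance_end_sample = stance_end, rate = rate)
}

# Map each raw sample of the interval of interest onto its cycle position
# (1..100 flight, 101..300 stance), clamped outside; used to paint the
# cycle-defined envelopes onto real time.
cycle_positions <- function(n_samples, interval_start, touchdown, stance_end,
                            flight_points = 100L, stance_points = 200L) {
  pos <- rep(1, n_samples)
  fl <- interval_start:(touchdown - 1L)
  st <- touchdown:stance_end
  pos[fl] <- 1 + (seq_along(fl) - 1) / (length(fl) - 1) * (flight_points - 1)
  pos[st] <- flight_points + 1 +
    (seq_along(st) - 1) / (length(st) - 1) * (stance_points - 1)
  if (stance_end < n_samples)
    pos[(stance_end + 1L):n_samples] <- flight_points + stance_points
  pos
}

#' Synthesize raw multichannel EMG for one trial
#'
#' Envelopes are the ground-truth reconstruction `M %*% P` evaluated along
#' the trial's cycle positions, corrupted by additive zero-truncated
#' Gaussian noise at the requested SNR, then multiplied by independent
#' zero-mean white-noise carriers band-passed to 20-450 Hz. The product is
#' a realistic interference-pattern surrogate: it is near zero-mean, passes
#' the 50 Hz high-pass, and its linear envelope tracks `M %*% P`.
#'
#' @param gt a `ground_truth` object
#' @param mech mechanics list from [synthesize_mechanics()]
#' @param seed integer seed
#' @return matrix muscles x samples (mV-like arbitrary units)
#' @export
synthesize_emg <- function(gt, mech, seed = 1L) {
  set.seed(seed)
  n <- nrow(mech$grf)
  rate <- mech$rate
  interval_start <- mech$touchdown_sample - as.integer(round(rate * 0.3))
  pos <- cycle_positions(n, interval_start, mech$touchdown_sample,
                         mech$stance_end_sample)
  env_cycle <- true_envelopes(gt)
  env <- t(apply(env_cycle, 1, function(e) approx(seq_len(300), e, pos)$y))

  if (is.finite(gt$noise_snr)) {
    sd_noise <- sqrt(rowMeans(env^2)) * 10^(-gt$noise_snr / 20)
    noise <- matrix(rnorm(length(env)), nrow(env)) * sd_noise
    env <- pmax(env + noise, 0)
  }

  bp <- signal::butter(4, c(20, 450) / (rate / 2), type = "pass")
  carrier <- t(apply(matrix(rnorm(gt$n_muscles * n), gt$n_muscles), 1,
                     function(w) {
                       y <- signal::filtfilt(bp, w)
                       y / sd(y)
                     }))
  emg <- env * carrier
  rownames(emg) <- landing_muscles
  emg
}

#' Synthesize one complete landing trial
#'
#' Combines [synthesize_mechanics()] and [synthesize_emg()], optionally
#' adding simple sagittal joint-moment and joint-angle series shaped after
#' a single-leg landing (moment bump peaking shortly after touchdown;
#' dorsiflexion excursion during stance).
#'
#' @param gt a `ground_truth` object (its `seed` drives all randomness)
#' @param bodyweight body weight in N
#' @param with_kinetics also generate `moments` and `angles` series
#' @return object of class `synthetic_trial`: list with `emg_raw`, `grf`,
#'   `cop`, `touchdown_sample_true`, `stance_end_sample`, `bodyweight`,
#'   `rate`, `condition`, optional `moments`/`angles`, and `ground_truth`
#' @export
synthesize_trial <- function(gt, bodyweight = 660, with_kinetics = TRUE) {
  mech <- synthesize_mechanics(gt$condition, bodyweight, seed = gt$seed)
  emg <- synthesize_emg(gt, mech, seed = gt$seed + 1L)
  trial <- list(emg_raw = emg, grf = mech$grf, cop = mech$cop,
                touchdown_sample_true = mech$touchdown_sample,
                stance_end_sample = mech$stance_end_sample,
                bodyweight = bodyweight, rate = mech$rate,
                condition = gt$condition, ground_truth = gt)
  if (with_kinetics) {
    n <- nrow(mech$grf)
    td <- mech$touchdown_sample
    s <- pmax(seq_len(n) - td, 0)
    peaks <- c(ankle = 184, knee = 137, hip = 262)
    ttp <- c(ankle = 56, knee = 73, hip = 77)
    trial$moments <- t(sapply(names(peaks), function(j) {
      peaks[[j]] * (s / ttp[[j]]) * exp(1 - s / ttp[[j]])  # gamma-like bump
    }))
    ang0 <- c(ankle = 110, knee = 160, hip = 170)
    exc <- c(ankle = 45, knee = 35, hip = 20)
    trial$angles <- t(sapply(names(ang0), function(j) {
      ang0[[j]] - exc[[j]] * (s / 150) * exp(1 - s / 150)
    }))
  }
  class(trial) <- "synthetic_trial"
  trial
}

#' Synthesize a seeded cohort of landing trials
#'
#' One global seed fans out into independent per-trial substreams, so whole
#' cohorts are reproducible and individual trials can be regenerated.
#'
#' @param n_trials number of trials
#' @param condition `"SG"` or `"UG"`
#' @param seed global integer seed
#' @param bodyweight body weight in N
#' @param noise_snr envelope SNR in dB
#' @param ... further arguments to [default_ground_truth()]
#' @return list of `synthetic_trial` objects
#' @export
synthesize_cohort <- function(n_trials, condition = c("SG", "UG"), seed = 1L,
                              bodyweight = 660, noise_snr = 20, ...) {
  condition <- match.arg(condition)
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max - 2L, n_trials)
  lapply(trial_seeds, function(s) {
    gt <- default_ground_truth(condition = condition, noise_snr = noise_snr,
                               seed = s, ...)
    synthesize_trial(gt, bodyweight = bodyweight)
  })
}

#' Write a cohort of trials to a fixture directory
#'
#' Each trial becomes a subdirectory of per-stream wide CSV files (column 1
#' is time in s, remaining columns the channels) plus a `meta.json` sidecar
#' holding ground truth and trial metadata. This is the pipeline's native
#' plain-text fixture format.
#'
#' @param trials list of `synthetic_trial` objects
#' @param dir output directory (created if missing)
#' @return invisibly, the trial directories written
#' @export
write_trials <- function(trials, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    td <- file.path(dir, sprintf("trial_%03d", i))
    dir.create(td, showWarnings = FALSE)
    tm <- (seq_len(ncol(tr$emg_raw)) - 1) / tr$rate
    write_stream <- function(x, name) {
      df <- data.frame(time = tm, t(x), check.names = FALSE)
      write.csv(df, file.path(td, paste0(name, ".csv")), row.names = FALSE)
    }
    write_stream(tr$emg_raw, "emg")
    write_stream(t(tr$grf), "grf")
    write_stream(t(tr$cop), "cop")
    if (!is.null(tr$moments)) write_stream(tr$moments, "moments")
    if (!is.null(tr$angles)) write_stream(tr$angles, "angles")
    gt <- tr$ground_truth
    meta <- list(
      condition = tr$condition, bodyweight = tr$bodyweight, rate = tr$rate,
      muscle_labels = rownames(tr$emg_raw),
      touchdown_sample_true = tr$touchdown_sample_true,
      stance_end_sample = tr$stance_end_sample,
      ground_truth = list(
        modules_true = gt$modules_true, primitive_params = gt$primitive_params,
        noise_snr = gt$noise_snr, p_true = gt$p_true, seed = gt$seed))
    jsonlite::write_json(meta, file.path(td, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
    td
  }, character(1))
  invisible(paths)
}

#' Read a cohort of trials from a fixture directory
#'
#' @param dir directory written by [write_trials()]
#' @return list of `synthetic_trial` objects
#' @export
read_trials <- function(dir) {
  tds <- sort(list.dirs(dir, recursive = FALSE))
  if (!length(tds)) stop("no trial directories found in ", dir)
  lapply(tds, function(td) {
    meta <- jsonlite::read_json(file.path(td, "meta.json"),
                                simplifyVector = TRUE)
    read_stream <- function(name) {
      f <- file.path(td, paste0(name, ".csv"))
      if (!file.exists(f)) return(NULL)
      x <- read.csv(f, check.names = FALSE)
      t(as.matrix(x[, -1, drop = FALSE]))
    }
    gt <- meta$ground_truth
    modules <- as.matrix(gt$modules_true)
    dimnames(modules) <- list(meta$muscle_labels, NULL)
    trial <- list(
      emg_raw = read_stream("emg"), grf = t(read_stream("grf")),
      cop = t(read_stream("cop")),
      touchdown_sample_true = meta$touchdown_sample_true,
      stance_end_sample = meta$stance_end_sample,
      bodyweight = meta$bodyweight, rate = meta$rate,
      condition = meta$condition,
      ground_truth = structure(
        list(modules_true = modules,
             primitive_params = as.data.frame(gt$primitive_params),
             noise_snr = gt$noise_snr, n_muscles = nrow(modules),
             p_true = gt$p_true, condition = meta$condition, seed = gt$seed),
        class = "ground_truth"))
    mo <- read_stream("moments"); an <- read_stream("angles")
    if (!is.null(mo)) trial$moments <- mo
    if (!is.null(an)) trial$angles <- an
    class(trial) <- "synthetic_trial"
    trial
  })
}
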