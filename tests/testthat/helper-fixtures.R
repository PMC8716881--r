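# Shared fixtures, memoised so expensive cohorts are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

# A processed 50-trial stable-ground cohort with known 3-synergy ground
# truth at 20 dB envelope SNR: conditioned, segmented, time- and
# amplitude-normalized, synergies extracted per trial (ranks 1..13), plus a
# dedicated rank-3 factorization matched against the ground truth.
processed_sg_cohort <- function(n_trials = 50L, seed = 101L) {
  key <- sprintf("sg_%d_%d", n_trials, seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])

  trials <- synthesize_cohort(n_trials, "SG", seed = seed, noise_snr = 20)
  nts <- lapply(trials, function(tr) {
    seg <- segment_landing(tr$grf[, 3L], tr$bodyweight, rate = tr$rate)
    env <- condition_emg(tr$emg_raw, tr$rate)
    nt <- normalize_trial(env, tr$grf, seg, condition = tr$condition)
    nt$segmentation <- seg
    nt$touchdown_sample_true <- tr$touchdown_sample_true
    nt
  })
  envs <- lapply(nts, `[[`, "emg")
  for (i in seq_along(nts))
    nts[[i]]$emg <- normalize_amplitude(nts[[i]]$emg, envs)

  set.seed(seed + 1L)
  ex_seeds <- sample.int(.Machine$integer.max - 2L, n_trials)
  extractions <- Map(function(nt, s)
    suppressWarnings(extract_synergies(nt$emg, seed = s)),
    nts, ex_seeds)

  gt <- trials[[1L]]$ground_truth
  P_true <- t(vapply(seq_len(gt$p_true), function(j)
    generate_primitive(gt$primitive_params$center[j],
                       gt$primitive_params$width[j]), numeric(300)))
  # amplitude normalization rescales each muscle row of V, so the planted
  # modules as represented in the analysis space are the row-rescaled ones
  M_ref <- gt$modules_true / apply(true_envelopes(gt), 1L, max)
  matches <- Map(function(nt, s) {
    fit3 <- nmf_factorize(nt$emg, p = 3L, seed = s)
    nf <- suppressWarnings(normalize_factors(fit3$M, fit3$P))
    match_synergies(nf$M, M_ref, nf$P, P_true)
  }, nts, ex_seeds)

  out <- list(trials = trials, normalized = nts, extractions = extractions,
              matches = matches, ground_truth = gt, P_true = P_true)
  .fixture_cache[[key]] <- out
  out
}

# brute-force count of supra-half-maximum points (independent FWHM oracle)
fwhm_bruteforce <- function(x) {
  x <- x - min(x)
  thr <- max(x) / 2
  n <- 0L
  for (v in x) if (v > thr) n <- n + 1L
  n
}
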