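# End-to-end orchestration: simulate -> condition -> segment/normalize ->
# extract -> classify -> metrics, with every printed constant of the
# analysis exposed as a named configuration key and a deterministic
# artifact tree per run.

#' Pipeline configuration with the analysis' canonical constants
#'
#' All thresholds default to the printed constants of the landing analysis:
#' 20 N touchdown threshold, body-weight band of +-2.5 %, 300 ms
#' pre-touchdown window with 100+200-point normalization, rank-selection
#' regression MSE 1e-5, elbow interpolation MSE 1e-3, 10 NMF restarts,
#' 20 k-means start sets, classification score tolerance 0.05.
#'
#' @param seed global integer seed fanned out to every stage
#' @param n_trials trials simulated per condition (52 with exclusion, so 50
#'   enter the analysis)
#' @param bodyweight simulated body weight, N
#' @param noise_snr envelope SNR of the simulated EMG, dB
#' @param drop_first_last drop the first and last landing of each series
#' @param touchdown_threshold N; `bw_band` fraction; `rank_mse`, `elbow_mse`
#'   selection thresholds; `nmf_restarts`, `kmeans_nstart`, `score_tol`
#'   algorithm settings
#' @param touchdown_threshold,bw_band,rank_mse,elbow_mse,nmf_restarts,kmeans_nstart,score_tol see above
#' @param out_dir optional directory for CSV/JSON artifacts
#' @return named list of class `run_config`
#' @export
pipeline_config <- function(seed = 1L, n_trials = 52L, bodyweight = 660,
                            noise_snr = 20, drop_first_last = TRUE,
                            touchdown_threshold = 20, bw_band = 0.025,
                            rank_mse = 1e-5, elbow_mse = 1e-3,
                            nmf_restarts = 10L, kmeans_nstart = 20L,
                            score_tol = 0.05, out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), n_trials = as.integer(n_trials),
              bodyweight = bodyweight, noise_snr = noise_snr,
              drop_first_last = drop_first_last,
              touchdown_threshold = touchdown_threshold, bw_band = bw_band,
              rank_mse = rank_mse, elbow_mse = elbow_mse,
              nmf_restarts = as.integer(nmf_restarts),
              kmeans_nstart = as.integer(kmeans_nstart),
              score_tol = score_tol, out_dir = out_dir)
  thr <- c(cfg$touchdown_threshold, cfg$bw_band, cfg$rank_mse, cfg$elbow_mse)
  if (any(thr <= 0)) stop("all thresholds must be positive")
  class(cfg) <- "run_config"
  cfg
}

# stage: condition + segment + time-normalize one trial; NULL on rejection
process_trial <- function(trial, cfg) {
  tryCatch({
    seg <- segment_landing(trial$grf[, 3L], trial$bodyweight,
                           rate = trial$rate)
    env <- condition_emg(trial$emg_raw, trial$rate)
    nt <- normalize_trial(env, trial$grf, seg,
                          angles = trial$angles, moments = trial$moments,
                          condition = trial$condition)
    nt$segmentation <- seg
    nt$envelope_raw <- env
    nt$cop_stance <- trial$cop[seg$touchdown_index:seg$stance_end_index, ,
                               drop = FALSE]
    nt$touchdown_sample_true <- trial$touchdown_sample_true
    nt
  }, error = function(e) {
    warning("trial rejected: ", conditionMessage(e))
    NULL
  })
}

#' Run the complete landing-synergy analysis on synthetic cohorts
#'
#' Simulates one series of landings per condition, conditions and
#' amplitude-normalizes the EMG (reference maxima from the stable-ground
#' series), segments and time-normalizes every trial, extracts the muscle
#' synergies per trial, classifies them per condition, and computes the
#' spatiotemporal metrics. Failed trials are quarantined and reported, not
#' silently dropped. With `out_dir` set, writes deterministic CSV/JSON
#' artifacts (normalized trials, synergy sets, classification and metric
#' tables, a JSON summary).
#'
#' @param config a [pipeline_config()]
#' @param trials optional named list (`SG`, `UG`) of pre-generated trial
#'   cohorts; by default cohorts are simulated from the config
#' @return list with per-condition `normalized`, `synergies`,
#'   `classification`, tidy `metrics` and `cop_areas` tables, `summary`,
#'   and `quarantined` counts
#' @export
run_pipeline <- function(config = pipeline_config(), trials = NULL) {
  cfg <- config
  set.seed(cfg$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 2L, 6L)

  if (is.null(trials)) {
    trials <- list(
      SG = synthesize_cohort(cfg$n_trials, "SG", seed = stage_seeds[1L],
                             bodyweight = cfg$bodyweight,
                             noise_snr = cfg$noise_snr),
      UG = synthesize_cohort(cfg$n_trials, "UG", seed = stage_seeds[2L],
                             bodyweight = cfg$bodyweight,
                             noise_snr = cfg$noise_snr))
  }
  if (!length(trials) || !all(lengths(trials) > 0))
    stop("no input trials")
  if (cfg$drop_first_last) {
    trials <- lapply(trials, function(tt) {
      if (length(tt) > 2L) tt[-c(1L, length(tt))] else tt
    })
  }

  processed <- lapply(trials, function(tt) lapply(tt, process_trial, cfg))
  quarantined <- vapply(processed, function(p) sum(vapply(p, is.null,
                                                          logical(1))),
                        integer(1))
  processed <- lapply(processed, function(p) Filter(Negate(is.null), p))

  # amplitude normalization against the SG-series interval-of-interest maxima
  sg_envs <- lapply(processed$SG, `[[`, "emg")
  processed <- lapply(processed, function(p) lapply(p, function(nt) {
    nt$emg <- normalize_amplitude(nt$emg, sg_envs)
    nt
  }))

  # per-trial synergy extraction
  set.seed(stage_seeds[3L])
  syn <- lapply(processed, function(p) {
    seeds <- sample.int(.Machine$integer.max - 2L, length(p))
    Map(function(nt, s) extract_synergies(nt$emg, seed = s,
                                          n_restarts = cfg$nmf_restarts,
                                          tol = cfg$rank_mse),
        p, seeds)
  })

  # per-condition classification of the pooled primitives/modules
  cls <- list()
  for (cond in names(syn)) {
    prim <- do.call(rbind, lapply(syn[[cond]], `[[`, "P"))
    mods <- do.call(rbind, lapply(syn[[cond]], function(s) t(s$M)))
    idx <- rep(seq_along(syn[[cond]]),
               vapply(syn[[cond]], `[[`, integer(1), "p"))
    cl <- classify_synergies(prim, mods, seed = stage_seeds[4L],
                             score_tol = cfg$score_tol)
    cl$table$trial <- idx
    # per-trial synergy index, matching the metrics table
    cl$table$synergy <- sequence(vapply(syn[[cond]], `[[`, integer(1), "p"))
    cls[[cond]] <- cl
  }

  metrics <- do.call(rbind, lapply(names(syn), function(cond) {
    do.call(rbind, Map(function(s, trial_id) {
      do.call(rbind, lapply(seq_len(s$p), function(j) {
        cais <- vapply(c("hip", "knee", "ankle"), function(jt)
          coactivation_index(s$M[, j], jt)$cai, numeric(1))
        data.frame(condition = cond, trial = trial_id, synergy = j,
                   fwhm = fwhm(s$P[j, ]), coa = coa(s$P[j, ]),
                   cai_hip = cais[["hip"]], cai_knee = cais[["knee"]],
                   cai_ankle = cais[["ankle"]])
      }))
    }, syn[[cond]], seq_along(syn[[cond]])))
  }))

  cop_areas <- do.call(rbind, lapply(names(processed), function(cond) {
    data.frame(condition = cond,
               trial = seq_along(processed[[cond]]),
               cop_area = vapply(processed[[cond]], function(nt)
                 cop_ellipse_area(nt$cop_stance), numeric(1)))
  }))

  # named lists (not named vectors) so the JSON summary keeps the names
  summary <- list(
    seed = cfg$seed,
    n_trials = as.list(vapply(processed, length, integer(1))),
    quarantined = as.list(quarantined),
    k = as.list(vapply(cls, `[[`, integer(1), "k")),
    cluster_names = lapply(cls, `[[`, "cluster_names"),
    fundamental_fraction = as.list(vapply(cls, function(cl)
      mean(cl$table$label == "fundamental"), numeric(1))),
    mean_rank = as.list(vapply(syn, function(s)
      mean(vapply(s, `[[`, integer(1), "p")), numeric(1))),
    mean_cop_area = as.list(tapply(cop_areas$cop_area, cop_areas$condition,
                                   mean)))

  res <- list(config = cfg, normalized = processed, synergies = syn,
              classification = cls, metrics = metrics,
              cop_areas = cop_areas, summary = summary,
              quarantined = quarantined)
  if (!is.null(cfg$out_dir)) write_run_artifacts(res, cfg$out_dir)
  res
}

# deterministic CSV/JSON artifact tree for a finished run
write_run_artifacts <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(res$metrics, file.path(dir, "synergy_metrics.csv"),
            row.names = FALSE)
  write.csv(res$cop_areas, file.path(dir, "cop_areas.csv"),
            row.names = FALSE)
  for (cond in names(res$classification)) {
    cl <- res$classification[[cond]]
    write.csv(cl$table,
              file.path(dir, sprintf("classification_%s.csv", cond)),
              row.names = FALSE)
    write.csv(as.data.frame(cl$centroid_primitives),
              file.path(dir, sprintf("centroids_%s.csv", cond)),
              row.names = FALSE)
  }
  jsonlite::write_json(res$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
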