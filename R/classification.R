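# Unsupervised classification of extracted synergies: k-means on motor
# primitives with an elbow rule for the cluster count, module clustering at
# the imposed k, a FWHM+CoA score comparing the two partitions, and
# fundamental/combined labelling by partition agreement.

as_primitive_matrix <- function(primitives) {
  if (is.list(primitives)) primitives <- do.call(rbind, primitives)
  primitives <- as.matrix(primitives)
  if (!nrow(primitives)) stop("empty primitive collection")
  primitives
}

#' Cluster motor primitives over a range of cluster counts
#'
#' Runs Hartigan-Wong k-means with 20 random start sets for every candidate
#' cluster count `k = 1..m` and records the within-cluster sum of squares
#' curve, min-max normalized to `[0, 1]`.
#'
#' @param primitives matrix (or list) of 300-point primitive series, one
#'   series per row
#' @param m number of muscles, the upper bound on the cluster count
#' @param seed integer seed
#' @param nstart random start sets per k (default 20)
#' @return list with `fits` (one `kmeans` object per k), `wss_curve_raw`,
#'   and the normalized `wss_curve`
#' @export
cluster_primitives <- function(primitives, m = length(landing_muscles),
                               seed = 1L, nstart = 20L) {
  x <- as_primitive_matrix(primitives)
  if (nrow(x) < 2L) stop("need at least 2 primitive series to cluster")
  # k-means needs at least k distinct points; duplicates are allowed in the
  # input but cap the candidate range accordingly
  kmax <- min(m, nrow(x) - 1L, nrow(unique(x)))
  set.seed(seed)
  fits <- lapply(seq_len(kmax), function(k) {
    kmeans(x, centers = k, nstart = nstart, iter.max = 100L,
           algorithm = "Hartigan-Wong")
  })
  wss <- vapply(fits, `[[`, numeric(1), "tot.withinss")
  rng <- diff(range(wss))
  wss_norm <- if (rng == 0) rep(0, length(wss)) else
    (wss - min(wss)) / rng
  list(fits = fits, wss_curve_raw = wss, wss_curve = wss_norm)
}

#' Select the cluster count from the normalized WSS curve
#'
#' Finds the longest trailing segment of the curve that a least-squares
#' straight line interpolates with mean squared error below `tol`; the
#' cluster count is the index at which that segment starts, i.e. the elbow
#' beyond which adding clusters only removes scatter linearly. With `q`
#' interpolable trailing points out of `m`, the selected count is
#' `m - q + 1`, so a curve that is linear throughout yields one cluster.
#'
#' @param wss_curve WSS-versus-k curve normalized to `[0, 1]`, length `m`
#' @param m number of muscles (upper clamp for the count)
#' @param tol interpolation MSE threshold (default 1e-3)
#' @return selected cluster count
#' @export
select_k <- function(wss_curve, m = length(wss_curve), tol = 1e-3) {
  n <- length(wss_curve)
  if (n < 2L) return(1L)
  for (ii in seq_len(n)) {
    y <- wss_curve[ii:n]
    mse <- if (length(y) < 3L) 0 else {
      x <- ii:n
      mean(lm(y ~ x)$residuals^2)
    }
    if (mse < tol) return(min(ii, m))
  }
  min(n, m)
}

#' Cluster motor modules at an imposed cluster count
#'
#' @param modules matrix of module weight vectors, one synergy per row
#' @param k cluster count imposed from the primitive-side analysis
#' @param seed integer seed
#' @param nstart random start sets (default 20)
#' @return `kmeans` fit
#' @export
cluster_modules <- function(modules, k, seed = 1L, nstart = 20L) {
  modules <- as_primitive_matrix(modules)
  if (k > nrow(modules)) stop("more clusters than synergies")
  set.seed(seed)
  kmeans(modules, centers = k, nstart = nstart, iter.max = 100L,
         algorithm = "Hartigan-Wong")
}

#' Spatiotemporal score of a synergy partition
#'
#' For each cluster, the member primitives' FWHM and CoA are averaged; the
#' cluster means are then averaged across clusters and the summed mean FWHM
#' and mean CoA normalized by the cycle length (300). The score summarizes
#' where and how widely a partition's synergies are active, and is used to
#' compare primitive- and module-based clusterings.
#'
#' @param primitives matrix of primitive series, one synergy per row
#' @param assignments integer cluster label per synergy
#' @return unitless score
#' @export
score_classification <- function(primitives, assignments) {
  x <- as_primitive_matrix(primitives)
  stopifnot(nrow(x) == length(assignments))
  fw <- apply(x, 1L, fwhm)
  ca <- apply(x, 1L, coa)
  cl_fw <- tapply(fw, assignments, mean)
  cl_ca <- tapply(ca, assignments, mean)
  (mean(cl_fw) + mean(cl_ca)) / ncol(x)
}

# Align the labels of partition b onto partition a by the one-to-one
# relabelling maximizing co-occurrence (exhaustive over permutations).
align_partitions <- function(a, b, k) {
  tab <- matrix(0L, k, k)
  for (i in seq_along(a)) tab[a[i], b[i]] <- tab[a[i], b[i]] + 1L
  perms <- permutations_of(k)
  scores <- vapply(perms, function(pr) sum(tab[cbind(seq_len(k), pr)]),
                   numeric(1))
  best <- perms[[which.max(scores)]]
  # best[j] = module label matched to primitive label j; invert to relabel b
  inv <- integer(k)
  inv[best] <- seq_len(k)
  inv[b]
}

#' Label synergies as fundamental or combined
#'
#' Aligns the module-based cluster labels onto the primitive-based ones by
#' maximal co-occurrence; synergies on which the two classifiers agree are
#' fundamental, discordant ones combined (spurious merges). When the two
#' partitions' spatiotemporal scores differ by more than `score_tol`, no
#' matching is declared and the primitive-based classification is retained
#' alone (all synergies labelled by it, matching flagged as failed).
#'
#' @param assignments_primitive,assignments_module integer cluster labels
#'   per synergy from the two classifiers
#' @param score_primitive,score_module partition scores from
#'   [score_classification()]
#' @param score_tol absolute score-difference tolerance (default 0.05)
#' @return list with `labels` (`"fundamental"`/`"combined"`),
#'   `assignments_module_aligned`, and `matching_failed`
#' @export
label_synergies <- function(assignments_primitive, assignments_module,
                            score_primitive, score_module,
                            score_tol = 0.05) {
  k <- max(assignments_primitive)
  if (abs(score_primitive - score_module) > score_tol) {
    return(list(labels = rep("fundamental", length(assignments_primitive)),
                assignments_module_aligned = rep(NA_integer_,
                                                 length(assignments_module)),
                matching_failed = TRUE))
  }
  aligned <- align_partitions(assignments_primitive, assignments_module, k)
  list(labels = ifelse(aligned == assignments_primitive,
                       "fundamental", "combined"),
       assignments_module_aligned = aligned,
       matching_failed = FALSE)
}

#' Classify a condition's extracted synergies
#'
#' Full unsupervised classification: k-means over the pooled motor
#' primitives for `k = 1..m`, elbow selection of the cluster count,
#' module clustering at the imposed k, partition scoring, fundamental /
#' combined labelling, and post hoc functional naming of the clusters by
#' the order of their centroid centres of activity along the cycle
#' (touchdown, then weight acceptance, then stabilization when three
#' clusters are found).
#'
#' @param primitives matrix (or list) of primitive series, one synergy per
#'   row, pooled over the condition's trials
#' @param modules matrix (or list) of matching module weight vectors
#' @param m number of muscles (default 13)
#' @param seed integer seed
#' @param score_tol score tolerance passed to [label_synergies()]
#' @return object of class `synergy_classification`: a `table` data frame
#'   (synergy, cluster, functional name, label), `k`, the normalized
#'   `wss_curve`, `centroid_primitives`, scores and the failure flag
#' @export
classify_synergies <- function(primitives, modules,
                               m = length(landing_muscles), seed = 1L,
                               score_tol = 0.05) {
  x <- as_primitive_matrix(primitives)
  mods <- as_primitive_matrix(modules)
  stopifnot(nrow(x) == nrow(mods))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 2L, 2L)

  cp <- cluster_primitives(x, m = m, seed = seeds[1L])
  k <- select_k(cp$wss_curve, m = m)
  k <- min(k, length(cp$fits))
  fit_p <- cp$fits[[k]]
  fit_m <- cluster_modules(mods, k, seed = seeds[2L])

  score_p <- score_classification(x, fit_p$cluster)
  score_m <- score_classification(x, fit_m$cluster)
  lab <- label_synergies(fit_p$cluster, fit_m$cluster, score_p, score_m,
                         score_tol = score_tol)

  centroid_coa <- apply(fit_p$centers, 1L, coa)
  ord <- order(centroid_coa)
  fnames <- if (k == 3L) c("touchdown", "weight_acceptance", "stabilization")
            else paste0("cluster_", seq_len(k))
  cluster_name <- character(k)
  cluster_name[ord] <- fnames

  tbl <- data.frame(
    synergy = seq_len(nrow(x)),
    cluster_primitive = fit_p$cluster,
    cluster_module = lab$assignments_module_aligned,
    functional_name = cluster_name[fit_p$cluster],
    label = lab$labels)

  structure(list(table = tbl, k = k, wss_curve = cp$wss_curve,
                 centroid_primitives = fit_p$centers,
                 centroid_coa = centroid_coa,
                 cluster_names = cluster_name,
                 score_primitive = score_p, score_module = score_m,
                 matching_failed = lab$matching_failed, seed = seed),
            class = "synergy_classification")
}

#' @export
print.synergy_classification <- function(x, ...) {
  cat(sprintf(
    "synergy_classification: k = %d (%s); %d/%d fundamental%s\n",
    x$k, paste(x$cluster_names[order(x$centroid_coa)], collapse = " < "),
    sum(x$table$label == "fundamental"), nrow(x$table),
    if (x$matching_failed) "; module matching FAILED" else ""))
  invisible(x)
}
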