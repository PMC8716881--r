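# Muscle-synergy extraction: classical squared-error ("Gaussian") NMF by
# Lee-Seung multiplicative updates (inner loop in C++), with R^2-regression
# model-order selection and scale normalization of the factors.

#' Non-negative matrix factorization of one trial's envelope matrix
#'
#' Factorizes the nonnegative muscles x time matrix `V` into motor modules
#' `M` (muscles x p) and motor primitives `P` (p x time) so that
#' `V ~ M %*% P`, minimizing the squared Frobenius error with multiplicative
#' updates. Reconstruction quality is
#' `R^2 = 1 - ||V - MP||_F^2 / ||V - mean(V)||_F^2`. Several random restarts
#' are run from elementwise uniform initializations and the best fit kept;
#' everything is driven by `seed`, so results are reproducible.
#'
#' @param V nonnegative numeric matrix, muscles x time points
#' @param p factorization rank, `1 <= p <= nrow(V)`
#' @param seed integer seed for the restart initializations
#' @param n_restarts random restarts per rank (default 10)
#' @param tol minimal R-squared improvement counted as progress (default
#'   1e-5)
#' @param patience consecutive stalled iterations before stopping (default
#'   20)
#' @param max_iter iteration cap per restart (default 1000)
#' @param init optional list with strictly positive `W` (muscles x p) and
#'   `H` (p x time) used as one extra deterministic warm-start candidate
#'   alongside the random restarts
#' @return list with `M`, `P`, `r_squared`, `iterations`, `err_trace` (of
#'   the winning restart)
#' @export
nmf_factorize <- function(V, p, seed = 1L, n_restarts = 10L, tol = 1e-5,
                          patience = 20L, max_iter = 1000L, init = NULL) {
  V <- as.matrix(V)
  if (any(V < 0)) stop("'V' must be elementwise nonnegative")
  if (all(V == 0)) stop("all-zero input matrix; nothing to factorize")
  m <- nrow(V); n <- ncol(V)
  if (p < 1L || p > m) stop("rank 'p' must lie in 1..nrow(V)")

  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    W0 <- matrix(runif(m * p, min = .Machine$double.eps), m, p)
    H0 <- matrix(runif(p * n, min = .Machine$double.eps), p, n)
    fit <- .nmf_mu_cpp(V, W0, H0, tol, patience, max_iter)
    if (is.null(best) || fit$r2 > best$r2) best <- fit
  }
  if (!is.null(init)) {
    stopifnot(all(dim(init$W) == c(m, p)), all(dim(init$H) == c(p, n)))
    fit <- .nmf_mu_cpp(V, init$W, init$H, tol, patience, max_iter)
    if (fit$r2 > best$r2) best <- fit
  }
  rownames(best$W) <- rownames(V)
  list(M = best$W, P = best$H, r_squared = best$r2,
       iterations = best$iterations, err_trace = best$err_trace)
}

#' Select the number of synergies from the R-squared curve
#'
#' The model order is the smallest rank `k` for which a least-squares line
#' fitted to the R-squared-versus-rank curve restricted to ranks `k..m` has
#' mean squared error below `tol`: past that rank the curve is already
#' linear, so extra synergies no longer improve the reconstruction.
#'
#' @param r_squared_curve R-squared values at ranks `1..m`
#' @param tol regression MSE threshold (default 1e-5)
#' @return selected rank, with attribute `converged` (FALSE when no segment
#'   satisfied the threshold and `m` was returned)
#' @export
select_rank <- function(r_squared_curve, tol = 1e-5) {
  m <- length(r_squared_curve)
  if (any(diff(r_squared_curve) < -1e-4))
    warning("R-squared curve decreases beyond tolerance; proceeding")
  for (k in seq_len(m)) {
    y <- r_squared_curve[k:m]
    mse <- if (length(y) < 3L) 0 else {
      x <- k:m
      mean(lm(y ~ x)$residuals^2)
    }
    if (mse < tol) return(structure(k, converged = TRUE))
  }
  structure(m, converged = FALSE)
}

#' Transfer the scale indeterminacy of NMF onto the modules
#'
#' Scales each motor primitive (row of `P`) to unit maximum and multiplies
#' the corresponding module column by the inverse factor, leaving the
#' reconstruction `M %*% P` unchanged. All-zero primitives are dropped with
#' a warning.
#'
#' @param M modules matrix, muscles x p
#' @param P primitives matrix, p x time
#' @return list with rescaled `M` and `P`
#' @export
normalize_factors <- function(M, P) {
  s <- apply(P, 1L, max)
  if (any(s == 0)) {
    warning("dropping all-zero primitive(s)")
    keep <- s > 0
    M <- M[, keep, drop = FALSE]
    P <- P[keep, , drop = FALSE]
    s <- s[keep]
  }
  list(M = M * rep(s, each = nrow(M)), P = P / s)
}

#' Extract the muscle synergies of one normalized trial
#'
#' Runs [nmf_factorize()] at every candidate rank `1..m`, builds the
#' R-squared curve, selects the model order with [select_rank()], and
#' normalizes the winning factors with [normalize_factors()]. Per-rank
#' restart families get independent substreams of `seed`. Besides its
#' random restarts, each rank receives one warm-start candidate nested in
#' the previous rank's best fit (augmented by a small random component),
#' which keeps the R-squared curve non-decreasing up to convergence noise.
#'
#' @param V nonnegative muscles x 300 envelope matrix
#' @param seed integer seed
#' @param ranks candidate ranks (default `1:nrow(V)`)
#' @param ... passed on to [nmf_factorize()]
#' @return object of class `synergy_set`: `M`, `P`, `p`, `r_squared`,
#'   `r_squared_curve`, `rank_converged`, `seed`, `iterations`
#' @export
extract_synergies <- function(V, seed = 1L, ranks = seq_len(nrow(V)), ...) {
  set.seed(seed)
  rank_seeds <- sample.int(.Machine$integer.max - 2L, length(ranks))
  ranks_ord <- order(ranks)
  fits <- vector("list", length(ranks))
  prev <- NULL
  small <- 0.01 * mean(V)
  for (i in ranks_ord) {
    p <- ranks[i]
    init <- NULL
    if (!is.null(prev) && ncol(prev$M) == p - 1L) {
      # nested warm start: previous solution plus one small positive component
      set.seed(rank_seeds[i] %% .Machine$integer.max + 1L)
      init <- list(
        W = cbind(prev$M + small, matrix(runif(nrow(V), 0, small), nrow(V))),
        H = rbind(prev$P + small, matrix(runif(ncol(V), 0, small),
                                         1L, ncol(V))))
    }
    fits[[i]] <- nmf_factorize(V, p, seed = rank_seeds[i], init = init, ...)
    prev <- fits[[i]]
  }
  curve <- vapply(fits, `[[`, numeric(1), "r_squared")
  p_sel <- select_rank(curve)
  fit <- fits[[which(ranks == as.integer(p_sel))]]
  nf <- normalize_factors(fit$M, fit$P)
  structure(list(M = nf$M, P = nf$P, p = as.integer(p_sel),
                 r_squared = fit$r_squared, r_squared_curve = curve,
                 rank_converged = attr(p_sel, "converged"),
                 seed = as.integer(seed), iterations = fit$iterations),
            class = "synergy_set")
}

#' @export
print.synergy_set <- function(x, ...) {
  cat(sprintf("synergy_set: %d muscles, %d synergies, R^2 = %.4f\n",
              nrow(x$M), x$p, x$r_squared))
  invisible(x)
}

#' Match estimated synergies to a reference set
#'
#' Finds the one-to-one assignment of estimated to reference synergies that
#' maximizes the total cosine similarity between module columns, by
#' exhaustive permutation (exact for the small ranks used here). Useful for
#' validating factor recovery on synthetic cohorts.
#'
#' @param M_est,M_ref module matrices with equal column counts (<= 8)
#' @param P_est,P_ref optional primitive matrices (synergies in rows); when
#'   given, matched primitive Pearson correlations are returned too
#' @return list with `perm` (reference column matched to each estimated
#'   column), `cosine` per matched pair, and optionally `correlation`
#' @export
match_synergies <- function(M_est, M_ref, P_est = NULL, P_ref = NULL) {
  p <- ncol(M_est)
  stopifnot(ncol(M_ref) == p, p <= 8L)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sim <- outer(seq_len(p), seq_len(p),
               Vectorize(function(i, j) cosine(M_est[, i], M_ref[, j])))
  perms <- permutations_of(p)
  scores <- vapply(perms, function(pr) sum(sim[cbind(seq_len(p), pr)]),
                   numeric(1))
  best <- perms[[which.max(scores)]]
  out <- list(perm = best, cosine = sim[cbind(seq_len(p), best)])
  if (!is.null(P_est) && !is.null(P_ref)) {
    out$correlation <- vapply(seq_len(p), function(i) {
      stats::cor(P_est[i, ], P_ref[best[i], ])
    }, numeric(1))
  }
  out
}

# all permutations of 1..k, as a list (insert k at every position of each
# permutation of 1..k-1)
permutations_of <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- permutations_of(k - 1L)
  out <- vector("list", k * length(sub))
  idx <- 1L
  for (s in sub) for (pos in seq_len(k)) {
    out[[idx]] <- append(s, k, after = pos - 1L)
    idx <- idx + 1L
  }
  out
}
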