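test_that("well-separated primitive families cluster purely", {
  set.seed(31)
  fam1 <- t(sapply(1:10, function(i)
    generate_primitive(80 + rnorm(1, sd = 3), 40) + runif(300, 0, 0.02)))
  fam2 <- t(sapply(1:10, function(i)
    generate_primitive(180 + rnorm(1, sd = 3), 40) + runif(300, 0, 0.02)))
  x <- rbind(fam1, fam2)
  cp <- cluster_primitives(x, m = 13L, seed = 5L)
  fit2 <- cp$fits[[2L]]
  truth <- rep(1:2, each = 10L)
  # brute-force nearest-centroid check + purity up to label permutation
  nearest <- apply(x, 1L, function(row) {
    which.min(colSums((t(fit2$centers) - row)^2))
  })
  expect_identical(as.integer(fit2$cluster), as.integer(nearest))
  expect_true(length(unique(fit2$cluster[truth == 1])) == 1L &&
              length(unique(fit2$cluster[truth == 2])) == 1L &&
              fit2$cluster[1L] != fit2$cluster[20L])
  # WSS curve is normalized to [0, 1] and non-increasing
  expect_equal(range(cp$wss_curve), c(0, 1))
  expect_true(all(diff(cp$wss_curve) <= 1e-8))
})

test_that("identical series give zero within-cluster scatter at one cluster", {
  x <- matrix(rep(generate_primitive(100, 30), 4), 4, byrow = TRUE)
  cp <- cluster_primitives(x, m = 13L, seed = 1L)
  expect_equal(cp$wss_curve_raw[1L], 0, tolerance = 1e-20)
})

test_that("seeded clustering is reproducible", {
  set.seed(32)
  x <- matrix(runif(30 * 300), 30)
  c1 <- cluster_primitives(x, seed = 4L)
  c2 <- cluster_primitives(x, seed = 4L)
  expect_identical(lapply(c1$fits, `[[`, "cluster"),
                   lapply(c2$fits, `[[`, "cluster"))
})

test_that("the elbow rule counts linearly interpolable trailing points", {
  m <- 13L
  # linear curve throughout: a single cluster suffices
  expect_identical(select_k(seq(1, 0, length.out = m), m), 1L)

  # sharp elbow at k = 3: the trailing 11 points (k = 3..13) are linear,
  # segments starting earlier are not
  curve <- c(1, 0.5, seq(0.1, 0, length.out = 11))
  # brute-force oracle over trailing-segment regression MSEs
  k_oracle <- m
  for (ii in 1:m) {
    y <- curve[ii:m]; x <- ii:m
    mse <- if (length(y) < 3) 0 else mean(lm(y ~ x)$residuals^2)
    if (mse < 1e-3) { k_oracle <- ii; break }
  }
  expect_identical(k_oracle, 3L)
  expect_identical(select_k(curve, m), 3L)

  # perturbations far below the tolerance do not move the elbow
  set.seed(33)
  curve2 <- curve + c(0, 0, runif(11, -1e-5, 1e-5))
  expect_identical(select_k(curve2, m), 3L)
})

test_that("module clustering at an imposed k separates disjoint groups", {
  set.seed(34)
  proto <- diag(3)[rep(1:3, each = 8L), ] %x% t(rep(1, 4))  # 24 x 12
  mods <- proto + matrix(runif(24 * 12, 0, 0.05), 24)
  fit <- cluster_modules(mods, k = 3L, seed = 2L)
  truth <- rep(1:3, each = 8L)
  # pure partition: the contingency table is a permutation matrix
  expect_true(all(colSums(table(fit$cluster, truth) > 0) == 1) &&
              all(rowSums(table(fit$cluster, truth) > 0) == 1))
  expect_error(cluster_modules(mods[1:2, ], k = 3L), "more clusters")
  # permuting the input permutes assignments with it
  perm <- sample(24L)
  fit2 <- cluster_modules(mods[perm, ], k = 3L, seed = 2L)
  expect_true(all(colSums(table(fit2$cluster, truth[perm]) > 0) == 1))
})

test_that("the partition score is (mean FWHM + mean CoA) / 300", {
  p <- generate_primitive(150, 60)
  s <- score_classification(matrix(p, 1L), 1L)
  expect_equal(s, (fwhm(p) + coa(p)) / 300)
  # the quoted arithmetic case: FWHM 60 and CoA 150 give 0.70
  expect_equal(round(s, 2), 0.70)

  # relabelling clusters leaves the score unchanged
  set.seed(35)
  x <- matrix(runif(12 * 300, 0.1, 1), 12)
  a <- rep(1:3, each = 4L)
  expect_equal(score_classification(x, a),
               score_classification(x, c(2L, 3L, 1L)[a]))
})

test_that("fundamental and combined labels follow classifier agreement", {
  a <- rep(1:3, each = 4L)
  s <- 0.5
  lab <- label_synergies(a, a, s, s)
  expect_true(all(lab$labels == "fundamental"))
  expect_false(lab$matching_failed)

  # module labels permuted wholesale still agree after alignment
  b <- c(3L, 1L, 2L)[a]
  lab2 <- label_synergies(a, b, s, s)
  expect_true(all(lab2$labels == "fundamental"))

  # one synergy swapped between clusters: exactly one combined
  b3 <- b; b3[1L] <- 1L   # synergy 1 moves to another module cluster
  lab3 <- label_synergies(a, b3, s, s)
  expect_identical(sum(lab3$labels == "combined"), 1L)
  expect_identical(which(lab3$labels == "combined"), 1L)

  # discordant scores: matching fails, primitive-based partition retained
  lab4 <- label_synergies(a, b, 0.5, 0.62)
  expect_true(lab4$matching_failed)
  expect_true(all(lab4$labels == "fundamental"))
  expect_true(all(is.na(lab4$assignments_module_aligned)))
})

test_that("cohort classification recovers the three planted synergies ordered in time", {
  set.seed(36)
  centers <- c(90, 120, 210)
  prim <- do.call(rbind, lapply(1:15, function(i)
    t(sapply(centers, function(ct)
      generate_primitive(ct + rnorm(1, sd = 4), 50) + runif(300, 0, 0.03)))))
  gt <- default_ground_truth("SG")
  mods <- do.call(rbind, lapply(1:15, function(i)
    t(gt$modules_true + matrix(runif(13 * 3, 0, 0.08), 13))))
  cl <- classify_synergies(prim, mods, seed = 10L)
  expect_identical(cl$k, 3L)
  ord_names <- cl$cluster_names[order(cl$centroid_coa)]
  expect_identical(ord_names,
                   c("touchdown", "weight_acceptance", "stabilization"))
  expect_gte(mean(cl$table$label == "fundamental"), 0.95)
  expect_false(cl$matching_failed)
})
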