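test_that("migration-curve fit recovers noise-free Gaussian parameters", {
  ladder <- ladder_spec()
  d_true <- reference_migration(as.numeric(ladder))
  curve <- fit_migration_curve(sort(d_true), ladder)
  expect_equal(curve$r_squared, 1.0, tolerance = 1e-9)
  expect_equal(unname(curve$params["A"]), 350, tolerance = 1e-3)
  expect_equal(unname(curve$params["mu"]), 1, tolerance = 1e-4)
  expect_equal(unname(curve$params["c"]), 10, tolerance = 1e-2)
  # tidy/glance expose the fit in broom style
  td <- tidy(curve)
  expect_named(td, c("term", "estimate"))
  expect_setequal(td$term, c("A", "mu", "sigma", "c"))
  expect_equal(glance(curve)$r.squared, 1.0, tolerance = 1e-9)
})

test_that("migration-curve fit survives realistic position noise", {
  ladder <- ladder_spec()
  d_true <- reference_migration(as.numeric(ladder))
  set.seed(41)
  for (i in 1:10) {
    noisy <- sort(d_true + rnorm(length(d_true), 0, 1.6)) # ~1% of range
    curve <- fit_migration_curve(noisy, ladder)
    expect_gte(curve$r_squared, 0.95)
    # the identifiable quantity on a Gaussian flank is the fitted curve,
    # not the raw parameters: it must track the true migration closely
    grid <- seq(100, 1000, by = 50)
    expect_lt(max(abs(predict_distance(curve, grid) -
                        reference_migration(grid))), 5) # ~3 sigma
  }
})

test_that("insufficient or disordered ladders are rejected", {
  expect_error(fit_migration_curve(c(10, 50), ladder_spec(c(1000, 100))),
               "InsufficientLadder")
  expect_error(fit_migration_curve(c(10, 50, 40, 80, 90, 100, 110, 120,
                                     130, 140), ladder_spec()),
               "strictly increasing")
  expect_error(fit_migration_curve(rep(1, 10), ladder_spec()),
               "strictly increasing")
})

test_that("self-normalization is the identity and warps are undone", {
  ladder <- ladder_spec()
  d_true <- reference_migration(as.numeric(ladder))
  ref <- fit_migration_curve(sort(d_true), ladder)
  lanes <- tibble::tibble(sample_id = "x",
                          band_position = c(40, 80, 120, 160))
  self_norm <- normalize_gel(lanes, ref, ref)
  expect_equal(self_norm$normalized_position, lanes$band_position,
               tolerance = 1e-9)

  # affine warp of the whole gel, ladder included, is removed exactly
  warp <- function(x) 7 + 1.08 * x
  warped_curve <- fit_migration_curve(sort(warp(d_true)), ladder)
  norm <- normalize_gel(
    tibble::tibble(sample_id = "x", band_position = warp(c(40, 80, 120, 160))),
    warped_curve, ref)
  expect_equal(norm$normalized_position, c(40, 80, 120, 160),
               tolerance = 0.5)
  expect_false(any(norm$extrapolated))
})

test_that("bands beyond the ladder range are flagged, not dropped", {
  ladder <- ladder_spec()
  d_true <- reference_migration(as.numeric(ladder))
  ref <- fit_migration_curve(sort(d_true), ladder)
  out <- normalize_gel(
    tibble::tibble(sample_id = "x", band_position = c(100, max(d_true) + 15)),
    ref, ref)
  expect_equal(nrow(out), 2)
  expect_false(out$extrapolated[1])
  expect_true(out$extrapolated[2])
})

test_that("normalization refuses poorly fitted curves", {
  ladder <- ladder_spec(seq(400, 100, -100))
  bad <- fit_migration_curve(c(10, 11, 12, 100), ladder,
                             model = "log_linear")
  expect_lt(bad$r_squared, 0.95)
  ref <- fit_migration_curve(
    sort(reference_migration(as.numeric(ladder))), ladder)
  expect_error(normalize_gel(
    tibble::tibble(sample_id = "x", band_position = 50), bad, ref),
    "R\\^2")
})

test_that("band similarity reproduces the worked examples", {
  expect_equal(band_similarity(c(10, 50, 90), c(10, 50, 90)), 100)
  expect_equal(band_similarity(c(10, 50, 90), c(13, 50, 200)), 200 / 3,
               tolerance = 1e-9)
  expect_equal(band_similarity(10, 100), 0)
  expect_equal(band_similarity(numeric(0), numeric(0)), 100)
  expect_equal(band_similarity(numeric(0), c(10, 20)), 0)
  # Jaccard variant
  expect_equal(band_similarity(c(10, 50, 90), c(13, 50, 200),
                               method = "jaccard"), 50)
})

test_that("band similarity equals the exhaustive assignment oracle", {
  set.seed(47)
  for (i in 1:500) {
    a <- sort(runif(sample(0:6, 1), 0, 60))
    b <- sort(runif(sample(0:6, 1), 0, 60))
    expect_equal(band_similarity(a, b, tolerance = 4),
                 oracle_band_similarity(a, b, 4),
                 tolerance = 1e-9,
                 label = paste("bands", i))
  }
})

test_that("band similarity is symmetric, bounded, monotone in tolerance", {
  set.seed(53)
  for (i in 1:50) {
    a <- runif(sample(1:6, 1), 0, 50)
    b <- runif(sample(1:6, 1), 0, 50)
    s <- vapply(c(0.5, 1, 2, 4, 8, 16),
                function(tol) band_similarity(a, b, tol), double(1))
    expect_true(all(diff(s) >= -1e-12))
    expect_true(all(s >= 0 & s <= 100))
    expect_equal(band_similarity(a, b, 4), band_similarity(b, a, 4))
  }
})

test_that("similarity is invariant under a shared monotone renormalization", {
  # warping both source gels identically (and their ladders) must not
  # change tolerance-matched similarity after normalization
  sim <- simulate_gel(true_patterns = list(p1 = c(40, 62, 90),
                                           p2 = c(52, 78, 110),
                                           p3 = c(45, 99, 130)),
                      group_sizes = c(3L, 3L, 2L), n_gels = 2L,
                      position_noise_sd = 0, seed = 59)
  res <- gel_workflow(sim$bands)
  sim2 <- sim
  sim2$bands$band_position <- 5 + 1.1 * sim2$bands$band_position
  res2 <- gel_workflow(sim2$bands)
  expect_equal(res$similarity, res2$similarity, tolerance = 1e-4)
})

test_that("UPGMA reproduces the hand-worked 3-leaf tree", {
  d <- matrix(c(0, 10, 40, 10, 0, 40, 40, 40, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_dendrogram(d, is_distance = TRUE)
  expect_equal(tr$merges$height, c(5, 20))
  expect_equal(tr$merges$cluster_a[1], "A")
  expect_equal(tr$merges$cluster_b[1], "B")
  expect_equal(tr$newick, "((A:5,B:5):15,C:20);")
  expect_error(upgma_dendrogram(matrix(c(0, 1, 2, 0), 2, 2),
                                is_distance = TRUE), "symmetric")
})

test_that("UPGMA matches average-linkage hclust on random matrices", {
  set.seed(61)
  for (i in 1:200) {
    k <- 5
    d <- matrix(0, k, k, dimnames = list(LETTERS[1:k], LETTERS[1:k]))
    d[upper.tri(d)] <- runif(k * (k - 1) / 2, 1, 100)
    d <- d + t(d)
    tr <- upgma_dendrogram(d, is_distance = TRUE)
    coph_mine <- ape::cophenetic.phylo(tr$phylo)
    coph_ref <- as.matrix(stats::cophenetic(
      stats::hclust(stats::as.dist(d), method = "average")))
    expect_equal(coph_mine[rownames(coph_ref), colnames(coph_ref)],
                 coph_ref, tolerance = 1e-8)
    # ultrametric: merge heights non-decreasing
    expect_true(all(diff(tr$merges$height) >= -1e-9))
  }
})

test_that("UPGMA labels and topology are invariant to input order", {
  set.seed(67)
  k <- 6
  d <- matrix(0, k, k, dimnames = list(letters[1:k], letters[1:k]))
  d[upper.tri(d)] <- runif(k * (k - 1) / 2, 1, 100)
  d <- d + t(d)
  perm <- sample(k)
  tr1 <- upgma_dendrogram(d, is_distance = TRUE)
  tr2 <- upgma_dendrogram(d[perm, perm], is_distance = TRUE)
  expect_equal(ape::cophenetic.phylo(tr2$phylo)[letters[1:k], letters[1:k]],
               ape::cophenetic.phylo(tr1$phylo)[letters[1:k], letters[1:k]])
  # identical patterns merge at distance zero
  tr0 <- upgma_dendrogram(matrix(100, 2, 2,
                                 dimnames = list(c("x", "y"), c("x", "y"))))
  expect_equal(tr0$merges$distance, 0)
})

test_that("dendrogram cutting groups samples merged below the cut", {
  d <- matrix(c(0, 4, 50, 4, 0, 50, 50, 50, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_dendrogram(d, is_distance = TRUE)
  cl <- cut_dendrogram(tr, similarity_cutoff = 90) # max distance 10
  expect_equal(cl$cluster[cl$sample_id == "A"],
               cl$cluster[cl$sample_id == "B"])
  expect_false(cl$cluster[cl$sample_id == "C"] ==
                 cl$cluster[cl$sample_id == "A"])
})

test_that("partition congruence behaves like the adjusted Rand index", {
  a <- setNames(c(1, 1, 2, 2, 3), paste0("s", 1:5))
  expect_equal(compare_partitions(a, a)$ari, 1.0)

  singletons <- setNames(1:8, paste0("s", 1:8))
  lumped <- setNames(rep(1, 8), paste0("s", 1:8))
  expect_lte(compare_partitions(singletons, lumped)$ari, 0)

  expect_error(compare_partitions(a, setNames(1:3, c("s1", "s2", "zzz"))),
               "mismatch")

  # randomized labels at fixed margins: chance-level agreement
  set.seed(71)
  base <- setNames(rep(1:4, each = 6), paste0("s", 1:24))
  aris <- replicate(1000, {
    shuffled <- setNames(sample(unname(base)), names(base))
    compare_partitions(base, shuffled)$ari
  })
  expect_lt(abs(mean(aris)), 0.02)
})

test_that("ARI agrees with the mclust implementation", {
  skip_if_not_installed("mclust")
  set.seed(73)
  for (i in 1:20) {
    x <- sample(1:4, 30, replace = TRUE)
    y <- sample(1:3, 30, replace = TRUE)
    ids <- paste0("s", 1:30)
    expect_equal(compare_partitions(setNames(x, ids), setNames(y, ids))$ari,
                 mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
  }
})
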