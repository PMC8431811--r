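test_that("alignment simulator is deterministic and respects its blueprint", {
  s1 <- simulate_msa(10, seed = 99)
  s2 <- simulate_msa(10, seed = 99)
  expect_identical(s1$alignment$seq, s2$alignment$seq)
  expect_false(identical(s1$alignment$seq,
                         simulate_msa(10, seed = 100)$alignment$seq))

  frozen <- simulate_msa(6, tibble::tibble(
    kind = "conserved", length = 80L, sub_prob = 0), seed = 1)
  expect_equal(length(unique(frozen$alignment$seq)), 1)
  expect_equal(frozen$blocks$start, 1L)
  expect_equal(frozen$blocks$end, 80L)
})

test_that("conserved blocks have lower mean entropy than variable blocks", {
  deltas <- vapply(1:50, function(seed) {
    sim <- simulate_msa(12, seed = seed)
    prof <- conservation_profile(sim$alignment)
    blocks <- sim$blocks
    mean_in <- function(kind) {
      idx <- unlist(purrr::map2(blocks$start[blocks$kind == kind],
                                blocks$end[blocks$kind == kind], seq))
      mean(prof$entropy[idx])
    }
    mean_in("variable") - mean_in("conserved")
  }, double(1))
  expect_true(all(deltas > 0))
})

test_that("template simulator plants recoverable groups", {
  fwd <- "GCAGTAAATCGGGGCTAATAC"
  rev <- "CCCGTTACAACCATGGTA"
  set.seed(5)
  v <- random_oligo(170)
  flip <- function(s, pos) {
    ch <- substr(s, pos, pos)
    paste0(substr(s, 1, pos - 1),
           setdiff(c("A", "C", "G", "T"), ch)[1],
           substr(s, pos + 1, nchar(s)))
  }
  variants <- c(v, flip(v, 68), flip(flip(v, 68), 122))
  sim <- simulate_templates(fwd, rev, variants, copies = c(17, 15, 5),
                            seed = 7)
  expect_equal(nrow(sim$templates), 37)
  amp <- amplify(sim$templates, fwd, rev, size_window = c(150, 300))
  # amplification succeeds on every template
  expect_true(all(amp$status == "ok"))
  groups <- group_by_identity(amp)
  expect_equal(groups$size, c(17L, 15L, 5L))
  # truth partition is recovered exactly
  truth <- setNames(sim$truth$group, sim$truth$id)
  got <- setNames(rep(groups$group, groups$size),
                  unlist(groups$member_ids))
  expect_equal(compare_partitions(got, truth)$ari, 1.0)
})

test_that("planted substitution positions are reported exactly", {
  fwd <- "GCAGTAAATCGGGGCTAATAC"
  rev <- "CCCGTTACAACCATGGTA"
  set.seed(9)
  base <- random_oligo(166)
  mutate_at <- function(s, pos) {
    ch <- substr(s, pos, pos)
    paste0(substr(s, 1, pos - 1),
           setdiff(c("A", "C", "G", "T"), ch)[1],
           substr(s, pos + 1, nchar(s)))
  }
  variants <- c(base, mutate_at(base, 47), mutate_at(mutate_at(base, 47), 101))
  sim <- simulate_templates(fwd, rev, variants, copies = 2, seed = 11)
  amp <- amplify(sim$templates, fwd, rev, size_window = c(150, 300))
  groups <- group_by_identity(amp)
  subs <- pairwise_substitutions(groups)
  # insert offset by the forward primer length
  expect_equal(subs$positions$position, nchar(fwd) + c(47L, 101L))
  expect_equal(max(subs$matrix), 2L)
})

test_that("gel simulator honors its blueprint and seed", {
  sim <- simulate_gel(seed = 21)
  expect_identical(sim$bands, simulate_gel(seed = 21)$bands)
  expect_equal(nrow(sim$truth), 73)
  expect_equal(unname(table(sim$truth$group)[paste0("pattern", 1:7)]),
               c(17L, 15L, 7L, 20L, 8L, 5L, 1L), ignore_attr = TRUE)
  # ladder lanes first and last on every gel
  for (g in unique(sim$bands$gel_id)) {
    lanes <- sim$bands$lane_id[sim$bands$gel_id == g]
    expect_equal(lanes[1], "ladder_first")
    expect_equal(lanes[length(lanes)], "ladder_last")
  }
  # ladder rungs stay monotone after warping
  ladders <- dplyr::filter(sim$bands, .data$is_ladder)
  for (key in unique(paste(ladders$gel_id, ladders$lane_id))) {
    pos <- ladders$band_position[paste(ladders$gel_id,
                                       ladders$lane_id) == key]
    expect_true(all(diff(sort(pos)) > 0))
  }
  # three bands per sample lane
  per_lane <- dplyr::count(dplyr::filter(sim$bands, !.data$is_ladder),
                           .data$gel_id, .data$lane_id)
  expect_true(all(per_lane$n == 3))
})

test_that("zero warp and zero noise reproduce the true patterns exactly", {
  pats <- list(p1 = c(40, 60, 90), p2 = c(50, 75, 110))
  sim <- simulate_gel(true_patterns = pats, group_sizes = c(2L, 2L),
                      n_gels = 2L, warp_slope_range = c(1, 1),
                      warp_offset_range = c(0, 0),
                      position_noise_sd = 0, seed = 31)
  res <- gel_workflow(sim$bands)
  for (k in seq_len(nrow(res$normalized))) {
    row <- res$normalized[k, ]
    truth <- pats[[sim$truth$group[sim$truth$sample_id == row$sample_id]]]
    expect_true(any(abs(truth - row$normalized_position) < 1e-6))
  }
})

test_that("end-to-end clustering recovers the planted partition", {
  sim <- simulate_gel(seed = 11)
  res <- gel_workflow(sim$bands)
  expect_true(all(vapply(res$curves, function(c) c$r_squared, 1) >= 0.95))
  truth <- setNames(sim$truth$group, sim$truth$sample_id)
  expect_equal(compare_partitions(res$clusters, truth)$ari, 1.0)
})

test_that("band tables round-trip through TSV", {
  sim <- simulate_gel(group_sizes = c(2L, 1L),
                      true_patterns = list(a = c(40, 60, 90),
                                           b = c(50, 80, 100)),
                      n_gels = 1L, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(sim$bands, path)
  back <- read_band_table(path)
  expect_equal(nrow(back), nrow(sim$bands))
  expect_true(all(c("gel_id", "lane_id", "sample_id", "band_position",
                    "is_ladder") %in% names(back)))
})
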