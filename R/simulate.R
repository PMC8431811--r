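# Deterministic synthetic-data generators: alignments with a planted
# conserved/variable block architecture, template sets with planted primer
# sites, and multi-gel band tables with known cluster truth. Each generator
# is a pure function of its arguments including the seed.

#' Simulate a multiple sequence alignment with planted conservation blocks
#'
#' Draws an ancestral sequence and mutates each block's columns at its own
#' per-column substitution probability, so conserved blocks stay
#' near-invariant while variable blocks diverge. Optional independent gap
#' (indel) events per sequence and column.
#'
#' @param n_sequences Number of sequences.
#' @param blocks A data frame with columns `kind` (`"conserved"` /
#'   `"variable"`), `length` (columns) and `sub_prob` (per-column
#'   substitution probability per sequence). Defaults to a
#'   conserved-variable-conserved architecture mirroring a primer-flanked
#'   hypervariable core.
#' @param indel_prob Per-column gap probability per sequence (default 0).
#' @param seed Integer seed; same seed, same alignment.
#' @return A list with `alignment` (an [as_alignment()] tibble) and
#'   `blocks` (the blueprint with 1-based `start`/`end` coordinates
#'   appended).
#' @export
simulate_msa <- function(n_sequences = 24,
                         blocks = tibble::tibble(
                           kind = c("conserved", "variable", "conserved"),
                           length = c(21L, 160L, 21L),
                           sub_prob = c(0.005, 0.35, 0.005)),
                         indel_prob = 0, seed = 1L) {
  stopifnot(all(blocks$sub_prob >= 0 & blocks$sub_prob <= 1),
            sum(blocks$length) >= 60, indel_prob >= 0, indel_prob <= 1)
  withr::local_seed(seed)
  bases <- c("A", "C", "G", "T")
  total <- sum(blocks$length)
  ancestor <- sample(bases, total, replace = TRUE)
  col_prob <- rep(blocks$sub_prob, blocks$length)

  seqs <- vapply(seq_len(n_sequences), function(i) {
    s <- ancestor
    mut <- stats::runif(total) < col_prob
    if (any(mut)) {
      s[mut] <- vapply(s[mut], function(b) sample(setdiff(bases, b), 1),
                       character(1))
    }
    if (indel_prob > 0) {
      s[stats::runif(total) < indel_prob] <- "-"
    }
    paste(s, collapse = "")
  }, character(1))

  ends <- cumsum(blocks$length)
  blocks$start <- ends - blocks$length + 1L
  blocks$end <- ends
  list(
    alignment = as_alignment(stats::setNames(
      seqs, sprintf("sim%03d", seq_len(n_sequences)))),
    blocks = blocks
  )
}

#' Simulate template sequences with planted primer sites
#'
#' Each template is `flank + fwd_site + insert + revcomp(rev_site) +
#' flank`, with random flanks, so amplification with the planted pair must
#' recover exactly the insert-delimited product, and exact-identity
#' grouping must recover the insert-identity partition.
#'
#' @param fwd_site,rev_site Primer binding sites, 5' to 3' (the reverse
#'   site as the reverse primer sequence; its reverse complement is
#'   embedded in the template).
#' @param inserts Character vector of insert variants, one per group.
#' @param copies Integer vector, templates per group (recycled against
#'   `inserts`).
#' @param flank_len Range of random flank lengths, nt (default
#'   `c(30, 80)`).
#' @param seed Integer seed.
#' @return A list with `templates` (tibble `id`, `seq`, `group`) and
#'   `truth` (tibble `id`, `group`).
#' @export
simulate_templates <- function(fwd_site, rev_site, inserts,
                               copies = 5L, flank_len = c(30L, 80L),
                               seed = 1L) {
  stopifnot(length(inserts) >= 1, !any(grepl("[^ACGTacgtu]",
                                             c(fwd_site, rev_site, inserts))))
  withr::local_seed(seed)
  copies <- rep_len(copies, length(inserts))
  bases <- c("A", "C", "G", "T")
  rand_flank <- function() {
    paste(sample(bases, sample(flank_len[1]:flank_len[2], 1),
                 replace = TRUE), collapse = "")
  }
  rows <- purrr::imap_dfr(inserts, function(ins, g) {
    tibble::tibble(
      group = paste0("group", g),
      seq = vapply(seq_len(copies[g]), function(i) {
        paste0(rand_flank(), normalize_nt(fwd_site), normalize_nt(ins),
               reverse_complement(normalize_nt(rev_site)), rand_flank())
      }, character(1))
    )
  })
  rows$id <- sprintf("tpl%03d", seq_len(nrow(rows)))
  list(
    templates = rows[, c("id", "seq", "group")],
    truth = rows[, c("id", "group")]
  )
}

#' Default reference migration model used by the gel simulator
#'
#' Gaussian-flank migration: `d(s) = 350 exp(-(s - 1)^2 / (2 * 0.8^2)) +
#' 10` with `s = log10(size)`, decreasing over the 100-1000 bp ladder
#' range (about 170 down to 25 position units).
#'
#' @param size_bp Fragment sizes in bp.
#' @return Migration positions.
#' @export
reference_migration <- function(size_bp) {
  s <- log10(size_bp)
  350 * exp(-(s - 1)^2 / (2 * 0.8^2)) + 10
}

#' Simulate a multi-gel band table with known cluster truth
#'
#' Plants `length(true_patterns)` distinct three-band fingerprints (or any
#' patterns supplied), replicates them to `group_sizes` sample lanes,
#' distributes the lanes across `n_gels` gels, applies a per-gel monotone
#' affine warp (shared by the gel's ladder lanes, loaded first and last)
#' and Gaussian position noise. Defaults mirror a seven-group screen of 73
#' isolates with three-band patterns across eight gels and a 100-bp
#' ladder.
#'
#' @param true_patterns Named list of band-position vectors on the
#'   reference scale. Default: seven well-separated three-band patterns.
#' @param group_sizes Integer vector of lane counts per pattern (default
#'   `c(17, 15, 7, 20, 8, 5, 1)`).
#' @param n_gels Number of gels (default 8).
#' @param warp_slope_range,warp_offset_range Ranges of the per-gel affine
#'   warp `a + b * x` (defaults `c(0.9, 1.1)` and `c(-5, 5)`).
#' @param position_noise_sd Gaussian band-position noise, reference units
#'   (default 0.5).
#' @param ladder A [ladder_spec()] (default 100-1000 bp rungs).
#' @param seed Integer seed.
#' @return A list with `bands` (tibble `gel_id`, `lane_id`, `sample_id`,
#'   `band_position`, `is_ladder`) and `truth` (tibble `sample_id`,
#'   `group`).
#' @export
simulate_gel <- function(true_patterns = NULL,
                         group_sizes = c(17L, 15L, 7L, 20L, 8L, 5L, 1L),
                         n_gels = 8L,
                         warp_slope_range = c(0.9, 1.1),
                         warp_offset_range = c(-5, 5),
                         position_noise_sd = 0.5,
                         ladder = ladder_spec(), seed = 1L) {
  withr::local_seed(seed)
  if (is.null(true_patterns)) {
    # seven three-band fingerprints spread over the usable position range
    base <- seq(40, 160, length.out = 7)
    true_patterns <- stats::setNames(
      lapply(seq_len(7), function(g) {
        sort(base[g] + c(-18, 0, 15) + (g %% 3) * 2)
      }), paste0("pattern", seq_len(7)))
  }
  stopifnot(length(group_sizes) == length(true_patterns),
            position_noise_sd >= 0)
  ladder_pos_true <- reference_migration(as.numeric(ladder))

  samples <- tibble::tibble(
    sample_id = sprintf("iso%03d", seq_len(sum(group_sizes))),
    group = rep(names(true_patterns), group_sizes)
  )
  samples$gel_id <- paste0(
    "gel", rep_len(seq_len(n_gels), nrow(samples))[sample(nrow(samples))])

  warp <- tibble::tibble(
    gel_id = paste0("gel", seq_len(n_gels)),
    slope = stats::runif(n_gels, warp_slope_range[1], warp_slope_range[2]),
    offset = stats::runif(n_gels, warp_offset_range[1],
                          warp_offset_range[2])
  )

  bands <- purrr::pmap_dfr(warp, function(gel_id, slope, offset) {
    gel_samples <- samples[samples$gel_id == gel_id, ]
    w <- function(x) offset + slope * x
    ladder_rows <- purrr::map_dfr(c("ladder_first", "ladder_last"),
      function(lid) {
        tibble::tibble(
          gel_id = gel_id, lane_id = lid, sample_id = lid,
          band_position = w(ladder_pos_true) +
            stats::rnorm(length(ladder_pos_true), 0, position_noise_sd),
          is_ladder = TRUE)
      })
    sample_rows <- purrr::pmap_dfr(
      gel_samples[, c("sample_id", "group")],
      function(sample_id, group) {
        p <- true_patterns[[group]]
        tibble::tibble(
          gel_id = gel_id, lane_id = sample_id, sample_id = sample_id,
          band_position = sort(w(p) + stats::rnorm(length(p), 0,
                                                   position_noise_sd)),
          is_ladder = FALSE)
      })
    dplyr::bind_rows(
      ladder_rows[ladder_rows$lane_id == "ladder_first", ],
      sample_rows,
      ladder_rows[ladder_rows$lane_id == "ladder_last", ])
  })

  list(bands = bands, truth = samples[, c("sample_id", "group")])
}

#' End-to-end normalization and clustering of a simulated band table
#'
#' Fits each gel's ladder curve from its first ladder lane, normalizes all
#' sample lanes onto the first gel's scale, builds the similarity matrix
#' and UPGMA dendrogram, and cuts it at `similarity_cutoff`.
#'
#' @param bands Band tibble as produced by [simulate_gel()] (or
#'   [read_band_table()]).
#' @param ladder A [ladder_spec()] matching the ladder lanes.
#' @param tolerance Band-match tolerance (default 4).
#' @param similarity_cutoff Dendrogram cut (default 90).
#' @param reference_gel Gel id used as the common coordinate scale
#'   (default: first gel in sorted order).
#' @return A list: `normalized` (band tibble with `normalized_position`),
#'   `curves` (named list of migration curves), `similarity` (matrix),
#'   `tree` (`upgma_tree`), `clusters` (tibble `sample_id`, `cluster`).
#' @export
gel_workflow <- function(bands, ladder = ladder_spec(), tolerance = 4,
                         similarity_cutoff = 90, reference_gel = NULL) {
  gels <- sort(unique(bands$gel_id))
  if (is.null(reference_gel)) reference_gel <- gels[1]
  curves <- purrr::map(stats::setNames(gels, gels), function(g) {
    lad <- bands[bands$gel_id == g & bands$is_ladder, ]
    first_lane <- lad[lad$lane_id == sort(unique(lad$lane_id))[1], ]
    fit_migration_curve(sort(first_lane$band_position), ladder)
  })
  normalized <- purrr::map_dfr(gels, function(g) {
    lanes <- bands[bands$gel_id == g & !bands$is_ladder, ]
    normalize_gel(lanes, curves[[g]], curves[[reference_gel]])
  })
  sim <- similarity_matrix(normalized, tolerance = tolerance)
  tree <- upgma_dendrogram(sim)
  list(normalized = normalized, curves = curves, similarity = sim,
       tree = tree, clusters = cut_dendrogram(tree, similarity_cutoff))
}
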