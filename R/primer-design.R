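# Conserved-window search and universal primer-pair enumeration over a
# conservation profile, with nearest-neighbor thermodynamic screening.

#' Find conserved windows in a conservation profile
#'
#' Scans the per-column profile for maximal runs in which every column has
#' entropy at or below `max_entropy` and similarity at or above
#' `min_similarity`, keeping runs at least as long as the shortest primer.
#'
#' @param profile A [conservation_profile()] tibble.
#' @param max_entropy Per-column entropy ceiling (units of the profile's
#'   log base).
#' @param min_similarity Per-column similarity floor (percent).
#' @param len_range Primer length range, `c(min, max)`, within 15-30 nt.
#' @return A tibble of maximal windows: `start`, `end`, `length`,
#'   `mean_entropy`, `mean_similarity`. May be empty.
#' @export
find_conserved_windows <- function(profile, max_entropy, min_similarity,
                                   len_range = c(18L, 24L)) {
  stopifnot(len_range[1] >= 15, len_range[2] <= 30,
            len_range[1] <= len_range[2])
  ok <- !is.na(profile$entropy) & !is.na(profile$similarity) &
    profile$entropy <= max_entropy & profile$similarity >= min_similarity
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= len_range[1]
  if (!any(keep)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          length = integer(), mean_entropy = double(),
                          mean_similarity = double()))
  }
  tibble::tibble(start = starts[keep], end = ends[keep]) |>
    dplyr::mutate(
      length = .data$end - .data$start + 1L,
      mean_entropy = purrr::map2_dbl(
        .data$start, .data$end,
        ~mean(profile$entropy[.x:.y])),
      mean_similarity = purrr::map2_dbl(
        .data$start, .data$end,
        ~mean(profile$similarity[.x:.y]))
    )
}

#' Majority consensus of an alignment slice
#'
#' Per-column modal nucleotide among A/C/G/T (gaps and ambiguity codes
#' never contribute; ties broken alphabetically). Gap-majority columns are
#' dropped from the oligo, so the returned string can be shorter than the
#' window.
#'
#' @param aln An alignment.
#' @param start,end 1-based inclusive alignment columns.
#' @return A consensus oligo string, 5' to 3' on the alignment strand.
#' @export
consensus_oligo <- function(aln, start, end) {
  aln <- as_alignment(aln)
  m <- alignment_matrix(aln)[, start:end, drop = FALSE]
  apply(m, 2, function(col) {
    nt <- table(factor(col, levels = c("A", "C", "G", "T")))
    gaps <- sum(col == "-")
    if (gaps > max(nt)) "" else names(nt)[which.max(nt)]
  }) |> paste(collapse = "")
}

# Ungapped slice of one aligned sequence over alignment columns.
ungapped_slice <- function(aligned_seq, start, end) {
  gsub("-", "", substr(aligned_seq, start, end), fixed = TRUE)
}

#' Fraction of alignment sequences a primer binds
#'
#' For each sequence the ungapped residues under the primer's alignment
#' window are compared with the primer (forward strand) or its reverse
#' complement site orientation (reverse strand). A sequence counts as bound
#' when its slice has the primer's length, at most `max_mismatch`
#' mismatches overall, and no mismatch within the `anchor_3prime` bases at
#' the primer's 3' end. Ambiguity codes in the template count as
#' mismatches.
#'
#' @param aln An alignment.
#' @param primer Primer sequence, 5' to 3'.
#' @param start,end Alignment window (1-based inclusive) of the binding
#'   site.
#' @param strand `"forward"` or `"reverse"`.
#' @param max_mismatch Maximum mismatches tolerated (default 0).
#' @param anchor_3prime 3'-terminal bases that must match exactly
#'   (default 3).
#' @return Fraction in \[0, 1\].
#' @export
universality <- function(aln, primer, start, end,
                         strand = c("forward", "reverse"),
                         max_mismatch = 0L, anchor_3prime = 3L) {
  aln <- as_alignment(aln)
  strand <- match.arg(strand)
  primer <- normalize_nt(primer)
  pl <- nchar(primer)
  pc <- strsplit(primer, "", fixed = TRUE)[[1]]
  hits <- vapply(aln$seq, function(s) {
    slice <- ungapped_slice(s, start, end)
    if (strand == "reverse") slice <- reverse_complement(slice)
    if (nchar(slice) != pl) return(FALSE)
    sc <- strsplit(slice, "", fixed = TRUE)[[1]]
    mm <- pc != sc
    if (sum(mm) > max_mismatch) return(FALSE)
    if (anchor_3prime > 0 &&
        any(mm[seq.int(pl - min(anchor_3prime, pl) + 1L, pl)])) {
      return(FALSE)
    }
    TRUE
  }, logical(1))
  mean(hits)
}

#' Enumerate and rank universal primer pairs
#'
#' Slides primer-length sub-windows over the conserved windows, builds the
#' majority-consensus oligo for each (reverse candidates as the reverse
#' complement of the consensus slice), and forms all forward/reverse
#' combinations whose expected amplicon length across the alignment falls
#' in `len_window`. Each pair is screened thermodynamically and, when
#' `require_variable_core` is set, must enclose at least one column whose
#' entropy exceeds the `var_quantile` quantile of the profile. Pairs are
#' ranked by universality (desc), enclosed maximum entropy (desc), distance
#' of the median amplicon length from `target_len` (asc), thermodynamic
#' penalty (asc), then leftmost forward coordinate.
#'
#' The thermodynamic penalty is
#' `|Tm_F - Tm_R| + max(0, -dG_het - 8) + sum(max(0, -dG_self - 8))`:
#' pairs are penalized for Tm imbalance and for dimers more stable than
#' -8 kcal/mol.
#'
#' @param aln The alignment the profile came from.
#' @param profile Its [conservation_profile()].
#' @param windows Conserved windows from [find_conserved_windows()].
#' @param target_len Target amplicon length in nt (default 200).
#' @param len_window Acceptable expected amplicon length range, nt
#'   (default `c(150, 260)`).
#' @param len_range Primer length range (default `c(18, 24)`).
#' @param require_variable_core Require an enclosed high-entropy column
#'   (default TRUE).
#' @param var_quantile Quantile of profile entropy defining "high"
#'   (default 0.9).
#' @param max_mismatch,anchor_3prime Universality rule (defaults 0 and 3).
#' @param conditions [thermo_conditions()] for Tm.
#' @param min_universality Drop pairs below this binding fraction
#'   (default 0; keep all and let the ranking decide).
#' @return A ranked tibble of class `primer_pairs`, one row per pair:
#'   sequences, alignment coordinates, per-primer window statistics, Tm and
#'   free-energy screen, universality, expected length range, penalty.
#' @export
enumerate_pairs <- function(aln, profile, windows,
                            target_len = 200L, len_window = c(150L, 260L),
                            len_range = c(18L, 24L),
                            require_variable_core = TRUE,
                            var_quantile = 0.9,
                            max_mismatch = 0L, anchor_3prime = 3L,
                            conditions = thermo_conditions(),
                            min_universality = 0) {
  aln <- as_alignment(aln)
  if (nrow(windows) == 0) return(empty_pairs())

  cands <- enumerate_candidates(aln, profile, windows, len_range)
  if (nrow(cands) == 0) return(empty_pairs())

  combos <- tidyr::expand_grid(f = seq_len(nrow(cands)),
                               r = seq_len(nrow(cands))) |>
    dplyr::filter(cands$end[.data$f] < cands$start[.data$r])
  if (nrow(combos) == 0) return(empty_pairs())

  var_threshold <- stats::quantile(profile$entropy, var_quantile,
                                   na.rm = TRUE, names = FALSE)

  pairs <- purrr::pmap_dfr(combos, function(f, r) {
    fw <- cands[f, ]
    rv <- cands[r, ]
    span_lens <- vapply(aln$seq, function(s) {
      nchar(ungapped_slice(s, fw$start, rv$end))
    }, integer(1))
    med_len <- stats::median(span_lens)
    if (med_len < len_window[1] || med_len > len_window[2]) return(NULL)
    enclosed <- if (rv$start - fw$end > 1) {
      profile$entropy[(fw$end + 1):(rv$start - 1)]
    } else numeric(0)
    enclosed_max <- if (length(enclosed)) max(enclosed, na.rm = TRUE) else NA_real_
    if (require_variable_core &&
        (is.na(enclosed_max) || enclosed_max < var_threshold)) {
      return(NULL)
    }
    rev_seq <- reverse_complement(rv$oligo)
    u_f <- universality(aln, fw$oligo, fw$start, fw$end, "forward",
                        max_mismatch, anchor_3prime)
    u_r <- universality(aln, rev_seq, rv$start, rv$end, "reverse",
                        max_mismatch, anchor_3prime)
    tibble::tibble(
      fwd_seq = fw$oligo, rev_seq = rev_seq,
      fwd_start = fw$start, fwd_end = fw$end,
      rev_start = rv$start, rev_end = rv$end,
      fwd_mean_entropy = fw$mean_entropy,
      rev_mean_entropy = rv$mean_entropy,
      fwd_mean_similarity = fw$mean_similarity,
      rev_mean_similarity = rv$mean_similarity,
      universality = min(u_f, u_r),
      enclosed_max_entropy = enclosed_max,
      expected_len_min = min(span_lens),
      expected_len_max = max(span_lens),
      expected_len_median = med_len
    )
  })
  if (is.null(pairs) || nrow(pairs) == 0) return(empty_pairs())

  pairs <- pairs |>
    dplyr::filter(.data$universality >= min_universality) |>
    thermo_screen(conditions = conditions) |>
    dplyr::mutate(
      thermo_penalty = abs(.data$tm_fwd - .data$tm_rev) +
        pmax(0, -.data$heterodimer - 8) +
        pmax(0, -.data$self_dimer_fwd - 8) +
        pmax(0, -.data$self_dimer_rev - 8)
    ) |>
    dplyr::arrange(dplyr::desc(.data$universality),
                   dplyr::desc(.data$enclosed_max_entropy),
                   abs(.data$expected_len_median - target_len),
                   .data$thermo_penalty,
                   .data$fwd_start)
  class(pairs) <- c("primer_pairs", class(pairs))
  pairs
}

empty_pairs <- function() {
  out <- tibble::tibble(
    fwd_seq = character(), rev_seq = character(),
    fwd_start = integer(), fwd_end = integer(),
    rev_start = integer(), rev_end = integer(),
    fwd_mean_entropy = double(), rev_mean_entropy = double(),
    fwd_mean_similarity = double(), rev_mean_similarity = double(),
    universality = double(), enclosed_max_entropy = double(),
    expected_len_min = integer(), expected_len_max = integer(),
    expected_len_median = double(),
    tm_fwd = double(), tm_rev = double(),
    self_dimer_fwd = double(), self_dimer_rev = double(),
    hairpin_fwd = double(), hairpin_rev = double(),
    heterodimer = double(), thermo_penalty = double()
  )
  class(out) <- c("primer_pairs", class(out))
  out
}

# All primer-length sub-windows of the maximal conserved windows, with
# consensus oligos. Sub-windows whose consensus lost columns to
# gap-majority are dropped (a primer must be a contiguous oligo).
enumerate_candidates <- function(aln, profile, windows, len_range) {
  purrr::pmap_dfr(windows[, c("start", "end")], function(start, end) {
    lens <- seq(len_range[1], min(len_range[2], end - start + 1L))
    purrr::map_dfr(lens, function(L) {
      starts <- seq.int(start, end - L + 1L)
      tibble::tibble(start = starts, end = starts + L - 1L)
    })
  }) |>
    dplyr::distinct() |>
    dplyr::mutate(
      oligo = purrr::map2_chr(.data$start, .data$end,
                              ~consensus_oligo(aln, .x, .y)),
      mean_entropy = purrr::map2_dbl(
        .data$start, .data$end, ~mean(profile$entropy[.x:.y])),
      mean_similarity = purrr::map2_dbl(
        .data$start, .data$end, ~mean(profile$similarity[.x:.y]))
    ) |>
    dplyr::filter(nchar(.data$oligo) == .data$end - .data$start + 1L)
}
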