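# In-silico PCR: primer binding-site search with mismatch and 3'-anchor
# rules, product extraction with a size-exclusion window, exact-identity
# amplicon grouping, and pairwise substitution summaries.

#' Find primer binding sites on a template
#'
#' Slides the primer along the plus strand and its reverse complement along
#' the minus strand. A site qualifies when it has at most `max_mismatch`
#' mismatches and none within the `anchor_3prime` bases at the primer's
#' 3' end (which for a minus-strand site is the left edge of the matched
#' region on the plus strand). Ambiguous template positions count as
#' mismatches.
#'
#' @param template Template sequence (plus strand, 5' to 3').
#' @param primer Primer, 5' to 3'.
#' @param max_mismatch Maximum mismatches (default 2).
#' @param anchor_3prime Mismatch-free 3'-terminal length (default 3).
#' @return A tibble with `start`, `end` (1-based inclusive, plus-strand
#'   coordinates), `strand` (`"+"`/`"-"`), `mismatches`, sorted by `start`.
#' @export
find_binding_sites <- function(template, primer, max_mismatch = 2L,
                               anchor_3prime = 3L) {
  template <- normalize_nt(template)
  primer <- normalize_nt(primer)
  tl <- nchar(template)
  pl <- nchar(primer)
  empty <- tibble::tibble(start = integer(), end = integer(),
                          strand = character(), mismatches = integer())
  if (pl > tl || pl == 0L) return(empty)

  tc <- strsplit(template, "", fixed = TRUE)[[1]]
  scan <- function(pat, anchor_left) {
    pc <- strsplit(pat, "", fixed = TRUE)[[1]]
    anchor_idx <- if (anchor_left) seq_len(min(anchor_3prime, pl)) else
      seq.int(pl - min(anchor_3prime, pl) + 1L, pl)
    starts <- integer(0)
    mms <- integer(0)
    for (o in 0:(tl - pl)) {
      mm <- tc[(o + 1):(o + pl)] != pc
      n_mm <- sum(mm)
      if (n_mm > max_mismatch) next
      if (anchor_3prime > 0 && any(mm[anchor_idx])) next
      starts <- c(starts, o + 1L)
      mms <- c(mms, n_mm)
    }
    list(starts = starts, mms = mms)
  }

  plus <- scan(primer, anchor_left = FALSE)
  minus <- scan(reverse_complement(primer), anchor_left = TRUE)
  dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(start = plus$starts, end = plus$starts + pl - 1L,
                   strand = "+", mismatches = plus$mms),
    tibble::tibble(start = minus$starts, end = minus$starts + pl - 1L,
                   strand = "-", mismatches = minus$mms)
  ), .data$start)
}

#' In-silico PCR over a set of templates
#'
#' For each template, enumerates every forward-site/reverse-site
#' combination (forward primer on the plus strand, reverse primer on the
#' minus strand, forward site upstream), keeps products whose length falls
#' in `size_window` — the computational size-exclusion step — and reports a
#' per-template status: `"ok"` (exactly one in-window product),
#' `"no_amplification"`, or `"ambiguous"` (several in-window products; the
#' products are listed, never silently dropped). The amplicon spans primer
#' site to primer site inclusive.
#'
#' @param templates A data frame with `id` and `seq` columns, or a named
#'   character vector of sequences.
#' @param fwd,rev Forward and reverse primer sequences, 5' to 3'.
#' @param size_window Product length window in nt (default `c(150, 300)`).
#' @param max_mismatch,anchor_3prime Site-matching rule (defaults 2 and 3;
#'   templates may diverge from consensus primers).
#' @return A tibble with one row per retained product plus one row per
#'   failed template: `template_id`, `status`, `n_products`, `amplicon`,
#'   `length`, `fwd_start`, `fwd_end`, `rev_start`, `rev_end`.
#' @export
amplify <- function(templates, fwd, rev, size_window = c(150L, 300L),
                    max_mismatch = 2L, anchor_3prime = 3L) {
  if (is.character(templates)) {
    if (is.null(names(templates))) {
      names(templates) <- paste0("template", seq_along(templates))
    }
    templates <- tibble::tibble(id = names(templates),
                                seq = unname(templates))
  }
  stopifnot(all(c("id", "seq") %in% names(templates)))

  purrr::pmap_dfr(templates[, c("id", "seq")], function(id, seq) {
    seq <- normalize_nt(seq)
    f_sites <- dplyr::filter(
      find_binding_sites(seq, fwd, max_mismatch, anchor_3prime),
      .data$strand == "+")
    r_sites <- dplyr::filter(
      find_binding_sites(seq, rev, max_mismatch, anchor_3prime),
      .data$strand == "-")
    products <- tidyr::expand_grid(f = seq_len(nrow(f_sites)),
                                   r = seq_len(nrow(r_sites)))
    if (nrow(products) > 0) {
      products <- products |>
        dplyr::mutate(
          fwd_start = f_sites$start[.data$f], fwd_end = f_sites$end[.data$f],
          rev_start = r_sites$start[.data$r], rev_end = r_sites$end[.data$r],
          length = .data$rev_end - .data$fwd_start + 1L
        ) |>
        dplyr::filter(.data$fwd_end < .data$rev_start,
                      .data$length >= size_window[1],
                      .data$length <= size_window[2])
    }
    n <- nrow(products)
    if (n == 0) {
      return(tibble::tibble(
        template_id = id, status = "no_amplification", n_products = 0L,
        amplicon = NA_character_, length = NA_integer_,
        fwd_start = NA_integer_, fwd_end = NA_integer_,
        rev_start = NA_integer_, rev_end = NA_integer_))
    }
    products |>
      dplyr::transmute(
        template_id = id,
        status = if (n == 1L) "ok" else "ambiguous",
        n_products = n,
        amplicon = substr(seq, .data$fwd_start, .data$rev_end),
        length = .data$length,
        fwd_start = .data$fwd_start, fwd_end = .data$fwd_end,
        rev_start = .data$rev_start, rev_end = .data$rev_end)
  })
}

#' Group amplicons by exact sequence identity
#'
#' Partitions amplicons into groups of pairwise-identical sequences
#' (case- and U/T-normalized), the computational analogue of sample-sets
#' whose members share 100% amplicon identity. Groups are ordered by size
#' (descending), ties by representative sequence.
#'
#' @param amplicons A data frame with `template_id` and `amplicon` columns
#'   (rows with `NA` amplicons are ignored), or a named character vector.
#' @return A tibble with `group` (`set1`, `set2`, ...), `representative`,
#'   `size`, and a `member_ids` list-column. Sizes sum to the number of
#'   amplicons grouped.
#' @export
group_by_identity <- function(amplicons) {
  if (is.character(amplicons)) {
    ids <- names(amplicons) %||% paste0("amplicon", seq_along(amplicons))
    amplicons <- tibble::tibble(template_id = ids,
                                amplicon = unname(amplicons))
  }
  stopifnot(all(c("template_id", "amplicon") %in% names(amplicons)))
  out <- amplicons |>
    dplyr::filter(!is.na(.data$amplicon)) |>
    dplyr::mutate(representative = normalize_nt(.data$amplicon)) |>
    dplyr::summarise(member_ids = list(sort(.data$template_id)),
                     size = dplyr::n(),
                     .by = "representative") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$representative) |>
    dplyr::mutate(group = paste0("set", dplyr::row_number()), .before = 1)
  out[, c("group", "representative", "size", "member_ids")]
}

#' Pairwise substitutions among group representatives
#'
#' Compares equal-length representative sequences position by position,
#' reporting the 1-based polymorphic columns with each group's residue and
#' the symmetric matrix of pairwise substitution counts (Hamming
#' distances). Unequal-length representatives must be aligned beforehand
#' (supply the aligned sequences); otherwise an error is raised.
#'
#' @param reps Named character vector of representative sequences, or a
#'   data frame with `group` and `representative` columns (e.g. from
#'   [group_by_identity()]).
#' @return A list of class `substitution_summary`: `positions` (tibble,
#'   one row per polymorphic column, one residue column per group),
#'   `matrix` (symmetric integer matrix, zero diagonal), `n_columns`.
#' @export
pairwise_substitutions <- function(reps) {
  if (is.data.frame(reps)) {
    reps <- stats::setNames(reps$representative, reps$group)
  }
  if (is.null(names(reps))) names(reps) <- paste0("set", seq_along(reps))
  reps <- normalize_nt(reps)
  lens <- nchar(reps)
  if (length(unique(lens)) != 1L) {
    stop("representatives differ in length (",
         paste(unique(lens), collapse = ", "),
         "); align them first and pass the aligned sequences")
  }
  m <- do.call(rbind, strsplit(reps, "", fixed = TRUE))
  rownames(m) <- names(reps)
  poly <- which(apply(m, 2, function(col) length(unique(col)) > 1L))
  positions <- tibble::as_tibble(
    c(list(position = as.integer(poly)),
      stats::setNames(lapply(rownames(m), function(g) m[g, poly]),
                      rownames(m)))
  )
  k <- nrow(m)
  mat <- matrix(0L, k, k, dimnames = list(rownames(m), rownames(m)))
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      d <- sum(m[i, ] != m[j, ])
      mat[i, j] <- mat[j, i] <- d
    }
  }
  structure(list(positions = positions, matrix = mat,
                 n_columns = unname(lens[1])),
            class = "substitution_summary")
}

#' @export
print.substitution_summary <- function(x, ...) {
  cat("<substitution summary over ", x$n_columns, " columns; ",
      nrow(x$positions), " polymorphic>\n", sep = "")
  print(x$positions)
  cat("\npairwise substitution counts:\n")
  print(x$matrix)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write amplicons as FASTA
#'
#' @param amplicons Tibble from [amplify()] (rows with products).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_amplicon_fasta <- function(amplicons, path) {
  ok <- dplyr::filter(amplicons, !is.na(.data$amplicon))
  set <- Biostrings::DNAStringSet(stats::setNames(ok$amplicon,
                                                  ok$template_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
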