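#' Shannon entropy of one alignment column
#'
#' Entropy over the five states A, T, C, G and `-` (gap), with
#' \eqn{S = -\sum_m P(x_m) \log P(x_m)} and \eqn{0 \log 0 \equiv 0}.
#' IUPAC ambiguity codes are excluded from the counts; a column consisting
#' entirely of ambiguity codes is undefined and raises an error.
#'
#' @param column Character vector of residue symbols (one alignment column).
#' @param log_base Logarithm base: `"e"` (default), `"2"`, `"10"`, or a
#'   numeric base.
#' @return Non-negative entropy in units of the chosen base, at most
#'   `log(5)` in that base.
#' @export
shannon_entropy <- function(column, log_base = "e") {
  counts <- column_state_counts(column)
  n <- sum(counts)
  if (length(column) == 0L) stop("empty column")
  if (n == 0L) stop("column has no countable residues (all ambiguity codes)")
  p <- counts[counts > 0] / n
  -sum(p * log(p, base = resolve_log_base(log_base))) + 0 # +0 drops IEEE -0
}

#' Similarity score of one alignment column
#'
#' Percentage of the most frequent nucleotide in the column. Gap rows count
#' in the denominator but a gap can never be the modal symbol; ambiguity
#' codes are excluded entirely.
#'
#' @inheritParams shannon_entropy
#' @return A percentage in \[0, 100\].
#' @export
similarity_percent <- function(column) {
  counts <- column_state_counts(column)
  n <- sum(counts)
  if (length(column) == 0L) stop("empty column")
  if (n == 0L) stop("column has no countable residues (all ambiguity codes)")
  nt <- counts[c("A", "C", "G", "T")]
  100 * max(nt) / n
}

# Counts over the five entropy states; ambiguity codes dropped.
column_state_counts <- function(column) {
  column <- normalize_nt(column)
  states <- c("A", "C", "G", "T", "-")
  counts <- table(factor(column, levels = states))
  stats::setNames(as.integer(counts), states)
}

resolve_log_base <- function(log_base) {
  if (is.numeric(log_base)) return(log_base)
  switch(as.character(log_base),
    "e" = exp(1), "2" = 2, "10" = 10,
    stop("log_base must be 'e', '2', '10' or a number")
  )
}

#' Per-column conservation profile of an alignment
#'
#' Computes Shannon entropy (five states: A, T, C, G, gap), similarity
#' (percentage of the modal nucleotide) and coverage (fraction of rows that
#' are unambiguous residues or gaps) for every alignment column. Columns are
#' numbered from 1. Columns where every row is an ambiguity code are
#' reported as `NA` with `defined = FALSE` rather than aborting.
#'
#' @param aln An alignment (see [as_alignment()]); data frame with
#'   `id`/`seq`, named character vector, or `XStringSet`.
#' @inheritParams shannon_entropy
#' @return A tibble of class `conservation_profile` with columns `column`,
#'   `entropy`, `similarity`, `coverage`, `defined`.
#' @examples
#' aln <- c(s1 = "ACG", s2 = "ACG", s3 = "ACG", s4 = "ACT")
#' conservation_profile(aln)
#' @export
conservation_profile <- function(aln, log_base = "e") {
  aln <- as_alignment(aln)
  m <- alignment_matrix(aln)
  base <- resolve_log_base(log_base)
  states <- c("A", "C", "G", "T", "-")

  per_col <- purrr::map(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    counts <- table(factor(col, levels = states))
    counts <- as.integer(counts)
    n <- sum(counts)
    if (n == 0L) {
      return(tibble::tibble(entropy = NA_real_, similarity = NA_real_,
                            coverage = 0, defined = FALSE))
    }
    p <- counts[counts > 0] / n
    tibble::tibble(
      entropy = -sum(p * log(p, base = base)) + 0,
      similarity = 100 * max(counts[1:4]) / n,
      coverage = n / length(col),
      defined = TRUE
    )
  })

  out <- dplyr::bind_cols(
    tibble::tibble(column = seq_len(ncol(m))),
    dplyr::bind_rows(per_col)
  )
  class(out) <- c("conservation_profile", class(out))
  attr(out, "log_base") <- log_base
  out
}

#' Write a conservation profile as TSV
#'
#' @param profile A [conservation_profile()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(profile[, c("column", "entropy", "similarity", "coverage")],
                   path)
  invisible(path)
}

#' Line plot of a conservation profile
#'
#' Mirrors the usual two-track view: similarity (%) and Shannon entropy per
#' alignment column, with optional shaded primer windows.
#'
#' @param object A `conservation_profile`.
#' @param windows Optional tibble with `start`/`end` columns to shade.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot conservation_profile
#' @export
autoplot.conservation_profile <- function(object, windows = NULL, ...) {
  long <- tidyr::pivot_longer(
    object, c("entropy", "similarity"),
    names_to = "statistic", values_to = "value"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$column, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$statistic),
                       linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(~statistic, ncol = 1, scales = "free_y") +
    ggplot2::scale_colour_manual(
      values = c(entropy = "#2166ac", similarity = "#b2182b"),
      guide = "none"
    ) +
    ggplot2::labs(x = "alignment column", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(windows) && nrow(windows) > 0) {
    p <- p + ggplot2::geom_rect(
      data = windows,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "grey40",
      inherit.aes = FALSE
    )
  }
  p
}
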