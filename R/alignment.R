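#' Read an aligned FASTA file into an alignment tibble
#'
#' Reads a nucleotide multiple sequence alignment and returns it as a tibble
#' with one row per sequence. Sequences are normalized on ingest: uppercased,
#' `U` converted to `T`, and `.` gap characters converted to `-`.
#'
#' @param path Path to an aligned FASTA file.
#' @return A tibble with columns `id` and `seq`, validated as an alignment
#'   (equal sequence lengths, unique ids).
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  as_alignment(tibble::tibble(
    id = names(set),
    seq = as.character(set)
  ))
}

#' Coerce to a validated alignment tibble
#'
#' Accepts a data frame with `id`/`seq` columns, a named character vector, or
#' a `Biostrings::XStringSet`, normalizes the sequences (uppercase, U to T,
#' `.` to `-`) and checks the alignment invariants: all sequences the same
#' length, at least one column, unique ids.
#'
#' @param x Alignment input (data frame, named character vector, XStringSet).
#' @return A tibble with columns `id`, `seq` and class `sscp_alignment`.
#' @export
as_alignment <- function(x) {
  if (inherits(x, "XStringSet")) {
    x <- tibble::tibble(id = names(x), seq = as.character(x))
  } else if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    x <- tibble::tibble(id = names(x), seq = unname(x))
  }
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  seq <- normalize_nt(x$seq)
  lens <- nchar(seq)
  if (length(seq) == 0L) stop("alignment contains no sequences")
  if (length(unique(lens)) != 1L) {
    stop("sequences differ in length: not a valid alignment")
  }
  if (lens[1] < 1L) stop("alignment must have at least one column")
  if (anyDuplicated(x$id)) stop("sequence ids must be unique")
  out <- tibble::tibble(id = as.character(x$id), seq = seq)
  class(out) <- c("sscp_alignment", class(out))
  out
}

#' @export
print.sscp_alignment <- function(x, ...) {
  cat("<alignment: ", nrow(x), " sequences x ", nchar(x$seq[1]),
      " columns>\n", sep = "")
  NextMethod()
}

# Uppercase, U->T, '.'->'-'; everything else (IUPAC codes) left intact.
normalize_nt <- function(seq) {
  chartr("U.", "T-", toupper(seq))
}

# Character matrix view (rows = sequences, columns = alignment columns).
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  rownames(m) <- aln$id
  m
}

#' Reverse complement of a DNA string
#'
#' Gap characters are preserved; IUPAC ambiguity codes are complemented.
#'
#' @param seq A character vector of DNA strings.
#' @return The reverse complement(s), same length as `seq`.
#' @export
reverse_complement <- function(seq) {
  comp <- chartr("ACGTRYKMBVDHacgtrykmbvdh",
                 "TGCAYRMKVBHDtgcayrmkvbhd", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}
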