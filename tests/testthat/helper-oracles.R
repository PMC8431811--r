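# Independent oracles used across the suite. Each re-derives the quantity
# it checks by enumeration or direct counting, sharing no code path with
# the implementation under test.

# --- column statistics ------------------------------------------------------

oracle_entropy <- function(column, base = exp(1)) {
  column <- chartr("u.", "T-", toupper(column))
  freq <- vapply(c("A", "C", "G", "T", "-"),
                 function(s) sum(column == s), numeric(1))
  p <- freq[freq > 0] / sum(freq)
  -sum(p * log(p)) / log(base)
}

oracle_similarity <- function(column) {
  column <- chartr("u.", "T-", toupper(column))
  freq <- vapply(c("A", "C", "G", "T"),
                 function(s) sum(column == s), numeric(1))
  denom <- sum(freq) + sum(column == "-")
  100 * max(freq) / denom
}

# --- duplex / hairpin free energies ----------------------------------------

# Exhaustive enumeration of every anti-parallel, non-crossing pairing of
# two oligos under the same scoring rules as the implementation (stacks,
# loop penalties, exterior dangles, minimum-helix rule), via recursion over
# ordered pair lists.
oracle_duplex_dg <- function(seq_a, seq_b, temperature_c = 25,
                             min_helix = 3L, max_loop = 30L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  temp_k <- temperature_c + 273.15
  pairs <- which(outer(a, b, function(x, y) comp[x] == y), arr.ind = TRUE)
  if (nrow(pairs) == 0) return(0)
  seqa <- paste(a, collapse = "")
  n <- length(a); m <- length(b)

  left_dangle <- function(i, j) {
    g <- 0
    if (i > 1) g <- g + sscpkit:::dangle_dg(5L, paste0(a[i], b[j]),
                                            a[i - 1], temp_k)
    if (j < m) g <- g + sscpkit:::dangle_dg(3L, paste0(b[j], a[i]),
                                            b[j + 1], temp_k)
    g
  }
  right_dangle <- function(i, j) {
    g <- 0
    if (i < n) g <- g + sscpkit:::dangle_dg(3L, paste0(a[i], b[j]),
                                            a[i + 1], temp_k)
    if (j > 1) g <- g + sscpkit:::dangle_dg(5L, paste0(b[j], a[i]),
                                            b[j - 1], temp_k)
    g
  }

  best <- 0
  recurse <- function(i, j, score, run, qualified) {
    total <- score + right_dangle(i, j)
    if ((qualified || run >= min_helix) && total < best) best <<- total
    nxt <- pairs[pairs[, 1] > i & pairs[, 2] < j, , drop = FALSE]
    for (k in seq_len(nrow(nxt))) {
      i2 <- nxt[k, 1]; j2 <- nxt[k, 2]
      da <- i2 - i - 1L; db <- j - j2 - 1L
      if (da == 0L && db == 0L) {
        g <- sscpkit:::stack_dg(substr(seqa, i, i + 1), temp_k)
        recurse(i2, j2, score + g, run + 1L,
                qualified || run + 1L >= min_helix)
      } else if (da + db <= max_loop) {
        g <- sscpkit:::duplex_gap_penalty(da, db, temp_k)
        recurse(i2, j2, score + g, 1L, qualified || run >= min_helix)
      }
    }
  }
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    recurse(i, j, left_dangle(i, j), 1L, min_helix <= 1L)
  }
  min(best, 0)
}

# Naive triple-loop stem-loop enumeration under the implementation's
# scoring rules.
oracle_hairpin_dg <- function(seq, min_loop = 3L, temperature_c = 25) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  temp_k <- temperature_c + 273.15
  seqc <- paste(s, collapse = "")
  best <- Inf
  for (i in seq_len(n)) for (j in seq_len(n)) for (len in 2:max(2, n)) {
    if (j <= i) next
    loop <- j - i + 1 - 2 * len
    if (loop < min_loop) next
    idx <- 0:(len - 1)
    if (i + len - 1 >= j - len + 1) next
    if (!all(comp[s[i + idx]] == s[j - idx])) next
    g <- sum(sscpkit:::stack_dg(
      substring(seqc, (i:(i + len - 2)), (i + 1):(i + len - 1)), temp_k)) +
      sscpkit:::loop_penalty("hairpin", loop, temp_k)
    if (g < best) best <- g
  }
  if (is.finite(best)) best else 0
}

# --- band matching ----------------------------------------------------------

# Exhaustive maximum one-to-one matching of bands within a tolerance.
oracle_band_matches <- function(a, b, tol) {
  if (length(a) == 0 || length(b) == 0) return(0L)
  if (length(a) > length(b)) return(oracle_band_matches(b, a, tol))
  best <- 0L
  assign_next <- function(i, used, count) {
    if (count + (length(a) - i + 1) <= best) return()
    if (i > length(a)) {
      if (count > best) best <<- count
      return()
    }
    for (j in seq_along(b)) {
      if (!used[j] && abs(a[i] - b[j]) <= tol) {
        used[j] <- TRUE
        assign_next(i + 1, used, count + 1L)
        used[j] <- FALSE
      }
    }
    assign_next(i + 1, used, count)
  }
  assign_next(1L, rep(FALSE, length(b)), 0L)
  best
}

oracle_band_similarity <- function(a, b, tol) {
  if (length(a) == 0 && length(b) == 0) return(100)
  if (length(a) == 0 || length(b) == 0) return(0)
  100 * 2 * oracle_band_matches(a, b, tol) / (length(a) + length(b))
}

# --- random oligos ----------------------------------------------------------

random_oligo <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
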