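# Nearest-neighbor thermodynamics for short DNA oligos: two-state melting
# temperature, and minimum-free-energy self-dimer / heterodimer / hairpin
# structures under a simplified loop model.
#
# Parameter set: unified NN values (SantaLucia 1998). dH in kcal/mol,
# dS in cal/(mol K). Stacks are keyed by the 5'->3' top-strand dinucleotide;
# the table is closed under reverse complement.

.nn_dh <- c(
  AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
  CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
  TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0
)
.nn_ds <- c(
  AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
  CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
  TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2, CC = -19.9
)
# Duplex initiation per terminal base pair.
.init_dh <- c(AT = 2.3, GC = 0.1)
.init_ds <- c(AT = 4.1, GC = -2.8)

.gas_constant <- 1.987 # cal/(mol K)

#' Thermodynamic conditions for oligo calculations
#'
#' @param monovalent_mM Monovalent cation concentration (mM). Default 50.
#' @param divalent_mM Divalent cation concentration (mM); folded into a
#'   monovalent equivalent as `120 * sqrt(divalent_mM)`. Default 0.
#' @param oligo_uM Total oligonucleotide strand concentration (uM).
#'   Default 0.25.
#' @return A list of class `thermo_conditions`.
#' @export
thermo_conditions <- function(monovalent_mM = 50, divalent_mM = 0,
                              oligo_uM = 0.25) {
  stopifnot(monovalent_mM >= 0, divalent_mM >= 0, oligo_uM > 0)
  structure(list(monovalent_mM = monovalent_mM, divalent_mM = divalent_mM,
                 oligo_uM = oligo_uM),
            class = "thermo_conditions")
}

check_oligo <- function(seq, min_len = 1L, max_len = Inf) {
  seq <- normalize_nt(seq)
  n <- nchar(seq)
  if (n < min_len || n > max_len) {
    stop("oligo length ", n, " outside [", min_len, ", ", max_len, "]")
  }
  if (grepl("[^ACGT]", seq)) {
    stop("oligo contains non-ACGT characters (ambiguity codes not allowed): ",
         seq)
  }
  seq
}

duplex_dh_ds <- function(seq) {
  n <- nchar(seq)
  stacks <- substring(seq, 1:(n - 1), 2:n)
  ends <- ifelse(substring(seq, c(1, n), c(1, n)) %in% c("G", "C"),
                 "GC", "AT")
  list(
    dh = sum(.nn_dh[stacks]) + sum(.init_dh[ends]),
    ds = sum(.nn_ds[stacks]) + sum(.init_ds[ends])
  )
}

is_self_complementary <- function(seq) {
  identical(seq, reverse_complement(seq))
}

#' Two-state nearest-neighbor melting temperature
#'
#' Computes the duplex melting temperature of an oligo against its perfect
#' complement using unified nearest-neighbor parameters, an entropic
#' monovalent-salt correction (`0.368 * (N - 1) * ln[Na+]`), and the
#' standard strand-concentration term: `CT/4` for non-self-complementary
#' duplexes at equal strand concentrations, `CT` (with the symmetry entropy
#' correction) for self-complementary ones.
#'
#' @param seq Oligo sequence, 5' to 3', unambiguous A/C/G/T, 8-60 nt.
#' @param conditions A [thermo_conditions()] object.
#' @return Melting temperature in degrees Celsius.
#' @examples
#' melting_temperature("GCAGTAAATCGGGGCTAATAC")
#' @export
melting_temperature <- function(seq, conditions = thermo_conditions()) {
  seq <- check_oligo(seq, min_len = 8L, max_len = 60L)
  n <- nchar(seq)
  th <- duplex_dh_ds(seq)
  na_eq <- (conditions$monovalent_mM +
              120 * sqrt(conditions$divalent_mM)) / 1000
  if (na_eq <= 0) stop("need a positive salt concentration")
  ds <- th$ds + 0.368 * (n - 1) * log(na_eq)
  ct <- conditions$oligo_uM * 1e-6
  if (is_self_complementary(seq)) {
    ds <- ds - 1.4
    k <- ct
  } else {
    k <- ct / 4
  }
  th$dh * 1000 / (ds + .gas_constant * log(k)) - 273.15
}

# -- free-energy machinery ---------------------------------------------------

# Stack dG at temperature T (Kelvin): dH - T dS.
stack_dg <- function(stacks, temp_k) {
  .nn_dh[stacks] - temp_k * .nn_ds[stacks] / 1000
}

# Destabilizing loop costs, kcal/mol at 37 C (standard DNA loop table,
# Jacobson-Stockmayer extrapolation beyond 30). Loops are treated as purely
# entropic, so dG scales linearly with absolute temperature.
.loop37 <- list(
  hairpin  = c(`3` = 3.5, `4` = 3.5, `5` = 3.3, `6` = 4.0, `7` = 4.3,
               `8` = 4.5, `9` = 4.6, `10` = 4.8, `12` = 4.9, `14` = 5.1,
               `16` = 5.3, `18` = 5.5, `20` = 5.7, `25` = 6.1, `30` = 6.3),
  bulge    = c(`1` = 4.0, `2` = 2.9, `3` = 3.1, `4` = 3.2, `5` = 3.3,
               `6` = 3.5, `7` = 3.7, `8` = 3.9, `9` = 4.1, `10` = 4.3,
               `12` = 4.5, `14` = 4.8, `16` = 5.0, `18` = 5.2, `20` = 5.3,
               `25` = 5.6, `30` = 5.9),
  interior = c(`2` = 3.2, `3` = 3.2, `4` = 3.6, `5` = 4.0, `6` = 4.4,
               `7` = 4.6, `8` = 4.8, `9` = 4.9, `10` = 5.0, `12` = 5.2,
               `14` = 5.4, `16` = 5.6, `18` = 5.8, `20` = 5.9, `25` = 6.3,
               `30` = 6.6)
)

loop_penalty <- function(kind, size, temp_k) {
  tab <- .loop37[[kind]]
  sizes <- as.integer(names(tab))
  if (size <= 0) stop("loop size must be positive")
  if (size <= max(sizes)) {
    # interpolate on the tabulated grid
    g37 <- stats::approx(sizes, tab, xout = size, rule = 2)$y
  } else {
    g37 <- tab[length(tab)] +
      1.75 * .gas_constant / 1000 * 310.15 * log(size / max(sizes))
  }
  unname(g37) * temp_k / 310.15
}

# Gap cost between consecutive base pairs of a duplex: (da, db) unpaired
# bases on the two strands. (0,0) is a stack and handled by the caller.
duplex_gap_penalty <- function(da, db, temp_k) {
  if (da == 0 || db == 0) loop_penalty("bulge", da + db, temp_k)
  else loop_penalty("interior", da + db, temp_k)
}

.complement_base <- c(A = "T", C = "G", G = "C", T = "A")

# Dangling-end free energies (kcal/mol at 37 C) and enthalpies for DNA,
# Mathews-style tables. Keyed by closing pair written 5'base+partner on the
# strand bearing the dangle, then by the dangling base. dG(T) obtained from
# the dH / dS split.
.dangle5_g37 <- list(
  CG = c(A = -0.9, C = -0.5, G = -0.7, T = -0.6),
  GC = c(A = -0.8, C = -0.5, G = -0.8, T = -0.7),
  AT = c(A = -0.5, C = -0.2, G = -0.6, T = -0.3),
  TA = c(A = -0.5, C = -0.2, G = -0.5, T = -0.3)
)
.dangle5_h <- list(
  CG = c(A = -6.2, C = -3.3, G = -5.1, T = -0.9),
  GC = c(A = -4.6, C = -4.2, G = -4.7, T = -5.0),
  AT = c(A = -0.9, C = -0.6, G = -2.5, T = -9.0),
  TA = c(A = 0.8, C = 2.0, G = 1.5, T = 1.1)
)
.dangle3_g37 <- list(
  CG = c(A = -0.4, C = -0.2, G = -0.4, T = -0.3),
  GC = c(A = -1.1, C = -0.4, G = -1.1, T = -0.8),
  AT = c(A = -0.2, C = -0.2, G = -0.2, T = -0.2),
  TA = c(A = -0.2, C = -0.2, G = -0.2, T = -0.2)
)
.dangle3_h <- list(
  CG = c(A = -1.9, C = -0.2, G = -4.0, T = -5.5),
  GC = c(A = -8.0, C = -2.5, G = -3.1, T = -3.9),
  AT = c(A = -5.3, C = 2.0, G = -4.8, T = 0.9),
  TA = c(A = 4.3, C = 6.3, G = 2.5, T = 2.6)
)

dangle_dg <- function(side, pair, base, temp_k) {
  g37 <- if (side == 5L) .dangle5_g37 else .dangle3_g37
  h <- if (side == 5L) .dangle5_h else .dangle3_h
  g <- g37[[pair]][base]
  dh <- h[[pair]][base]
  ds <- (dh - g) / 310.15
  out <- dh - temp_k * ds
  # dangles are stabilizing-or-nothing
  min(unname(out), 0)
}

#' Minimum free energy of a two-strand dimer
#'
#' Finds the most stable anti-parallel pairing of two oligos under a
#' nearest-neighbor model that allows bulges and interior loops: matched
#' Watson-Crick pairs are scored by stacking free energies evaluated at the
#' reporting temperature, and unpaired gaps between helices by a
#' length-dependent entropic loop cost. No duplex-initiation term is added,
#' matching how primer-QC tools report dimer ΔG. Structures must contain at
#' least one helix of `min_helix` (default 3) consecutive pairs; if none
#' exists the function returns 0.
#'
#' @param seq_a,seq_b Oligos, 5' to 3' (use the same sequence twice for a
#'   self-dimer).
#' @param temperature_c Reporting temperature in Celsius (default 25, the
#'   conventional dimer-report temperature).
#' @param min_helix Minimum consecutive-pair helix length for a structure to
#'   count (default 3).
#' @return Free energy in kcal/mol (0 when no qualifying structure exists;
#'   symmetric in its arguments).
#' @examples
#' duplex_delta_g("GCAGTAAATCGGGGCTAATAC", "CCCGTTACAACCATGGTA")
#' @export
duplex_delta_g <- function(seq_a, seq_b, temperature_c = 25, min_helix = 3L,
                           max_loop = 30L) {
  a <- strsplit(check_oligo(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(check_oligo(seq_b), "", fixed = TRUE)[[1]]
  temp_k <- temperature_c + 273.15
  n <- length(a)
  m <- length(b)
  seqa <- paste(a, collapse = "")

  # pair (i, j): a[i] with b[j], antiparallel (i ascending, j descending)
  can_pair <- outer(a, b, function(x, y) .complement_base[x] == y)
  if (!any(can_pair)) return(0)

  # States per last-pair (i, j):
  #   dpu[i, j, r]: best score, no helix of min_helix yet, current run r
  #                 (r in 1..min_helix-1)
  #   dpq[i, j]:    best score with the min-helix requirement already met
  ru <- max(min_helix - 1L, 1L)
  dpu <- array(Inf, dim = c(n, m, ru))
  dpq <- matrix(Inf, n, m)
  stack_g <- c(stack_dg(substring(seqa, seq_len(max(n - 1, 1)),
                                  seq_len(max(n - 1, 1)) + 1), temp_k), 0)

  # Dangling unpaired neighbors stabilize the two exterior ends of the
  # final structure. Left-end dangles depend only on the opening pair and
  # right-end dangles only on the closing pair, so they attach at the DP
  # boundary conditions.
  left_dangle <- function(i, j) {
    g <- 0
    if (i > 1) g <- g + dangle_dg(5L, paste0(a[i], b[j]), a[i - 1], temp_k)
    if (j < m) g <- g + dangle_dg(3L, paste0(b[j], a[i]), b[j + 1], temp_k)
    g
  }
  right_dangle <- function(i, j) {
    g <- 0
    if (i < n) g <- g + dangle_dg(3L, paste0(a[i], b[j]), a[i + 1], temp_k)
    if (j > 1) g <- g + dangle_dg(5L, paste0(b[j], a[i]), b[j - 1], temp_k)
    g
  }

  for (i in seq_len(n)) for (j in rev(seq_len(m))) {
    if (!can_pair[i, j]) next
    open_g <- left_dangle(i, j)
    if (min_helix <= 1L) {
      if (open_g < dpq[i, j]) dpq[i, j] <- open_g
    } else if (open_g < dpu[i, j, 1]) {
      dpu[i, j, 1] <- open_g
    }

    # stack extension from (i-1, j+1)
    if (i > 1 && j < m && can_pair[i - 1, j + 1]) {
      g <- stack_g[i - 1]
      if (is.finite(dpq[i - 1, j + 1])) {
        cand <- dpq[i - 1, j + 1] + g
        if (cand < dpq[i, j]) dpq[i, j] <- cand
      }
      for (r in seq_len(ru)) {
        prev <- dpu[i - 1, j + 1, r]
        if (!is.finite(prev)) next
        cand <- prev + g
        if (r + 1L >= min_helix) {
          if (cand < dpq[i, j]) dpq[i, j] <- cand
        } else if (cand < dpu[i, j, r + 1L]) {
          dpu[i, j, r + 1L] <- cand
        }
      }
    }

    # loop closure from any earlier pair (pi, pj), gap capped at max_loop
    if (i == 1 || j == m) next
    for (pi in seq_len(i - 1)) {
      da <- i - pi - 1L
      if (da > max_loop) next
      for (pj in seq(j + 1, m)) {
        db <- pj - j - 1L
        if (da == 0L && db == 0L) next # stack, handled above
        if (da + db > max_loop) break
        prev_q <- dpq[pi, pj]
        prev_u <- suppressWarnings(min(dpu[pi, pj, ]))
        if (!is.finite(prev_q) && !is.finite(prev_u)) next
        g <- duplex_gap_penalty(da, db, temp_k)
        if (is.finite(prev_q) && prev_q + g < dpq[i, j]) {
          dpq[i, j] <- prev_q + g
        }
        if (is.finite(prev_u)) {
          if (min_helix <= 1L) {
            if (prev_u + g < dpq[i, j]) dpq[i, j] <- prev_u + g
          } else if (prev_u + g < dpu[i, j, 1]) {
            dpu[i, j, 1] <- prev_u + g
          }
        }
      }
    }
  }
  best <- Inf
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (!is.finite(dpq[i, j])) next
    cand <- dpq[i, j] + right_dangle(i, j)
    if (cand < best) best <- cand
  }
  if (!is.finite(best) || best >= 0) 0 else unname(best)
}

#' Minimum free energy of a hairpin
#'
#' Scans all simple stem-loop decompositions of an oligo: contiguous
#' Watson-Crick stems of at least two base pairs scored by nearest-neighbor
#' stacking at the reporting temperature, closed by a hairpin loop of at
#' least `min_loop` unpaired bases with a length-dependent entropic cost.
#' Returns the minimum free energy found; positive values indicate the best
#' available hairpin is unstable, and 0 is returned when no stem can form.
#'
#' @param seq Oligo, 5' to 3'.
#' @param min_loop Minimum loop length in nt (default 3).
#' @param temperature_c Reporting temperature in Celsius (default 25).
#' @return Free energy in kcal/mol (0 sentinel when no stem exists).
#' @export
hairpin_delta_g <- function(seq, min_loop = 3L, temperature_c = 25) {
  s <- strsplit(check_oligo(seq), "", fixed = TRUE)[[1]]
  n <- length(s)
  temp_k <- temperature_c + 273.15
  seqc <- paste(s, collapse = "")
  best <- Inf
  if (n >= 2 * 2 + min_loop) {
    for (i in seq_len(n - 3 - min_loop)) {
      for (j in seq(i + 3 + min_loop, n)) {
        max_stem <- (j - i + 1 - min_loop) %/% 2
        if (max_stem < 2) next
        stem <- 0L
        while (stem < max_stem &&
               .complement_base[s[i + stem]] == s[j - stem]) {
          stem <- stem + 1L
        }
        if (stem < 2) next
        for (len in 2:stem) {
          loop_size <- j - i + 1 - 2 * len
          g <- sum(stack_dg(substring(seqc, i:(i + len - 2),
                                      (i + 1):(i + len - 1)), temp_k)) +
            loop_penalty("hairpin", loop_size, temp_k)
          if (g < best) best <- g
        }
      }
    }
  }
  if (!is.finite(best)) 0 else best
}

#' Thermodynamic screen of primer pairs
#'
#' Data-frame-in, tibble-out convenience wrapper: for each row with
#' `fwd_seq` and `rev_seq`, computes both melting temperatures, self-dimer
#' and hairpin free energies, and the heterodimer free energy.
#'
#' @param pairs A data frame with columns `fwd_seq` and `rev_seq`.
#' @param conditions A [thermo_conditions()] object.
#' @param temperature_c Reporting temperature for ΔG values (default 25).
#' @return The input tibble with columns `tm_fwd`, `tm_rev`,
#'   `self_dimer_fwd`, `self_dimer_rev`, `hairpin_fwd`, `hairpin_rev`,
#'   `heterodimer` appended.
#' @export
thermo_screen <- function(pairs, conditions = thermo_conditions(),
                          temperature_c = 25) {
  stopifnot(all(c("fwd_seq", "rev_seq") %in% names(pairs)))
  # per-oligo quantities computed once per unique sequence
  memo <- function(seqs, f) {
    u <- unique(seqs)
    vals <- vapply(u, f, double(1))
    unname(vals[match(seqs, u)])
  }
  hetero_key <- paste(pairs$fwd_seq, pairs$rev_seq)
  dplyr::mutate(
    tibble::as_tibble(pairs),
    tm_fwd = memo(.data$fwd_seq, function(s)
      melting_temperature(s, conditions)),
    tm_rev = memo(.data$rev_seq, function(s)
      melting_temperature(s, conditions)),
    self_dimer_fwd = memo(.data$fwd_seq, function(s)
      duplex_delta_g(s, s, temperature_c = temperature_c)),
    self_dimer_rev = memo(.data$rev_seq, function(s)
      duplex_delta_g(s, s, temperature_c = temperature_c)),
    hairpin_fwd = memo(.data$fwd_seq, function(s)
      hairpin_delta_g(s, temperature_c = temperature_c)),
    hairpin_rev = memo(.data$rev_seq, function(s)
      hairpin_delta_g(s, temperature_c = temperature_c)),
    heterodimer = {
      u <- !duplicated(hetero_key)
      vals <- purrr::map2_dbl(.data$fwd_seq[u], .data$rev_seq[u],
                              ~duplex_delta_g(.x, .y,
                                              temperature_c = temperature_c))
      unname(vals[match(hetero_key, hetero_key[u])])
    }
  )
}
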