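# Gel-fingerprint analysis: ladder migration curves, cross-gel band
# normalization, tolerance-matched band similarity, UPGMA dendrograms and
# partition congruence.

#' Ladder specification
#'
#' @param fragment_sizes Rung sizes in bp, given (or sorted) in decreasing
#'   size order: larger fragments migrate less.
#' @return A numeric vector of class `ladder_spec`.
#' @export
ladder_spec <- function(fragment_sizes = seq(1000, 100, by = -100)) {
  sizes <- sort(as.numeric(fragment_sizes), decreasing = TRUE)
  stopifnot(length(sizes) >= 2, all(sizes > 0), !anyDuplicated(sizes))
  structure(sizes, class = "ladder_spec")
}

#' Read a digitized band table
#'
#' Expects TSV columns `gel_id`, `lane_id`, `sample_id`, `band_position`
#' and optionally `intensity` and `is_ladder`.
#'
#' @param path TSV path.
#' @return A tibble sorted by gel, lane, position.
#' @export
read_band_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("gel_id", "lane_id", "sample_id", "band_position")
                %in% names(x)))
  if (!"is_ladder" %in% names(x)) x$is_ladder <- FALSE
  dplyr::arrange(x, .data$gel_id, .data$lane_id, .data$band_position)
}

#' Fit a ladder migration curve
#'
#' Least-squares fit of migration distance `d` against `s = log10(size)`
#' for the rungs of a reference ladder. The default Gaussian form is
#' `d(s) = A exp(-(s - mu)^2 / (2 sigma^2)) + c`; the alternative is the
#' classic log-linear `d(s) = a + b s`. The fitted curve must be monotone
#' over the ladder's size range (an error otherwise), and callers should
#' reject fits with `r_squared < 0.95` before using them for
#' normalization.
#'
#' @param positions Migration positions of the ladder bands, strictly
#'   increasing (increasing = farther migration), one per rung, ordered to
#'   match `spec` (largest fragment first).
#' @param spec A [ladder_spec()].
#' @param model `"gaussian"` (default) or `"log_linear"`.
#' @return An object of class `migration_curve` with elements `model`,
#'   `params`, `r_squared`, `s_range`, `d_range`, `n_rungs`.
#' @export
fit_migration_curve <- function(positions, spec = ladder_spec(),
                                model = c("gaussian", "log_linear")) {
  model <- match.arg(model)
  sizes <- as.numeric(spec)
  if (length(positions) != length(sizes)) {
    stop("ladder has ", length(positions), " bands but the spec lists ",
         length(sizes), " fragment sizes")
  }
  if (length(positions) < 4) {
    stop("InsufficientLadder: need at least 4 rungs, got ",
         length(positions))
  }
  if (any(diff(positions) <= 0)) {
    stop("ladder band positions must be strictly increasing with migration")
  }
  s <- log10(sizes)          # decreasing (largest first)
  d <- as.numeric(positions) # increasing

  if (model == "log_linear") {
    fit <- stats::lm(d ~ s)
    params <- c(a = unname(stats::coef(fit)[1]),
                b = unname(stats::coef(fit)[2]))
    fitted_d <- stats::fitted(fit)
  } else {
    # monotone flank of a Gaussian: center placed below the s range
    start <- list(A = (max(d) - min(d)) * 2, mu = min(s) - 0.5,
                  sigma = diff(range(s)) , c = min(d) - 1)
    fit <- minpack.lm::nlsLM(
      d ~ A * exp(-(s - mu)^2 / (2 * sigma^2)) + c,
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    params <- stats::coef(fit)
    fitted_d <- stats::fitted(fit)
  }
  r2 <- 1 - sum((d - fitted_d)^2) / sum((d - mean(d))^2)
  curve <- structure(
    list(model = model, params = params, r_squared = r2,
         s_range = range(s), d_range = range(d),
         n_rungs = length(d)),
    class = "migration_curve")
  grid <- curve_distance(curve, seq(min(s), max(s), length.out = 101))
  if (any(diff(grid) >= 0)) {
    stop("fitted migration curve is not monotone over the ladder range")
  }
  curve
}

# d(s) for a fitted curve, s = log10(size).
curve_distance <- function(curve, s) {
  p <- curve$params
  if (curve$model == "log_linear") {
    unname(p["a"] + p["b"] * s)
  } else {
    unname(p["A"] * exp(-(s - p["mu"])^2 / (2 * p["sigma"]^2)) + p["c"])
  }
}

#' Predicted migration distance for fragment sizes
#'
#' @param curve A [fit_migration_curve()] object.
#' @param size_bp Fragment sizes in bp.
#' @return Predicted migration positions.
#' @export
predict_distance <- function(curve, size_bp) {
  curve_distance(curve, log10(size_bp))
}

#' Invert a migration curve: position to fragment size
#'
#' Numerically inverts the monotone fitted curve. Positions outside the
#' ladder's fitted migration range are still inverted when possible over a
#' modest extrapolation margin but flagged; positions beyond the invertible
#' range give `NA`.
#'
#' @param curve A [fit_migration_curve()] object.
#' @param position Migration positions.
#' @param s_margin Extrapolation margin on the log10(size) scale
#'   (default 0.3).
#' @return A tibble with `position`, `size_bp`, `extrapolated`.
#' @export
invert_distance <- function(curve, position, s_margin = 0.3) {
  lo <- curve$s_range[1] - s_margin
  hi <- curve$s_range[2] + s_margin
  size <- vapply(position, function(p) {
    f <- function(s) curve_distance(curve, s) - p
    if (f(lo) * f(hi) > 0) return(NA_real_)
    10^stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  }, double(1))
  tibble::tibble(
    position = position,
    size_bp = size,
    extrapolated = is.na(size) | position < curve$d_range[1] |
      position > curve$d_range[2]
  )
}

#' @export
print.migration_curve <- function(x, ...) {
  cat("<migration curve: ", x$model, ", R^2 = ",
      formatC(x$r_squared, digits = 4, format = "f"),
      ", ", x$n_rungs, " rungs>\n", sep = "")
  print(x$params)
  invisible(x)
}

#' @method tidy migration_curve
#' @export
tidy.migration_curve <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @method glance migration_curve
#' @export
glance.migration_curve <- function(x, ...) {
  tibble::tibble(model = x$model, r.squared = x$r_squared,
                 n = x$n_rungs)
}

#' Normalize a gel's lanes onto a reference gel's coordinate scale
#'
#' Maps each band position through the gel's own ladder curve to a
#' fragment size, then through the reference gel's curve back to a
#' position. A gel normalized against its own curve is the identity map
#' (up to numerical tolerance). Bands outside the invertible range are
#' flagged, never dropped.
#'
#' @param lanes A data frame with `sample_id` and `band_position` columns
#'   (ladder lanes should be excluded by the caller or marked with
#'   `is_ladder` to be filtered here).
#' @param curve The gel's own [fit_migration_curve()].
#' @param reference_curve The reference gel's curve. Both must have
#'   `r_squared >= min_r_squared`.
#' @param min_r_squared Fit-quality gate (default 0.95).
#' @return The input tibble with `size_bp`, `normalized_position`,
#'   `extrapolated` appended.
#' @export
normalize_gel <- function(lanes, curve, reference_curve,
                          min_r_squared = 0.95) {
  stopifnot(all(c("sample_id", "band_position") %in% names(lanes)))
  if (curve$r_squared < min_r_squared ||
      reference_curve$r_squared < min_r_squared) {
    stop("migration curve R^2 below ", min_r_squared,
         "; refusing to normalize")
  }
  if ("is_ladder" %in% names(lanes)) {
    lanes <- dplyr::filter(lanes, !.data$is_ladder)
  }
  inv <- invert_distance(curve, lanes$band_position)
  dplyr::mutate(
    tibble::as_tibble(lanes),
    size_bp = inv$size_bp,
    normalized_position = ifelse(
      is.na(inv$size_bp), NA_real_,
      curve_distance(reference_curve, log10(inv$size_bp))),
    extrapolated = inv$extrapolated
  )
}

#' Band-difference similarity between two band patterns
#'
#' Bands are matched one-to-one when their positions differ by at most
#' `tolerance` (on a common normalized scale), maximizing the number of
#' matches; on sorted positions a greedy sweep attains the maximum. The
#' similarity is the Dice coefficient `100 * 2m / (nA + nB)` over matched
#' bands (or Jaccard `100 * m / (nA + nB - m)`). Two empty patterns are
#' defined as 100 (identical absence); one empty pattern gives 0.
#'
#' @param a,b Numeric vectors of band positions.
#' @param tolerance Maximum position difference for a match (default 4).
#' @param method `"dice"` (default) or `"jaccard"`.
#' @return A percentage in \[0, 100\]; symmetric in `a` and `b`.
#' @export
band_similarity <- function(a, b, tolerance = 4, method = c("dice",
                                                            "jaccard")) {
  method <- match.arg(method)
  a <- sort(as.numeric(a))
  b <- sort(as.numeric(b))
  na <- length(a)
  nb <- length(b)
  if (na == 0 && nb == 0) return(100)
  if (na == 0 || nb == 0) return(0)
  m <- count_band_matches(a, b, tolerance)
  if (method == "dice") 100 * 2 * m / (na + nb)
  else 100 * m / (na + nb - m)
}

# Maximum one-to-one matching with |a_i - b_j| <= tol on sorted inputs:
# the greedy two-pointer sweep is optimal for interval-threshold matching
# on a line.
count_band_matches <- function(a, b, tol) {
  i <- 1L; j <- 1L; m <- 0L
  while (i <= length(a) && j <= length(b)) {
    if (abs(a[i] - b[j]) <= tol) {
      m <- m + 1L; i <- i + 1L; j <- j + 1L
    } else if (a[i] < b[j]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  m
}

#' Pairwise band-similarity matrix
#'
#' @param patterns A data frame with `sample_id` and a position column
#'   (`normalized_position` if present, else `band_position`), or a named
#'   list of numeric position vectors.
#' @inheritParams band_similarity
#' @return A symmetric numeric matrix (percent similarity, 100 diagonal).
#' @export
similarity_matrix <- function(patterns, tolerance = 4,
                              method = c("dice", "jaccard")) {
  method <- match.arg(method)
  pats <- as_pattern_list(patterns)
  ids <- names(pats)
  k <- length(pats)
  mat <- matrix(100, k, k, dimnames = list(ids, ids))
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      s <- band_similarity(pats[[i]], pats[[j]], tolerance, method)
      mat[i, j] <- mat[j, i] <- s
    }
  }
  mat
}

as_pattern_list <- function(patterns) {
  if (is.data.frame(patterns)) {
    pos_col <- if ("normalized_position" %in% names(patterns)) {
      "normalized_position"
    } else "band_position"
    stopifnot("sample_id" %in% names(patterns))
    split(patterns[[pos_col]], patterns$sample_id)
  } else {
    stopifnot(is.list(patterns), !is.null(names(patterns)))
    patterns
  }
}

#' UPGMA dendrogram from a similarity matrix
#'
#' Converts similarity to distance (`100 - similarity`) and agglomerates
#' by unweighted pair-group average linkage: at each step the pair of
#' clusters with the smallest average inter-point distance merges, at an
#' ultrametric node height of half that distance. Ties are broken by the
#' lexicographically smallest pair of cluster labels, so the result is
#' invariant to input order.
#'
#' @param mat A symmetric similarity matrix (percent) with row/column
#'   names, or a distance matrix if `is_distance = TRUE`.
#' @param is_distance Interpret `mat` directly as distances (default
#'   FALSE).
#' @return An object of class `upgma_tree`: `merges` (tibble with the two
#'   merged cluster labels, the merge distance and node height), `newick`,
#'   `phylo` (an [ape::read.tree()] object), `labels`.
#' @export
upgma_dendrogram <- function(mat, is_distance = FALSE) {
  mat <- as.matrix(mat)
  if (!isSymmetric(mat, tol = 1e-8, check.attributes = FALSE)) {
    stop("input matrix must be symmetric")
  }
  if (nrow(mat) < 2) stop("need at least 2 patterns")
  d <- if (is_distance) mat else 100 - mat
  labels <- rownames(d) %||% paste0("L", seq_len(nrow(d)))
  dimnames(d) <- list(labels, labels)

  # active clusters: label -> member leaf indices, newick fragment, height
  clust <- stats::setNames(
    lapply(seq_along(labels), function(i) {
      list(members = i, newick = labels[i], height = 0)
    }), labels)
  merges <- list()

  while (length(clust) > 1) {
    keys <- sort(names(clust))
    best <- NULL
    for (x in seq_len(length(keys) - 1)) for (y in (x + 1):length(keys)) {
      a <- clust[[keys[x]]]; b <- clust[[keys[y]]]
      dist_ab <- mean(d[a$members, b$members])
      if (is.null(best) || dist_ab < best$dist - 1e-12) {
        best <- list(x = keys[x], y = keys[y], dist = dist_ab)
      }
    }
    a <- clust[[best$x]]; b <- clust[[best$y]]
    h <- best$dist / 2
    new_label <- paste0("(", best$x, "+", best$y, ")")
    nwk <- paste0("(", a$newick, ":", format(h - a$height, digits = 10),
                  ",", b$newick, ":", format(h - b$height, digits = 10),
                  ")")
    merges[[length(merges) + 1]] <- tibble::tibble(
      cluster_a = best$x, cluster_b = best$y,
      distance = best$dist, height = h,
      leaves_a = list(labels[a$members]),
      leaves_b = list(labels[b$members]))
    clust[[best$x]] <- NULL
    clust[[best$y]] <- NULL
    clust[[new_label]] <- list(members = c(a$members, b$members),
                               newick = nwk, height = h)
  }
  root <- clust[[1]]
  newick <- paste0(root$newick, ";")
  structure(
    list(merges = dplyr::bind_rows(merges), newick = newick,
         phylo = ape::read.tree(text = newick), labels = labels),
    class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("<UPGMA dendrogram: ", length(x$labels), " leaves>\n", sep = "")
  print(x$merges)
  invisible(x)
}

#' @export
plot.upgma_tree <- function(x, ...) {
  ape::plot.phylo(x$phylo, ...)
  invisible(x)
}

#' Write a dendrogram as Newick
#'
#' @param tree An `upgma_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  writeLines(tree$newick, path)
  invisible(path)
}

#' Cut a UPGMA dendrogram at a similarity threshold
#'
#' Samples merged at distance `<= 100 - similarity_cutoff` form one
#' cluster.
#'
#' @param tree An `upgma_tree`.
#' @param similarity_cutoff Percent similarity defining cluster membership.
#' @return A tibble with `sample_id` and `cluster` (integer labels,
#'   numbered by first appearance in sorted id order).
#' @export
cut_dendrogram <- function(tree, similarity_cutoff) {
  max_dist <- 100 - similarity_cutoff
  ids <- sort(tree$labels)
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (k in seq_len(nrow(tree$merges))) {
    if (tree$merges$distance[k] > max_dist) next
    la <- tree$merges$leaves_a[[k]]
    lb <- tree$merges$leaves_b[[k]]
    ra <- find(match(la[1], ids))
    for (l in c(la, lb)) parent[find(match(l, ids))] <- ra
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  tibble::tibble(sample_id = ids,
                 cluster = as.integer(factor(roots, levels = unique(roots))))
}

#' Congruence of two partitions of the same samples
#'
#' Cross-tabulates two cluster assignments and computes the adjusted Rand
#' index, a chance-corrected agreement in \[-1, 1\] (1 for identical
#' partitions, about 0 for independent ones).
#'
#' @param a,b Data frames with `sample_id` and `cluster` columns, or named
#'   vectors of cluster labels.
#' @return A list of class `partition_congruence`: `table` (contingency),
#'   `ari`, `n`.
#' @export
compare_partitions <- function(a, b) {
  a <- as_assignment(a)
  b <- as_assignment(b)
  missing_a <- setdiff(names(b), names(a))
  missing_b <- setdiff(names(a), names(b))
  if (length(missing_a) || length(missing_b)) {
    stop("sample id mismatch; only in first: ",
         paste(missing_b, collapse = ", "),
         "; only in second: ", paste(missing_a, collapse = ", "))
  }
  b <- b[names(a)]
  tab <- table(first = a, second = b)
  structure(list(table = tab, ari = adjusted_rand_index(tab),
                 n = length(a)),
            class = "partition_congruence")
}

as_assignment <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("sample_id", "cluster") %in% names(x)))
    stats::setNames(as.character(x$cluster), x$sample_id)
  } else {
    stopifnot(!is.null(names(x)))
    stats::setNames(as.character(x), names(x))
  }
}

# Hubert & Arabie adjusted Rand index from a contingency table.
adjusted_rand_index <- function(tab) {
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1) # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' @export
print.partition_congruence <- function(x, ...) {
  cat("<partition congruence over ", x$n, " samples: ARI = ",
      formatC(x$ari, digits = 4, format = "f"), ">\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Heatmap of a similarity matrix
#'
#' @param mat A [similarity_matrix()] result.
#' @return A ggplot object.
#' @export
plot_similarity_heatmap <- function(mat) {
  long <- tibble::as_tibble(as.table(mat), .name_repair = "minimal")
  names(long) <- c("a", "b", "similarity")
  ggplot2::ggplot(long, ggplot2::aes(.data$a, .data$b,
                                     fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "similarity (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
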