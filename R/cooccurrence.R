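# Pairwise co-occurrence classification against a fixed-marginals swap null.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Scaled C-score for a species pair
#'
#' `C_ij = (R_i - D)(R_j - D) / (R_i * R_j)` where `R_i`, `R_j` are the two
#' species' occurrence (row) totals and `D` is the number of sites holding
#' both. Ranges from 0 (complete aggregation: identical site sets) to 1
#' (complete segregation: disjoint site sets). Symmetric in `i`, `j`;
#' vectorized.
#'
#' @param r_i,r_j Row totals, `>= 1`.
#' @param d Shared-site counts, `0 <= d <= min(r_i, r_j)`.
#' @return C-scores in `[0, 1]`.
#' @export
#' @examples
#' c_score(5, 5, 5)   # complete aggregation -> 0
#' c_score(4, 6, 0)   # complete segregation -> 1
#' c_score(4, 2, 1)   # 0.375
c_score <- function(r_i, r_j, d) {
  if (any(r_i < 1) || any(r_j < 1))
    stop("row totals must be >= 1")
  if (any(d < 0) || any(d > pmin(r_i, r_j)))
    stop("shared-site count d must satisfy 0 <= d <= min(r_i, r_j)")
  (r_i - d) * (r_j - d) / (r_i * r_j)
}

swap_defaults <- function(m, burn_in, thin) {
  n_pres <- sum(m)
  list(burn_in = if (is.null(burn_in)) 10L * n_pres else as.integer(burn_in),
       thin = if (is.null(thin)) n_pres else as.integer(thin))
}

#' Randomize a matrix by checkerboard swaps, preserving marginals
#'
#' Runs `n_swaps` trial swaps: each draws a random 2x2 submatrix and swaps
#' it iff it is a checkerboard, which leaves every row and column total
#' unchanged and (because the proposal is symmetric) makes the chain's
#' stationary distribution uniform over all matrices with the observed
#' marginals. A matrix with no swappable checkerboard (e.g. a single row)
#' is returned unchanged with a note.
#'
#' @param m An [occurrence_matrix()] (or plain 0/1 matrix).
#' @param n_swaps Number of trial swaps.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A matrix with identical dimnames and marginals.
#' @export
swap_null_matrix <- function(m, n_swaps, seed = NULL) {
  storage.mode(m) <- "integer"
  if (nrow(m) < 2L || ncol(m) < 2L) {
    message("matrix has no swappable checkerboard; returned unchanged")
    return(m)
  }
  out <- with_seed(seed, cpp_swap_chain(m, as.integer(n_swaps)))
  dimnames(out) <- dimnames(m)
  attributes(out)$biozone <- attr(m, "biozone")
  class(out) <- class(m)
  out
}

#' Sampled null C-scores for one species pair
#'
#' Draws `n_null` null replicates from a single thinned swap chain and
#' returns the pair's C-score in each; used to check the sampled null
#' against exhaustive enumeration on small matrices.
#'
#' @inheritParams swap_null_matrix
#' @param pair Length-2 vector of species ids (rownames of `m`).
#' @param n_null Number of retained replicates.
#' @param burn_in,thin Trial swaps before the first sample and between
#'   samples; defaults 10x and 1x the number of presences.
#' @return Numeric vector of `n_null` C-scores.
#' @export
pair_null_cscores <- function(m, pair, n_null, burn_in = NULL, thin = NULL,
                              seed = NULL) {
  storage.mode(m) <- "integer"
  i <- match(pair[1], rownames(m)); j <- match(pair[2], rownames(m))
  if (anyNA(c(i, j))) stop("pair species not found in matrix")
  s <- swap_defaults(m, burn_in, thin)
  with_seed(seed, cpp_pair_null_samples(m, i - 1L, j - 1L,
                                        as.integer(n_null),
                                        s$burn_in, s$thin))
}

#' Classify all species pairs as aggregated, segregated or random
#'
#' For every unordered species pair in one biozone's matrix, computes the
#' observed scaled C-score and two one-sided Monte-Carlo p-values against a
#' null of `n_null` matrices drawn from a single burned-in, thinned swap
#' chain with fixed row and column totals:
#' `p_agg = (1 + #\{null C <= obs\}) / (1 + n_null)` (found together more
#' than chance) and `p_seg = (1 + #\{null C >= obs\}) / (1 + n_null)`.
#' A pair is `aggregated` if `p_agg <= alpha`, `segregated` if
#' `p_seg <= alpha`, else `random`; if a degenerate null puts both at or
#' below `alpha` the smaller p-value wins and exact ties fall to `random`
#' (logged). The observed value is counted in its own null (add-one rule)
#' so p-values are never zero.
#'
#' @param m An [occurrence_matrix()] for one biozone.
#' @param n_null Null replicates (default 1000; `>= 100` for inference).
#' @param burn_in,thin Trial swaps before the first replicate and between
#'   replicates; defaults 10x and 1x the number of presences.
#' @param alpha Per-tail significance level (default 0.05).
#' @param seed Optional integer seed.
#' @param filter_expected Drop pairs whose expected shared-site count
#'   `R_i R_j / n_sites` is below 1 (the filter used by some co-occurrence
#'   tools); off by default, matching the plain null-distribution route.
#' @return `data.frame` with one row per pair: `species_i`, `species_j`
#'   (`i < j` lexicographically), `R_i`, `R_j`, `D`, `c_score`, `p_agg`,
#'   `p_seg`, `classification`, `biozone`.
#' @export
classify_pairs <- function(m, n_null = 1000, burn_in = NULL, thin = NULL,
                           alpha = 0.05, seed = NULL,
                           filter_expected = FALSE) {
  stopifnot(alpha > 0, alpha < 0.5)
  if (n_null < 100) warning("n_null < 100 is too small for inference")
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 species and 2 sites to classify pairs")
  storage.mode(m) <- "integer"
  R <- rowSums(m)
  Dm <- tcrossprod(m)
  s <- swap_defaults(m, burn_in, thin)
  counts <- with_seed(seed,
    cpp_pair_null_counts(m, Dm, as.integer(n_null), s$burn_in, s$thin))
  idx <- which(upper.tri(Dm), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  p_agg <- (1 + counts$le[idx]) / (1 + n_null)
  p_seg <- (1 + counts$ge[idx]) / (1 + n_null)
  cls <- rep("random", length(i))
  cls[p_agg <= alpha & p_agg < p_seg] <- "aggregated"
  cls[p_seg <= alpha & p_seg < p_agg] <- "segregated"
  both <- p_agg <= alpha & p_seg <= alpha & p_agg == p_seg
  if (any(both))
    message(sum(both), " pair(s) with degenerate tied null kept as random")
  res <- data.frame(
    species_i = rownames(m)[i], species_j = rownames(m)[j],
    R_i = unname(R[i]), R_j = unname(R[j]), D = Dm[idx],
    c_score = c_score(R[i], R[j], Dm[idx]),
    p_agg = p_agg, p_seg = p_seg, classification = cls,
    biozone = if (is.null(attr(m, "biozone"))) NA_character_
              else attr(m, "biozone"),
    stringsAsFactors = FALSE)
  if (filter_expected) {
    keep <- res$R_i * res$R_j / ncol(m) >= 1
    if (any(!keep))
      message(sum(!keep), " pair(s) dropped by expected-overlap filter")
    res <- res[keep, , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Census of pair classifications per biozone
#'
#' @param results Named list of [classify_pairs()] tables, one per biozone.
#' @return `data.frame` with per-biozone counts of aggregated, segregated
#'   and random pairs, `total_significant` (aggregated + segregated) and
#'   `n_pairs`.
#' @export
pair_census <- function(results) {
  rows <- lapply(names(results), function(bz) {
    cl <- results[[bz]]$classification
    data.frame(biozone = bz,
               aggregated = sum(cl == "aggregated"),
               segregated = sum(cl == "segregated"),
               random = sum(cl == "random"),
               total_significant = sum(cl != "random"),
               n_pairs = length(cl), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Exhaustively enumerate binary matrices with fixed marginals
#'
#' Brute-force reference for small matrices (`<= ~16` cells): enumerates
#' every 0/1 matrix sharing the input's row and column totals. Used as the
#' independent oracle for the swap null's uniform stationary distribution.
#'
#' @param m Small 0/1 matrix.
#' @return List of matrices (dimnames preserved), including `m` itself.
#' @export
enumerate_fixed_marginals <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr * nc > 20L) stop("enumeration limited to matrices with <= 20 cells")
  rs <- rowSums(m); cs <- colSums(m)
  out <- list()
  for (bits in 0:(2^(nr * nc) - 1L)) {
    cand <- matrix(as.integer(intToBits(bits)[seq_len(nr * nc)]), nr, nc)
    if (all(rowSums(cand) == rs) && all(colSums(cand) == cs)) {
      dimnames(cand) <- dimnames(m)
      out[[length(out) + 1L]] <- cand
    }
  }
  out
}
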