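# Distances over palynofloral compositions, 2-axis NMDS, PERMANOVA.

#' Pool per-biozone matrices into one matrix over all sites
#'
#' Union of taxa as rows, all sites (across biozones) as columns. Site ids
#' must be unique across biozones.
#'
#' @param matrices Named list of per-biozone [occurrence_matrix()] objects.
#' @return Plain 0/1 matrix plus attribute `site_biozone` (named vector).
#' @export
pool_matrices <- function(matrices) {
  taxa <- sort(unique(unlist(lapply(matrices, rownames))))
  sites <- unlist(lapply(matrices, colnames))
  if (anyDuplicated(sites)) stop("site ids must be unique across biozones")
  out <- matrix(0L, length(taxa), length(sites),
                dimnames = list(taxa, sites))
  bz <- character(0)
  for (b in names(matrices)) {
    m <- matrices[[b]]
    out[rownames(m), colnames(m)] <- m
    bz <- c(bz, setNames(rep(b, ncol(m)), colnames(m)))
  }
  out <- out[, order(colnames(out)), drop = FALSE]
  attr(out, "site_biozone") <- bz[colnames(out)]
  out
}

#' Jaccard or cosine distances between site compositions
#'
#' Jaccard: `d(s,t) = 1 - |A intersect B| / |A union B|` on the two sites'
#' taxon sets (via [vegan::vegdist()] with `binary = TRUE`). Cosine (the
#' supplementary replicate): `d(s,t) = 1 - D_st / sqrt(R_s R_t)` on the
#' binary presence vectors, where `D_st` is the shared-taxon count and
#' `R_s` the site's richness.
#'
#' @param m Taxa-by-sites 0/1 matrix (e.g. from [pool_matrices()]).
#' @param metric `"jaccard"` (default) or `"cosine"`.
#' @return Symmetric matrix of class `dist_matrix` with zero diagonal and
#'   attribute `metric`; `site_biozone` is carried through if present.
#' @export
#' @examples
#' m <- matrix(c(1,1,0, 0,1,1), 3, 2,
#'             dimnames = list(c("a","b","c"), c("s1","s2")))
#' community_distances(m)["s1", "s2"]  # sets {a,b} vs {b,c} -> 2/3
community_distances <- function(m, metric = c("jaccard", "cosine")) {
  metric <- match.arg(metric)
  if (any(colSums(m) == 0L)) stop("every site needs at least one taxon")
  x <- t(m)
  if (metric == "jaccard") {
    d <- as.matrix(vegan::vegdist(x, method = "jaccard", binary = TRUE))
  } else {
    shared <- tcrossprod(x)
    r <- rowSums(x)
    d <- 1 - shared / sqrt(outer(r, r))
    diag(d) <- 0
  }
  structure(d, metric = metric,
            site_biozone = attr(m, "site_biozone"),
            class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix (%s): %d sites\n", attr(x, "metric"), nrow(x)))
  invisible(x)
}

orient_scores <- function(scores) {
  scores <- scale(scores, center = TRUE, scale = FALSE)
  rot <- prcomp(scores, center = FALSE)$x
  first <- which(rownames(scores) == sort(rownames(scores))[1L])
  for (a in seq_len(ncol(rot)))
    if (rot[first, a] < 0) rot[, a] <- -rot[, a]
  colnames(rot) <- paste0("NMDS", seq_len(ncol(rot)))
  rot
}

#' Nonmetric multidimensional scaling with deterministic orientation
#'
#' Two-axis NMDS minimizing Kruskal stress-1 with primary tie handling
#' (engine: [vegan::monoMDS()], global model), best of `n_restarts` random
#' initial configurations drawn from the seed. Because stress depends only
#' on the rank order of the input dissimilarities, results are invariant to
#' monotone transforms of the distances. The winning configuration is
#' centered, rotated to its principal axes, and each axis sign-fixed so the
#' lexicographically smallest site id scores non-negatively -- downstream
#' per-axis differences depend on orientation, so the convention must be
#' deterministic (the axes of any published ordination are reproducible
#' only up to rotation/reflection).
#'
#' @param d A `dist_matrix` from [community_distances()] (or any symmetric
#'   distance matrix with dimnames).
#' @param k Number of axes (default 2).
#' @param n_restarts Random restarts (default 50).
#' @param maxit Maximum iterations per start (default 500).
#' @param seed Integer seed for the restarts.
#' @return List of class `nmds_result`: `scores` (sites x `NMDS1..k`),
#'   `stress` (Kruskal stress-1 in `[0, 1]`), `stress_ok`
#'   (`stress < 0.2`, the conventional interpretability limit),
#'   `n_restarts`, `seed`, `site_biozone`.
#' @export
nmds <- function(d, k = 2, n_restarts = 50, maxit = 500, seed = NULL) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 4L) stop("need at least 4 sites for NMDS")
  if (all(dm == 0)) stop("degenerate: all sites identical")
  dd <- as.dist(dm)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      y0 <- matrix(rnorm(n * k), n, k)
      fit <- vegan::monoMDS(dd, y = y0, k = k, model = "global",
                            maxit = maxit, smin = 1e-7, sfgrmin = 1e-7)
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
  })
  scores <- best$points
  rownames(scores) <- rownames(dm)
  structure(list(scores = orient_scores(scores), stress = best$stress,
                 stress_ok = best$stress < 0.2, n_restarts = n_restarts,
                 seed = seed, site_biozone = attr(d, "site_biozone")),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: %d sites, %d axes, stress = %.4f (%s)\n",
              nrow(x$scores), ncol(x$scores), x$stress,
              if (x$stress_ok) "below the 0.2 limit" else "above 0.2"))
  invisible(x)
}

ss_within <- function(d2, groups) {
  sw <- 0
  for (g in unique(groups)) {
    idx <- groups == g
    sw <- sw + sum(d2[idx, idx]) / (2 * sum(idx))
  }
  sw
}

permanova_f <- function(d2, groups) {
  n <- nrow(d2); k <- length(unique(groups))
  sst <- sum(d2) / (2 * n)
  ssw <- ss_within(d2, groups)
  ((sst - ssw) / (k - 1)) / (ssw / (n - k))
}

#' PERMANOVA with pairwise Bonferroni-corrected comparisons
#'
#' Distance-based permutational MANOVA. The pseudo-F is
#' `((SS_T - SS_W)/(k-1)) / (SS_W/(n-k))` with sums of squares computed
#' from squared distances; significance by permuting whole-site group
#' labels, `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`. Every group
#' pair is additionally tested on the corresponding submatrix, with
#' Bonferroni correction (`p_bonferroni = min(1, p_raw * n_tests)`).
#'
#' @param d Distance matrix (`dist_matrix` or plain symmetric matrix).
#' @param groups Group label per site, in site order; if omitted, taken
#'   from the `site_biozone` attribute.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @return List of class `permanova_result`: `F`, `p`, `n_perm`, `groups`,
#'   `pairwise` (`data.frame` with `group_a`, `group_b`, `F`, `p_raw`,
#'   `p_bonferroni`).
#' @export
permanova <- function(d, groups = NULL, n_perm = 10000, seed = NULL) {
  dm <- as.matrix(d)
  if (is.null(groups)) groups <- attr(d, "site_biozone")
  if (is.null(groups)) stop("groups must be supplied")
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(dm))
  if (length(unique(groups)) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 sites")
  d2 <- dm^2
  one_test <- function(d2, groups) {
    f_obs <- permanova_f(d2, groups)
    hits <- 0L
    for (p in seq_len(n_perm)) {
      if (permanova_f(d2, sample(groups)) >= f_obs) hits <- hits + 1L
    }
    list(F = f_obs, p = (1 + hits) / (1 + n_perm))
  }
  with_seed(seed, {
    omni <- one_test(d2, groups)
    gl <- sort(unique(groups))
    pairs <- combn(gl, 2)
    n_tests <- ncol(pairs)
    pw <- lapply(seq_len(n_tests), function(i) {
      idx <- groups %in% pairs[, i]
      t <- one_test(d2[idx, idx, drop = FALSE], groups[idx])
      data.frame(group_a = pairs[1, i], group_b = pairs[2, i], F = t$F,
                 p_raw = t$p, p_bonferroni = min(1, t$p * n_tests),
                 stringsAsFactors = FALSE)
    })
    structure(list(F = omni$F, p = omni$p, n_perm = n_perm, groups = groups,
                   pairwise = do.call(rbind, pw)),
              class = "permanova_result")
  })
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, p = %.4g (%d permutations)\n",
              x$F, x$p, x$n_perm))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
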