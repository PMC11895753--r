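# Trait and preference differences within pair types, the cross-biozone
# richness-preserving null, and Cohen's D effect sizes.

#' Absolute ecological differences within classified species pairs
#'
#' Joins each classified pair to the trait table and preference table and
#' records `|delta ln mass|` and the per-axis `|delta preference|`. Pairs
#' with a missing trait or preference on either side are dropped with a
#' logged count.
#'
#' @param pairs [classify_pairs()] output (one biozone, or several bound
#'   together).
#' @param traits Trait table (`species_id`, `ln_mass`).
#' @param prefs [species_preferences()] output.
#' @return `data.frame`: pair ids, `biozone`, `classification`, `d_mass`,
#'   `d_pref1`, `d_pref2`.
#' @export
pair_differences <- function(pairs, traits, prefs) {
  mi <- match(pairs$species_i, traits$species_id)
  mj <- match(pairs$species_j, traits$species_id)
  pi <- match(pairs$species_i, prefs$species_id)
  pj <- match(pairs$species_j, prefs$species_id)
  ok <- !(is.na(mi) | is.na(mj) | is.na(pi) | is.na(pj))
  if (any(!ok))
    message(sum(!ok), " pair(s) dropped for missing trait or preference")
  out <- data.frame(
    species_i = pairs$species_i[ok], species_j = pairs$species_j[ok],
    biozone = pairs$biozone[ok], classification = pairs$classification[ok],
    d_mass = abs(traits$ln_mass[mi[ok]] - traits$ln_mass[mj[ok]]),
    d_pref1 = abs(prefs$pref1[pi[ok]] - prefs$pref1[pj[ok]]),
    d_pref2 = abs(prefs$pref2[pi[ok]] - prefs$pref2[pj[ok]]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Mean and median differences per biozone x pair type x variable
#'
#' Long-format summary over the three variables (`mass`, `pref1`,
#' `pref2`). Cells with no pairs (e.g. no segregated pairs in a bin,
#' the Wasatchian 0 situation) are simply absent from the output; the
#' effect table marks them explicitly.
#'
#' @param diffs [pair_differences()] output.
#' @return `data.frame`: `biozone`, `classification`, `variable`,
#'   `mean_diff`, `median_diff`, `n_pairs`, plus `sum_diff`/`sumsq_diff`
#'   used for pooled null dispersion.
#' @export
summarize_types <- function(diffs) {
  vars <- c(mass = "d_mass", pref1 = "d_pref1", pref2 = "d_pref2")
  rows <- list()
  for (bz in unique(diffs$biozone)) {
    for (cl in unique(diffs$classification[diffs$biozone == bz])) {
      sub <- diffs[diffs$biozone == bz & diffs$classification == cl, ]
      for (v in names(vars)) {
        x <- sub[[vars[[v]]]]
        rows[[length(rows) + 1L]] <- data.frame(
          biozone = bz, classification = cl, variable = v,
          mean_diff = mean(x), median_diff = median(x),
          n_pairs = length(x), sum_diff = sum(x), sumsq_diff = sum(x^2),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$biozone, out$classification, out$variable), ]
}

randomize_richness <- function(mammal_matrices, pool) {
  out <- list()
  for (bz in names(mammal_matrices)) {
    m <- mammal_matrices[[bz]]
    k <- colSums(m)
    if (length(pool) < max(k))
      stop("species pool smaller than maximum site richness")
    r <- matrix(0L, length(pool), ncol(m),
                dimnames = list(pool, colnames(m)))
    for (s in seq_along(k))
      r[sample.int(length(pool), k[s]), s] <- 1L
    out[[bz]] <- occurrence_matrix(r, bz, quiet = TRUE)
  }
  out
}

#' Richness-preserving null for pair-type ecological differences
#'
#' The null randomizes the assignment of species among sites across all
#' three biozones while preserving each site's observed richness (and
#' hence per-bin site counts), controlling for taphonomic heterogeneity in
#' species-per-site and sites-per-bin. Per replicate, every site is
#' refilled with `k` distinct species drawn uniformly (no abundance
#' weighting) from the pooled cross-bin species list, `k` being the site's
#' observed richness; the full downstream pipeline is then re-run on the
#' randomized matrices -- pair classification per biozone (with a reduced
#' inner null), inherited habitat scores, species preferences, pair
#' differences and type summaries. Species' body masses travel with their
#' identities and are never randomized independently of occurrences.
#' Seeding is nested (master seed + replicate counter), so increasing
#' `n_reps` leaves earlier replicates unchanged.
#'
#' @param mammal_matrices Named list of observed per-biozone matrices.
#' @param site_habitats [match_sites()] output (fixed across replicates).
#' @param traits Trait table.
#' @param n_reps Null replicates (default 100).
#' @param n_null_inner Swap-null replicates inside each classification
#'   (default 200).
#' @param alpha Classification significance level.
#' @param seed Master seed.
#' @param reclassify Re-run pair classification per replicate (default,
#'   coherent with null distributions of per-type differences); if
#'   `FALSE`, the observed classifications are reused and only the
#'   preferences are recomputed (cheaper).
#' @param observed_pairs Required when `reclassify = FALSE`: bound
#'   [classify_pairs()] tables.
#' @return List of class `pair_null`: `replicates` (long `data.frame`
#'   with a `rep` column followed by [summarize_types()] columns), plus
#'   the settings.
#' @export
richness_preserving_null <- function(mammal_matrices, site_habitats, traits,
                                     n_reps = 100, n_null_inner = 200,
                                     alpha = 0.05, seed = 1,
                                     reclassify = TRUE,
                                     observed_pairs = NULL) {
  pool <- sort(unique(unlist(lapply(mammal_matrices, rownames))))
  if (!reclassify && is.null(observed_pairs))
    stop("observed_pairs needed when reclassify = FALSE")
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed((seed + r) %% .Machine$integer.max)
    rand <- randomize_richness(mammal_matrices, pool)
    prefs <- species_preferences(rand, site_habitats)
    if (reclassify) {
      pairs <- do.call(rbind, lapply(rand, function(m)
        classify_pairs(m, n_null = n_null_inner, alpha = alpha)))
    } else {
      pairs <- observed_pairs
    }
    diffs <- suppressMessages(pair_differences(pairs, traits, prefs))
    s <- summarize_types(diffs)
    s <- cbind(rep = r, s)
    reps[[r]] <- s
  }
  structure(list(replicates = do.call(rbind, reps), n_reps = n_reps,
                 n_null_inner = n_null_inner, alpha = alpha, seed = seed,
                 reclassify = reclassify),
            class = "pair_null")
}

#' @export
print.pair_null <- function(x, ...) {
  cat(sprintf("richness-preserving null: %d replicates (inner null %d, %s)\n",
              x$n_reps, x$n_null_inner,
              if (x$reclassify) "re-classified" else "observed classes"))
  invisible(x)
}

d_magnitude <- function(d, eps = 1e-9) {
  ifelse(is.na(d), NA_character_,
         ifelse(abs(d) <= 0.2 + eps, "small",
                ifelse(abs(d) >= 0.8 - eps, "large", "medium")))
}

#' Cohen's D of an observed mean against a randomization null
#'
#' `d = (observed_mean - mean(null_means)) / sd`, where the denominator is
#' by default the sample standard deviation (n-1) of the per-replicate null
#' means -- the standardized-effect-size form whose null distribution the
#' violin plots display -- or, with `null_sd` supplied, an
#' observation-level (pooled) null standard deviation. Magnitude follows
#' the conventional cutpoints: `|d| <= 0.2` small (nonsignificant),
#' `|d| >= 0.8` large (significant), else medium.
#'
#' @param observed_mean Observed cell mean.
#' @param null_means Vector of per-replicate null means (`>= 30` for a
#'   stable denominator).
#' @param null_sd Optional externally computed null standard deviation to
#'   use as the denominator.
#' @return List of class `effect_size`: `d`, `magnitude`,
#'   `observed_mean`, `null_mean`, `null_sd`, `n_reps`.
#' @export
#' @examples
#' cohens_d(0.5, rnorm(100, 0.5, 0.1))$magnitude  # ~0 -> "small"
cohens_d <- function(observed_mean, null_means, null_sd = NULL) {
  if (length(null_means) < 30)
    warning("fewer than 30 null replicates; d is unstable")
  s <- if (is.null(null_sd)) sd(null_means) else null_sd
  if (!is.finite(s) || s <= 0) stop("degenerate null: zero sd")
  d <- (observed_mean - mean(null_means)) / s
  structure(list(d = d, magnitude = d_magnitude(d),
                 observed_mean = observed_mean,
                 null_mean = mean(null_means), null_sd = s,
                 n_reps = length(null_means)),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's D = %.3f (%s); observed %.4g vs null %.4g (sd %.4g)\n",
              x$d, x$magnitude, x$observed_mean, x$null_mean, x$null_sd))
  invisible(x)
}

pooled_null_sd <- function(n, s, ss) {
  N <- sum(n)
  if (N < 2) return(NA_real_)
  v <- (sum(ss) - sum(s)^2 / N) / (N - 1)
  sqrt(max(v, 0))
}

#' Effect-size table over biozone x pair type x variable
#'
#' Assembles the full grid of Cohen's D values comparing observed mean
#' (and median) pair differences to the richness-preserving null. Cells
#' observed with zero pairs -- such as segregated pairs in a bin where
#' none were discernible -- are retained with `absent = TRUE` and `NA`
#' effect sizes, so the table's shape is stable across datasets.
#'
#' @param obs_summary [summarize_types()] of the observed differences.
#' @param null A [richness_preserving_null()] result.
#' @param sd_type Denominator for d: `"replicate_means"` (default; sd of
#'   per-replicate null means) or `"pooled"` (observation-level null sd
#'   across all replicates' pair differences).
#' @return `data.frame`: `biozone`, `classification`, `variable`,
#'   `observed_mean`, `observed_median`, `n_pairs`, `null_mean`,
#'   `null_sd`, `d`, `d_median`, `magnitude`, `n_reps_present`, `absent`.
#' @export
effect_table <- function(obs_summary, null,
                         sd_type = c("replicate_means", "pooled")) {
  sd_type <- match.arg(sd_type)
  nr <- null$replicates
  bzs <- intersect(biozones(),
                   unique(c(obs_summary$biozone, nr$biozone)))
  grid <- expand.grid(biozone = bzs,
                      classification = c("aggregated", "segregated",
                                         "random"),
                      variable = c("mass", "pref1", "pref2"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    o <- obs_summary[obs_summary$biozone == g$biozone &
                     obs_summary$classification == g$classification &
                     obs_summary$variable == g$variable, ]
    nl <- nr[nr$biozone == g$biozone &
             nr$classification == g$classification &
             nr$variable == g$variable, ]
    absent <- nrow(o) == 0L || nrow(nl) < 2L
    if (absent) {
      return(cbind(g, data.frame(
        observed_mean = NA_real_, observed_median = NA_real_,
        n_pairs = if (nrow(o)) o$n_pairs else 0L,
        null_mean = if (nrow(nl)) mean(nl$mean_diff) else NA_real_,
        null_sd = NA_real_, d = NA_real_, d_median = NA_real_,
        magnitude = NA_character_, n_reps_present = nrow(nl),
        absent = TRUE)))
    }
    s <- if (sd_type == "pooled")
      pooled_null_sd(nl$n_pairs, nl$sum_diff, nl$sumsq_diff)
    else sd(nl$mean_diff)
    d <- if (is.finite(s) && s > 0)
      (o$mean_diff - mean(nl$mean_diff)) / s else NA_real_
    s_med <- if (sd_type == "pooled") s else sd(nl$median_diff)
    d_med <- if (is.finite(s_med) && s_med > 0)
      (o$median_diff - mean(nl$median_diff)) / s_med else NA_real_
    cbind(g, data.frame(
      observed_mean = o$mean_diff, observed_median = o$median_diff,
      n_pairs = o$n_pairs, null_mean = mean(nl$mean_diff), null_sd = s,
      d = d, d_median = d_med, magnitude = d_magnitude(d),
      n_reps_present = nrow(nl), absent = FALSE))
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$biozone, biozones()), out$classification,
                   out$variable), ]
  rownames(out) <- NULL
  attr(out, "sd_type") <- sd_type
  out
}
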