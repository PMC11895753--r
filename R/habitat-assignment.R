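# Grinnellian preferences: mammal sites inherit the NMDS scores of the
# nearest contemporaneous palynofloral site; species average over sites.

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0 km (adequate at the
#' ~200 km basin scale of these data). Vectorized.
#'
#' @param lat1,lon1,lat2,lon2 Decimal degrees.
#' @return Distance(s) in km.
#' @export
#' @examples
#' haversine_km(0, 0, 0, 180)  # half circumference, ~20015 km
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("coordinates out of range")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

#' Match each mammal site to its nearest contemporaneous floral site
#'
#' For every mammal site, finds the palynofloral site of the same biozone
#' at minimum great-circle distance (ties broken by lexicographically
#' smallest floral site id) and attaches that site's NMDS scores. Floral
#' sites in other biozones are never considered, however close.
#'
#' @param sites Site metadata ([read_sites()] layout), both kinds.
#' @param ordination An [nmds()] result over the floral sites.
#' @return `data.frame` of class rows: `mammal_site_id`,
#'   `matched_floral_site_id`, `distance_km`, `biozone`, `NMDS1`, `NMDS2`.
#' @export
match_sites <- function(sites, ordination) {
  mam <- sites[sites$kind == "mammal", , drop = FALSE]
  flo <- sites[sites$kind == "palynofloral", , drop = FALSE]
  flo <- flo[flo$site_id %in% rownames(ordination$scores), , drop = FALSE]
  flo <- flo[order(flo$site_id), , drop = FALSE]  # tie rule
  rows <- lapply(seq_len(nrow(mam)), function(i) {
    cand <- flo[flo$biozone == mam$biozone[i], , drop = FALSE]
    if (nrow(cand) == 0L)
      stop("no contemporaneous palynofloral site for biozone ",
           mam$biozone[i])
    dkm <- haversine_km(mam$lat[i], mam$lon[i], cand$lat, cand$lon)
    best <- which.min(dkm)  # first minimum = smallest site_id on ties
    sc <- ordination$scores[cand$site_id[best], ]
    data.frame(mammal_site_id = mam$site_id[i],
               matched_floral_site_id = cand$site_id[best],
               distance_km = dkm[best], biozone = mam$biozone[i],
               NMDS1 = sc[["NMDS1"]], NMDS2 = sc[["NMDS2"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Time-transgressive species environmental preferences
#'
#' Each species' preference is the unweighted mean of the inherited
#' (NMDS1, NMDS2) scores over all mammal sites it occupies, pooled across
#' all three biozones; each occupied site counts once regardless of
#' specimen counts.
#'
#' @param mammal_matrices Named list of per-biozone matrices.
#' @param site_habitats Output of [match_sites()].
#' @return `data.frame`: `species_id`, `pref1`, `pref2`, `n_sites`.
#' @export
species_preferences <- function(mammal_matrices, site_habitats) {
  sp_sites <- list()
  for (bz in names(mammal_matrices)) {
    m <- mammal_matrices[[bz]]
    idx <- which(m == 1L, arr.ind = TRUE)
    df <- data.frame(species_id = rownames(m)[idx[, 1L]],
                     site_id = colnames(m)[idx[, 2L]],
                     stringsAsFactors = FALSE)
    sp_sites[[bz]] <- df
  }
  occ <- unique(do.call(rbind, sp_sites))
  hit <- match(occ$site_id, site_habitats$mammal_site_id)
  if (anyNA(hit))
    stop("occupied mammal site(s) missing from site_habitats: ",
         paste(unique(occ$site_id[is.na(hit)]), collapse = ", "))
  occ$NMDS1 <- site_habitats$NMDS1[hit]
  occ$NMDS2 <- site_habitats$NMDS2[hit]
  agg <- aggregate(cbind(NMDS1, NMDS2) ~ species_id, data = occ, FUN = mean)
  n <- as.vector(table(occ$species_id)[agg$species_id])
  out <- data.frame(species_id = agg$species_id, pref1 = agg$NMDS1,
                    pref2 = agg$NMDS2, n_sites = n,
                    stringsAsFactors = FALSE)
  out[order(out$species_id), ]
}

#' Per-biozone summaries of species environmental preferences
#'
#' Summarizes preferences over the species present in each bin
#' (`all_taxa`) or only those first occurring there
#' (`first_occurrences`). Because preferences are time-transgressive a
#' species contributes the same value to every bin it occurs in. The
#' dispersion statistic is configurable: sample variance (n-1) or range
#' (max - min); both are reported, `dispersion1/2` follows
#' `dispersion_stat`. A bin whose Wasatchian-style situation leaves all
#' species sharing one inherited score (single floral site) simply yields
#' zero dispersion.
#'
#' @param prefs [species_preferences()] output.
#' @param mammal_matrices Named list of per-biozone matrices.
#' @param subset `"all_taxa"` or `"first_occurrences"`.
#' @param dispersion_stat `"variance"` (default) or `"range"`.
#' @return `data.frame` per bin: means, medians, dispersions per axis and
#'   `n_species`; bins with an empty subset are omitted.
#' @export
bin_preference_summaries <- function(prefs, mammal_matrices,
                                     subset = c("all_taxa",
                                                "first_occurrences"),
                                     dispersion_stat = c("variance",
                                                         "range")) {
  subset <- match.arg(subset)
  dispersion_stat <- match.arg(dispersion_stat)
  sb <- species_by_bin(mammal_matrices)
  if (subset == "first_occurrences")
    sb <- sb[sb$first_occurrence, , drop = FALSE]
  disp <- function(x) {
    if (dispersion_stat == "variance") {
      if (length(x) > 1L) var(x) else 0
    } else diff(range(x))
  }
  rows <- lapply(intersect(biozones(), unique(sb$biozone)), function(bz) {
    p <- prefs[prefs$species_id %in% sb$species_id[sb$biozone == bz], ,
               drop = FALSE]
    if (nrow(p) == 0L) return(NULL)
    data.frame(biozone = bz, subset = subset,
               mean1 = mean(p$pref1), mean2 = mean(p$pref2),
               median1 = median(p$pref1), median2 = median(p$pref2),
               dispersion1 = disp(p$pref1), dispersion2 = disp(p$pref2),
               dispersion_stat = dispersion_stat,
               n_species = nrow(p), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare a species-level variable between biozones
#'
#' Omnibus Kruskal-Wallis test plus pairwise two-sided Mann-Whitney U tests
#' with Bonferroni correction, over species values grouped by biozone (a
#' species contributes to every bin it occurs in). A classical one-way
#' ANOVA omnibus is available behind `parametric = TRUE`; the pairwise
#' tests stay nonparametric either way, matching the reported pairwise
#' Mann-Whitney comparisons.
#'
#' @param values `data.frame` with columns `biozone` and `value` (one row
#'   per species x bin), e.g. preferences joined to [species_by_bin()].
#' @param parametric Use one-way ANOVA for the omnibus test.
#' @return List of class `bin_test_result`: `omnibus` (`statistic`, `p`,
#'   `method`), `pairwise` (`data.frame` with `group_a`, `group_b`, `W`,
#'   `p_raw`, `p_bonferroni`).
#' @export
between_bin_tests <- function(values, parametric = FALSE) {
  values$biozone <- as.character(values$biozone)
  tab <- table(values$biozone)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need >= 2 biozones with >= 2 species each")
  if (parametric) {
    fit <- aov(value ~ factor(biozone), data = values)
    s <- summary(fit)[[1L]]
    omni <- list(statistic = s[["F value"]][1L], p = s[["Pr(>F)"]][1L],
                 method = "one-way ANOVA")
  } else {
    kw <- kruskal.test(value ~ factor(biozone), data = values)
    omni <- list(statistic = unname(kw$statistic), p = kw$p.value,
                 method = "Kruskal-Wallis")
  }
  gl <- sort(names(tab))
  pairs <- combn(gl, 2)
  n_tests <- ncol(pairs)
  pw <- lapply(seq_len(n_tests), function(i) {
    x <- values$value[values$biozone == pairs[1, i]]
    y <- values$value[values$biozone == pairs[2, i]]
    w <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
    data.frame(group_a = pairs[1, i], group_b = pairs[2, i],
               W = unname(w$statistic), p_raw = w$p.value,
               p_bonferroni = min(1, w$p.value * n_tests),
               stringsAsFactors = FALSE)
  })
  structure(list(omnibus = omni, pairwise = do.call(rbind, pw)),
            class = "bin_test_result")
}

#' @export
print.bin_test_result <- function(x, ...) {
  cat(sprintf("%s omnibus: statistic = %.4f, p = %.4g\n",
              x$omnibus$method, x$omnibus$statistic, x$omnibus$p))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
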