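# Synthetic Bighorn-Basin-shaped datasets with planted ground truth.
#
# A single latent 1-D habitat gradient drives both palynofloral
# composition and mammal occupancy: floral taxa and mammal species carry
# habitat optima on the gradient, sites carry habitat values around
# bin-level means, and occupancy probability decays with the
# site-to-optimum mismatch. This is the minimal structure under which
# ordination scores of nearby floral sites are an informative proxy for a
# mammal's environmental preference.

#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the shape of the real study system: 3 ordered biozones;
#' 8/13/9 palynofloral sites per bin (30 total); 126 mammal sites; 173
#' mammal species with log-normal masses; site coordinates in a ~200 km
#' basin-scale box.
#'
#' @param floral_sites_per_bin Named counts of floral sites per biozone.
#' @param n_floral_taxa_pool Size of the global floral taxon reservoir.
#' @param taxa_per_bin_pool Taxa available to each bin's sites.
#' @param floral_turnover Fraction of a bin's taxon pool replaced relative
#'   to the previous bin, in `[0, 1]`; drives the between-bin
#'   compositional clustering.
#' @param floral_base_p Per-taxon inclusion probability at zero habitat
#'   mismatch.
#' @param floral_niche_width Gaussian niche width of floral taxa on the
#'   latent gradient.
#' @param mammal_sites_per_bin Named counts of mammal sites per biozone
#'   (default sums to 126).
#' @param n_mammal_species Total mammal species (default 173).
#' @param mass_log_mean,mass_log_sd ln-gram body-mass distribution.
#' @param base_occupancy Occupancy probability at zero habitat mismatch.
#' @param habitat_filter_strength `>= 0`; 0 gives neutral (habitat-blind)
#'   occupancy, larger values make occupancy decay faster with
#'   `(site habitat - species optimum)^2`. Default 2 plants a moderate
#'   environmental filter.
#' @param species_breadth Habitat breadth of mammal species.
#' @param n_planted_aggregated,n_planted_segregated Numbers of planted
#'   species pairs with forced co-presence / complementary presence.
#' @param coord_box Named lat/lon bounds (`lat_min`, `lat_max`,
#'   `lon_min`, `lon_max`).
#' @param site_habitat_sd Site-level habitat noise around the bin mean.
#' @param bin_habitat_means Latent habitat mean per biozone; the PETM bin
#'   sits apart from the bracketing bins, which the ordination should
#'   recover.
#' @param first_bin_probs Probability a species first occurs in each bin
#'   (faunal turnover concentrates first occurrences at the PETM).
#' @param seed Master seed; flora, mammal occupancy and pair planting use
#'   nested sub-seeds so changing only the planted counts leaves
#'   non-planted species' occupancy unchanged.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(floral_sites_per_bin = c(Cf3 = 8, Wa0 = 13,
                                                  Wa1_2 = 9),
                         n_floral_taxa_pool = 120,
                         taxa_per_bin_pool = 60,
                         floral_turnover = 0.6,
                         floral_base_p = 0.5,
                         floral_niche_width = 1.0,
                         mammal_sites_per_bin = c(Cf3 = 34, Wa0 = 54,
                                                  Wa1_2 = 38),
                         n_mammal_species = 173,
                         mass_log_mean = 6.0, mass_log_sd = 2.0,
                         base_occupancy = 0.25,
                         habitat_filter_strength = 2.0,
                         species_breadth = 0.7,
                         n_planted_aggregated = 0,
                         n_planted_segregated = 0,
                         coord_box = c(lat_min = 44.0, lat_max = 45.8,
                                       lon_min = -109.2, lon_max = -107.6),
                         site_habitat_sd = 0.35,
                         bin_habitat_means = c(Cf3 = -1, Wa0 = 1,
                                               Wa1_2 = 0),
                         first_bin_probs = c(0.4, 0.4, 0.2),
                         seed = 1) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$floral_sites_per_bin >= 1),
            all(cfg$mammal_sites_per_bin >= 1),
            cfg$n_mammal_species >= 1,
            cfg$floral_turnover >= 0, cfg$floral_turnover <= 1,
            cfg$habitat_filter_strength >= 0,
            cfg$taxa_per_bin_pool <= cfg$n_floral_taxa_pool)
  structure(cfg, class = "synth_config")
}

rand_coords <- function(n, box) {
  data.frame(lat = runif(n, box[["lat_min"]], box[["lat_max"]]),
             lon = runif(n, box[["lon_min"]], box[["lon_max"]]))
}

#' Generate palynofloral matrices, sites and latent habitats
#'
#' Each bin's sites draw taxa from a bin-specific pool; consecutive pools
#' share a `1 - floral_turnover` fraction of taxa. Every taxon has a
#' habitat optimum on the latent gradient and each site includes it with
#' probability `floral_base_p * exp(-(x_site - optimum)^2 / (2 width^2))`;
#' sites are topped up to a minimum richness of 3 from the
#' best-matching taxa so no site is empty.
#'
#' @param cfg A [synth_config()].
#' @return List: `matrices` (per-biozone [occurrence_matrix()]), `sites`
#'   (metadata rows, `kind = "palynofloral"`), `site_habitat` (named
#'   vector), `taxon_optima` (named vector).
#' @export
generate_flora <- function(cfg) {
  set.seed(cfg$seed)
  reservoir <- sprintf("t%03d", seq_len(cfg$n_floral_taxa_pool))
  optima <- setNames(runif(length(reservoir), -2, 2), reservoir)
  m_pool <- cfg$taxa_per_bin_pool
  pools <- list()
  pools[[1]] <- sample(reservoir, m_pool)
  for (b in 2:3) {
    keep <- sample(pools[[b - 1]], round((1 - cfg$floral_turnover) * m_pool))
    fresh_from <- setdiff(reservoir, pools[[b - 1]])
    need <- m_pool - length(keep)
    if (need > length(fresh_from))
      stop("floral taxon reservoir too small for requested turnover")
    pools[[b]] <- c(keep, sample(fresh_from, need))
  }
  names(pools) <- biozones()
  matrices <- list(); site_rows <- list(); hab <- numeric(0)
  for (b in seq_along(biozones())) {
    bz <- biozones()[b]
    n_sites <- cfg$floral_sites_per_bin[[bz]]
    ids <- sprintf("F%s_%02d", bz, seq_len(n_sites))
    xy <- rand_coords(n_sites, cfg$coord_box)
    x <- cfg$bin_habitat_means[[bz]] + rnorm(n_sites, 0, cfg$site_habitat_sd)
    hab <- c(hab, setNames(x, ids))
    pool <- pools[[bz]]
    m <- matrix(0L, length(pool), n_sites, dimnames = list(pool, ids))
    for (s in seq_len(n_sites)) {
      p <- cfg$floral_base_p *
        exp(-(x[s] - optima[pool])^2 / (2 * cfg$floral_niche_width^2))
      m[, s] <- rbinom(length(pool), 1L, p)
      if (sum(m[, s]) < 3L) {
        top <- order(p, decreasing = TRUE)[1:3]
        m[top, s] <- 1L
      }
    }
    matrices[[bz]] <- occurrence_matrix(m, bz, quiet = TRUE)
    site_rows[[bz]] <- data.frame(site_id = ids, lat = xy$lat, lon = xy$lon,
                                  biozone = bz, kind = "palynofloral",
                                  stringsAsFactors = FALSE)
  }
  list(matrices = matrices, sites = do.call(rbind, site_rows),
       site_habitat = hab, taxon_optima = optima)
}

draw_species_occupancy <- function(cfg, species, sites_by_bin,
                                   site_habitat) {
  # species: data.frame(species_id, center, breadth, first, last)
  occ <- list()
  for (b in seq_along(biozones())) {
    bz <- biozones()[b]
    ids <- sites_by_bin[[bz]]
    x <- site_habitat[ids]
    present_sp <- species[species$first <= b & species$last >= b, ]
    m <- matrix(0L, nrow(species), length(ids),
                dimnames = list(species$species_id, ids))
    for (k in seq_len(nrow(present_sp))) {
      sp <- present_sp[k, ]
      p <- pmin(1, cfg$base_occupancy *
                  exp(-cfg$habitat_filter_strength *
                      (x - sp$center)^2 / sp$breadth^2))
      m[sp$species_id, ] <- rbinom(length(ids), 1L, p)
    }
    occ[[bz]] <- m
  }
  occ
}

#' Generate mammal matrices, sites, traits and ground truth
#'
#' Mammal sites are placed next to a parent floral site of the same bin
#' (small coordinate jitter) and inherit its latent habitat value with
#' noise, so nearest-floral-site matching is meaningful. Each species gets
#' a habitat optimum, a breadth and an ln-mass; per-bin occupancy is
#' Bernoulli with probability
#' `base_occupancy * exp(-filter_strength (x_site - optimum)^2 / breadth^2)`
#' over its duration (first to last bin). Planted aggregated pairs share
#' an optimum and have their presences unioned (identical site sets);
#' planted segregated pairs get opposite optima and shared sites assigned
#' to the nearer optimum, leaving disjoint site sets. Forcing is overlaid
#' after probabilistic occupancy and planted species are re-drawn under a
#' separate sub-seed, so non-planted occupancy is invariant to the planted
#' counts.
#'
#' @param cfg A [synth_config()].
#' @param flora Output of [generate_flora()].
#' @return List: `matrices`, `sites`, `traits`, `ground_truth` (list with
#'   `species`, `planted_pairs`, `site_habitat`).
#' @export
generate_mammals <- function(cfg, flora) {
  set.seed(cfg$seed + 1)
  n_sp <- cfg$n_mammal_species
  n_plant <- 2L * (cfg$n_planted_aggregated + cfg$n_planted_segregated)
  if (n_plant > n_sp) stop("more planted pair members than species")
  species <- data.frame(
    species_id = sprintf("m%03d", seq_len(n_sp)),
    center = runif(n_sp, -2, 2), breadth = cfg$species_breadth,
    ln_mass = rnorm(n_sp, cfg$mass_log_mean, cfg$mass_log_sd),
    first = sample.int(3, n_sp, replace = TRUE,
                       prob = cfg$first_bin_probs),
    stringsAsFactors = FALSE)
  species$last <- vapply(species$first, function(f) {
    span <- seq(f, 3)
    span[sample.int(length(span), 1)]
  }, numeric(1))

  # sites jittered around parent floral sites
  site_rows <- list(); hab <- numeric(0); sites_by_bin <- list()
  parents <- character(0)
  for (bz in biozones()) {
    n_sites <- cfg$mammal_sites_per_bin[[bz]]
    ids <- sprintf("M%s_%03d", bz, seq_len(n_sites))
    fl <- flora$sites[flora$sites$biozone == bz, ]
    par <- sample(fl$site_id, n_sites, replace = TRUE)
    pi <- match(par, fl$site_id)
    site_rows[[bz]] <- data.frame(
      site_id = ids, lat = fl$lat[pi] + rnorm(n_sites, 0, 0.02),
      lon = fl$lon[pi] + rnorm(n_sites, 0, 0.02), biozone = bz,
      kind = "mammal", stringsAsFactors = FALSE)
    hab <- c(hab, setNames(flora$site_habitat[par] +
                             rnorm(n_sites, 0, 0.1), ids))
    parents <- c(parents, setNames(par, ids))
    sites_by_bin[[bz]] <- ids
  }
  occ <- draw_species_occupancy(cfg, species, sites_by_bin, hab)

  # guarantees run before planting so they are invariant to the planted
  # counts: every species occurs somewhere, every site holds something
  total_occ <- Reduce(`+`, lapply(occ, rowSums))
  for (k in which(total_occ == 0)) {
    sp <- species[k, ]
    bz <- biozones()[sp$first]
    x <- hab[sites_by_bin[[bz]]]
    occ[[bz]][k, which.min(abs(x - sp$center))] <- 1L
  }
  for (bz in biozones()) {
    b <- match(bz, biozones())
    in_bin <- which(species$first <= b & species$last >= b)
    for (s in which(colSums(occ[[bz]]) == 0)) {
      x <- hab[sites_by_bin[[bz]]][s]
      occ[[bz]][in_bin[which.min(abs(species$center[in_bin] - x))], s] <- 1L
    }
  }

  # planting (separate sub-seed; only planted species' rows are touched)
  planted <- data.frame(species_i = character(0), species_j = character(0),
                        intended = character(0), stringsAsFactors = FALSE)
  if (n_plant > 0L) {
    set.seed(cfg$seed + 2)
    picks <- sample(species$species_id, n_plant)
    take <- function(n) {
      out <- picks[seq_len(n)]; picks <<- picks[-seq_len(n)]; out
    }
    plant_one <- function(kind) {
      ij <- sort(take(2L))
      i <- match(ij[1], species$species_id)
      j <- match(ij[2], species$species_id)
      species$first[c(i, j)] <<- 1L; species$last[c(i, j)] <<- 3L
      if (kind == "aggregated") {
        ctr <- runif(1, -1, 1)
        species$center[c(i, j)] <<- ctr
      } else {
        species$center[i] <<- -1.5; species$center[j] <<- 1.5
      }
      for (bz in biozones()) {
        ids <- sites_by_bin[[bz]]; x <- hab[ids]
        draw <- function(ctr) {
          p <- pmin(1, cfg$base_occupancy *
                      exp(-cfg$habitat_filter_strength *
                          (x - ctr)^2 / cfg$species_breadth^2))
          rbinom(length(ids), 1L, p)
        }
        ri <- draw(species$center[i]); rj <- draw(species$center[j])
        if (kind == "aggregated") {
          u <- as.integer(ri | rj)
          k_force <- max(2L, round(0.25 * length(ids)))
          near <- order(abs(x - species$center[i]))[seq_len(k_force)]
          u[near] <- 1L
          occ[[bz]][ij[1], ] <<- u; occ[[bz]][ij[2], ] <<- u
        } else {
          k_force <- max(2L, round(0.2 * length(ids)))
          near_i <- order(abs(x - species$center[i]))[seq_len(k_force)]
          near_j <- order(abs(x - species$center[j]))[seq_len(k_force)]
          ri[near_i] <- 1L; rj[near_j] <- 1L
          both <- ri == 1L & rj == 1L
          to_i <- both & (abs(x - species$center[i]) <=
                            abs(x - species$center[j]))
          rj[both & to_i] <- 0L; ri[both & !to_i] <- 0L
          occ[[bz]][ij[1], ] <<- ri; occ[[bz]][ij[2], ] <<- rj
        }
      }
      data.frame(species_i = ij[1], species_j = ij[2], intended = kind,
                 stringsAsFactors = FALSE)
    }
    agg <- lapply(seq_len(cfg$n_planted_aggregated), function(...)
      plant_one("aggregated"))
    seg <- lapply(seq_len(cfg$n_planted_segregated), function(...)
      plant_one("segregated"))
    planted <- do.call(rbind, c(agg, seg))
  }

  # redrawing planted rows can (rarely) empty a site whose only occupant
  # was a planted species; refill from the planted species themselves so
  # non-planted occupancy stays invariant to the planted counts
  if (n_plant > 0L) {
    planted_ids <- c(planted$species_i, planted$species_j)
    for (bz in biozones()) {
      for (s in which(colSums(occ[[bz]]) == 0)) {
        x <- hab[sites_by_bin[[bz]]][s]
        ctr <- species$center[match(planted_ids, species$species_id)]
        occ[[bz]][planted_ids[which.min(abs(ctr - x))], s] <- 1L
      }
    }
  }

  matrices <- lapply(biozones(), function(bz)
    occurrence_matrix(occ[[bz]], bz, quiet = TRUE))
  names(matrices) <- biozones()
  sites <- do.call(rbind, site_rows)
  gt_sites <- data.frame(site_id = names(hab), habitat = unname(hab),
                         parent_floral_site = unname(parents),
                         stringsAsFactors = FALSE)
  list(matrices = matrices, sites = sites,
       traits = data.frame(species_id = species$species_id,
                           ln_mass = species$ln_mass,
                           stringsAsFactors = FALSE),
       ground_truth = list(species = species, planted_pairs = planted,
                           site_habitat = gt_sites))
}

#' Generate a complete synthetic dataset with ground truth
#'
#' @param cfg A [synth_config()].
#' @return List: `dataset` (a [paleo_dataset()]), `ground_truth` (never
#'   consumed by the analysis pipeline), `flora_extras` (latent floral
#'   habitat and taxon optima, for generator diagnostics).
#' @export
generate_dataset <- function(cfg = synth_config()) {
  flora <- generate_flora(cfg)
  mam <- generate_mammals(cfg, flora)
  gt <- mam$ground_truth
  gt$site_habitat <- rbind(
    gt$site_habitat,
    data.frame(site_id = names(flora$site_habitat),
               habitat = unname(flora$site_habitat),
               parent_floral_site = NA_character_,
               stringsAsFactors = FALSE))
  list(dataset = paleo_dataset(rbind(flora$sites, mam$sites),
                               mam$matrices, flora$matrices, mam$traits),
       ground_truth = gt,
       flora_extras = list(site_habitat = flora$site_habitat,
                           taxon_optima = flora$taxon_optima))
}

#' Write a dataset (and its ground truth) as canonical CSV files
#'
#' Emits `sites.csv`, `mammal_occurrences.csv`, `floral_occurrences.csv`
#' and `traits.csv` in the formats the readers expect (write-then-read
#' round-trips exactly), plus `ground_truth_*.csv` files that the analysis
#' pipeline never reads.
#'
#' @param dataset A [paleo_dataset()].
#' @param ground_truth Optional ground-truth list from
#'   [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, ground_truth = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(dataset$sites, file.path(dir, "sites.csv"),
            row.names = FALSE, quote = FALSE)
  write_occurrences(dataset$mammal, file.path(dir, "mammal_occurrences.csv"))
  write_occurrences(dataset$floral, file.path(dir, "floral_occurrences.csv"))
  tr <- data.frame(species_id = dataset$traits$species_id,
                   ln_mass_g = dataset$traits$ln_mass)
  write.csv(tr, file.path(dir, "traits.csv"), row.names = FALSE,
            quote = FALSE)
  if (!is.null(ground_truth)) {
    write.csv(ground_truth$species,
              file.path(dir, "ground_truth_species.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(ground_truth$planted_pairs,
              file.path(dir, "ground_truth_pairs.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(ground_truth$site_habitat,
              file.path(dir, "ground_truth_sites.csv"),
              row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
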