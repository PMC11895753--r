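test_that("haversine distances match closed forms on a 6371 km sphere", {
  expect_equal(haversine_km(10, 20, 10, 20), 0)
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371, tolerance = 1e-6)
  expect_equal(haversine_km(0, 0, 0, 90), pi * 6371 / 2, tolerance = 1e-6)
  expect_error(haversine_km(95, 0, 0, 0), "out of range")
})

test_that("mammal sites match the nearest contemporaneous floral site only", {
  sites <- tiny_sites()
  ord <- fake_ordination(c("fA", "fB", "fC"),
                         matrix(c(0.3, -0.1, 0.5, 0.2, -0.4, 0.0),
                                3, 2, byrow = TRUE))
  sh <- match_sites(sites, ord)
  expect_equal(sh$matched_floral_site_id[sh$mammal_site_id == "m1"], "fA")
  expect_equal(sh$matched_floral_site_id[sh$mammal_site_id == "m2"], "fB")
  # m3 (Wa0) sits nearer fA (Cf3) than fC (Wa0); the same-bin site wins
  expect_equal(sh$matched_floral_site_id[sh$mammal_site_id == "m3"], "fC")
  expect_equal(sh$NMDS1[sh$mammal_site_id == "m1"], 0.3)
  expect_true(all(sh$distance_km >= 0))
})

test_that("equidistant floral sites break ties to the smallest site id", {
  sites <- data.frame(
    site_id = c("fB", "fA", "mX"), lat = c(45, 45, 45),
    lon = c(-108.1, -107.9, -108.0), biozone = "Cf3",
    kind = c("palynofloral", "palynofloral", "mammal"))
  ord <- fake_ordination(c("fA", "fB"),
                         matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE))
  sh <- match_sites(sites, ord)
  expect_equal(sh$matched_floral_site_id, "fA")
  # with only one floral site in the bin, it is matched at any distance
  sites1 <- sites[-1, ]
  expect_equal(match_sites(sites1, ord)$matched_floral_site_id, "fA")
})

test_that("species preferences average inherited scores over occupied sites", {
  sh <- data.frame(mammal_site_id = c("m1", "m2", "m3"),
                   matched_floral_site_id = c("fA", "fB", "fC"),
                   distance_km = c(1, 1, 1),
                   biozone = c("Cf3", "Cf3", "Wa0"),
                   NMDS1 = c(0.3, 0, 1), NMDS2 = c(-0.1, 0, 1))
  mats <- list(
    Cf3 = occ(1, 0,
              0, 1, species = c("one", "two"), sites = c("m1", "m2")),
    Wa0 = occ(1, species = "two", sites = "m3", biozone = "Wa0"))
  prefs <- species_preferences(mats, sh)
  expect_equal(prefs$pref1[prefs$species_id == "one"], 0.3)
  expect_equal(prefs$pref2[prefs$species_id == "one"], -0.1)
  # species "two" occupies m2 (0,0) and m3 (1,1) across two bins
  expect_equal(prefs$pref1[prefs$species_id == "two"], (0 + 1) / 2)
  expect_equal(prefs$n_sites[prefs$species_id == "two"], 2)
  # preferences lie within the range of inherited site scores
  expect_true(all(prefs$pref1 >= min(sh$NMDS1) & prefs$pref1 <= max(sh$NMDS1)))
})

test_that("three-site two-bin preference matches the hand-computed mean", {
  sh <- data.frame(mammal_site_id = c("m1", "m2", "m3"),
                   matched_floral_site_id = "f", distance_km = 0,
                   biozone = c("Cf3", "Cf3", "Wa0"),
                   NMDS1 = c(0.2, 0.4, 0.9), NMDS2 = c(0, 0.1, -0.4))
  mats <- list(Cf3 = occ(1, 1, species = "sp", sites = c("m1", "m2")),
               Wa0 = occ(1, species = "sp", sites = "m3", biozone = "Wa0"))
  prefs <- species_preferences(mats, sh)
  expect_equal(prefs$pref1, mean(c(0.2, 0.4, 0.9)))
  expect_equal(prefs$pref2, mean(c(0, 0.1, -0.4)))
})

test_that("bin summaries compute the documented statistics", {
  mats <- list(Cf3 = occ(1, 1, 1, 1, species = c("u", "v"),
                         sites = c("m1", "m2")))
  prefs <- data.frame(species_id = c("u", "v"), pref1 = c(0, 0.1),
                      pref2 = c(0.5, 0.5), n_sites = c(2, 2))
  s <- bin_preference_summaries(prefs, mats, "all_taxa", "variance")
  expect_equal(s$mean1, 0.05)
  expect_equal(s$dispersion1, 0.005)  # sample variance, n-1
  expect_equal(s$dispersion2, 0)      # zero within-bin variance tolerated
  r <- bin_preference_summaries(prefs, mats, "all_taxa", "range")
  expect_equal(r$dispersion1, 0.1)
  one <- bin_preference_summaries(prefs[1, ], mats, "all_taxa")
  expect_equal(one$mean1, one$median1)
  expect_equal(one$dispersion1, 0)
})

test_that("first-occurrence summaries drop carried-over species exactly", {
  mats <- list(
    Cf3 = occ(1, species = "old", sites = "m1"),
    Wa0 = occ(1, 1, species = c("new", "old"), sites = "m2",
              biozone = "Wa0"))
  prefs <- data.frame(species_id = c("new", "old"), pref1 = c(1, 0),
                      pref2 = c(1, 0), n_sites = 1)
  all_w <- bin_preference_summaries(prefs, mats, "all_taxa")
  fo_w <- bin_preference_summaries(prefs, mats, "first_occurrences")
  expect_equal(all_w$n_species[all_w$biozone == "Wa0"], 2)
  expect_equal(fo_w$n_species[fo_w$biozone == "Wa0"], 1)
  expect_equal(fo_w$mean1[fo_w$biozone == "Wa0"], 1)
})

test_that("between-bin tests behave at the null, under shift, and in count", {
  same <- data.frame(biozone = rep(c("Cf3", "Wa0"), each = 5),
                     value = rep(1:5, 2))
  r <- between_bin_tests(same)
  expect_equal(r$pairwise$p_raw, 1)
  set.seed(17)
  shift <- data.frame(biozone = rep(c("Cf3", "Wa0"), each = 30),
                      value = c(rnorm(30), rnorm(30) + 5))
  r2 <- between_bin_tests(shift)
  expect_lt(r2$pairwise$p_raw, 0.001)
  expect_lt(r2$omnibus$p, 0.001)
  three <- data.frame(biozone = rep(biozones(), each = 10),
                      value = rnorm(30))
  r3 <- between_bin_tests(three)
  expect_equal(nrow(r3$pairwise), 3)
  expect_equal(r3$pairwise$p_bonferroni, pmin(1, r3$pairwise$p_raw * 3))
  r3p <- between_bin_tests(three, parametric = TRUE)
  expect_match(r3p$omnibus$method, "ANOVA")
  expect_error(between_bin_tests(data.frame(biozone = "Cf3", value = 1)),
               ">= 2")
})
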