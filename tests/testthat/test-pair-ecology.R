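make_pairs <- function(i, j, cls, bz = "Cf3") {
  data.frame(species_i = i, species_j = j, R_i = 2, R_j = 2, D = 1,
             c_score = 0.25, p_agg = 0.5, p_seg = 0.5,
             classification = cls, biozone = bz, stringsAsFactors = FALSE)
}

test_that("pair differences are absolute and complete on a hand fixture", {
  pairs <- make_pairs(c("a", "a", "b"), c("b", "c", "c"),
                      c("aggregated", "random", "segregated"))
  traits <- data.frame(species_id = c("a", "b", "c"),
                       ln_mass = c(2, 5, 2.5))
  prefs <- data.frame(species_id = c("a", "b", "c"),
                      pref1 = c(0.1, 0.1, -0.2),
                      pref2 = c(0, 0.4, 0.2), n_sites = 1)
  d <- pair_differences(pairs, traits, prefs)
  expect_equal(d$d_mass, c(3, 0.5, 2.5))
  expect_equal(d$d_pref1, c(0, 0.3, 0.3))
  expect_equal(d$d_pref2, c(0.4, 0.2, 0.2))
  expect_true(all(d$d_mass >= 0))
  # pairs with a missing trait are dropped with a message
  expect_message(
    d2 <- pair_differences(pairs, traits[-3, ], prefs), "dropped")
  expect_equal(nrow(d2), 1)
})

test_that("type summaries give means, medians and absent empty cells", {
  pairs <- make_pairs(c("a", "b", "c"), c("b", "c", "d"), "aggregated")
  traits <- data.frame(species_id = letters[1:4], ln_mass = c(0, 1, 3, 12))
  prefs <- data.frame(species_id = letters[1:4], pref1 = 0, pref2 = 0,
                      n_sites = 1)
  d <- pair_differences(pairs, traits, prefs)  # masses differ 1, 2, 9
  s <- summarize_types(d)
  mass <- s[s$variable == "mass", ]
  expect_equal(mass$mean_diff, 4)
  expect_equal(mass$median_diff, 2)
  expect_equal(mass$n_pairs, 3)
  expect_false(any(s$classification == "segregated"))  # cell absent
  one <- summarize_types(d[1, ])
  expect_equal(one$mean_diff, one$median_diff)
})

test_that("the richness-preserving null conserves per-site richness exactly", {
  set.seed(21)
  mats <- list(
    Cf3 = occurrence_matrix(
      matrix(rbinom(8 * 6, 1, 0.5), 8, 6,
             dimnames = list(sprintf("s%02d", 1:8),
                             sprintf("c%02d", 1:6))), "Cf3", quiet = TRUE),
    Wa0 = occurrence_matrix(
      matrix(rbinom(8 * 5, 1, 0.5), 8, 5,
             dimnames = list(sprintf("s%02d", 1:8),
                             sprintf("w%02d", 1:5))), "Wa0", quiet = TRUE))
  pool <- sort(unique(unlist(lapply(mats, rownames))))
  for (rep in 1:5) {
    rand <- paleopairs:::randomize_richness(mats, pool)
    for (bz in names(mats)) {
      obs_rich <- colSums(mats[[bz]])
      new_rich <- colSums(rand[[bz]])[names(obs_rich)]
      expect_identical(unname(new_rich), unname(obs_rich))
      expect_equal(ncol(rand[[bz]]), ncol(mats[[bz]]))
      expect_true(all(rand[[bz]] %in% 0:1))
    }
  }
})

test_that("the null is deterministic and nested in the replicate counter", {
  set.seed(22)
  g <- generate_dataset(small_cfg(seed = 30))
  d <- g$dataset
  ord <- fake_ordination(
    d$sites$site_id[d$sites$kind == "palynofloral"],
    matrix(rnorm(2 * sum(d$sites$kind == "palynofloral")), ncol = 2))
  sh <- match_sites(d$sites, ord)
  args <- list(d$mammal, sh, d$traits, n_null_inner = 100, seed = 5)
  n3 <- do.call(richness_preserving_null, c(args, n_reps = 3))
  n3b <- do.call(richness_preserving_null, c(args, n_reps = 3))
  expect_identical(n3$replicates, n3b$replicates)
  n5 <- do.call(richness_preserving_null, c(args, n_reps = 5))
  expect_identical(n3$replicates,
                   n5$replicates[n5$replicates$rep <= 3, ])
})

test_that("Cohen's D values and magnitude labels follow the cutpoints", {
  set.seed(23)
  null_means <- rnorm(100, 1, 0.3)
  at_null <- cohens_d(mean(null_means), null_means)
  expect_equal(at_null$d, 0)
  expect_identical(at_null$magnitude, "small")
  s <- sd(null_means)
  up <- cohens_d(mean(null_means) + 0.8 * s, null_means)
  expect_equal(up$d, 0.8)
  expect_identical(up$magnitude, "large")
  down <- cohens_d(mean(null_means) - 0.2 * s, null_means)
  expect_equal(down$d, -0.2)
  expect_identical(down$magnitude, "small")
  mid <- cohens_d(mean(null_means) + 0.5 * s, null_means)
  expect_identical(mid$magnitude, "medium")
  expect_error(cohens_d(1, rep(2, 50)), "degenerate")
  expect_warning(cohens_d(1, rnorm(10)), "unstable")
})

test_that("the effect table has the full grid with absent cells marked", {
  pairs <- rbind(
    make_pairs(c("a", "b"), c("b", "c"), c("aggregated", "random"), "Cf3"),
    make_pairs("a", "c", "aggregated", "Wa0"))
  traits <- data.frame(species_id = letters[1:3], ln_mass = 1:3)
  prefs <- data.frame(species_id = letters[1:3], pref1 = c(0, 1, 2),
                      pref2 = 0, n_sites = 1)
  obs <- summarize_types(pair_differences(pairs, traits, prefs))
  reps <- do.call(rbind, lapply(1:40, function(r) {
    s <- obs
    s$mean_diff <- s$mean_diff + rnorm(nrow(s), 0, 0.1)
    s$median_diff <- s$median_diff + rnorm(nrow(s), 0, 0.1)
    cbind(rep = r, s)
  }))
  null <- structure(list(replicates = reps, n_reps = 40,
                         n_null_inner = 100, alpha = 0.05, seed = 1,
                         reclassify = TRUE), class = "pair_null")
  et <- effect_table(obs, null)
  expect_lte(nrow(et), 18)  # 2 bins x 3 types x 3 variables
  expect_equal(nrow(et), 18)
  seg <- et[et$classification == "segregated", ]
  expect_true(all(seg$absent))
  expect_true(all(is.na(seg$d)))
  present <- et[!et$absent, ]
  expect_true(all(is.finite(present$d)))
  expect_identical(paleopairs:::d_magnitude(c(0.1, -0.5, 2, NA)),
                   c("small", "medium", "large", NA))
})

test_that("stronger planted filtering gives more negative aggregated-pair d", {
  run_effects <- function(strength, seed) {
    g <- generate_dataset(small_cfg(habitat_filter_strength = strength,
                                    seed = seed))
    d <- g$dataset
    flo_ids <- d$sites$site_id[d$sites$kind == "palynofloral"]
    hab <- g$ground_truth$site_habitat
    sc <- cbind(hab$habitat[match(flo_ids, hab$site_id)], 0)
    ord <- fake_ordination(flo_ids, sc)  # latent gradient as axis 1
    sh <- match_sites(d$sites, ord)
    prefs <- species_preferences(d$mammal, sh)
    pairs <- do.call(rbind, lapply(d$mammal, classify_pairs,
                                   n_null = 300, seed = seed))
    obs <- summarize_types(pair_differences(pairs, d$traits, prefs))
    null <- richness_preserving_null(d$mammal, sh, d$traits, n_reps = 15,
                                     n_null_inner = 100, seed = seed)
    et <- effect_table(obs, null)
    et$d[et$classification == "aggregated" & et$variable == "pref1" &
           !et$absent]
  }
  d_strong <- mean(run_effects(4, 31))
  d_neutral <- mean(run_effects(0, 31))
  expect_lt(d_strong, d_neutral)
  expect_lt(d_strong, -0.8)
})
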