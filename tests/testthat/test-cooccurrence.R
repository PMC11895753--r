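test_that("C-score endpoints and hand-computed values are exact", {
  expect_identical(c_score(5, 5, 5), 0)       # complete aggregation
  expect_identical(c_score(4, 6, 0), 1)       # complete segregation
  expect_identical(c_score(4, 2, 1), 0.375)   # (4-1)(2-1)/(4*2)
  expect_error(c_score(4, 2, 3), "min")
  expect_error(c_score(0, 2, 0), ">= 1")
})

test_that("C-score is symmetric and bounded on random valid inputs", {
  set.seed(1)
  for (k in 1:200) {
    ri <- sample(1:30, 1); rj <- sample(1:30, 1)
    d <- sample(0:min(ri, rj), 1)
    a <- c_score(ri, rj, d); b <- c_score(rj, ri, d)
    expect_identical(a, b)
    expect_gte(a, 0); expect_lte(a, 1)
  }
})

test_that("swaps conserve row and column totals exactly", {
  set.seed(2)
  m <- matrix(rbinom(30 * 20, 1, 0.3), 30, 20,
              dimnames = list(sprintf("s%02d", 1:30),
                              sprintf("x%02d", 1:20)))
  for (seed in 1:3) {
    s <- swap_null_matrix(m, 5000, seed = seed)
    expect_identical(rowSums(s), rowSums(m))
    expect_identical(colSums(s), colSums(m))
  }
})

test_that("the 2x2 identity swaps only to the anti-diagonal", {
  m <- diag(2); dimnames(m) <- list(c("a", "b"), c("s1", "s2"))
  anti <- matrix(c(0, 1, 1, 0), 2, dimnames = dimnames(m))
  seen_anti <- FALSE
  for (seed in 1:20) {
    s <- unclass(swap_null_matrix(m, 5, seed = seed))
    attr(s, "biozone") <- NULL
    expect_true(identical(s + 0, m) || identical(s + 0, anti))
    if (identical(s + 0, anti)) seen_anti <- TRUE
  }
  expect_true(seen_anti)  # the only other configuration is reachable
})

test_that("matrices without checkerboards are returned unchanged", {
  m <- matrix(1L, 1, 5, dimnames = list("a", paste0("s", 1:5)))
  expect_message(s <- swap_null_matrix(m, 100, seed = 1), "unchanged")
  expect_identical(unclass(s)[1, ], unclass(m)[1, ])
})

test_that("classification recovers planted aggregation and segregation", {
  set.seed(3)
  bg <- matrix(rbinom(30 * 20, 1, 0.5), 30, 20)
  m <- rbind(rep(c(1L, 0L), each = 10), rep(c(1L, 0L), each = 10), bg)
  dimnames(m) <- list(c("agg1", "agg2", sprintf("b%02d", 1:30)),
                      sprintf("x%02d", 1:20))
  r <- classify_pairs(occurrence_matrix(m, "Cf3", quiet = TRUE),
                      n_null = 500, seed = 4)
  pair <- r[r$species_i == "agg1" & r$species_j == "agg2", ]
  expect_identical(pair$classification, "aggregated")
  expect_lte(pair$p_agg, 0.05)
  expect_identical(pair$c_score, 0)

  m2 <- m
  m2[2, ] <- rep(c(0L, 1L), each = 10)  # disjoint halves
  rownames(m2)[2] <- "seg2"
  r2 <- classify_pairs(occurrence_matrix(m2, "Cf3", quiet = TRUE),
                       n_null = 500, seed = 4)
  pair2 <- r2[r2$species_i == "agg1" & r2$species_j == "seg2", ]
  expect_identical(pair2$classification, "segregated")
  expect_identical(pair2$c_score, 1)
})

test_that("identical config and seed give byte-identical results", {
  set.seed(5)
  m <- occurrence_matrix(
    matrix(rbinom(15 * 12, 1, 0.4), 15, 12,
           dimnames = list(sprintf("s%02d", 1:15),
                           sprintf("x%02d", 1:12))),
    "Wa0", quiet = TRUE)
  expect_identical(classify_pairs(m, n_null = 300, seed = 9),
                   classify_pairs(m, n_null = 300, seed = 9))
})

test_that("sampled null matches exhaustive enumeration on a small matrix", {
  m <- matrix(c(1, 0, 1, 1, 1, 0, 0, 1, 1), 3, 3,
              dimnames = list(paste0("s", 1:3), paste0("x", 1:3)))
  en <- enumerate_fixed_marginals(m)
  cs <- vapply(en, function(M) {
    R <- rowSums(M)
    c_score(R[1], R[2], sum(M[1, ] * M[2, ]))
  }, numeric(1))
  p_true <- table(round(cs, 10)) / length(cs)
  samp <- pair_null_cscores(m, c("s1", "s2"), n_null = 2000, seed = 6)
  p_hat <- table(factor(round(samp, 10), levels = names(p_true))) /
    length(samp)
  tv <- 0.5 * sum(abs(as.numeric(p_hat) - as.numeric(p_true)))
  expect_lt(tv, 0.1)
})

test_that("p-values are valid (never anti-conservative) on null matrices", {
  set.seed(7)
  m0 <- matrix(rbinom(12 * 10, 1, 0.4), 12, 10,
               dimnames = list(sprintf("s%02d", 1:12),
                               sprintf("x%02d", 1:10)))
  m0 <- occurrence_matrix(m0, "Cf3", quiet = TRUE)
  hits <- replicate(30, {
    obs <- swap_null_matrix(m0, 2000)  # a draw from the null itself
    r <- classify_pairs(obs, n_null = 200)
    mean(r$p_agg <= 0.05)
  })
  # binomial slack: 3 SD above alpha at these replicate counts
  expect_lte(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / (30 * 66)))
})

test_that("pair census partitions all pairs and counts significants", {
  m <- occurrence_matrix(
    matrix(c(1, 1, 0, 1, 0, 1, 1, 0, 1, 1, 1, 0), 4, 3,
           dimnames = list(paste0("s", 1:4), paste0("x", 1:3))),
    "Cf3", quiet = TRUE)
  r <- classify_pairs(m, n_null = 200, seed = 1)
  cen <- pair_census(list(Cf3 = r))
  expect_equal(cen$n_pairs, choose(4, 2))
  expect_equal(cen$aggregated + cen$segregated + cen$random, cen$n_pairs)
  expect_equal(cen$total_significant, cen$aggregated + cen$segregated)
  # a census may legitimately contain zero segregations
  fake <- r; fake$classification <- "random"
  cen0 <- pair_census(list(Wa0 = fake))
  expect_identical(cen0$segregated, 0L)
  expect_identical(cen0$total_significant, 0L)
})
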