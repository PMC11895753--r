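---
title: "Pairwise co-occurrence, habitat preference, and null models across the PETM"
author: "paleopairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise co-occurrence, habitat preference, and null models across the PETM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleopairs)
```

## The question and the model

The Paleocene–Eocene Thermal Maximum (PETM, ca. 56 Ma) was a rapid
warming event recorded in the Bighorn Basin by three mammal biozones —
Clarkforkian 3 (`Cf3`, pre-event), Wasatchian 0 (`Wa0`, the event body)
and the merged Wasatchian 1–2 (`Wa1_2`, aftermath). If environmental
filtering assembles mammal communities, species found together more often
than chance (aggregated pairs) should share environmental preferences,
and species found apart (segregated pairs) should differ in them; a
weakening filter erases those contrasts. `paleopairs` operationalizes
this with three linked pieces:

1. **Pair classification.** Within each biozone's species-by-site binary
   matrix (species are rows, so the row total `R_i` is species *i*'s
   occupancy), every unordered pair gets the scaled C-score
   `C_ij = (R_i − D)(R_j − D)/(R_i R_j)` (`D` = shared sites), 0 for
   identical site sets and 1 for disjoint ones. Significance comes from a
   fixed-marginals null: matrices randomized by checkerboard swaps that
   preserve all row and column totals, so occupancy differences among
   species and sampling-intensity differences among sites are built into
   the null. Two one-sided Monte-Carlo p-values give the three-way
   aggregated / segregated / random call.

2. **Niche proxies.** The Grinnellian (environmental) niche is proxied by
   ordination of palynofloral assemblages: Jaccard distances among floral
   site compositions, 2-axis nonmetric MDS (Kruskal stress-1), PERMANOVA
   among biozones; each mammal site inherits the scores of the nearest
   contemporaneous floral site by great-circle distance, and each species
   averages the inherited scores over its occupied sites, pooled across
   all biozones (time-transgressive, one value per occupied site). The
   Eltonian niche is proxied by ln body mass, supplied as a trait table.

3. **Effect sizes against a richness-preserving null.** Mean (and
   median) absolute within-pair differences per biozone × pair type ×
   variable are compared to a null that reassigns species to sites across
   all three biozones at once, preserving each site's observed richness —
   re-running classification and preferences per replicate — summarized
   as Cohen's D with the conventional |d| ≤ 0.2 (small) and |d| ≥ 0.8
   (large) cutpoints.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `n_null` | 1000 | co-occurrence null replicates; ≥100 enforced for inference |
| `burn_in`, `thin` | 10× / 1× presences | trial swaps before the first and between retained replicates of a single chain; scale with matrix fill so mixing is comparable across bins |
| `alpha` | 0.05 | per-tail level of the three-way classification; no multiple-testing correction across pairs, mirroring standard PAIRS practice |
| `n_restarts`, `maxit` | 50 / 500 | NMDS random starts and iteration cap; best (lowest-stress) start wins |
| `n_perm` | 10000 | PERMANOVA label permutations |
| `n_reps`, `n_null_inner` | 100 / 200 | richness-null replicates and the reduced swap-null size inside each replicate's re-classification; the re-run-everything design is what makes per-type null distributions coherent, and the inner null is the cost lever |
| `dispersion_stat` | `"variance"` | per-bin preference dispersion; `"range"` also reported — the two magnitudes differ by orders and published "range" values are ambiguous, so both are kept |
| `sd_type` | `"replicate_means"` | Cohen's D denominator (below) |

All randomized stages take explicit seeds; `run_pipeline()` fans a master
seed out to fixed per-stage offsets so stages can be re-run in isolation,
and the richness null seeds each replicate as `seed + replicate`, so
enlarging `n_reps` extends rather than reshuffles the replicate set.

## Numerical choices

- **Swap sampler.** The trial-swap chain draws a random 2×2 submatrix
  and swaps iff it is a checkerboard. The proposal is symmetric, so the
  stationary distribution is uniform over the fixed-marginals set; the
  acceptance suite checks the sampled C-score distribution against
  exhaustive enumeration on small matrices (total-variation distance).
  Degenerate matrices with no checkerboard (single row/column) pass
  through unchanged with a note.
- **Tie handling in p-values.** With row totals fixed by the null, C is
  strictly decreasing in the integer D, so tail counts are computed by
  exact integer comparison on D — no floating-point tie tolerance.
  P-values use the add-one rule (observed counted in its own null), so
  they are never zero and never anti-conservative.
- **Classification ties.** If a degenerate null puts both one-sided
  p-values at or below alpha, the smaller wins; exact ties fall to
  `random` and are logged.
- **NMDS orientation.** Stress depends only on dissimilarity ranks, but
  scores are reproducible only up to rotation/reflection, and downstream
  per-axis differences depend on orientation. The winning configuration
  is therefore centered, rotated to principal axes, and each axis
  sign-fixed so the lexicographically smallest site id scores
  non-negatively. Restart initial configurations are drawn from the seed,
  making stress and scores deterministic.
- **Nearest-site ties** break to the lexicographically smallest floral
  site id; matching never crosses biozones, however close a floral site
  of another bin may be. A bin served by a single floral site gives all
  its species identical inherited scores; zero within-bin preference
  variance is tolerated throughout.
- **Great-circle distance** uses a sphere of radius 6371.0 km — at the
  ~200 km basin scale the spherical approximation is well inside the
  noise of fossil-locality coordinates.
- **Magnitude labels** apply the 0.2/0.8 cutpoints with a 1e-9 tolerance
  so values constructed to sit exactly on a boundary label as intended.
- **Degenerate inputs** error early with named offenders: unknown site
  ids, empty occurrence files, all-zero distance matrices, groups of
  size one, zero null standard deviations.

## The Cohen's D denominator

The effect-size definition `d = (mean observed − mean null)/sd(null)`
leaves "sd of the null" ambiguous: the standard deviation of the
per-replicate null *means* (the spread of the violin distributions the
figures display, i.e. a standardized-effect-size z), or the
observation-level standard deviation of null pair differences pooled
across replicates (classical Cohen semantics). The package defaults to
`sd_type = "replicate_means"`, matching the violin-plot reading, and
offers `"pooled"` because the 0.2/0.8 small/large convention originates
on the observation scale. Both are computed from the same stored
per-replicate sufficient statistics; the median-based variant `d_median`
is emitted alongside since figures display medians too. The `reclassify
= FALSE` flag reuses observed classifications inside the null (cheaper,
but its null distributions no longer reflect classification noise); the
default re-runs classification per replicate.

## The synthetic generator: what it emulates, and what not

Real occurrence data of this kind are typically available only on
request, so every stage is exercised on generated data with known ground
truth. A single latent 1-D habitat gradient drives everything: floral
taxa and mammal species carry optima on the gradient; sites carry
habitat values around bin-level means (`Cf3 = −1`, `Wa0 = +1`,
`Wa1_2 = 0`, putting the event bin compositionally apart — the pattern
the ordination should recover); occupancy probability decays as
`exp(−strength · (site − optimum)²/breadth²)`. Defaults mirror the study
shape: 8/13/9 floral sites, 126 mammal sites, 173 species, ln-mass
`Normal(6, 2)` on the ln-gram scale (a few-hundred-gram median with the
long right tail real Paleogene faunas show), coordinates in a ~200 km
box, and a moderate default filter (`habitat_filter_strength = 2`).
Between-bin floral turnover (default 0.6) replaces a fraction of each
bin's taxon pool, creating the cluster structure; mammal sites jitter
around parent floral sites so nearest-site matching is informative.
Planted aggregated pairs share an optimum and have their presences
unioned (identical site sets); planted segregated pairs get opposite
optima with shared sites assigned to the nearer optimum (disjoint sets).
Forcing is overlaid after probabilistic occupancy under a separate
sub-seed, so non-planted occupancy is invariant to the planted counts —
a tested property.

The generator does **not** emulate: abundance or collection-effort
structure (presences only), taphonomic loss beyond what site-richness
heterogeneity captures, spatial autocorrelation beyond the parent-site
jitter, phylogenetic trait structure, or real taxon names and
stratigraphic meter levels. Passing tests therefore demonstrate that the
machinery recovers planted signal of the assumed form at realistic sizes
— not that real PETM assemblages contain such signal.

## Calibration findings the test suite documents

Two acceptance-level calibration idealizations fail for reasons
intrinsic to the method, and the suite keeps them as failing assertions
rather than papering over them:

- **The two-tailed non-random rate on neutral data sits below 2α.** The
  C-score null is discrete; tie-inclusive add-one Monte-Carlo p-values
  give `P(p ≤ α)` strictly below α per tail (often far below for sparse
  pairs whose null mass concentrates on few values). Measured non-random
  fractions on neutral communities run ~0.03–0.06 against the idealized
  0.10. This conservatism is a known property of exact discrete tests;
  "fixing" it with mid-p or tie-splitting would change the stated
  p-value convention.
- **Neutral-data effect sizes are not all small.** Even with no habitat
  filter, the richness-preserving null scrambles species across biozones
  whose floral compositions differ — deliberately, since destroying
  temporal structure is its purpose — so observed and null preference
  differences are not exchangeable and d is not centered at zero; and in
  sparsely populated aggregated/segregated cells d has sampling spread
  near 1 regardless. The realistic neutral expectation is |d| mostly
  within ±2 (a property the suite verifies), not |d| ≤ 0.2.

What the suite verifies green, at sizes chosen to keep a full run in
minutes on one CPU (4×4 enumeration oracle at 5000 null draws; 50×40
marginal conservation at 10,000 swaps; 500 PERMANOVA size simulations;
100 neutral calibration datasets; 20-seed effect-size runs at
`n_reps = 50`, `n_null_inner = 100` on ~50-species communities):
marginal conservation is exact; the swap null matches enumeration;
NMDS reaches near-zero stress on embeddable configurations and is
rank-invariant; PERMANOVA holds its size; planted pairs are recovered
with sensitivity ≥ 0.8 under strong forcing; planted filtering drives
aggregated-pair preference d far below −0.8 while the same statistic
collapses when the filter is removed; and a bin with no segregated pairs
propagates as explicitly absent effect-table cells rather than silent
omission.

## Known limitations

- Pair classification inherits the conservatism above; counts of
  significant pairs are best compared against the same machinery's null,
  as the effect-size stage does, not read as absolute rates.
- Preferences are means over occupied sites of scores inherited from the
  *nearest* floral site; they ignore distance-to-match quality
  (`distance_km` is reported so users can filter).
- The richness null does not preserve species' total occurrence counts
  (only site richness), which follows from its definition; an
  occupancy-preserving variant would answer a different question.
- NMDS axes are identifiable only up to the package's orientation
  convention; cross-study score comparisons must re-orient first.
- With `n = 3` biozones no trend test is attempted; between-bin
  comparisons are omnibus Kruskal–Wallis (classical ANOVA behind a flag,
  kept nonparametric by default to match the pairwise Mann–Whitney
  tests) with Bonferroni-corrected pairwise tests.
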