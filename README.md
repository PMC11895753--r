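# paleopairs

Community-assembly analysis of fossil mammal assemblages across the
Paleocene–Eocene Thermal Maximum (PETM), built for quantitative
paleoecologists working with presence/absence occurrence data binned into
biozones. The package classifies species pairs by co-occurrence, proxies
each species' Grinnellian (environmental) niche through ordination of
contemporaneous palynofloral assemblages and its Eltonian niche through ln
body mass, and asks whether niche differences within pair types depart
from a randomization null — the workflow used to test whether
environmental filtering of Bighorn Basin mammal communities weakened
through the PETM.

## The statistics at the core

**Pair classification.** For species *i*, *j* in one biozone's
species-by-site matrix, the scaled C-score is

> C_ij = (R_i − D)(R_j − D) / (R_i · R_j)

with R_i, R_j the species' occurrence (row) totals and D the number of
shared sites: 0 means complete aggregation (identical site sets), 1
complete segregation (disjoint sets). Each pair's observed C is compared
to a null distribution from checkerboard-swap randomizations that keep
every row and column total fixed, so differences in species occupancy and
per-site sampling intensity are carried into the null. Two one-sided
Monte-Carlo p-values (add-one rule) classify each pair as aggregated
(p_agg ≤ α), segregated (p_seg ≤ α), or random.

**Habitat proxy.** Palynofloral site compositions are ordinated by 2-axis
nonmetric multidimensional scaling (Kruskal stress-1) of Jaccard (or
cosine) distances, with PERMANOVA and pairwise Bonferroni-corrected tests
among biozones. Every mammal site inherits the (NMDS1, NMDS2) scores of
its geographically closest contemporaneous floral site (great-circle
distance); a species' environmental preference is the unweighted mean of
inherited scores over all sites it occupies, pooled across biozones.

**Effect sizes.** Absolute within-pair differences in ln mass and in each
preference axis are averaged per biozone × pair type, then compared to a
null that refills every site with k species drawn uniformly from the
pooled cross-biozone species list (k = the site's observed richness),
re-running classification and preferences per replicate. Departure is
measured by Cohen's D, `d = (mean observed − mean null) / sd(null)`, with
|d| ≤ 0.2 small and |d| ≥ 0.8 large.

## Worked example

Real occurrence data of this kind are typically restricted-access, so the
package ships a generator that emulates the study system's shape (three
biozones, ~30 floral and ~126 mammal sites, ~173 species) with tunable
habitat filtering and planted aggregated/segregated pairs as ground
truth. A scaled-down run with strong filtering:

```r
library(paleopairs)

cfg <- synth_config(
  floral_sites_per_bin = c(Cf3 = 5, Wa0 = 6, Wa1_2 = 5),
  mammal_sites_per_bin = c(Cf3 = 16, Wa0 = 20, Wa1_2 = 16),
  n_mammal_species = 50, base_occupancy = 0.3,
  habitat_filter_strength = 3, n_planted_aggregated = 3, seed = 1)
g <- generate_dataset(cfg)

res <- run_pipeline(run_config(
  dataset = g$dataset, out_dir = "results",
  n_perm = 999, n_null = 1000, n_reps = 50, n_null_inner = 100,
  n_restarts = 20, seed = 42))
print(res)
```

```
paleopairs run
  NMDS stress 0.1358 | PERMANOVA F 3.406 (p 0.001)
 biozone aggregated segregated random total_significant n_pairs
     Cf3         11          0     67                11      78
     Wa0         16          0    335                16     351
   Wa1_2         12          0    313                12     325
  large effect sizes: 14 of 18 cells
```

The stress (0.136) is below the conventional 0.2 interpretability limit,
the three biozones' floral compositions separate (all pairwise Bonferroni
p ≤ 0.03), and most pairs are random with a minority aggregated — the
shape real assemblages show. The aggregated pairs' preference differences
against the null:

```r
subset(res$effects, classification == "aggregated" & variable == "pref1")
```

```
 biozone observed_mean null_mean null_sd     d magnitude n_pairs
     Cf3        0.0875     0.373  0.0897 -3.18     large      11
     Wa0        0.1157     0.385  0.0657 -4.10     large      16
   Wa1_2        0.0483     0.364  0.0568 -5.56     large      12
```

Aggregated species are far more similar in environmental preference than
the richness-preserving null expects (d ≤ −3) — the signature of the
habitat filter the generator planted. With `habitat_filter_strength = 0`
these effect sizes collapse toward the null band. `run_pipeline()` writes
every table (pair results, census, preferences, effect sizes, null
replicate means for violin plots) plus a JSON manifest with seeds and
timings to `out_dir`; datasets can equally be read from CSV files via
`run_config(input_dir = ...)` or a YAML config via `read_run_config()`.

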