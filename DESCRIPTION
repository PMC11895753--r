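Package: paleopairs
Title: Species-Pair Co-Occurrence and Niche Differences Across the
    Paleocene-Eocene Thermal Maximum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for community-assembly analysis of
    fossil mammal assemblages across the Paleocene-Eocene Thermal Maximum
    (PETM). Classifies species pairs as aggregated, segregated or randomly
    associated from scaled C-scores against fixed-marginals (swap) null
    models; ordinates palynofloral site compositions by nonmetric
    multidimensional scaling with PERMANOVA; assigns mammal species
    Grinnellian environmental preferences from the ordination scores of
    nearby contemporaneous floral sites; and compares body-mass and
    habitat-preference differences among pair types to a richness-preserving
    randomization null via standardized (Cohen's D) effect sizes. Includes a
    synthetic community generator with planted ground truth so every stage
    is testable without restricted-access occurrence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    vegan,
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
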