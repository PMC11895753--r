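# Shared fixtures: everything is built in code at test time.

occ <- function(..., species, sites, biozone = "Cf3", quiet = TRUE) {
  m <- matrix(c(...), length(species), length(sites), byrow = TRUE,
              dimnames = list(species, sites))
  occurrence_matrix(m, biozone, quiet = quiet)
}

# 6 sites, two spatially separated floral sites per bin, crafted coordinates
tiny_sites <- function() {
  data.frame(
    site_id = c("fA", "fB", "fC", "m1", "m2", "m3"),
    lat = c(45.0, 45.5, 45.0, 45.01, 45.49, 45.0),
    lon = c(-108.0, -108.0, -108.5, -108.0, -108.0, -108.01),
    biozone = c("Cf3", "Cf3", "Wa0", "Cf3", "Cf3", "Wa0"),
    kind = c("palynofloral", "palynofloral", "palynofloral",
             "mammal", "mammal", "mammal"),
    stringsAsFactors = FALSE)
}

fake_ordination <- function(ids, scores) {
  colnames(scores) <- c("NMDS1", "NMDS2")
  rownames(scores) <- ids
  structure(list(scores = scores, stress = 0.05, stress_ok = TRUE),
            class = "nmds_result")
}

# small neutral / filtered generator configs used across tests
small_cfg <- function(...) {
  synth_config(floral_sites_per_bin = c(Cf3 = 5, Wa0 = 6, Wa1_2 = 5),
               mammal_sites_per_bin = c(Cf3 = 12, Wa0 = 16, Wa1_2 = 12),
               n_mammal_species = 30, base_occupancy = 0.3, ...)
}

write_tmp_csv <- function(df, name) {
  path <- file.path(tempdir(), name)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
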