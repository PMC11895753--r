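#' @useDynLib paleopairs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate aov kruskal.test median p.adjust prcomp rbinom
#'   rnorm runif sd setNames var wilcox.test as.dist dist
#' @importFrom utils read.csv write.csv combn packageVersion
NULL

#' Biozone labels in temporal order
#'
#' The three North American Land Mammal Age (NALMA) biozones used as time
#' bins, oldest first: Clarkforkian 3 (latest Paleocene), Wasatchian 0 (the
#' PETM body) and the merged Wasatchian 1--2 (post-PETM). All matrices and
#' tables in the package key on these labels.
#'
#' @return Character vector `c("Cf3", "Wa0", "Wa1_2")`, oldest first.
#' @export
#' @examples
#' biozones()
biozones <- function() c("Cf3", "Wa0", "Wa1_2")

#' Age annotations for the biozones (not used in computation)
#' @return Named character vector of approximate age spans.
#' @export
biozone_ages <- function() {
  c(Cf3 = "ca. 56.2-55.8 Ma", Wa0 = "ca. 55.8-55.7 Ma",
    Wa1_2 = "ca. 55.7-54.8 Ma")
}

assert_biozone <- function(x) {
  bad <- setdiff(unique(x), biozones())
  if (length(bad) > 0L)
    stop("unknown biozone label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(biozones(), collapse = ", "), ")",
         call. = FALSE)
  invisible(x)
}

#' Construct a validated presence/absence occurrence matrix
#'
#' Species are rows and sites are columns, fixing the convention that the
#' row total `R_i` is the number of occurrences of species `i`. Cells must
#' be 0/1; empty rows and columns are dropped with a warning (fossil species
#' lists routinely include taxa absent from a given bin). Rows and columns
#' are sorted lexicographically so matrix construction is deterministic.
#'
#' @param m Numeric/integer matrix with species as rownames and sites as
#'   colnames, cells in `{0, 1}`.
#' @param biozone Biozone label, one of [biozones()].
#' @param quiet Suppress the empty row/column warning (used by generators).
#' @return An integer matrix of class `occ_matrix` with attribute
#'   `biozone`.
#' @export
#' @examples
#' m <- matrix(c(1, 1, 0, 1), 2, 2,
#'             dimnames = list(c("sp_a", "sp_b"), c("s1", "s2")))
#' occurrence_matrix(m, "Cf3")
occurrence_matrix <- function(m, biozone, quiet = FALSE) {
  stopifnot(is.matrix(m))
  assert_biozone(biozone)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("occurrence matrix needs species rownames and site colnames")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("species_ids and site_ids must be unique")
  storage.mode(m) <- "integer"
  if (anyNA(m) || any(m != 0L & m != 1L))
    stop("occurrence cells must be 0 or 1")
  empty_r <- rowSums(m) == 0L
  empty_c <- colSums(m) == 0L
  if (any(empty_r) || any(empty_c)) {
    if (!quiet)
      warning(sprintf("dropping %d empty species row(s) and %d empty site column(s) in %s",
                      sum(empty_r), sum(empty_c), biozone), call. = FALSE)
    m <- m[!empty_r, !empty_c, drop = FALSE]
  }
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  structure(m, biozone = biozone, class = c("occ_matrix", "matrix", "array"))
}

#' @export
print.occ_matrix <- function(x, ...) {
  cat(sprintf("occ_matrix [%s]: %d species x %d sites, %d presences\n",
              attr(x, "biozone"), nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Read site metadata
#'
#' @param path CSV with header `site_id,lat,lon,biozone,kind` (UTF-8).
#' @return `data.frame` with validated columns; `kind` is `"mammal"` or
#'   `"palynofloral"`.
#' @export
read_sites <- function(path) {
  s <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "lat", "lon", "biozone", "kind")
  if (!all(need %in% names(s)))
    stop("sites file must have columns: ", paste(need, collapse = ","))
  if (anyDuplicated(s$site_id))
    stop("duplicate site_id in sites file")
  if (any(s$lat < -90 | s$lat > 90) || any(s$lon < -180 | s$lon > 180))
    stop("site coordinates out of bounds")
  assert_biozone(s$biozone)
  bad <- setdiff(unique(s$kind), c("mammal", "palynofloral"))
  if (length(bad) > 0L) stop("unknown site kind: ", paste(bad, collapse = ", "))
  s[need]
}

#' Read long-format occurrences into per-biozone matrices
#'
#' Canonical input is one occurrence per row (`species_id,site_id`); the
#' biozone of each record is resolved through the site metadata. Duplicate
#' records collapse to a single presence. One binary matrix per biozone
#' containing at least one record is returned, with deterministic
#' (lexicographic) row and column order.
#'
#' @param path CSV with header `species_id,site_id`.
#' @param sites Site metadata from [read_sites()].
#' @param kind `"mammal"` or `"palynofloral"`; records must point at sites
#'   of this kind.
#' @return Named list of [occurrence_matrix()] objects, one per biozone
#'   present, in [biozones()] order.
#' @export
read_occurrences <- function(path, sites, kind = c("mammal", "palynofloral")) {
  kind <- match.arg(kind)
  occ <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species_id", "site_id") %in% names(occ)))
    stop("occurrences file must have columns species_id,site_id")
  if (nrow(occ) == 0L) stop("occurrences file is empty: ", path)
  occurrences_to_matrices(occ, sites, kind)
}

#' Build per-biozone matrices from an occurrence table
#'
#' @param occ `data.frame` with columns `species_id`, `site_id`.
#' @inheritParams read_occurrences
#' @return As [read_occurrences()].
#' @export
occurrences_to_matrices <- function(occ, sites,
                                    kind = c("mammal", "palynofloral")) {
  kind <- match.arg(kind)
  use <- sites[sites$kind == kind, , drop = FALSE]
  unknown <- !(occ$site_id %in% use$site_id)
  if (any(unknown)) {
    i <- which(unknown)[1L]
    stop(sprintf("occurrence row %d refers to unknown %s site_id '%s'",
                 i, kind, occ$site_id[i]))
  }
  occ$biozone <- use$biozone[match(occ$site_id, use$site_id)]
  out <- list()
  for (bz in biozones()) {
    rec <- unique(occ[occ$biozone == bz, c("species_id", "site_id")])
    if (nrow(rec) == 0L) next
    sp <- sort(unique(rec$species_id))
    st <- sort(unique(rec$site_id))
    m <- matrix(0L, length(sp), length(st), dimnames = list(sp, st))
    m[cbind(match(rec$species_id, sp), match(rec$site_id, st))] <- 1L
    out[[bz]] <- occurrence_matrix(m, bz)
  }
  out
}

#' Read a wide site-by-species table (convenience reader)
#'
#' Accepts the transposed layout common in spreadsheet exports: one row per
#' site, first column `site_id`, remaining columns one per species holding
#' 0/1. Post-conditions match [read_occurrences()].
#'
#' @inheritParams read_occurrences
#' @export
read_occurrences_wide <- function(path, sites,
                                  kind = c("mammal", "palynofloral")) {
  kind <- match.arg(kind)
  w <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(w)[1L] != "site_id") stop("first column must be site_id")
  long <- data.frame(
    species_id = rep(names(w)[-1L], each = nrow(w)),
    site_id = rep(w$site_id, times = ncol(w) - 1L),
    present = as.vector(as.matrix(w[, -1L, drop = FALSE])),
    stringsAsFactors = FALSE)
  long <- long[long$present == 1, c("species_id", "site_id")]
  if (nrow(long) == 0L) stop("wide occurrences file has no presences")
  occurrences_to_matrices(long, sites, kind)
}

#' Write per-biozone matrices as a long-format occurrence CSV
#'
#' Inverse of [read_occurrences()]: writing then reading reproduces cells,
#' row order and column order exactly.
#'
#' @param matrices Named list of [occurrence_matrix()] objects.
#' @param path Output CSV path.
#' @export
write_occurrences <- function(matrices, path) {
  rows <- lapply(matrices, function(m) {
    idx <- which(m == 1L, arr.ind = TRUE)
    data.frame(species_id = rownames(m)[idx[, 1L]],
               site_id = colnames(m)[idx[, 2L]], stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  long <- long[order(long$species_id, long$site_id), ]
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the species trait table (ln body mass)
#'
#' @param path CSV with header `species_id,ln_mass_g` (natural-log grams).
#' @return `data.frame` with columns `species_id`, `ln_mass`.
#' @export
read_traits <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species_id", "ln_mass_g") %in% names(tr)))
    stop("traits file must have columns species_id,ln_mass_g")
  if (anyDuplicated(tr$species_id)) stop("duplicate species_id in traits")
  if (any(!is.finite(tr$ln_mass_g))) stop("ln_mass_g must be finite")
  data.frame(species_id = tr$species_id, ln_mass = tr$ln_mass_g,
             stringsAsFactors = FALSE)
}

#' Assemble a dataset object
#'
#' @param sites Site metadata ([read_sites()] layout).
#' @param mammal_matrices,floral_matrices Named lists of per-biozone
#'   [occurrence_matrix()] objects.
#' @param traits Trait table (`species_id`, `ln_mass`).
#' @return List of class `paleo_dataset`.
#' @export
paleo_dataset <- function(sites, mammal_matrices, floral_matrices, traits) {
  structure(list(sites = sites, mammal = mammal_matrices,
                 floral = floral_matrices, traits = traits),
            class = "paleo_dataset")
}

#' @export
print.paleo_dataset <- function(x, ...) {
  cat("paleo_dataset\n")
  for (bz in names(x$mammal))
    cat(sprintf("  mammal %-6s %3d species x %3d sites\n", bz,
                nrow(x$mammal[[bz]]), ncol(x$mammal[[bz]])))
  for (bz in names(x$floral))
    cat(sprintf("  floral %-6s %3d taxa    x %3d sites\n", bz,
                nrow(x$floral[[bz]]), ncol(x$floral[[bz]])))
  cat(sprintf("  traits: %d species\n", nrow(x$traits)))
  invisible(x)
}

#' Read a dataset written by [write_dataset()] from a directory
#'
#' @param dir Directory holding `sites.csv`, `mammal_occurrences.csv`,
#'   `floral_occurrences.csv`, `traits.csv`.
#' @return A [paleo_dataset()].
#' @export
read_dataset <- function(dir) {
  sites <- read_sites(file.path(dir, "sites.csv"))
  paleo_dataset(
    sites,
    read_occurrences(file.path(dir, "mammal_occurrences.csv"), sites, "mammal"),
    read_occurrences(file.path(dir, "floral_occurrences.csv"), sites,
                     "palynofloral"),
    read_traits(file.path(dir, "traits.csv")))
}

#' Validate a dataset for the downstream pipeline
#'
#' Report-only: lists species that occur but lack a trait record, matrix
#' site ids that do not resolve to site metadata of the matching kind and
#' biozone, and -- fatal for habitat assignment -- mammal biozones with no
#' contemporaneous palynofloral site. Downstream stages refuse datasets
#' whose report has `fatal = TRUE`.
#'
#' @param d A [paleo_dataset()].
#' @return List of class `paleo_validation` with elements
#'   `missing_traits`, `unresolved_sites`, `bins_without_flora`, `fatal`.
#' @export
validate_dataset <- function(d) {
  stopifnot(inherits(d, "paleo_dataset"))
  sp <- unique(unlist(lapply(d$mammal, rownames)))
  missing_traits <- setdiff(sp, d$traits$species_id)
  unresolved <- character(0)
  for (kind in c("mammal", "floral")) {
    skind <- if (kind == "mammal") "mammal" else "palynofloral"
    for (bz in names(d[[kind]])) {
      ok <- d$sites$site_id[d$sites$kind == skind & d$sites$biozone == bz]
      unresolved <- c(unresolved, setdiff(colnames(d[[kind]][[bz]]), ok))
    }
  }
  bins_without_flora <- setdiff(names(d$mammal), names(d$floral))
  structure(list(missing_traits = missing_traits,
                 unresolved_sites = unresolved,
                 bins_without_flora = bins_without_flora,
                 fatal = length(bins_without_flora) > 0L ||
                   length(unresolved) > 0L),
            class = "paleo_validation")
}

#' @export
print.paleo_validation <- function(x, ...) {
  cat("paleo_dataset validation:",
      if (x$fatal) "FATAL problems\n" else "ok\n")
  if (length(x$missing_traits))
    cat("  species lacking traits:", length(x$missing_traits), "\n")
  if (length(x$unresolved_sites))
    cat("  unresolved matrix site ids:",
        paste(x$unresolved_sites, collapse = ", "), "\n")
  if (length(x$bins_without_flora))
    cat("  mammal bins without contemporaneous flora:",
        paste(x$bins_without_flora, collapse = ", "), "\n")
  invisible(x)
}

#' First biozone in which a species occurs
#'
#' Used to restrict per-bin summaries to first occurrences (immigrants and
#' originations), mirroring the "first occur in that time bin" subset of
#' the regional preference distributions.
#'
#' @param species_id Species key.
#' @param mammal_matrices Named list of per-biozone matrices.
#' @return A biozone label.
#' @export
first_occurrence_bin <- function(species_id, mammal_matrices) {
  for (bz in biozones()) {
    m <- mammal_matrices[[bz]]
    if (!is.null(m) && species_id %in% rownames(m)) return(bz)
  }
  stop("species '", species_id, "' occurs in no biozone")
}

#' Species-by-biozone presence table
#'
#' @param mammal_matrices Named list of per-biozone matrices.
#' @return `data.frame` with columns `species_id`, `biozone`,
#'   `first_occurrence` (logical).
#' @export
species_by_bin <- function(mammal_matrices) {
  rows <- lapply(names(mammal_matrices), function(bz)
    data.frame(species_id = rownames(mammal_matrices[[bz]]), biozone = bz,
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  first <- vapply(unique(out$species_id), first_occurrence_bin,
                  character(1), mammal_matrices = mammal_matrices)
  out$first_occurrence <- first[out$species_id] == out$biozone
  out[order(out$biozone, out$species_id), ]
}
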