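# End-to-end orchestration: one config in, every results table out.

#' Build a run configuration
#'
#' Either `input_dir` (a directory of canonical CSVs, see
#' [write_dataset()]) or `dataset` (an in-memory [paleo_dataset()]) must
#' be supplied. The master seed fans out to per-stage seeds via fixed
#' offsets (ordination +1, co-occurrence +2 per bin index, effects null
#' +10), so stages can be re-run in isolation.
#'
#' @param input_dir Directory with `sites.csv`, `mammal_occurrences.csv`,
#'   `floral_occurrences.csv`, `traits.csv`.
#' @param dataset In-memory dataset, alternative to `input_dir`.
#' @param out_dir Output directory for tables and the manifest; `NULL`
#'   keeps results in memory only.
#' @param metric Floral distance metric, `"jaccard"` or `"cosine"`.
#' @param n_restarts,nmds_maxit NMDS settings.
#' @param n_perm PERMANOVA permutations.
#' @param n_null,alpha Co-occurrence null size and per-tail level.
#' @param n_reps,n_null_inner Richness-preserving null settings.
#' @param dispersion_stat Dispersion for bin preference summaries.
#' @param sd_type Cohen's D denominator (see [effect_table()]).
#' @param seed Master seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, dataset = NULL, out_dir = NULL,
                       metric = "jaccard", n_restarts = 50,
                       nmds_maxit = 500, n_perm = 10000, n_null = 1000,
                       alpha = 0.05, n_reps = 100, n_null_inner = 200,
                       dispersion_stat = "variance",
                       sd_type = "replicate_means", seed = 42) {
  if (is.null(input_dir) && is.null(dataset))
    stop("one of input_dir or dataset is required")
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are an
#' error. Paths are interpreted relative to the YAML file's directory.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), "dataset")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (k in c("input_dir", "out_dir"))
    if (!is.null(y[[k]]) && !grepl("^/", y[[k]]))
      y[[k]] <- file.path(dirname(path), y[[k]])
  do.call(run_config, y)
}

stage_table <- function(res, name, out_dir, header) {
  if (is.null(out_dir)) return(invisible(NULL))
  path <- file.path(out_dir, paste0(name, ".csv"))
  con <- file(path, "w")
  writeLines(header, con)
  write.csv(res, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the full community-assembly analysis
#'
#' Sequences the pipeline: validate -> floral distances -> NMDS ->
#' PERMANOVA -> nearest-site habitat matching -> species preferences ->
#' pair classification per biozone -> pair census -> pair differences ->
#' type summaries -> richness-preserving null -> effect table ->
#' between-bin preference and mass tests. With `out_dir` set, every table
#' is written as CSV (each with a header comment carrying the package
#' version, seed and config hash) together with a machine-readable JSON
#' manifest (config echo, per-stage seeds, timings and row counts) that
#' suffices to reproduce the run.
#'
#' @param cfg A [run_config()] or path to a YAML config.
#' @return List of class `paleo_run` with all stage results.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time(); timings <- list()
  tick <- function(name, expr) {
    s <- Sys.time(); r <- expr
    timings[[name]] <<- round(as.numeric(Sys.time() - s, units = "secs"), 3)
    r
  }
  d <- if (!is.null(cfg$dataset)) cfg$dataset else read_dataset(cfg$input_dir)
  rep <- validate_dataset(d)
  if (rep$fatal) {
    print(rep)
    stop("dataset failed validation; see report above")
  }
  pooled <- pool_matrices(d$floral)
  dmat <- tick("distances", community_distances(pooled, cfg$metric))
  ord <- tick("nmds", nmds(dmat, n_restarts = cfg$n_restarts,
                           maxit = cfg$nmds_maxit, seed = cfg$seed + 1))
  perm <- tick("permanova", permanova(dmat, n_perm = cfg$n_perm,
                                      seed = cfg$seed + 1))
  habitats <- tick("match_sites", match_sites(d$sites, ord))
  prefs <- tick("preferences", species_preferences(d$mammal, habitats))
  pairs <- tick("classify", {
    out <- lapply(seq_along(d$mammal), function(b)
      classify_pairs(d$mammal[[b]], n_null = cfg$n_null,
                     alpha = cfg$alpha, seed = cfg$seed + 2 + b))
    names(out) <- names(d$mammal)
    out
  })
  census <- pair_census(pairs)
  diffs <- pair_differences(do.call(rbind, pairs), d$traits, prefs)
  obs_summary <- summarize_types(diffs)
  null <- tick("null_model", richness_preserving_null(
    d$mammal, habitats, d$traits, n_reps = cfg$n_reps,
    n_null_inner = cfg$n_null_inner, alpha = cfg$alpha,
    seed = cfg$seed + 10))
  effects <- effect_table(obs_summary, null, sd_type = cfg$sd_type)
  sb <- species_by_bin(d$mammal)
  pref_bins <- merge(sb, prefs, by = "species_id")
  tests <- list(
    pref1 = between_bin_tests(data.frame(biozone = pref_bins$biozone,
                                         value = pref_bins$pref1)),
    pref2 = between_bin_tests(data.frame(biozone = pref_bins$biozone,
                                         value = pref_bins$pref2)))
  mass_bins <- merge(sb, d$traits, by = "species_id")
  tests$mass <- between_bin_tests(data.frame(biozone = mass_bins$biozone,
                                             value = mass_bins$ln_mass))
  summaries <- rbind(
    bin_preference_summaries(prefs, d$mammal, "all_taxa",
                             cfg$dispersion_stat),
    bin_preference_summaries(prefs, d$mammal, "first_occurrences",
                             cfg$dispersion_stat))
  res <- structure(list(
    config = cfg, validation = rep, ordination = ord, permanova = perm,
    site_habitats = habitats, preferences = prefs, pairs = pairs,
    census = census, differences = diffs, type_summaries = obs_summary,
    null = null, effects = effects, bin_summaries = summaries,
    bin_tests = tests), class = "paleo_run")
  if (!is.null(cfg$out_dir)) write_run(res, cfg$out_dir, timings, t0)
  res
}

write_run <- function(res, out_dir, timings, t0) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg <- res$config
  cfg_echo <- unclass(cfg)
  cfg_echo$dataset <- if (is.null(cfg$dataset)) NULL else "<in-memory>"
  hashed <- cfg_echo[setdiff(names(cfg_echo), "out_dir")]  # analysis-relevant keys only
  cfg_hash <- sum(utf8ToInt(paste(
    names(hashed), vapply(hashed, function(x)
      paste(format(x), collapse = ","), character(1)), collapse = ";")))
  header <- sprintf("# paleopairs %s | seed %d | config-hash %d",
                    as.character(packageVersion("paleopairs")),
                    cfg$seed, cfg_hash)
  scores <- data.frame(site_id = rownames(res$ordination$scores),
                       biozone = res$ordination$site_biozone,
                       res$ordination$scores, stringsAsFactors = FALSE)
  stage_table(scores, "nmds_scores", out_dir, c(
    header, sprintf("# stress %.6f (interpretable: %s)",
                    res$ordination$stress, res$ordination$stress_ok)))
  pw <- res$permanova$pairwise
  overall <- data.frame(group_a = "(all)", group_b = "(all)",
                        F = res$permanova$F, p_raw = res$permanova$p,
                        p_bonferroni = NA_real_)
  stage_table(rbind(overall, pw), "permanova", out_dir, header)
  stage_table(res$site_habitats, "site_habitats", out_dir, header)
  stage_table(res$preferences, "species_preferences", out_dir, header)
  stage_table(do.call(rbind, res$pairs), "pair_results", out_dir, header)
  stage_table(res$census, "pair_census", out_dir, header)
  stage_table(res$differences, "pair_differences", out_dir, header)
  stage_table(res$type_summaries, "type_summaries", out_dir, header)
  stage_table(res$null$replicates, "null_means", out_dir, header)
  stage_table(res$effects, "effect_sizes", out_dir, header)
  stage_table(res$bin_summaries, "bin_preference_summaries", out_dir, header)
  manifest <- list(
    package = "paleopairs",
    version = as.character(packageVersion("paleopairs")),
    config = cfg_echo, config_hash = cfg_hash,
    stage_seeds = list(nmds = cfg$seed + 1, permanova = cfg$seed + 1,
                       classify = cfg$seed + 2 + seq_along(res$pairs),
                       null_model = cfg$seed + 10),
    timings_sec = timings,
    total_sec = round(as.numeric(Sys.time() - t0, units = "secs"), 3),
    row_counts = list(pairs = nrow(do.call(rbind, res$pairs)),
                      preferences = nrow(res$preferences),
                      effects = nrow(res$effects)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.paleo_run <- function(x, ...) {
  cat("paleopairs run\n")
  cat(sprintf("  NMDS stress %.4f | PERMANOVA F %.3f (p %.4g)\n",
              x$ordination$stress, x$permanova$F, x$permanova$p))
  print(x$census, row.names = FALSE)
  sig <- x$effects[which(!x$effects$absent &
                           x$effects$magnitude == "large"), ]
  cat(sprintf("  large effect sizes: %d of %d cells\n", nrow(sig),
              sum(!x$effects$absent)))
  invisible(x)
}
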