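#' Specify a synthetic metapangenome study design
#'
#' Builds the parameter object consumed by [simulate_catalog()],
#' [simulate_coverage()] and [simulate_annotations()]. The defaults describe
#' a small multi-site oral-metagenome study: a handful of closely related
#' species, each a specialist of one oral site, sequenced to ~10X mean depth
#' at its preferred site and to trace (0.05X) background depth elsewhere,
#' with overdispersed per-nucleotide coverage and shared high-coverage
#' "mobile element" segments that contaminate naive mean-depth statistics.
#'
#' @param n_species Number of species in the genome catalog.
#' @param genomes_per_species Genomes per species.
#' @param subgroups_per_species Subgroups each species is split into;
#'   subgroups are the unit that carries site preferences and planted
#'   exclusive functions.
#' @param genome_length Genome length in nucleotides (one contig per genome).
#' @param mean_gene_length Mean gene length in nucleotides; genes tile ~85%
#'   of each genome with short intergenic gaps.
#' @param sites Character vector of site labels samples are drawn from.
#' @param samples_per_site Metagenome samples per site.
#' @param preference_map Optional tibble (`group`, `site`, `multiplier`)
#'   giving the mean-depth multiplier of each subgroup at each preferred
#'   site. Default: subgroups are assigned preferred sites round-robin with
#'   multiplier 1 (strict specialists).
#' @param base_depth Mean per-nucleotide depth (X) at a preferred site.
#' @param background_depth Mean depth (X) at non-preferred sites.
#' @param dispersion Negative-binomial dispersion of per-nucleotide depth
#'   (variance = mu + dispersion * mu^2). Zero gives noise-free depth equal
#'   to the rounded mean.
#' @param spike_fraction Fraction of each genome covered by shared
#'   high-coverage segments (capped at 0.24 so the interquartile depth
#'   statistic provably excludes them).
#' @param spike_multiplier Depth multiplier applied on spike segments.
#' @param planted_exclusive_functions Optional named list: subgroup ->
#'   character vector of function accessions present only in that
#'   subgroup's genomes. Default plants three KO-style accessions per
#'   subgroup.
#' @param seed Integer root seed; all stages draw from named substreams of
#'   it, so identical designs reproduce bit-identical outputs.
#'
#' @return An object of class `sim_design` (a list with the fields above).
#' @examples
#' d <- sim_design(n_species = 2, genomes_per_species = 2,
#'                 genome_length = 5000, samples_per_site = 3, seed = 42)
#' d$sites
#' @export
sim_design <- function(n_species = 3,
                       genomes_per_species = 3,
                       subgroups_per_species = 1,
                       genome_length = 20000,
                       mean_gene_length = 900,
                       sites = c("SUPP", "TD", "BM"),
                       samples_per_site = 10,
                       preference_map = NULL,
                       base_depth = 10,
                       background_depth = 0.05,
                       dispersion = 0.5,
                       spike_fraction = 0.1,
                       spike_multiplier = 50,
                       planted_exclusive_functions = NULL,
                       seed = 1L) {
  for (fld in c("n_species", "genomes_per_species", "subgroups_per_species",
                "genome_length", "mean_gene_length", "samples_per_site")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 ||
        v != round(v)) {
      stop_metapan(sprintf("design field `%s` must be an integer >= 1", fld),
                   class = "metapanr_config_error")
    }
  }
  if (!is.character(sites) || length(sites) < 1L || anyDuplicated(sites)) {
    stop_metapan("design field `sites` must be distinct site labels",
                 class = "metapanr_config_error")
  }
  assert_scalar_number(base_depth, "base_depth", lower = 0, lower_open = TRUE)
  assert_scalar_number(background_depth, "background_depth", lower = 0)
  if (base_depth <= background_depth) {
    stop_metapan("design requires base_depth > background_depth",
                 class = "metapanr_config_error")
  }
  assert_scalar_number(dispersion, "dispersion", lower = 0)
  assert_scalar_number(spike_fraction, "spike_fraction", 0, 0.24)
  assert_scalar_number(spike_multiplier, "spike_multiplier", lower = 1)
  assert_scalar_number(seed, "seed", 0, .Machine$integer.max - 10)
  if (subgroups_per_species > genomes_per_species) {
    stop_metapan("design field `subgroups_per_species` cannot exceed genomes_per_species",
                 class = "metapanr_config_error")
  }

  species <- sprintf("sp%02d", seq_len(n_species))
  subgroups <- unlist(lapply(species, function(sp) {
    sprintf("%s.%d", sp, seq_len(subgroups_per_species))
  }))

  if (is.null(preference_map)) {
    preference_map <- tibble(
      group = subgroups,
      site = sites[(seq_along(subgroups) - 1L) %% length(sites) + 1L],
      multiplier = 1
    )
  } else {
    assert_columns(preference_map, c("group", "site", "multiplier"),
                   "preference_map")
    bad <- setdiff(preference_map$group, subgroups)
    if (length(bad) > 0) {
      stop_metapan(sprintf("preference_map names unknown subgroup(s): %s",
                           paste(bad, collapse = ", ")),
                   class = "metapanr_config_error")
    }
    if (any(preference_map$multiplier <= 0)) {
      stop_metapan("preference_map multipliers must be positive",
                   class = "metapanr_config_error")
    }
  }

  if (is.null(planted_exclusive_functions)) {
    planted_exclusive_functions <- setNames(
      lapply(subgroups, function(sg) sprintf("K_%s_excl%d", sg, 1:3)),
      subgroups
    )
  } else {
    bad <- setdiff(names(planted_exclusive_functions), subgroups)
    if (length(bad) > 0) {
      stop_metapan(sprintf("planted_exclusive_functions names unknown subgroup(s): %s",
                           paste(bad, collapse = ", ")),
                   class = "metapanr_config_error")
    }
  }

  structure(
    list(
      n_species = as.integer(n_species),
      genomes_per_species = as.integer(genomes_per_species),
      subgroups_per_species = as.integer(subgroups_per_species),
      genome_length = as.integer(genome_length),
      mean_gene_length = as.integer(mean_gene_length),
      sites = sites,
      samples_per_site = as.integer(samples_per_site),
      preference_map = preference_map,
      base_depth = base_depth,
      background_depth = background_depth,
      dispersion = dispersion,
      spike_fraction = spike_fraction,
      spike_multiplier = spike_multiplier,
      planted_exclusive_functions = planted_exclusive_functions,
      species = species,
      subgroups = subgroups,
      seed = as.integer(seed)
    ),
    class = "sim_design"
  )
}

#' @export
print.sim_design <- function(x, ...) {
  cat("<sim_design>\n")
  cat(sprintf("  %d species x %d genomes (%d subgroups/species), %s nt each\n",
              x$n_species, x$genomes_per_species, x$subgroups_per_species,
              format(x$genome_length, big.mark = ",")))
  cat(sprintf("  sites: %s (%d samples each)\n",
              paste(x$sites, collapse = ", "), x$samples_per_site))
  cat(sprintf("  depth: %gX preferred / %gX background, NB dispersion %g\n",
              x$base_depth, x$background_depth, x$dispersion))
  cat(sprintf("  spikes: %.0f%% of genome at %gx multiplier; seed %d\n",
              100 * x$spike_fraction, x$spike_multiplier, x$seed))
  invisible(x)
}
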