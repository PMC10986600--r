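#' Pipeline configuration
#'
#' Collects the file paths and thresholds of an end-to-end run. Paths
#' follow the layout written by [write_simulation()]; any stage whose
#' inputs are absent is skipped unless explicitly requested.
#'
#' @param input_dir Directory holding the input tables (catalog.tsv,
#'   contigs.tsv, metadata.tsv, coverage/, qc.tsv, ani.tsv,
#'   annotations.tsv, modules.tsv, gene_clusters.tsv, genes.gff3).
#' @param output_dir Directory the stage outputs and manifest are written
#'   to.
#' @param min_breadth Genome detection threshold on breadth (inclusive).
#' @param gene_threshold Gene detection threshold on covered fraction.
#' @param module_threshold Module completion threshold.
#' @param ani_threshold Dereplication ANI ceiling (percent).
#' @param min_completeness,max_contamination Genome QC bounds (percent).
#' @param tau Dominance threshold for the reciprocal-dominance test.
#' @param n_permutations Permutations for the dominance test.
#' @param dominance_taxa Focal species for the dominance test (default:
#'   the three most abundant species at `dominance_site`).
#' @param dominance_site Site whose samples enter the dominance test
#'   (NULL: all samples).
#' @param samples_per_site Samples retained per site in the gene
#'   detection map.
#' @param seed Root seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            min_breadth = 0.5, gene_threshold = 0.9,
                            module_threshold = 0.75, ani_threshold = 98,
                            min_completeness = 90, max_contamination = 5,
                            tau = 0.3, n_permutations = 1000,
                            dominance_taxa = NULL, dominance_site = NULL,
                            samples_per_site = 30, seed = 1L) {
  assert_scalar_number(min_breadth, "min_breadth", 0, 1)
  assert_scalar_number(gene_threshold, "gene_threshold", 0, 1)
  assert_scalar_number(module_threshold, "module_threshold", 0, 1)
  assert_scalar_number(ani_threshold, "ani_threshold", 0, 100)
  assert_scalar_number(min_completeness, "min_completeness", 0, 100)
  assert_scalar_number(max_contamination, "max_contamination", 0, 100)
  structure(
    list(input_dir = input_dir, output_dir = output_dir,
         min_breadth = min_breadth, gene_threshold = gene_threshold,
         module_threshold = module_threshold, ani_threshold = ani_threshold,
         min_completeness = min_completeness,
         max_contamination = max_contamination,
         tau = tau, n_permutations = n_permutations,
         dominance_taxa = dominance_taxa, dominance_site = dominance_site,
         samples_per_site = samples_per_site, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the metapangenomic pipeline end to end
#'
#' Executes, in order: genome prep (QC + dereplication), genome detection,
#' Q2Q3 relative abundance and species aggregation, Bray-Curtis ordering,
#' gene detection maps, the reciprocal-dominance test, module completeness
#' and function/module enrichment. Every stage writes a TSV under the
#' output directory, and a manifest records stage, outputs, parameters and
#' md5 checksums; reruns with identical inputs and seed reproduce
#' identical checksums.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest tibble (also written as
#'   `manifest.tsv`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop_metapan("`config` must be created by pipeline_config()",
                 class = "metapanr_config_error")
  }
  ind <- config$input_dir
  outd <- config$output_dir
  dir.create(outd, recursive = TRUE, showWarnings = FALSE)
  need <- function(f) {
    path <- file.path(ind, f)
    if (!file.exists(path)) {
      stop_metapan(sprintf("pipeline input missing: %s", f),
                   class = "metapanr_config_error")
    }
    path
  }
  tsv <- function(f) readr::read_tsv(need(f), show_col_types = FALSE)
  manifest <- list()
  note <- function(stage, files, params = "") {
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = stage, output = files,
      checksum = unname(tools::md5sum(file.path(outd, files))),
      params = params, seed = config$seed
    )
    rlang::inform(sprintf("[%s] wrote %s (%s)", stage,
                          paste(files, collapse = ", "), params))
  }
  emit <- function(df, f) {
    readr::write_tsv(df, file.path(outd, f))
    f
  }

  catalog <- tsv("catalog.tsv")
  contigs <- tsv("contigs.tsv")
  metadata <- tsv("metadata.tsv")

  # -- prep: QC filter + ANI dereplication ------------------------------
  qc <- qc_filter(tsv("qc.tsv"),
                  min_completeness = config$min_completeness,
                  max_contamination = config$max_contamination)
  reps <- dereplicate(read_ani_matrix(need("ani.tsv")), qc,
                      threshold = config$ani_threshold)
  kept <- reps$genome_id[reps$representative]
  note("prep", emit(reps, "representatives.tsv"),
       sprintf("min_completeness=%g max_contamination=%g ani_threshold=%g",
               config$min_completeness, config$max_contamination,
               config$ani_threshold))

  # -- coverage: detection + abundance ----------------------------------
  cov_dir <- need("coverage")
  files <- list.files(cov_dir, pattern = "\\.tsv$", full.names = TRUE)
  paths <- setNames(files, sub("\\.tsv$", "", basename(files)))
  profiles <- read_coverage_set(paths, contigs, metadata = metadata) |>
    filter(.data$genome_id %in% kept)
  detection <- detect_genomes(profiles, min_breadth = config$min_breadth)
  note("detect", emit(detection, "detection.tsv"),
       sprintf("min_breadth=%g", config$min_breadth))

  abundance <- relative_abundance(profiles, detection)
  species_map <- select(catalog, "genome_id", "species")
  species_ab <- aggregate_species_abundance(abundance, species_map)
  ord <- order_by_bray_curtis(species_ab)
  note("abundance",
       c(emit(select(abundance, -any_of("depth")), "abundance.tsv"),
         emit(species_ab, "species_abundance.tsv"),
         emit(tibble(species = ord$row_order), "row_order.tsv"),
         emit(tibble(sample_id = ord$col_order), "col_order.tsv")),
       "denominator=all-reference-genomes")

  # -- gene detection ----------------------------------------------------
  genes <- read_gene_models(need("genes.gff3"), "gff3", contigs) |>
    filter(.data$genome_id %in% kept)
  gmaps <- purrr::map(unique(genes$genome_id), function(gid) {
    gm <- gene_detection_map(filter(profiles, .data$genome_id == gid),
                             filter(genes, .data$genome_id == gid),
                             contigs = contigs,
                             samples_per_site = config$samples_per_site,
                             gene_threshold = config$gene_threshold)
    gm$detection |> select(-any_of("depth"))
  }) |> list_rbind()
  note("gene-detect", emit(gmaps, "gene_detection.tsv"),
       sprintf("gene_threshold=%g samples_per_site=%d",
               config$gene_threshold, config$samples_per_site))

  # -- reciprocal dominance ---------------------------------------------
  dom_ab <- species_ab
  if (!is.null(config$dominance_site)) {
    dom_ab <- filter(dom_ab, .data$site == config$dominance_site)
  }
  taxa <- config$dominance_taxa %||% {
    dom_ab |>
      group_by(.data$species) |>
      summarise(total = sum(.data$abundance), .groups = "drop") |>
      arrange(desc(.data$total)) |>
      head(3) |>
      pull("species")
  }
  dom <- dominance_test(rename(dom_ab, taxon = "species"), taxa = taxa,
                        tau = config$tau,
                        n_permutations = config$n_permutations,
                        seed = config$seed)
  note("dominance",
       c(emit(glance(dom), "dominance.tsv"),
         emit(tidy(dom), "dominance_labels.tsv")),
       sprintf("tau=%g n_permutations=%d taxa=%s", config$tau,
               config$n_permutations, paste(taxa, collapse = "+")))

  # -- modules + enrichment ---------------------------------------------
  annotations <- tsv("annotations.tsv") |>
    filter(.data$genome_id %in% kept)
  modules <- tsv("modules.tsv")
  compl <- module_completeness(annotations, modules,
                               threshold = config$module_threshold,
                               genomes = kept)
  note("modules", emit(compl, "module_completeness.tsv"),
       sprintf("module_threshold=%g", config$module_threshold))

  groups <- catalog |>
    filter(.data$genome_id %in% kept) |>
    transmute(.data$genome_id, group = .data$subgroup)
  enr_fun <- enrich_functions(annotations, groups)
  enr_mod <- enrich_modules(compl, groups)
  note("enrich",
       c(emit(enr_fun, "enrichment_functions.tsv"),
         emit(enr_mod, "enrichment_modules.tsv")),
       "groups=subgroup method=score-test fdr=BH")

  manifest <- list_rbind(manifest)
  readr::write_tsv(manifest, file.path(outd, "manifest.tsv"))
  invisible(manifest)
}
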