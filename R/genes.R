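## Gene-level read-recruitment analytics.
##
## Gene coordinates are 0-based half-open on their contig; contigs are
## concatenated in catalog order to form the genome-level depth vector, so
## a gene's positions inside that vector are offset + (start:end].

gene_positions <- function(gene_start, gene_end, offset, genome_length) {
  if (gene_start < 0 || gene_end <= gene_start ||
      offset + gene_end > genome_length) {
    stop_metapan(
      sprintf("gene [%d, %d) lies outside its contig/genome bounds",
              gene_start, gene_end),
      class = "metapanr_input_error"
    )
  }
  (offset + gene_start + 1L):(offset + gene_end)
}

#' Covered fraction of a gene
#'
#' Fraction of a gene's nucleotide positions with depth at least
#' `min_depth`. Strand plays no role. A gene counts as detected when at
#' least 90% of its nucleotides are covered at >= 1X — the slack below
#' 100% tolerates small differences between reference and environmental
#' genomes.
#'
#' @param depths Genome-level depth vector (contigs concatenated).
#' @param start,end 0-based half-open gene coordinates on its contig.
#' @param offset Contig offset within the concatenated genome vector.
#' @param min_depth Depth floor defining "covered".
#' @return Fraction in \[0, 1\].
#' @examples
#' gene_covered_fraction(c(1, 1, 0, 2, 3), start = 0, end = 4)
#' @export
gene_covered_fraction <- function(depths, start, end, offset = 0L,
                                  min_depth = 1) {
  pos <- gene_positions(start, end, offset, length(depths))
  mean(depths[pos] >= min_depth)
}

gene_offsets <- function(genes, contigs = NULL) {
  assert_columns(genes, c("gene_id", "genome_id", "contig_id", "start", "end"),
                 "genes")
  if (is.null(contigs)) {
    return(mutate(genes, offset = 0L))
  }
  assert_columns(contigs, c("contig_id", "offset"), "contigs")
  out <- genes |>
    left_join(select(contigs, "contig_id", "offset"), by = "contig_id")
  if (anyNA(out$offset)) {
    stop_metapan("gene references a contig absent from the contig table",
                 class = "metapanr_input_error")
  }
  out
}

#' Per-gene coverage across samples
#'
#' Computes the covered fraction and mean depth of every gene in every
#' coverage profile of its genome.
#'
#' @param profiles Coverage tibble (`genome_id`, `sample_id`, list-column
#'   `depth`, optional `site`).
#' @param genes Gene models (`gene_id`, `genome_id`, `contig_id`, `start`,
#'   `end`; 0-based half-open).
#' @param contigs Optional contig table (`contig_id`, `offset`) for
#'   multi-contig genomes; single-contig genomes may omit it.
#' @param min_depth Depth floor defining "covered".
#' @return Tibble with one row per (gene, sample): `covered_fraction` and
#'   `mean_depth`.
#' @export
gene_coverage <- function(profiles, genes, contigs = NULL, min_depth = 1) {
  check_profiles(profiles)
  genes <- gene_offsets(genes, contigs)
  cells <- inner_join(profiles, genes, by = "genome_id",
                      relationship = "many-to-many")
  cells |>
    mutate(
      covered_fraction = pmap_dbl(
        list(.data$depth, .data$start, .data$end, .data$offset),
        function(d, s, e, o) gene_covered_fraction(d, s, e, o, min_depth)
      ),
      mean_depth = pmap_dbl(
        list(.data$depth, .data$start, .data$end, .data$offset),
        function(d, s, e, o) mean(d[gene_positions(s, e, o, length(d))])
      )
    ) |>
    select(any_of(c("gene_id", "genome_id", "contig_id", "sample_id", "site",
                    "covered_fraction", "mean_depth")))
}

#' Gene detection map over top-coverage samples
#'
#' Builds the per-site binary gene detection map for one genome: for each
#' site the `samples_per_site` samples with the greatest genome-wide median
#' depth are selected (all of them when fewer exist; ties broken by sample
#' id), a gene is detected in a sample when at least `gene_threshold` of
#' its nucleotides have >= `min_depth` coverage, genes are ordered by
#' overall detection frequency (descending, ties by gene id) and samples
#' within a site by the proportion of genes they detect.
#'
#' @inheritParams gene_coverage
#' @param metadata Optional `sample_id` -> `site` table; required when the
#'   profiles carry no `site` column.
#' @param samples_per_site Number of top-median-coverage samples retained
#'   per site.
#' @param gene_threshold Covered-fraction threshold for gene detection
#'   (inclusive).
#' @return Object of class `gene_detection_map`: list with `detection`
#'   (gene x selected sample long tibble), `site_frequency` (per gene and
#'   site), `gene_order`, `sample_order` and `selected_samples`.
#' @export
gene_detection_map <- function(profiles, genes, contigs = NULL,
                               metadata = NULL, samples_per_site = 30,
                               gene_threshold = 0.9, min_depth = 1) {
  check_profiles(profiles)
  if (!"site" %in% names(profiles)) {
    if (is.null(metadata)) {
      stop_metapan("profiles carry no `site`; supply `metadata`",
                   class = "metapanr_input_error")
    }
    assert_columns(metadata, c("sample_id", "site"), "metadata")
    profiles <- left_join(profiles, metadata, by = "sample_id")
  }
  if (anyNA(profiles$site)) {
    stop_metapan("some samples have no site label",
                 class = "metapanr_input_error")
  }

  selected <- profiles |>
    mutate(median_depth = map_dbl(.data$depth, median)) |>
    group_by(.data$sample_id, .data$site) |>
    summarise(median_depth = max(.data$median_depth), .groups = "drop") |>
    group_by(.data$site) |>
    arrange(desc(.data$median_depth), .data$sample_id, .by_group = TRUE) |>
    slice_head(n = samples_per_site) |>
    ungroup()
  empty_sites <- setdiff(unique(profiles$site), selected$site)
  if (length(empty_sites) > 0) {
    rlang::warn(sprintf("site(s) without samples skipped: %s",
                        paste(empty_sites, collapse = ", ")))
  }

  detection <- gene_coverage(
    semi_join(profiles, selected, by = "sample_id"),
    genes, contigs, min_depth = min_depth
  ) |>
    mutate(detected = .data$covered_fraction >= gene_threshold)

  site_frequency <- detection |>
    group_by(.data$gene_id, .data$site) |>
    summarise(frequency = mean(.data$detected), .groups = "drop")

  gene_order <- detection |>
    group_by(.data$gene_id) |>
    summarise(frequency = mean(.data$detected), .groups = "drop") |>
    arrange(desc(.data$frequency), .data$gene_id) |>
    pull("gene_id")

  sample_order <- detection |>
    group_by(.data$sample_id, site = site_factor(.data$site)) |>
    summarise(prop_detected = mean(.data$detected), .groups = "drop") |>
    arrange(.data$site, desc(.data$prop_detected), .data$sample_id) |>
    pull("sample_id")

  structure(
    list(detection = detection, site_frequency = site_frequency,
         gene_order = gene_order, sample_order = sample_order,
         selected_samples = selected,
         gene_threshold = gene_threshold, min_depth = min_depth),
    class = "gene_detection_map"
  )
}

#' @export
print.gene_detection_map <- function(x, ...) {
  cat(sprintf("<gene_detection_map> %d genes x %d samples (%d sites), gene threshold %.2f\n",
              length(x$gene_order), length(x$sample_order),
              length(unique(x$selected_samples$site)), x$gene_threshold))
  invisible(x)
}

#' Core/accessory classification of gene clusters
#'
#' A gene cluster is core for a species when it is present (copy count
#' >= 1) in at least `core_fraction` of that species' genomes, and
#' accessory otherwise. The default demands presence in every genome.
#'
#' @param gene_clusters Long tibble (`cluster_id`, `genome_id`, `count`);
#'   absent combinations may simply be missing rows.
#' @param species_map `genome_id` -> `species` table covering every genome
#'   of interest (this table defines each species' genome count).
#' @param core_fraction Presence fraction at or above which a cluster is
#'   core.
#' @return Tibble with one row per (cluster, species with >= 1 carrier):
#'   `n_genomes`, `n_present`, and `label` ("core"/"accessory").
#' @export
classify_core_accessory <- function(gene_clusters, species_map,
                                    core_fraction = 1.0) {
  assert_columns(gene_clusters, c("cluster_id", "genome_id", "count"),
                 "gene_clusters")
  assert_columns(species_map, c("genome_id", "species"), "species_map")
  sizes <- species_map |> count(.data$species, name = "n_genomes")
  if (any(sizes$n_genomes == 0)) {
    stop_metapan("species with zero genomes", class = "metapanr_input_error")
  }
  unmapped <- setdiff(unique(gene_clusters$genome_id), species_map$genome_id)
  if (length(unmapped) > 0) {
    stop_metapan(sprintf("genome(s) missing from species_map: %s",
                         paste(unmapped, collapse = ", ")),
                 class = "metapanr_input_error")
  }
  gene_clusters |>
    filter(.data$count >= 1) |>
    left_join(species_map, by = "genome_id") |>
    distinct(.data$cluster_id, .data$species, .data$genome_id) |>
    count(.data$cluster_id, .data$species, name = "n_present") |>
    left_join(sizes, by = "species") |>
    mutate(label = ifelse(.data$n_present >= core_fraction * .data$n_genomes,
                          "core", "accessory")) |>
    select("cluster_id", "species", "n_genomes", "n_present", "label") |>
    arrange(.data$cluster_id, .data$species)
}

#' Mean gene coverage per site
#'
#' Mean depth over a gene's positions, averaged across the samples of each
#' site — the statistic used to check whether genes enriched in one genome
#' group actually recruit reads from the corresponding habitat.
#'
#' @inheritParams gene_detection_map
#' @return Tibble with one row per (gene, site): `mean_depth`.
#' @export
gene_mean_coverage_by_site <- function(profiles, genes, contigs = NULL,
                                       metadata = NULL) {
  check_profiles(profiles)
  if (!"site" %in% names(profiles)) {
    if (is.null(metadata)) {
      stop_metapan("profiles carry no `site`; supply `metadata`",
                   class = "metapanr_input_error")
    }
    profiles <- left_join(profiles, metadata, by = "sample_id")
  }
  gene_coverage(profiles, genes, contigs) |>
    group_by(.data$gene_id, .data$genome_id, .data$site) |>
    summarise(mean_depth = mean(.data$mean_depth), .groups = "drop") |>
    arrange(.data$gene_id, .data$site)
}
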