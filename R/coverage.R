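#' Breadth of coverage of a depth vector
#'
#' Fraction of nucleotide positions covered at depth of at least
#' `min_depth` (1X by default, inclusive).
#'
#' @param depths Non-negative integer/numeric vector, one value per
#'   nucleotide position.
#' @param min_depth Minimum depth for a position to count as covered.
#' @return Fraction in \[0, 1\].
#' @examples
#' breadth_of_coverage(c(0, 0, 1, 3, 2))
#' @export
breadth_of_coverage <- function(depths, min_depth = 1) {
  if (length(depths) == 0) {
    stop_metapan("depth vector is empty", class = "metapanr_input_error")
  }
  mean(depths >= min_depth)
}

#' Interquartile (Q2Q3) mean depth
#'
#' Robust mean depth: positions are ranked by depth and the mean is taken
#' over the middle half — 0-based rank indices `floor(n/4)` through
#' `ceiling(3n/4) - 1` of the sorted vector. The top quarter of positions
#' is excluded, so coverage spikes from mobile elements or conserved
#' regions shared across taxa do not inflate the statistic. For n < 4 the
#' slice spans the whole vector, i.e. the plain mean.
#'
#' @inheritParams breadth_of_coverage
#' @return Mean depth over the interquartile positions, between
#'   `min(depths)` and `max(depths)`.
#' @examples
#' q2q3_mean_depth(1:8)                        # mean(3,4,5,6) = 4.5
#' q2q3_mean_depth(c(rep(0, 4), rep(100, 4)))  # 50
#' @export
q2q3_mean_depth <- function(depths) {
  n <- length(depths)
  if (n == 0) {
    stop_metapan("depth vector is empty", class = "metapanr_input_error")
  }
  s <- sort(depths, method = "radix")
  lo <- floor(n / 4) + 1          # 1-based
  hi <- ceiling(3 * n / 4)
  mean(s[lo:hi])
}

check_profiles <- function(profiles) {
  assert_columns(profiles, c("genome_id", "sample_id", "depth"), "profiles")
  dup <- profiles |> count(.data$genome_id, .data$sample_id) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_metapan(sprintf("duplicate coverage profile for (%s, %s)",
                         dup$genome_id[1], dup$sample_id[1]),
                 class = "metapanr_input_error")
  }
  invisible(profiles)
}

#' Genome detection from breadth of coverage
#'
#' A genome is detected in a sample when its breadth of coverage at >= 1X
#' is at least `min_breadth` (50% by default, inclusive). Profiles are
#' completed to the full genome x sample grid; missing cells are treated
#' as zero coverage (competitive mapping emits nothing for unmapped
#' genomes).
#'
#' @param profiles Tibble with columns `genome_id`, `sample_id`, a
#'   list-column `depth` of per-nucleotide depth vectors, and optionally
#'   `site` (carried through).
#' @param min_breadth Detection threshold on breadth (inclusive).
#' @param min_depth Per-position depth floor defining "covered".
#' @return Tibble with one row per (genome, sample): `breadth` in \[0, 1\]
#'   and logical `detected`.
#' @export
detect_genomes <- function(profiles, min_breadth = 0.5, min_depth = 1) {
  check_profiles(profiles)
  out <- profiles |>
    mutate(breadth = map_dbl(.data$depth, breadth_of_coverage,
                             min_depth = min_depth)) |>
    select(-"depth") |>
    complete(genome_id = unique(profiles$genome_id),
             sample_id = unique(profiles$sample_id),
             fill = list(breadth = 0)) |>
    mutate(detected = .data$breadth >= min_breadth)
  if ("site" %in% names(profiles)) {
    out <- out |>
      select(-any_of("site")) |>
      left_join(distinct(profiles, .data$sample_id, .data$site),
                by = "sample_id") |>
      relocate("site", .after = "sample_id")
  }
  arrange(out, .data$genome_id, .data$sample_id)
}

#' Q2Q3-based relative abundance
#'
#' For every sample in which at least one reference genome is detected,
#' the relative abundance of genome g is its Q2Q3 mean depth divided by
#' the summed Q2Q3 mean depths of *all* reference genomes in that sample
#' (not only the detected ones). Samples where no genome is detected are
#' excluded entirely.
#'
#' @param profiles As in [detect_genomes()].
#' @param detection A [detect_genomes()] result computed from the same
#'   profiles; computed on the fly when omitted.
#' @inheritParams detect_genomes
#' @return Tibble with one row per (genome, included sample): `q2q3`,
#'   `abundance` (summing to 1 over genomes within each sample), and
#'   `detected`.
#' @export
relative_abundance <- function(profiles, detection = NULL,
                               min_breadth = 0.5, min_depth = 1) {
  check_profiles(profiles)
  if (is.null(detection)) {
    detection <- detect_genomes(profiles, min_breadth = min_breadth,
                                min_depth = min_depth)
  }
  assert_columns(detection, c("genome_id", "sample_id", "detected"),
                 "detection")
  included <- detection |>
    group_by(.data$sample_id) |>
    summarise(included = any(.data$detected), .groups = "drop") |>
    filter(.data$included)

  q2q3 <- profiles |>
    mutate(q2q3 = map_dbl(.data$depth, q2q3_mean_depth)) |>
    select(-"depth") |>
    complete(genome_id = unique(profiles$genome_id),
             sample_id = unique(profiles$sample_id),
             fill = list(q2q3 = 0)) |>
    semi_join(included, by = "sample_id")

  out <- q2q3 |>
    group_by(.data$sample_id) |>
    mutate(total = sum(.data$q2q3)) |>
    ungroup()
  if (any(out$total <= 0)) {
    # detection at >=50% breadth of >=1X forces a positive Q2Q3 total
    stop_metapan("included sample has zero total Q2Q3 depth",
                 class = "metapanr_degenerate_sample_error")
  }
  out <- out |>
    mutate(abundance = .data$q2q3 / .data$total) |>
    select(-"total") |>
    left_join(select(detection, "genome_id", "sample_id", "detected"),
              by = c("genome_id", "sample_id"))
  if ("site" %in% names(profiles)) {
    out <- out |>
      select(-any_of("site")) |>
      left_join(distinct(profiles, .data$sample_id, .data$site),
                by = "sample_id") |>
      relocate("site", .after = "sample_id")
  }
  arrange(out, .data$genome_id, .data$sample_id)
}

#' Aggregate genome abundances to species
#'
#' Species relative abundance in a sample is the sum of the relative
#' abundances of that species' member genomes.
#'
#' @param abundance A [relative_abundance()] result.
#' @param species_map Data frame mapping `genome_id` to `species` (each
#'   genome exactly once).
#' @return Tibble with one row per (species, sample): `abundance`, plus
#'   `site` when present in the input.
#' @export
aggregate_species_abundance <- function(abundance, species_map) {
  assert_columns(abundance, c("genome_id", "sample_id", "abundance"),
                 "abundance")
  assert_columns(species_map, c("genome_id", "species"), "species_map")
  if (anyDuplicated(species_map$genome_id)) {
    stop_metapan("species_map maps a genome to more than one species",
                 class = "metapanr_input_error")
  }
  unmapped <- setdiff(unique(abundance$genome_id), species_map$genome_id)
  if (length(unmapped) > 0) {
    stop_metapan(sprintf("genome(s) missing from species_map: %s",
                         paste(unmapped, collapse = ", ")),
                 class = "metapanr_input_error")
  }
  grouping <- c("species", "sample_id",
                intersect("site", names(abundance)))
  abundance |>
    left_join(select(species_map, "genome_id", "species"), by = "genome_id") |>
    group_by(across(all_of(grouping))) |>
    summarise(abundance = sum(.data$abundance), .groups = "drop") |>
    arrange(.data$species, .data$sample_id)
}

#' Bray-Curtis leaf ordering of an abundance matrix
#'
#' Orders species (rows) and samples (columns) by average-linkage
#' hierarchical clustering of Bray-Curtis distances, the convention used
#' for relative-abundance heatmaps. When a `site` column is present,
#' samples are clustered within each site block and sites keep the
#' canonical oral ordering.
#'
#' @param species_abundance Long tibble from
#'   [aggregate_species_abundance()] (`species`, `sample_id`, `abundance`,
#'   optional `site`).
#' @return List with character vectors `row_order` (species) and
#'   `col_order` (sample ids).
#' @export
order_by_bray_curtis <- function(species_abundance) {
  assert_columns(species_abundance, c("species", "sample_id", "abundance"),
                 "species_abundance")
  wide <- species_abundance |>
    select("species", "sample_id", "abundance") |>
    pivot_wider(names_from = "sample_id", values_from = "abundance",
                values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$species
  if (any(m < 0)) {
    stop_metapan("abundances must be non-negative",
                 class = "metapanr_input_error")
  }

  leaf_order <- function(x) {
    # rows of x are the objects to order
    if (nrow(x) <= 2) return(rownames(x))
    zero <- rowSums(x) == 0
    if (any(zero)) {
      rlang::inform("all-zero profiles present; their pairwise Bray-Curtis distance is taken as 0")
    }
    d <- if (any(zero)) {
      suppressWarnings(vegan::vegdist(x, method = "bray", na.rm = FALSE))
    } else {
      vegan::vegdist(x, method = "bray", na.rm = FALSE)
    }
    d[!is.finite(d)] <- 0  # all-zero pairs: 0/0 -> 0 by convention
    rownames(x)[hclust(d, method = "average")$order]
  }

  row_order <- leaf_order(m)
  if ("site" %in% names(species_abundance)) {
    sites <- species_abundance |>
      distinct(.data$sample_id, .data$site) |>
      mutate(site = site_factor(.data$site)) |>
      arrange(.data$site)
    col_order <- unlist(lapply(split(sites$sample_id, sites$site, drop = TRUE),
                               function(ids) {
                                 leaf_order(t(m[, ids, drop = FALSE]))
                               }), use.names = FALSE)
  } else {
    col_order <- leaf_order(t(m))
  }
  list(row_order = row_order, col_order = col_order)
}
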