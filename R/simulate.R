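#' Simulate a genome catalog with gene models and ground truth
#'
#' Generates the reference-genome side of a synthetic metapangenome study:
#' one random nucleotide sequence per genome, non-overlapping gene models
#' tiling at least 80% of each genome, subgroup/site-preference assignments,
#' and the coordinates of shared high-coverage "mobile element" segments.
#' Spike segments are placed at identical coordinates in every genome so
#' that cross-mapping between related genomes is emulated by construction.
#'
#' All randomness is drawn from the design's catalog substream, so the same
#' design yields byte-identical output on every call.
#'
#' @param design A [sim_design()] object.
#' @return An object of class `sim_catalog`: a list with tibbles `genomes`
#'   (genome_id, species, subgroup, length), `contigs` (genome_id,
#'   contig_id, length, offset), `genes` (gene_id, genome_id, contig_id,
#'   start, end, strand; 0-based half-open), a `DNAStringSet` `sequences`,
#'   the ground `truth` list and the `design`.
#' @examples
#' cat6 <- simulate_catalog(sim_design(n_species = 2, genomes_per_species = 3,
#'                                     genome_length = 5000, seed = 7))
#' nrow(cat6$genomes)
#' @export
simulate_catalog <- function(design) {
  if (!inherits(design, "sim_design")) {
    stop_metapan("`design` must be created by sim_design()",
                 class = "metapanr_config_error")
  }
  withr::with_seed(substream(design$seed, "catalog"), {
    genomes <- expand_grid(species = design$species,
                           g = seq_len(design$genomes_per_species)) |>
      mutate(
        subgroup = sprintf("%s.%d", .data$species,
                           (.data$g - 1L) %% design$subgroups_per_species + 1L),
        genome_id = sprintf("%s_g%02d", .data$species, .data$g),
        length = design$genome_length
      ) |>
      select("genome_id", "species", "subgroup", "length")

    contigs <- genomes |>
      transmute(genome_id = .data$genome_id,
                contig_id = paste0(.data$genome_id, "_c1"),
                length = .data$length,
                offset = 0L)

    seqs <- Biostrings::DNAStringSet(vapply(
      contigs$contig_id,
      function(cid) paste(sample(c("A", "C", "G", "T"), design$genome_length,
                                 replace = TRUE), collapse = ""),
      character(1)
    ))
    names(seqs) <- contigs$contig_id

    gap <- max(1L, round(design$mean_gene_length * 0.15 / 0.85))
    genes <- purrr::pmap(
      list(genomes$genome_id, contigs$contig_id),
      function(gid, cid) {
        L <- design$genome_length
        mgl <- design$mean_gene_length
        starts <- integer(0); ends <- integer(0)
        pos <- 0L
        repeat {
          len <- round(rnorm(1, mgl, 0.1 * mgl))
          len <- as.integer(min(max(len, max(90, 0.5 * mgl)), 1.5 * mgl))
          if (pos + len > L) break
          starts <- c(starts, pos); ends <- c(ends, pos + len)
          pos <- pos + len + gap
        }
        if (L - pos >= 90L) {  # fill the tail so short genomes stay >=80% genic
          starts <- c(starts, pos); ends <- c(ends, L)
        }
        tibble(
          gene_id = sprintf("%s_gene%04d", gid, seq_along(starts)),
          genome_id = gid, contig_id = cid,
          start = starts, end = ends,
          strand = sample(c("+", "-"), length(starts), replace = TRUE)
        )
      }
    ) |> list_rbind()

    # Shared spike intervals: same coordinates in every genome.
    spikes <- if (design$spike_fraction > 0) {
      n_seg <- 3L
      seg_len <- max(1L, floor(design$spike_fraction * design$genome_length / n_seg))
      anchors <- floor(seq(0, design$genome_length - seg_len, length.out = n_seg))
      tibble(segment = seq_len(n_seg),
             start = as.integer(anchors),
             end = as.integer(anchors + seg_len))
    } else {
      tibble(segment = integer(0), start = integer(0), end = integer(0))
    }

    preferred <- design$preference_map |>
      rename(subgroup = "group") |>
      inner_join(distinct(genomes, .data$genome_id, .data$subgroup),
                 by = "subgroup", relationship = "many-to-many") |>
      select("genome_id", "subgroup", "site", "multiplier")

    truth <- list(
      genomes = genomes,
      preferred_sites = preferred,
      spikes = spikes,
      exclusive_functions = tibble(
        accession = unlist(design$planted_exclusive_functions, use.names = FALSE),
        subgroup = rep(names(design$planted_exclusive_functions),
                       lengths(design$planted_exclusive_functions))
      )
    )

    structure(list(genomes = genomes, contigs = contigs, genes = genes,
                   sequences = seqs, truth = truth, design = design),
              class = "sim_catalog")
  })
}

#' @export
print.sim_catalog <- function(x, ...) {
  cat(sprintf("<sim_catalog> %d genomes, %d genes, %s nt each\n",
              nrow(x$genomes), nrow(x$genes),
              format(x$design$genome_length, big.mark = ",")))
  invisible(x)
}

#' Simulate site-structured per-nucleotide coverage profiles
#'
#' Draws a per-nucleotide depth vector for every (genome, sample) cell. The
#' mean depth of genome g in a sample from site m is `base_depth *
#' multiplier` when m is a preferred site of g's subgroup and
#' `background_depth` otherwise; spike segments have their mean multiplied
#' by `spike_multiplier`. Depths are negative-binomial with variance
#' `mu + dispersion * mu^2`; dispersion 0 short-circuits to the rounded
#' mean (noise-free).
#'
#' @param catalog A [simulate_catalog()] result.
#' @param design,truth Override the catalog's own design/truth (rarely
#'   needed).
#' @return A tibble with one row per (genome, sample): `genome_id`,
#'   `sample_id`, `site` and a list-column `depth` of integer vectors of
#'   genome length.
#' @examples
#' cat2 <- simulate_catalog(sim_design(n_species = 1, genomes_per_species = 1,
#'                                     genome_length = 2000,
#'                                     samples_per_site = 2, seed = 3))
#' prof <- simulate_coverage(cat2)
#' prof[, c("genome_id", "sample_id", "site")]
#' @export
simulate_coverage <- function(catalog, design = catalog$design,
                              truth = catalog$truth) {
  if (!inherits(catalog, "sim_catalog")) {
    stop_metapan("`catalog` must be created by simulate_catalog()",
                 class = "metapanr_config_error")
  }
  metadata <- expand_grid(site = design$sites,
                          i = seq_len(design$samples_per_site)) |>
    transmute(sample_id = sprintf("%s_s%02d", .data$site, .data$i),
              site = .data$site)

  L <- design$genome_length
  spike_mask <- rep(FALSE, L)
  if (nrow(truth$spikes) > 0) {
    for (k in seq_len(nrow(truth$spikes))) {
      spike_mask[(truth$spikes$start[k] + 1L):truth$spikes$end[k]] <- TRUE
    }
  }

  pref <- truth$preferred_sites
  cells <- expand_grid(genome_id = catalog$genomes$genome_id,
                       metadata) |>
    left_join(pref, by = c("genome_id", "site")) |>
    mutate(mu = ifelse(is.na(.data$multiplier),
                       design$background_depth,
                       design$base_depth * .data$multiplier))

  withr::with_seed(substream(design$seed, "coverage"), {
    depth <- purrr::map(cells$mu, function(mu) {
      mu_vec <- rep(mu, L)
      mu_vec[spike_mask] <- mu_vec[spike_mask] * design$spike_multiplier
      if (design$dispersion == 0) {
        as.integer(round(mu_vec))
      } else {
        as.integer(rnbinom(L, mu = mu_vec, size = 1 / design$dispersion))
      }
    })
    cells |>
      transmute(.data$genome_id, .data$sample_id, .data$site,
                depth = depth)
  })
}

#' Simulate gene-cluster, annotation and metabolic-module tables
#'
#' Emits the pangenome-side inputs with planted ground truth: per-species
#' core gene clusters present in every genome, random accessory clusters,
#' functional annotations comprising universal core functions, random
#' background functions, and the design's subgroup-exclusive planted
#' functions, plus KEGG-style module definitions. One module
#' (`M_boundary`) has four single-KO steps of which a designated genome
#' carries exactly three, pinning the 0.75 completeness boundary.
#'
#' @param catalog A [simulate_catalog()] result.
#' @param design Override the catalog's design.
#' @param n_core_clusters,n_accessory_clusters Gene clusters per species.
#' @param n_background_functions Background KO accessions with independent
#'   50% presence per genome.
#' @return A list with tibbles `gene_clusters` (cluster_id, genome_id,
#'   count), `annotations` (genome_id, accession, source), `modules`
#'   (module_id, step_index, alternatives) and a `truth` list naming the
#'   boundary genome and the planted exclusive functions.
#' @export
simulate_annotations <- function(catalog, design = catalog$design,
                                 n_core_clusters = 30L,
                                 n_accessory_clusters = 15L,
                                 n_background_functions = 50L) {
  if (!inherits(catalog, "sim_catalog")) {
    stop_metapan("`catalog` must be created by simulate_catalog()",
                 class = "metapanr_config_error")
  }
  genomes <- catalog$genomes
  withr::with_seed(substream(design$seed, "annotations"), {
    gene_clusters <- purrr::map(unique(genomes$species), function(sp) {
      ids <- genomes$genome_id[genomes$species == sp]
      core <- expand_grid(
        cluster_id = sprintf("GC_%s_core%03d", sp, seq_len(n_core_clusters)),
        genome_id = ids
      ) |> mutate(count = 1L)
      acc <- purrr::map(seq_len(n_accessory_clusters), function(k) {
        n_in <- sample(seq_len(max(1L, length(ids) - 1L)), 1L)
        tibble(cluster_id = sprintf("GC_%s_acc%03d", sp, k),
               genome_id = sample(ids, n_in), count = 1L)
      }) |> list_rbind()
      bind_rows(core, acc)
    }) |> list_rbind()

    core_fun <- expand_grid(
      accession = sprintf("K_core%03d", 1:10),
      genome_id = genomes$genome_id
    )
    background <- expand_grid(
      accession = sprintf("K_bg%03d", seq_len(n_background_functions)),
      genome_id = genomes$genome_id
    ) |> filter(runif(n()) < 0.5)
    excl <- catalog$truth$exclusive_functions |>
      inner_join(distinct(genomes, .data$genome_id, .data$subgroup),
                 by = "subgroup", relationship = "many-to-many") |>
      select("accession", "genome_id")
    # Step-alternative fixture: either paralog satisfies the same step.
    alt <- expand_grid(accession = "K_alt_b",
                       genome_id = genomes$genome_id) |>
      filter(runif(n()) < 0.5)

    boundary_genome <- genomes$genome_id[1L]
    boundary <- tibble(accession = sprintf("K_bnd%d", 1:3),
                       genome_id = boundary_genome)

    annotations <- bind_rows(core_fun, background, excl, alt, boundary) |>
      mutate(source = "KOfam") |>
      arrange(.data$genome_id, .data$accession)

    subgroup_modules <- catalog$truth$exclusive_functions |>
      group_by(subgroup = .data$subgroup) |>
      summarise(kos = list(.data$accession), .groups = "drop") |>
      purrr::pmap(function(subgroup, kos) {
        tibble(module_id = sprintf("M_%s", subgroup),
               step_index = seq_along(kos), alternatives = kos)
      }) |> list_rbind()

    modules <- bind_rows(
      tibble(module_id = "M_core", step_index = 1:4,
             alternatives = sprintf("K_core%03d", 1:4)),
      tibble(module_id = "M_boundary", step_index = 1:4,
             alternatives = sprintf("K_bnd%d", 1:4)),
      tibble(module_id = "M_alt", step_index = 1:2,
             alternatives = c("K_core001", "K_alt_a|K_alt_b")),
      subgroup_modules
    )

    list(
      gene_clusters = gene_clusters |> arrange(.data$cluster_id, .data$genome_id),
      annotations = annotations,
      modules = modules,
      truth = list(boundary_genome = boundary_genome,
                   exclusive_functions = catalog$truth$exclusive_functions)
    )
  })
}

#' Simulate CheckM-style QC and pairwise ANI tables
#'
#' Emits a completeness/contamination table and a pairwise ANI matrix
#' consistent with the catalog: distinct genomes sit at ~80-97% ANI, and
#' `n_redundant` genomes are made near-duplicates (ANI 98.5-99.5) of a
#' partner from the same subgroup with slightly lower completeness, so the
#' dereplication ground truth is that exactly those genomes are dropped.
#'
#' @param catalog A [simulate_catalog()] result.
#' @param n_redundant Number of planted near-duplicate genomes.
#' @return List with `qc` (genome_id, completeness, contamination), a square
#'   numeric `ani` matrix (percent, diagonal 100) and `truth$redundant`.
#' @export
simulate_qc_ani <- function(catalog, n_redundant = 1L) {
  genomes <- catalog$genomes
  n <- nrow(genomes)
  withr::with_seed(substream(catalog$design$seed, "annotations") + 7L, {
    qc <- tibble(
      genome_id = genomes$genome_id,
      completeness = round(runif(n, 95, 100), 2),
      contamination = round(runif(n, 0, 2), 2)
    )
    ani <- matrix(round(runif(n * n, 80, 90), 2), n, n,
                  dimnames = list(genomes$genome_id, genomes$genome_id))
    # same species: 90-97; never above the 98 threshold unless planted
    same_sp <- outer(genomes$species, genomes$species, "==")
    ani[same_sp] <- round(runif(sum(same_sp), 90, 97), 2)
    redundant <- character(0)
    candidates <- genomes |>
      group_by(.data$subgroup) |>
      filter(n() >= 2) |>
      ungroup()
    n_redundant <- min(n_redundant, nrow(candidates) %/% 2)
    if (n_redundant > 0) {
      for (k in seq_len(n_redundant)) {
        pair <- candidates$genome_id[c(2 * k - 1, 2 * k)]
        hi <- round(runif(1, 98.5, 99.5), 2)
        ani[pair[1], pair[2]] <- hi
        ani[pair[2], pair[1]] <- hi
        # the second of the pair loses on completeness -> deterministic drop
        qc$completeness[qc$genome_id == pair[2]] <-
          qc$completeness[qc$genome_id == pair[1]] - 1
        redundant <- c(redundant, pair[2])
      }
    }
    diag(ani) <- 100
    list(qc = qc, ani = ani, truth = list(redundant = redundant))
  })
}

#' Run the full synthetic generator
#'
#' Convenience wrapper chaining [simulate_catalog()],
#' [simulate_coverage()], [simulate_annotations()] and
#' [simulate_qc_ani()].
#'
#' @param design A [sim_design()] object.
#' @return A list with `catalog`, `profiles`, `metadata` (sample_id, site),
#'   `annotations` (the [simulate_annotations()] list), `qc_ani` and the
#'   `design`.
#' @export
simulate_metapangenome <- function(design) {
  catalog <- simulate_catalog(design)
  profiles <- simulate_coverage(catalog)
  list(
    catalog = catalog,
    profiles = profiles,
    metadata = distinct(profiles, .data$sample_id, .data$site),
    annotations = simulate_annotations(catalog),
    qc_ani = simulate_qc_ani(catalog),
    design = design
  )
}
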