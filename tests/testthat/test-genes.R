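test_that("gene covered fraction is inclusive at the 90% boundary", {
  depths <- c(rep(1L, 9), 0L)               # 10-nt gene, 9 covered
  expect_equal(gene_covered_fraction(depths, 0, 10), 0.9)
  expect_equal(gene_covered_fraction(c(rep(1L, 8), 0L, 0L), 0, 10), 0.8)
  expect_equal(gene_covered_fraction(rep(3L, 10), 0, 10), 1)
  expect_error(gene_covered_fraction(depths, 5, 12),
               class = "metapanr_input_error")
  expect_error(gene_covered_fraction(depths, -1, 5),
               class = "metapanr_input_error")
})

test_that("raising the depth floor never increases a covered fraction", {
  set.seed(9)
  for (i in 1:50) {
    d <- rnbinom(200, mu = 3, size = 1)
    f1 <- gene_covered_fraction(d, 10, 150, min_depth = 1)
    f2 <- gene_covered_fraction(d, 10, 150, min_depth = 2)
    f5 <- gene_covered_fraction(d, 10, 150, min_depth = 5)
    expect_true(f2 <= f1 && f5 <= f2)
  }
})

test_that("contig offsets place genes correctly in concatenated genomes", {
  prof <- tibble::tibble(genome_id = "g", sample_id = "s",
                         depth = list(c(rep(0L, 5), rep(2L, 5))))
  genes <- tibble::tibble(gene_id = c("a", "b"), genome_id = "g",
                          contig_id = c("c1", "c2"),
                          start = c(0L, 0L), end = c(5L, 5L), strand = "+")
  contigs <- tibble::tibble(contig_id = c("c1", "c2"),
                            offset = c(0L, 5L))
  gc <- gene_coverage(prof, genes, contigs)
  expect_equal(gc$covered_fraction[gc$gene_id == "a"], 0)
  expect_equal(gc$covered_fraction[gc$gene_id == "b"], 1)
})

test_that("gene detection map clamps small sites, ranks genes and samples", {
  d <- sim_design(n_species = 1, genomes_per_species = 1,
                  genome_length = 3000, mean_gene_length = 300,
                  sites = c("SUPP", "TD"), samples_per_site = 4,
                  base_depth = 10, background_depth = 0.02, seed = 17)
  catal <- simulate_catalog(d)
  prof <- simulate_coverage(catal)
  gm <- gene_detection_map(prof, catal$genes, catal$contigs,
                           samples_per_site = 30)
  # clamp: all 8 samples used even though 30 requested per site
  expect_equal(nrow(gm$selected_samples), 8)
  # gene order sorted by decreasing detection frequency
  freq <- tapply(gm$detection$detected, gm$detection$gene_id, mean)
  expect_true(!is.unsorted(rev(freq[gm$gene_order])))
  # selection is deterministic
  gm2 <- gene_detection_map(prof, catal$genes, catal$contigs,
                            samples_per_site = 30)
  expect_identical(gm$gene_order, gm2$gene_order)
  expect_identical(gm$sample_order, gm2$sample_order)
})

test_that("a site-specialist genome detects far more genes at its preferred site", {
  d <- sim_design(n_species = 1, genomes_per_species = 1,
                  genome_length = 10000, mean_gene_length = 500,
                  sites = c("SUPP", "TD", "BM"), samples_per_site = 5,
                  base_depth = 10, background_depth = 0.05, seed = 23)
  catal <- simulate_catalog(d)   # sp01.1 prefers SUPP (round-robin)
  prof <- simulate_coverage(catal)
  gm <- gene_detection_map(prof, catal$genes, catal$contigs)
  prop <- tapply(gm$detection$detected, gm$detection$site, mean)
  expect_gte(prop[["SUPP"]], 4 * max(prop[["TD"]], prop[["BM"]], 1e-6))
})

test_that("core/accessory classification respects the presence fraction", {
  clusters <- tibble::tibble(
    cluster_id = c("c1", "c1", "c1", "c2", "c2"),
    genome_id = c("g1", "g2", "g3", "g1", "g2"),
    count = 1L
  )
  map <- data.frame(genome_id = c("g1", "g2", "g3"), species = "S")
  out <- classify_core_accessory(clusters, map)
  expect_identical(out$label[out$cluster_id == "c1"], "core")
  expect_identical(out$label[out$cluster_id == "c2"], "accessory")
  # 54/54 at threshold 0.95 is core
  big <- tibble::tibble(cluster_id = "c", genome_id = sprintf("g%02d", 1:54),
                        count = 1L)
  big_map <- data.frame(genome_id = sprintf("g%02d", 1:54), species = "S")
  expect_identical(
    classify_core_accessory(big, big_map, core_fraction = 0.95)$label, "core")
  # 2/3 at threshold 2/3 is core (inclusive)
  expect_identical(
    classify_core_accessory(clusters[4:5, ], map, core_fraction = 2 / 3)$label,
    "core")
})

test_that("per-site mean gene coverage reflects planted depths", {
  prof <- tibble::tibble(
    genome_id = "g",
    sample_id = c("s1", "s2", "s3"),
    site = c("SUPP", "SUPP", "TD"),
    depth = list(rep(4L, 100), rep(6L, 100), rep(0L, 100))
  )
  genes <- tibble::tibble(gene_id = "gene1", genome_id = "g",
                          contig_id = "g", start = 10L, end = 60L,
                          strand = "+")
  mc <- gene_mean_coverage_by_site(prof, genes)
  expect_equal(mc$mean_depth[mc$site == "SUPP"], 5)
  expect_equal(mc$mean_depth[mc$site == "TD"], 0)
})

test_that("background-level recruitment keeps off-site gene coverage below 1X", {
  d <- sim_design(n_species = 1, genomes_per_species = 1,
                  genome_length = 5000, mean_gene_length = 500,
                  sites = c("SUPP", "TD"), samples_per_site = 4,
                  base_depth = 10, background_depth = 0.05,
                  spike_fraction = 0, seed = 29)
  catal <- simulate_catalog(d)
  prof <- simulate_coverage(catal)
  mc <- gene_mean_coverage_by_site(prof, catal$genes, catal$contigs)
  expect_true(all(mc$mean_depth[mc$site == "TD"] < 1))
  expect_true(all(mc$mean_depth[mc$site == "SUPP"] > 5))
})

test_that("genome breadth bounds the length-weighted mean of gene fractions", {
  sim <- simulate_metapangenome(tiny_design(seed = 61))
  catal <- sim$catalog
  prof <- sim$profiles[sim$profiles$site == "SUPP", ]
  det <- detect_genomes(prof)
  gc <- gene_coverage(prof, catal$genes, catal$contigs)
  genes <- catal$genes
  genes$len <- genes$end - genes$start
  for (i in which(det$breadth >= 0.9)) {
    gid <- det$genome_id[i]; sid <- det$sample_id[i]
    gg <- merge(gc[gc$genome_id == gid & gc$sample_id == sid, ],
                genes[, c("gene_id", "len")], by = "gene_id")
    wmean <- sum(gg$covered_fraction * gg$len) / sum(gg$len)
    genic <- sum(gg$len) / catal$genomes$length[catal$genomes$genome_id == gid]
    expect_gte(wmean, det$breadth[i] - (1 - genic) - 1e-12)
  }
})
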