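test_that("breadth of coverage counts positions at or above the depth floor", {
  expect_equal(breadth_of_coverage(c(1, 2, 0, 0, 3, 0, 0, 1, 1, 0)), 0.5)
  expect_equal(breadth_of_coverage(rep(0, 10)), 0)
  expect_equal(breadth_of_coverage(rep(2, 10)), 1)
  expect_error(breadth_of_coverage(numeric(0)), class = "metapanr_input_error")
})

test_that("q2q3 mean depth matches hand-worked middle-half slices", {
  expect_equal(q2q3_mean_depth(1:8), 4.5)                      # mean(3,4,5,6)
  expect_equal(q2q3_mean_depth(c(0, 0, 0, 0, 100, 100, 100, 100)), 50)
  expect_equal(q2q3_mean_depth(rep(7, 13)), 7)
  expect_equal(q2q3_mean_depth(c(5)), 5)                       # n < 4: plain mean
  expect_equal(q2q3_mean_depth(c(1, 9)), 5)
  expect_error(q2q3_mean_depth(integer(0)), class = "metapanr_input_error")
})

test_that("q2q3 equals the brute-force oracle on random vectors", {
  set.seed(1)
  for (i in 1:200) {
    n <- sample(1:2000, 1)
    x <- rnbinom(n, mu = runif(1, 0.1, 50), size = 0.8)
    expect_identical(q2q3_mean_depth(x), oracle_q2q3(x))
  }
})

test_that("q2q3 ignores any inflation of the top quarter of positions", {
  set.seed(2)
  for (i in 1:100) {
    n <- sample(8:1000, 1)
    x <- sample.int(10 * n, n)  # distinct values
    k <- floor(n / 4) - 1
    if (k < 1) next
    top <- order(x, decreasing = TRUE)[seq_len(k)]
    for (f in c(1, 10, 1000)) {
      y <- x
      y[top] <- y[top] * f
      expect_identical(q2q3_mean_depth(y), q2q3_mean_depth(x))
    }
  }
})

test_that("q2q3 is bounded by min, overall mean (right-skewed), and max", {
  set.seed(3)
  for (i in 1:50) {
    n <- sample(20:500, 1)
    x <- rnbinom(n, mu = 10, size = 2)
    x[sample(n, ceiling(n / 10))] <- 500L  # spiked, right-skewed
    q <- q2q3_mean_depth(x)
    expect_gte(q, min(x)); expect_lte(q, max(x))
    expect_lte(q, mean(x))
  }
})

test_that("detection is inclusive at the breadth threshold and monotone in coverage", {
  depths <- list(c(1, 1, 0, 0), c(1, 0, 0, 0), c(1, 1, 1, 0))
  prof <- tibble::tibble(genome_id = c("g1", "g2", "g3"), sample_id = "s1",
                         depth = depths)
  det <- detect_genomes(prof)
  expect_identical(det$detected[match(c("g1", "g2", "g3"), det$genome_id)],
                   c(TRUE, FALSE, TRUE))   # 0.50 exactly -> detected

  # adding coverage anywhere never flips detected -> undetected
  prof2 <- prof
  prof2$depth <- lapply(prof$depth, function(x) { x[1] <- x[1] + 5; x })
  det2 <- detect_genomes(prof2)
  expect_true(all(det2$detected >= det$detected))
})

test_that("missing grid cells count as zero coverage; duplicates error", {
  prof <- tibble::tibble(
    genome_id = c("g1", "g1", "g2"),
    sample_id = c("s1", "s2", "s1"),
    depth = list(rep(1L, 4), rep(1L, 4), rep(0L, 4))
  )
  det <- detect_genomes(prof)
  expect_equal(nrow(det), 4)  # completed to the 2x2 grid
  expect_equal(det$breadth[det$genome_id == "g2" & det$sample_id == "s2"], 0)

  dup <- prof[c(1, 1, 3), ]
  expect_error(detect_genomes(dup), class = "metapanr_input_error")
})

test_that("relative abundance divides by all reference genomes and drops empty samples", {
  prof <- tibble::tibble(
    genome_id = rep(c("g1", "g2", "g3"), each = 2),
    sample_id = rep(c("s1", "s2"), 3),
    depth = list(rep(5L, 8), rep(0L, 8),    # g1: only s1
                 rep(5L, 8), rep(0L, 8),    # g2: only s1
                 rep(0L, 8), rep(0L, 8))    # g3: nowhere -> s2 excluded
  )
  ab <- relative_abundance(prof)
  expect_setequal(unique(ab$sample_id), "s1")
  expect_equal(sort(ab$abundance[ab$sample_id == "s1"]), c(0, 0.5, 0.5))

  solo <- tibble::tibble(genome_id = c("g1", "g2"), sample_id = "s1",
                         depth = list(rep(5L, 8), rep(0L, 8)))
  ab2 <- relative_abundance(solo)
  expect_equal(ab2$abundance[ab2$genome_id == "g1"], 1)
  expect_equal(ab2$abundance[ab2$genome_id == "g2"], 0)
})

test_that("genome and species abundances conserve mass per included sample", {
  sim <- simulate_metapangenome(tiny_design(seed = 55))
  ab <- relative_abundance(sim$profiles)
  sums <- tapply(ab$abundance, ab$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  sp <- aggregate_species_abundance(ab, sim$catalog$genomes)
  sp_sums <- tapply(sp$abundance, sp$sample_id, sum)
  expect_true(all(abs(sp_sums - 1) < 1e-9))
})

test_that("species aggregation sums member genomes and ignores genome order", {
  ab <- tibble::tibble(genome_id = c("g1", "g2", "g3"), sample_id = "s1",
                       abundance = c(0.2, 0.3, 0.5))
  map <- data.frame(genome_id = c("g1", "g2", "g3"),
                    species = c("S", "S", "T"))
  sp <- aggregate_species_abundance(ab, map)
  expect_equal(sp$abundance[sp$species == "S"], 0.5)
  expect_equal(sp$abundance[sp$species == "T"], 0.5)
  expect_identical(sp, aggregate_species_abundance(ab[3:1, ], map))
  expect_error(aggregate_species_abundance(ab, map[1:2, ]),
               "g3", class = "metapanr_input_error")
})

test_that("Bray-Curtis ordering clusters identical samples together", {
  # two pairs of identical columns -> BC 0 within pair, 1 across
  ab <- tidyr::expand_grid(species = c("x", "y"),
                           sample_id = c("s1", "s2", "s3", "s4"))
  ab$abundance <- c(1, 1, 0, 0,  # x
                    0, 0, 1, 1)  # y
  ord <- order_by_bray_curtis(ab)
  pos <- match(c("s1", "s2", "s3", "s4"), ord$col_order)
  expect_equal(abs(pos[1] - pos[2]), 1)
  expect_equal(abs(pos[3] - pos[4]), 1)
  expect_setequal(ord$row_order, c("x", "y"))

  # formula check via vegan on a known pair
  d <- vegan::vegdist(rbind(c(0.2, 0.8), c(0.6, 0.4)), method = "bray")
  expect_equal(as.numeric(d), 0.4)
})

test_that("all-zero abundance profiles order without error", {
  ab <- tidyr::expand_grid(species = c("x", "y", "z"),
                           sample_id = c("s1", "s2", "s3"))
  ab$abundance <- c(1, 0, 0, 0, 1, 0, 0, 0, 0)  # z absent everywhere
  expect_no_error(suppressMessages(ord <- order_by_bray_curtis(ab)))
  expect_setequal(ord$row_order, c("x", "y", "z"))
})
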