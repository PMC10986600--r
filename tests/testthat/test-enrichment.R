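test_that("module completeness counts satisfied steps, inclusive at 0.75", {
  mod <- data.frame(module_id = "M1", step_index = 1:4,
                    alternatives = c("K1", "K2", "K3", "K4"))
  ann3 <- data.frame(genome_id = "g1", accession = c("K1", "K2", "K3"))
  out <- module_completeness(ann3, mod)
  expect_equal(out$completeness, 0.75)
  expect_true(out$complete)

  ann2 <- data.frame(genome_id = "g1", accession = c("K1", "K2"))
  out2 <- module_completeness(ann2, mod)
  expect_equal(out2$completeness, 0.5)
  expect_false(out2$complete)

  # either alternative satisfies a step
  alt <- data.frame(module_id = "M2", step_index = 1,
                    alternatives = "K1|K2")
  expect_equal(module_completeness(data.frame(genome_id = "g", accession = "K2"),
                                   alt)$completeness, 1)
  expect_error(module_completeness(ann3, mod[0, ]),
               class = "metapanr_definition_error")
})

test_that("flat module evaluation matches a boolean oracle on random genomes", {
  set.seed(11)
  kos <- sprintf("K%05d", 1:30)
  mod <- data.frame(module_id = "M", step_index = 1:6,
                    alternatives = c("K00001", "K00002|K00003", "K00004",
                                     "K00005|K00006|K00007", "K00008",
                                     "K00009"))
  alts <- strsplit(mod$alternatives, "|", fixed = TRUE)
  for (i in 1:25) {
    have <- sample(kos, sample(0:15, 1))
    ann <- data.frame(genome_id = "g",
                      accession = if (length(have)) have else "K_none")
    expected <- mean(vapply(alts, function(a) any(a %in% ann$accession),
                            logical(1)))
    expect_equal(module_completeness(ann, mod)$completeness, expected)
  }
})

test_that("two-group enrichment score equals the Pearson chi-squared oracle", {
  # 10/10 vs 0/10: n (ad - bc)^2 / row/col products = 20
  r <- enrichment_score(rep(c(TRUE, FALSE), c(10, 10)),
                        rep(c("A", "B"), each = 10))
  expect_equal(r$score, 20)
  # 3/4 vs 1/4 -> 2.0
  r2 <- enrichment_score(c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
                         rep(c("A", "B"), each = 4))
  expect_equal(r2$score, 2)
  # equal proportions -> 0, p 1
  r3 <- enrichment_score(rep(c(TRUE, FALSE), 4), rep(c("A", "B"), each = 4))
  expect_equal(r3$score, 0)
  expect_equal(r3$p_value, 1)
  # constant trait is degenerate
  r4 <- enrichment_score(rep(TRUE, 8), rep(c("A", "B"), each = 4))
  expect_equal(r4$score, 0)
  expect_equal(r4$p_value, 1)
})

test_that("score test matches chisq.test without continuity correction on random tables", {
  set.seed(12)
  for (i in 1:100) {
    a <- sample(1:15, 1); b <- sample(1:15, 1)
    c_ <- sample(1:15, 1); d <- sample(1:15, 1)
    pres <- rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c_, d))
    grp <- rep(c("A", "A", "B", "B"), c(a, b, c_, d))
    r <- enrichment_score(pres, grp)
    ref <- suppressWarnings(stats::chisq.test(table(grp, pres),
                                              correct = FALSE))
    expect_equal(r$score, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("multi-group scores match the k x 2 chi-squared oracle", {
  set.seed(13)
  for (i in 1:25) {
    grp <- rep(c("A", "B", "C"), times = sample(3:8, 3, replace = TRUE))
    pres <- runif(length(grp)) < 0.5
    if (all(pres) || !any(pres)) next
    r <- enrichment_score(pres, grp)
    ref <- suppressWarnings(stats::chisq.test(table(grp, pres),
                                              correct = FALSE))
    expect_equal(r$score, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$df, unname(ref$parameter))
  }
})

test_that("BH adjustment matches the step-up oracle and ties collapse", {
  set.seed(14)
  p <- runif(40)
  expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p))
  # equal p's give equal q's at that p
  expect_equal(unique(oracle_bh(rep(0.01, 7))), 0.01)
  q <- oracle_bh(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in p-rank
})

test_that("enrich_functions ranks a planted exclusive function on top", {
  genomes <- sprintf("g%02d", 1:40)
  groups <- data.frame(genome_id = genomes,
                       group = rep(c("A", "B"), each = 20))
  set.seed(15)
  bg <- tidyr::expand_grid(accession = sprintf("K_bg%03d", 1:50),
                           genome_id = genomes)
  bg <- bg[runif(nrow(bg)) < 0.5, ]
  planted <- data.frame(accession = "K_planted", genome_id = genomes[1:20])
  everywhere <- data.frame(accession = "K_all", genome_id = genomes)
  ann <- rbind(as.data.frame(bg), planted, everywhere)
  res <- enrich_functions(ann, groups)
  expect_identical(res$accession[1], "K_planted")
  expect_lt(res$q[res$accession == "K_planted"], 0.05)
  expect_identical(res$associated_groups[res$accession == "K_planted"], "A")
  expect_equal(res$score[res$accession == "K_all"], 0)
  expect_equal(res$q[res$accession == "K_all"], 1)
  # BH column matches the oracle on the same p vector
  expect_equal(res$q, oracle_bh(res$p))
})

test_that("group relabelling leaves scores unchanged", {
  genomes <- sprintf("g%02d", 1:20)
  groups1 <- data.frame(genome_id = genomes,
                        group = rep(c("A", "B"), each = 10))
  groups2 <- data.frame(genome_id = genomes,
                        group = rep(c("east", "west"), each = 10))
  set.seed(16)
  ann <- tidyr::expand_grid(accession = sprintf("K%03d", 1:30),
                            genome_id = genomes)
  ann <- as.data.frame(ann[runif(nrow(ann)) < 0.4, ])
  r1 <- enrich_functions(ann, groups1)
  r2 <- enrich_functions(ann, groups2)
  expect_equal(r1$score, r2$score)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$q, r2$q)
})

test_that("module enrichment flags a subgroup-exclusive complete module", {
  sim <- simulate_metapangenome(
    sim_design(n_species = 2, genomes_per_species = 6, genome_length = 2000,
               sites = c("SUPP", "TD"), samples_per_site = 2, seed = 19))
  ann <- sim$annotations
  mc <- module_completeness(ann$annotations, ann$modules)
  groups <- data.frame(genome_id = sim$catalog$genomes$genome_id,
                       group = sim$catalog$genomes$subgroup)
  res <- enrich_modules(mc, groups)
  planted <- res[res$module_id == "M_sp01.1", ]
  expect_lt(planted$q, 0.05)
  expect_identical(planted$associated_groups, "sp01.1")
  expect_equal(res$score[res$module_id == "M_core"], 0)
  # single-genome groups, complete vs incomplete -> 2x2 table score 2
  two <- data.frame(genome_id = c("x", "y"), module_id = "M",
                    complete = c(TRUE, FALSE))
  g2 <- data.frame(genome_id = c("x", "y"), group = c("A", "B"))
  expect_equal(enrich_modules(two, g2)$score, 2)
})
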