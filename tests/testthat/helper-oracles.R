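# Independent oracles used across the suite. Each is a deliberately
# separate implementation path from the package code it checks.

# Brute-force sort-and-slice interquartile mean: explicit 0-based rank
# loop over the sorted vector.
oracle_q2q3 <- function(x) {
  n <- length(x)
  s <- sort(x)
  ranks <- seq(floor(n / 4), ceiling(3 * n / 4) - 1)  # 0-based
  slice <- numeric(0)
  for (r in ranks) slice <- c(slice, s[r + 1])
  mean(slice)
}

# Benjamini-Hochberg step-up, written out: q_(i) = min_{j >= i} p_(j) m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, p[o[i]] * m / i)
    q_sorted[i] <- min(running, 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exact permutation p-value by exhaustive enumeration of all per-taxon
# permutations (feasible only for tiny instances). `m` is taxa x samples.
# Mirrors the test's ordering: co-dominance count first, summed
# second-largest share as the continuous refinement.
oracle_exhaustive_dominance_p <- function(m, tau, tie_break = "margin") {
  stopifnot(nrow(m) == 2)
  n <- ncol(m)
  perms <- gtools_perms(n)
  stats_codom <- function(mm) {
    tot <- colSums(mm)
    shares <- sweep(mm, 2, ifelse(tot > 0, tot, 1), "/")
    count <- sum(colSums(shares >= tau) >= 2 & tot > 0)
    second <- apply(shares, 2, function(x) sort(x, decreasing = TRUE)[2])
    c(count, sum(second[tot > 0]))
  }
  obs <- stats_codom(m)
  hits <- 0; total <- 0
  for (i in seq_len(nrow(perms))) {
    for (j in seq_len(nrow(perms))) {
      s <- stats_codom(rbind(m[1, perms[i, ]], m[2, perms[j, ]]))
      le <- if (tie_break == "margin") {
        s[1] < obs[1] || (s[1] == obs[1] && s[2] <= obs[2] + 1e-12)
      } else {
        s[1] <= obs[1]
      }
      hits <- hits + le
      total <- total + 1
    }
  }
  hits / total
}

# All permutations of 1..n as rows (tiny n only).
gtools_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1)))
  }
  unname(out)
}

# Small fixed study design reused across module tests.
tiny_design <- function(seed = 101, ...) {
  sim_design(n_species = 2, genomes_per_species = 2, genome_length = 2000,
             mean_gene_length = 300, sites = c("SUPP", "TD"),
             samples_per_site = 3, seed = seed, ...)
}

# Random abundance table for dominance tests: iid lognormal, so the
# permutation null holds exactly.
random_taxa_table <- function(n_taxa, n_samples, seed) {
  set.seed(seed)
  ab <- tidyr::expand_grid(taxon = sprintf("t%d", seq_len(n_taxa)),
                           sample_id = sprintf("s%03d", seq_len(n_samples)))
  ab$abundance <- stats::rlnorm(n_taxa * n_samples)
  ab
}
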