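## Reciprocal dominance among related taxa: a marginal-preserving
## permutation test of whether fewer samples than expected are
## co-dominated by two or more of the focal taxa.

dominance_matrix <- function(abundances, taxa = NULL) {
  assert_columns(abundances, c("sample_id", "abundance"), "abundances")
  taxon_col <- intersect(c("taxon", "species", "genome_id"),
                         names(abundances))[1]
  if (is.na(taxon_col)) {
    stop_metapan("abundances need a `taxon`, `species` or `genome_id` column",
                 class = "metapanr_input_error")
  }
  if (is.null(taxa)) taxa <- sort(unique(abundances[[taxon_col]]))
  missing <- setdiff(taxa, abundances[[taxon_col]])
  if (length(missing) > 0) {
    stop_metapan(sprintf("taxa absent from abundances: %s",
                         paste(missing, collapse = ", ")),
                 class = "metapanr_input_error")
  }
  wide <- abundances |>
    filter(.data[[taxon_col]] %in% taxa) |>
    select(taxon = all_of(taxon_col), "sample_id", "abundance") |>
    pivot_wider(names_from = "sample_id", values_from = "abundance",
                values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$taxon
  m <- m[taxa, order(colnames(m)), drop = FALSE]  # canonical sample order
  if (any(m < 0)) {
    stop_metapan("abundances must be non-negative",
                 class = "metapanr_input_error")
  }
  # restrict to samples where at least one focal taxon occurs
  m[, colSums(m) > 0, drop = FALSE]
}

codominance_count <- function(m, tau, renormalize = TRUE) {
  tot <- colSums(m)
  ok <- tot > 0
  thresh <- if (renormalize) tau * tot else tau
  sum(colSums(m >= rep(thresh, each = nrow(m))) >= 2 & ok)
}

# Count plus the continuous refinement used to break ties in the
# permutation ordering: the summed second-largest share across samples.
# More co-dominance-like arrangements have larger (count, margin).
codominance_stats <- function(m, tau, renormalize = TRUE) {
  n <- ncol(m)
  tot <- colSums(m)
  ok <- tot > 0
  shares <- if (renormalize) {
    sweep(m, 2, ifelse(ok, tot, 1), "/")
  } else {
    m
  }
  count <- sum(colSums(shares >= tau) >= 2 & ok)
  tmp <- shares
  tmp[cbind(max.col(t(tmp), ties.method = "first"), seq_len(n))] <- -Inf
  second <- tmp[cbind(max.col(t(tmp), ties.method = "first"), seq_len(n))]
  c(count = count, margin = sum(second[ok]))
}

#' Co-dominance count among focal taxa
#'
#' The observed statistic of the reciprocal-dominance test: the number of
#' samples in which two or more of the focal taxa are simultaneously
#' dominant, where a taxon is dominant when its share of the focal taxa's
#' summed abundance in that sample is at least `tau`. Under a perfectly
#' reciprocal ("only one taxon high at a time") arrangement the count
#' is 0.
#'
#' @param abundances Long tibble with a taxon column (`taxon`, `species`
#'   or `genome_id`), `sample_id` and `abundance`.
#' @param taxa Focal taxa (>= 2); defaults to all taxa present.
#' @param tau Dominance threshold on the within-sample share of the focal
#'   taxa's total, in (0, 1). Values >= 0.5 make co-dominance impossible
#'   after renormalization and are refused.
#' @param renormalize Rescale the focal rows to sum to 1 per sample before
#'   thresholding (the default); otherwise `tau` applies to the raw
#'   abundances.
#' @return Integer count of co-dominated samples.
#' @examples
#' ab <- tidyr::expand_grid(taxon = c("a", "b"), sample_id = c("s1", "s2"))
#' ab$abundance <- c(0.9, 0.5, 0.1, 0.5)
#' codominance_statistic(ab, tau = 0.3)
#' @export
codominance_statistic <- function(abundances, taxa = NULL, tau = 0.3,
                                  renormalize = TRUE) {
  check_tau(tau, renormalize)
  m <- dominance_matrix(abundances, taxa)
  codominance_count(m, tau, renormalize)
}

check_tau <- function(tau, renormalize) {
  assert_scalar_number(tau, "tau", 0, 1, lower_open = TRUE, upper_open = TRUE)
  if (renormalize && tau >= 0.5) {
    stop_metapan(
      "tau >= 0.5 with renormalized shares can never flag co-dominance; choose tau < 0.5",
      class = "metapanr_config_error"
    )
  }
  invisible(tau)
}

#' Permutation test for reciprocal dominance
#'
#' Tests whether the focal taxa co-dominate fewer samples than expected if
#' they occupied samples independently. The null is generated by
#' independently permuting each taxon's abundance vector across samples —
#' preserving every taxon's marginal abundance distribution while
#' destroying cross-taxon coupling — and the one-sided p-value is
#' `(1 + #\{T_perm <= T_obs\}) / (1 + n_permutations)`, never exactly zero.
#' A 95% CI for the Monte-Carlo p-value comes from the normal
#' approximation to the binomial permutation count. Columns are anchored
#' to sorted sample ids before permuting, so the seeded result does not
#' depend on input row order.
#'
#' The co-dominance count is a coarse integer, so tied counts between the
#' observed data and many permutations would make the p-value needlessly
#' conservative. By default ties are broken by a continuous refinement —
#' the summed second-largest within-sample share, with smaller values
#' meaning a more reciprocal arrangement — so the permutation ordering is
#' effectively continuous and the null p-value is close to uniform.
#' `tie_break = "none"` uses the raw count ordering instead.
#'
#' @inheritParams codominance_statistic
#' @param n_permutations Number of permutations (>= 99).
#' @param seed Integer seed for the permutation stream.
#' @param tie_break `"margin"` (lexicographic count-then-margin ordering,
#'   the calibrated default) or `"none"` (raw count ordering).
#' @return Object of class `dominance_test` with the observed statistic,
#'   p-value, CI, per-sample dominance labels and the null counts; see
#'   [tidy.dominance_test()] and [glance.dominance_test()].
#' @examples
#' ab <- tidyr::expand_grid(taxon = c("a", "b", "c"),
#'                          sample_id = sprintf("s%02d", 1:12))
#' ab$abundance <- as.numeric(t(diag(3)[rep(1:3, 4), ])) + 0.02
#' dominance_test(ab, tau = 0.3, n_permutations = 199, seed = 1)
#' @export
dominance_test <- function(abundances, taxa = NULL, tau = 0.3,
                           n_permutations = 10000, seed = NULL,
                           renormalize = TRUE,
                           tie_break = c("margin", "none")) {
  check_tau(tau, renormalize)
  tie_break <- match.arg(tie_break)
  if (n_permutations < 99) {
    stop_metapan("n_permutations must be at least 99",
                 class = "metapanr_config_error")
  }
  m <- dominance_matrix(abundances, taxa)
  n <- ncol(m)
  k <- nrow(m)
  if (n < 3) {
    stop_metapan("need at least 3 samples with focal-taxon signal",
                 class = "metapanr_input_error")
  }
  obs <- codominance_stats(m, tau, renormalize)
  t_obs <- as.integer(obs[["count"]])

  run <- function() {
    t_perm <- integer(n_permutations)
    s_perm <- numeric(n_permutations)
    perm <- m
    for (b in seq_len(n_permutations)) {
      for (j in seq_len(k)) perm[j, ] <- m[j, sample.int(n)]
      st <- codominance_stats(perm, tau, renormalize)
      t_perm[b] <- st[["count"]]
      s_perm[b] <- st[["margin"]]
    }
    list(t = t_perm, s = s_perm)
  }
  null <- if (is.null(seed)) run() else {
    withr::with_seed(substream(seed, "permutation"), run())
  }
  t_perm <- null$t

  n_le <- if (tie_break == "margin") {
    sum(t_perm < t_obs |
          (t_perm == t_obs & null$s <= obs[["margin"]] + 1e-12))
  } else {
    sum(t_perm <= t_obs)
  }
  p <- (1 + n_le) / (1 + n_permutations)
  se <- sqrt(p * (1 - p) / n_permutations)
  ci <- c(max(p - qnorm(0.975) * se, 1 / (1 + n_permutations)),
          min(p + qnorm(0.975) * se, 1))

  tot <- colSums(m)
  shares <- if (renormalize) sweep(m, 2, pmax(tot, .Machine$double.eps), "/") else m
  labels <- tibble(
    sample_id = colnames(m),
    n_dominant = colSums(shares >= tau),
    dominant_taxon = apply(shares, 2, function(x) {
      d <- rownames(m)[x >= tau]
      if (length(d) == 0) NA_character_ else paste(d, collapse = "+")
    }),
    codominated = colSums(shares >= tau) >= 2
  )

  structure(
    list(statistic = t_obs, margin = unname(obs[["margin"]]),
         p_value = p, conf_int = ci,
         n_permutations = n_permutations, n_samples = n,
         taxa = rownames(m), tau = tau, renormalize = renormalize,
         tie_break = tie_break,
         seed = seed, labels = labels, null_counts = t_perm),
    class = "dominance_test"
  )
}

#' @export
print.dominance_test <- function(x, ...) {
  cat("Reciprocal-dominance permutation test\n")
  cat(sprintf("  taxa: %s\n", paste(x$taxa, collapse = ", ")))
  cat(sprintf("  co-dominated samples: %d of %d (tau = %g)\n",
              x$statistic, x$n_samples, x$tau))
  cat(sprintf("  one-sided p = %.4g (95%% CI %.4g-%.4g, %d permutations)\n",
              x$p_value, x$conf_int[1], x$conf_int[2], x$n_permutations))
  invisible(x)
}

#' Tidy per-sample dominance labels
#'
#' @param x A [dominance_test()] result.
#' @param ... Unused.
#' @return Tibble with one row per sample: number of dominant taxa, the
#'   dominant taxon (or "+"-joined set), and whether the sample is
#'   co-dominated.
#' @method tidy dominance_test
#' @export
tidy.dominance_test <- function(x, ...) x$labels

#' One-row summary of a dominance test
#'
#' @inheritParams tidy.dominance_test
#' @return One-row tibble: statistic, p.value, conf.low, conf.high,
#'   n.samples, n.permutations, tau.
#' @method glance dominance_test
#' @export
glance.dominance_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value,
         conf.low = x$conf_int[1], conf.high = x$conf_int[2],
         n.samples = x$n_samples, n.permutations = x$n_permutations,
         tau = x$tau)
}

#' @describeIn dominance_test Histogram of the permutation null with the
#'   observed statistic marked.
#' @param object A `dominance_test` result.
#' @param ... Unused.
#' @method autoplot dominance_test
#' @export
autoplot.dominance_test <- function(object, ...) {
  df <- tibble(t_perm = object$null_counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_perm)) +
    ggplot2::geom_bar(fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$statistic, colour = "firebrick",
                        linetype = 2) +
    ggplot2::labs(
      x = "co-dominated samples under the permutation null",
      y = "permutations",
      title = sprintf("T_obs = %d, p = %.4g", object$statistic,
                      object$p_value)
    )
}
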