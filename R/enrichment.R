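## Metabolic-module completeness and group-wise functional enrichment.

parse_module_steps <- function(modules) {
  assert_columns(modules, c("module_id", "step_index", "alternatives"),
                 "modules")
  if (nrow(modules) == 0) {
    stop_metapan("module definition table is empty",
                 class = "metapanr_definition_error")
  }
  steps <- modules |>
    mutate(kos = purrr::map(strsplit(.data$alternatives, "|", fixed = TRUE),
                            trimws))
  if (any(lengths(steps$kos) == 0) || any(vapply(steps$kos, function(k)
    any(!nzchar(k)), logical(1)))) {
    stop_metapan("every module step needs at least one non-empty KO",
                 class = "metapanr_definition_error")
  }
  steps
}

#' Metabolic module completeness
#'
#' A module is an ordered list of enzymatic steps, each satisfiable by any
#' of its alternative KO accessions ("K1|K2"). Completeness of a module in
#' a genome is the fraction of steps with at least one alternative present
#' in the genome's annotations; the module is complete when that fraction
#' reaches `threshold` (0.75 by default, inclusive).
#'
#' @param annotations Long tibble (`genome_id`, `accession`, optional
#'   `source`) of per-genome function calls.
#' @param modules Module definitions (`module_id`, `step_index`,
#'   `alternatives` with "|"-separated KO alternatives).
#' @param threshold Completion threshold on the step fraction (inclusive).
#' @param genomes Optional character vector fixing the genome universe
#'   (defaults to the genomes present in `annotations`); genomes without
#'   any annotation score 0 on every module.
#' @return Tibble with one row per (genome, module): `completeness` in
#'   \[0, 1\] and logical `complete`.
#' @examples
#' ann <- data.frame(genome_id = "g1", accession = c("K1", "K2", "K3"))
#' mod <- data.frame(module_id = "M1", step_index = 1:4,
#'                   alternatives = c("K1", "K2", "K3", "K4"))
#' module_completeness(ann, mod)
#' @export
module_completeness <- function(annotations, modules, threshold = 0.75,
                                genomes = NULL) {
  assert_columns(annotations, c("genome_id", "accession"), "annotations")
  steps <- parse_module_steps(modules)
  genomes <- genomes %||% sort(unique(annotations$genome_id))
  ko_sets <- split(annotations$accession, annotations$genome_id)

  per_module <- steps |>
    group_by(.data$module_id) |>
    summarise(kos = list(.data$kos), .groups = "drop")

  expand_grid(genome_id = genomes, module_id = per_module$module_id) |>
    left_join(per_module, by = "module_id") |>
    mutate(
      completeness = purrr::map2_dbl(.data$kos, .data$genome_id, function(kk, g) {
        present <- ko_sets[[g]] %||% character(0)
        mean(vapply(kk, function(alts) any(alts %in% present), logical(1)))
      }),
      complete = .data$completeness >= threshold
    ) |>
    select("genome_id", "module_id", "completeness", "complete") |>
    arrange(.data$genome_id, .data$module_id)
}

#' Group enrichment score for a binary trait
#'
#' The enrichment engine: presence/absence of a function across genomes is
#' modelled by a logistic (logit-link) regression on group membership, and
#' the Rao score statistic for the group term is returned. For the
#' saturated group model this statistic equals the Pearson chi-squared
#' statistic (no continuity correction) on the groups x presence
#' contingency table — `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` for two
#' groups — with a chi-squared reference on (number of groups - 1) degrees
#' of freedom. A trait present in every genome or absent from all is
#' degenerate: score 0, p 1.
#'
#' @param presence Logical (or 0/1) vector, one entry per genome.
#' @param groups Group label per genome (>= 2 groups, each non-empty).
#' @return Named list: `score`, `p_value`, `df`.
#' @examples
#' enrichment_score(rep(c(TRUE, FALSE), c(10, 10)),
#'                  rep(c("A", "B"), each = 10))
#' @export
enrichment_score <- function(presence, groups) {
  presence <- as.logical(presence)
  if (length(presence) != length(groups) || anyNA(presence) || anyNA(groups)) {
    stop_metapan("presence and groups must align with no missing values",
                 class = "metapanr_input_error")
  }
  groups <- as.factor(groups)
  if (nlevels(groups) < 2 || any(tabulate(groups) == 0)) {
    stop_metapan("need at least two non-empty groups",
                 class = "metapanr_input_error")
  }
  df <- nlevels(groups) - 1L
  if (all(presence) || !any(presence)) {
    return(list(score = 0, p_value = 1, df = df))
  }
  obs <- table(groups, factor(presence, levels = c(FALSE, TRUE)))
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  score <- sum((obs - expected)^2 / expected)
  list(score = score, p_value = pchisq(score, df, lower.tail = FALSE),
       df = df)
}

# Shared engine: presence matrix rows -> scored, BH-adjusted tibble.
enrich_presence <- function(presence_tbl, groups, id_col) {
  assert_columns(groups, c("genome_id", "group"), "groups")
  if (anyDuplicated(groups$genome_id)) {
    stop_metapan("groups table labels a genome twice",
                 class = "metapanr_input_error")
  }
  unlabeled <- setdiff(unique(presence_tbl$genome_id), groups$genome_id)
  if (length(unlabeled) > 0) {
    stop_metapan(sprintf("genome(s) without group label: %s",
                         paste(unlabeled, collapse = ", ")),
                 class = "metapanr_input_error")
  }
  glab <- setNames(as.character(groups$group), groups$genome_id)
  genome_ids <- groups$genome_id
  g <- as.factor(glab[genome_ids])

  items <- split(presence_tbl$genome_id[presence_tbl$present],
                 presence_tbl[[id_col]][presence_tbl$present])
  all_ids <- sort(unique(presence_tbl[[id_col]]))

  rows <- purrr::map(all_ids, function(id) {
    pres <- genome_ids %in% (items[[id]] %||% character(0))
    sc <- enrichment_score(pres, g)
    props <- tapply(pres, g, mean)
    pooled <- mean(pres)
    assoc <- names(props)[props > pooled]
    tibble(!!id_col := id, score = sc$score, p = sc$p_value,
           associated_groups = paste(assoc, collapse = ","),
           props = list(as.list(props)))
  }) |> list_rbind()

  rows |>
    mutate(q = p.adjust(.data$p, method = "BH")) |>
    tidyr::unnest_wider("props", names_sep = "_") |>
    relocate("q", .after = "p") |>
    arrange(desc(.data$score), .data[[id_col]])
}

#' Group-wise enrichment of functional annotations
#'
#' Tests every annotation accession for unequal presence across genome
#' groups with the score statistic of [enrichment_score()], adjusting
#' p-values by Benjamini-Hochberg across all accessions tested in the
#' call. Associated groups are those whose observed presence proportion
#' exceeds the pooled proportion.
#'
#' @param annotations Long tibble (`genome_id`, `accession`, optional
#'   `source`).
#' @param groups `genome_id` -> `group` table defining the genome universe
#'   (genomes listed here but absent from `annotations` count as lacking
#'   every function).
#' @return Tibble sorted by score (descending): `accession`, `score`, `p`,
#'   `q`, `associated_groups`, and one `props_<group>` column per group.
#' @export
enrich_functions <- function(annotations, groups) {
  assert_columns(annotations, c("genome_id", "accession"), "annotations")
  presence_tbl <- annotations |>
    distinct(.data$genome_id, .data$accession) |>
    mutate(present = TRUE)
  enrich_presence(presence_tbl, groups, "accession")
}

#' Group-wise enrichment of complete metabolic modules
#'
#' Applies the [enrich_functions()] machinery to the boolean
#' complete/incomplete matrix of a [module_completeness()] result: a
#' module is "present" in a genome when complete there.
#'
#' @param completeness A [module_completeness()] result.
#' @param groups `genome_id` -> `group` table.
#' @return Tibble as in [enrich_functions()], keyed by `module_id`.
#' @export
enrich_modules <- function(completeness, groups) {
  assert_columns(completeness, c("genome_id", "module_id", "complete"),
                 "completeness")
  presence_tbl <- completeness |>
    transmute(.data$genome_id, module_id = .data$module_id,
              present = .data$complete)
  enrich_presence(presence_tbl, groups, "module_id")
}
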