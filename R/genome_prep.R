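#' Sanitize a genome assembly
#'
#' Drops contigs shorter than `min_len` nucleotides (a 300 nt floor by
#' default; a contig of exactly `min_len` is kept) and replaces every
#' character outside the canonical alphabet A/C/G/T/N — IUPAC ambiguity
#' codes included — by N, case-insensitively. Surviving contigs keep their
#' input order.
#'
#' @param sequences Named character vector of contig sequences, or a
#'   `Biostrings::DNAStringSet`/`BStringSet`. The return type matches the
#'   input type.
#' @param min_len Minimum contig length in nucleotides (inclusive).
#' @param genome_id Optional label used in the error message when every
#'   contig is removed.
#' @return Sanitized sequences of the same type as the input.
#' @examples
#' sanitize_genome(c(c1 = "ACGRYT", c2 = "acgt"), min_len = 4)
#' @export
sanitize_genome <- function(sequences, min_len = 300, genome_id = NULL) {
  is_xss <- methods::is(sequences, "XStringSet")
  seq_chr <- if (is_xss) as.character(sequences) else sequences
  if (!is.character(seq_chr) || length(seq_chr) == 0) {
    stop_metapan("`sequences` must hold at least one contig",
                 class = "metapanr_input_error")
  }
  keep <- nchar(seq_chr) >= min_len
  if (!any(keep)) {
    stop_metapan(
      sprintf("all contigs of genome %s are shorter than %d nt",
              genome_id %||% "<unnamed>", min_len),
      class = "metapanr_empty_genome_error"
    )
  }
  out <- toupper(seq_chr[keep])
  out <- gsub("[^ACGTN]", "N", out)
  if (is_xss) Biostrings::DNAStringSet(out) else out
}

#' Filter genomes on completeness and contamination
#'
#' Applies the reference-set quality rule: a genome passes when its
#' estimated completeness is at least `min_completeness` percent
#' (inclusive) and its contamination is strictly below `max_contamination`
#' percent.
#'
#' @param records Data frame with columns `genome_id`, `completeness`,
#'   `contamination` (percent).
#' @param min_completeness Inclusive completeness floor (percent).
#' @param max_contamination Exclusive contamination ceiling (percent).
#' @return The input as a tibble with a logical `pass` column appended.
#' @examples
#' qc_filter(data.frame(genome_id = c("a", "b"),
#'                      completeness = c(95, 89),
#'                      contamination = c(1, 0)))
#' @export
qc_filter <- function(records, min_completeness = 90, max_contamination = 5) {
  assert_columns(records, c("genome_id", "completeness", "contamination"),
                 "records")
  if (any(!is.finite(records$completeness)) ||
      any(records$completeness < 0 | records$completeness > 100)) {
    stop_metapan("completeness must lie in [0, 100]",
                 class = "metapanr_validation_error")
  }
  if (any(!is.finite(records$contamination)) || any(records$contamination < 0)) {
    stop_metapan("contamination must be non-negative",
                 class = "metapanr_validation_error")
  }
  as_tibble(records) |>
    mutate(pass = .data$completeness >= min_completeness &
             .data$contamination < max_contamination)
}

#' Dereplicate genomes on average nucleotide identity
#'
#' Greedy dereplication: QC-passing genomes are ranked by the dRep-style
#' score `completeness - 5 * contamination` (ties broken by genome id,
#' ascending) and accepted in that order unless their symmetrized ANI — the
#' maximum of the two directional values, ANIb being directional — exceeds
#' `threshold` percent with an already-accepted genome. The result is
#' independent of input row order.
#'
#' @param ani Square numeric matrix of pairwise ANI percentages with genome
#'   ids as dimnames, or a long data frame with columns `genome_a`,
#'   `genome_b`, `ani`.
#' @param qc A [qc_filter()] result (or any data frame with `genome_id`,
#'   `completeness`, `contamination` and optional `pass`).
#' @param threshold Maximum tolerated symmetrized ANI percent between two
#'   retained genomes; a pair conflicts iff ANI > threshold.
#' @return Tibble with one row per QC-passing genome: `genome_id`, `score`,
#'   logical `representative`, and `representative_of` (for excluded
#'   genomes, the retained genome they collapse into; NA for
#'   representatives).
#' @examples
#' ani <- matrix(c(100, 99, 99, 100), 2, 2,
#'               dimnames = list(c("a", "b"), c("a", "b")))
#' qc <- data.frame(genome_id = c("a", "b"),
#'                  completeness = c(99, 95), contamination = c(0, 0))
#' dereplicate(ani, qc)
#' @export
dereplicate <- function(ani, qc, threshold = 98) {
  assert_columns(qc, c("genome_id", "completeness", "contamination"), "qc")
  qc <- as_tibble(qc)
  if (!"pass" %in% names(qc)) qc <- qc_filter(qc)
  candidates <- qc |> filter(.data$pass)
  if (nrow(candidates) == 0) {
    return(tibble(genome_id = character(0), score = numeric(0),
                  representative = logical(0),
                  representative_of = character(0)))
  }

  if (is.data.frame(ani)) {
    assert_columns(ani, c("genome_a", "genome_b", "ani"), "ani")
    ids <- sort(unique(c(ani$genome_a, ani$genome_b)))
    m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
    m[cbind(ani$genome_a, ani$genome_b)] <- ani$ani
    diag(m) <- 100
    ani <- m
  }
  if (!is.matrix(ani) || is.null(rownames(ani)) || is.null(colnames(ani))) {
    stop_metapan("`ani` must be a named square matrix or a long data frame",
                 class = "metapanr_input_error")
  }
  missing <- setdiff(candidates$genome_id, rownames(ani))
  if (length(missing) > 0) {
    stop_metapan(sprintf("ANI matrix lacks entries for genome(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "metapanr_input_error")
  }
  ids <- candidates$genome_id
  sub <- ani[ids, ids, drop = FALSE]
  if (anyNA(sub)) {
    bad <- which(is.na(sub), arr.ind = TRUE)[1, ]
    stop_metapan(sprintf("missing ANI value for pair (%s, %s)",
                         ids[bad[1]], ids[bad[2]]),
                 class = "metapanr_input_error")
  }
  sym <- pmax(sub, t(sub))  # conservative: more merging

  ranked <- candidates |>
    mutate(score = .data$completeness - 5 * .data$contamination) |>
    arrange(desc(.data$score), .data$genome_id)

  reps <- character(0)
  rep_of <- setNames(rep(NA_character_, nrow(ranked)), ranked$genome_id)
  for (g in ranked$genome_id) {
    conflicts <- reps[sym[g, reps] > threshold]
    if (length(conflicts) == 0) {
      reps <- c(reps, g)
    } else {
      rep_of[g] <- conflicts[1]
    }
  }
  ranked |>
    transmute(.data$genome_id, .data$score,
              representative = .data$genome_id %in% reps,
              representative_of = unname(rep_of[.data$genome_id])) |>
    arrange(.data$genome_id)
}
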