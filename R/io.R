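## Interchange-format readers and writers. Internal coordinates are
## 0-based half-open everywhere; conversions happen only at the
## parse/serialize boundary (GFF3 and samtools-depth are 1-based).

#' Read per-nucleotide coverage for one sample
#'
#' Parses either a samtools-depth style TSV (`contig  pos  depth`, 1-based
#' positions, absent positions zero) or a bedGraph (`contig  start  end
#' depth`, 0-based half-open intervals) into genome-level depth vectors,
#' zero-filling unreported positions and concatenating contigs in the
#' order given by `contigs`.
#'
#' @param path File to read. Headerless; lines starting with `#` or
#'   `track` are skipped.
#' @param contigs Contig table (`contig_id`, `length`, optional
#'   `genome_id`, `offset`). Defines contig order and lengths.
#' @param format `"depth"` or `"bedgraph"`.
#' @param sample_id Sample label attached to the output.
#' @return Tibble with one row per genome (`genome_id`, `sample_id`,
#'   list-column `depth`). Without a `genome_id` column in `contigs`, each
#'   contig is its own genome.
#' @export
read_coverage <- function(path, contigs, format = c("depth", "bedgraph"),
                          sample_id = basename(path)) {
  format <- match.arg(format)
  assert_columns(contigs, c("contig_id", "length"), "contigs")
  if (!file.exists(path)) {
    stop_metapan(sprintf("coverage file not found: %s", path),
                 class = "metapanr_input_error")
  }
  lines <- readLines(path)
  keep <- !grepl("^(#|track)", lines) & nzchar(lines)
  lines <- lines[keep]
  line_no <- which(keep)
  n_fields <- if (format == "depth") 3L else 4L
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != n_fields)
  if (length(bad) > 0) {
    stop_metapan(sprintf("malformed %s line %d in %s", format,
                         line_no[bad[1]], path),
                 class = "metapanr_parse_error")
  }

  clen <- setNames(as.integer(contigs$length), contigs$contig_id)
  vecs <- lapply(clen, function(L) integer(L))

  if (length(lines) > 0) {
    m <- matrix(unlist(parts), ncol = n_fields, byrow = TRUE)
    contig <- m[, 1]
    unknown <- setdiff(unique(contig), names(clen))
    if (length(unknown) > 0) {
      stop_metapan(sprintf("coverage references unknown contig(s): %s",
                           paste(unknown, collapse = ", ")),
                   class = "metapanr_parse_error")
    }
    if (format == "depth") {
      pos <- suppressWarnings(as.integer(m[, 2]))
      dep <- suppressWarnings(as.integer(m[, 3]))
      if (anyNA(pos) || anyNA(dep)) {
        stop_metapan(sprintf("non-numeric field at line %d in %s",
                             line_no[which(is.na(pos) | is.na(dep))[1]], path),
                     class = "metapanr_parse_error")
      }
      oob <- pos < 1 | pos > clen[contig]
      if (any(oob)) {
        i <- which(oob)[1]
        stop_metapan(sprintf("position %d beyond contig %s length %d (line %d)",
                             pos[i], contig[i], clen[contig[i]], line_no[i]),
                     class = "metapanr_bounds_error")
      }
      for (cid in unique(contig)) {
        sel <- contig == cid
        vecs[[cid]][pos[sel]] <- dep[sel]
      }
    } else {
      start <- suppressWarnings(as.integer(m[, 2]))
      end <- suppressWarnings(as.integer(m[, 3]))
      dep <- suppressWarnings(as.integer(round(as.numeric(m[, 4]))))
      if (anyNA(start) || anyNA(end) || anyNA(dep)) {
        stop_metapan(sprintf("non-numeric field in bedGraph %s", path),
                     class = "metapanr_parse_error")
      }
      oob <- start < 0 | end <= start | end > clen[contig]
      if (any(oob)) {
        i <- which(oob)[1]
        stop_metapan(sprintf("interval [%d, %d) beyond contig %s length %d (line %d)",
                             start[i], end[i], contig[i], clen[contig[i]],
                             line_no[i]),
                     class = "metapanr_bounds_error")
      }
      for (i in seq_along(contig)) {
        vecs[[contig[i]]][(start[i] + 1L):end[i]] <- dep[i]
      }
    }
  }

  per_contig <- tibble(contig_id = names(vecs), depth = unname(vecs))
  if ("genome_id" %in% names(contigs)) {
    contigs |>
      select("genome_id", "contig_id") |>
      left_join(per_contig, by = "contig_id") |>
      group_by(.data$genome_id) |>
      summarise(depth = list(unlist(.data$depth, use.names = FALSE)),
                .groups = "drop") |>
      mutate(sample_id = sample_id) |>
      select("genome_id", "sample_id", "depth")
  } else {
    per_contig |>
      transmute(genome_id = .data$contig_id, sample_id = sample_id,
                depth = .data$depth)
  }
}

#' Read coverage for a set of samples
#'
#' Applies [read_coverage()] to one file per sample and binds the results,
#' attaching site labels when metadata is given.
#'
#' @param paths Named character vector: sample_id -> file path.
#' @param contigs,format As in [read_coverage()].
#' @param metadata Optional `sample_id` -> `site` table.
#' @return Coverage tibble suitable for [detect_genomes()].
#' @export
read_coverage_set <- function(paths, contigs, format = c("depth", "bedgraph"),
                              metadata = NULL) {
  format <- match.arg(format)
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    stop_metapan("`paths` must be named by sample id",
                 class = "metapanr_input_error")
  }
  out <- purrr::imap(paths, function(p, sid) {
    read_coverage(p, contigs, format, sample_id = sid)
  }) |> list_rbind()
  if (!is.null(metadata)) {
    assert_columns(metadata, c("sample_id", "site"), "metadata")
    out <- left_join(out, distinct(metadata, .data$sample_id, .data$site),
                     by = "sample_id")
  }
  out
}

#' Read gene models from GFF3 or a tabular gene-calls file
#'
#' GFF3 coordinates (1-based, inclusive) are converted to the internal
#' 0-based half-open convention on read; tabular gene calls (`gene_id`,
#' `contig_id`, `start`, `end`, `strand`, optional `genome_id`) are taken
#' as already half-open.
#'
#' @param path File to read.
#' @param format `"gff3"` or `"halfopen"` (TSV with header).
#' @param contigs Optional contig table supplying the `contig_id` ->
#'   `genome_id` mapping for GFF3 input.
#' @return Gene-model tibble (`gene_id`, `genome_id`, `contig_id`,
#'   `start`, `end`, `strand`).
#' @export
read_gene_models <- function(path, format = c("gff3", "halfopen"),
                             contigs = NULL) {
  format <- match.arg(format)
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    genes <- tibble(
      gene_id = gr$ID %||% sprintf("gene%05d", seq_along(gr)),
      contig_id = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
      end = GenomicRanges::end(gr),
      strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+")
    )
    if (!is.null(contigs) && "genome_id" %in% names(contigs)) {
      genes <- genes |>
        left_join(select(contigs, "contig_id", "genome_id"), by = "contig_id")
    } else {
      genes$genome_id <- genes$contig_id
    }
    select(genes, "gene_id", "genome_id", "contig_id", "start", "end",
           "strand")
  } else {
    g <- readr::read_tsv(path, show_col_types = FALSE)
    assert_columns(g, c("gene_id", "contig_id", "start", "end"), "gene calls")
    if (!"genome_id" %in% names(g)) g$genome_id <- g$contig_id
    if (!"strand" %in% names(g)) g$strand <- "+"
    select(as_tibble(g), "gene_id", "genome_id", "contig_id", "start",
           "end", "strand")
  }
}

#' Write a simulated study to disk
#'
#' Serializes a [simulate_metapangenome()] result to the on-disk layout
#' the pipeline readers consume: sanitized FASTA genomes, GFF3 gene
#' models, one samtools-depth TSV per sample, and TSV tables for catalog,
#' contigs, metadata, gene clusters, annotations, modules, QC and ANI,
#' plus ground-truth TSVs.
#'
#' @param sim A [simulate_metapangenome()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a tibble manifest of the files written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(file.path(dir, "coverage"), recursive = TRUE,
             showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)

  Biostrings::writeXStringSet(sim$catalog$sequences, p("genomes.fasta"))

  genes <- sim$catalog$genes
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$ID <- genes$gene_id
  gr$type <- "gene"
  gr$source <- "metapanr"
  rtracklayer::export(gr, p("genes.gff3"), format = "gff3")

  readr::write_tsv(sim$catalog$genomes, p("catalog.tsv"))
  readr::write_tsv(sim$catalog$contigs, p("contigs.tsv"))
  readr::write_tsv(sim$metadata, p("metadata.tsv"))
  readr::write_tsv(sim$annotations$gene_clusters, p("gene_clusters.tsv"))
  readr::write_tsv(sim$annotations$annotations, p("annotations.tsv"))
  readr::write_tsv(sim$annotations$modules, p("modules.tsv"))
  readr::write_tsv(sim$qc_ani$qc, p("qc.tsv"))
  ani <- as.data.frame(sim$qc_ani$ani)
  readr::write_tsv(cbind(genome_id = rownames(sim$qc_ani$ani), ani),
                   p("ani.tsv"))
  readr::write_tsv(sim$catalog$truth$preferred_sites,
                   p("truth_preferred_sites.tsv"))
  readr::write_tsv(sim$catalog$truth$exclusive_functions,
                   p("truth_exclusive_functions.tsv"))

  contig_of <- setNames(sim$catalog$contigs$contig_id,
                        sim$catalog$contigs$genome_id)
  cov_files <- sim$profiles |>
    group_by(.data$sample_id) |>
    group_map(function(rows, key) {
      lines <- purrr::pmap(list(rows$genome_id, rows$depth),
                           function(gid, d) {
                             nz <- which(d > 0)
                             if (length(nz) == 0) return(character(0))
                             paste(contig_of[[gid]], nz, d[nz], sep = "\t")
                           })
      f <- p("coverage", paste0(key$sample_id, ".tsv"))
      writeLines(unlist(lines), f)
      f
    }) |> unlist()

  manifest <- tibble(
    file = c("genomes.fasta", "genes.gff3", "catalog.tsv", "contigs.tsv",
             "metadata.tsv", "gene_clusters.tsv", "annotations.tsv",
             "modules.tsv", "qc.tsv", "ani.tsv",
             "truth_preferred_sites.tsv", "truth_exclusive_functions.tsv",
             file.path("coverage", basename(cov_files)))
  )
  invisible(manifest)
}

#' Read an ANI matrix TSV
#'
#' Square matrix with a `genome_id` header column matching the column
#' names.
#'
#' @param path TSV file.
#' @return Numeric matrix with genome ids as dimnames.
#' @export
read_ani_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
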