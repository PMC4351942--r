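#' Build a gene/exon feature index from a GFF3 annotation
#'
#' Keeps `gene` and `exon` features; a position inside a gene span but outside
#' every exon is intronic by construction.
#'
#' @param gff Path to a GFF3 file.
#' @param seqnames Optional character vector of all valid sequence names (a
#'   position on any of them classifies as intergenic even if the annotation
#'   never mentions the sequence). Defaults to the sequences seen in the GFF.
#' @return A list of class `te_features` with `genes` and `exons` (GRanges)
#'   and `seqnames`.
#' @export
read_features <- function(gff, seqnames = NULL) {
  gr <- rtracklayer::import(gff, format = "gff3")
  genes <- gr[gr$type == "gene"]
  exons <- gr[gr$type == "exon"]
  valid <- unique(c(
    as.character(unique(GenomicRanges::seqnames(gr))),
    seqnames
  ))
  structure(
    list(genes = GenomicRanges::reduce(genes),
         exons = GenomicRanges::reduce(exons),
         seqnames = valid),
    class = "te_features"
  )
}

#' Classify genomic positions as exon, intron or intergenic
#'
#' Exon when inside any exon; intron when inside a gene but no exon; else
#' intergenic. Every valid position gets exactly one category.
#'
#' @param features A `te_features` index from [read_features()].
#' @param genome_ref,position Equal-length vectors of positions.
#' @return Character vector of categories.
#' @export
classify_positions <- function(features, genome_ref, position) {
  stopifnot(length(genome_ref) == length(position))
  bad <- setdiff(unique(genome_ref), features$seqnames)
  if (length(bad)) {
    stop("unknown sequence name: ", paste(bad, collapse = ", "))
  }
  if (length(position) == 0) return(character(0))
  q <- GenomicRanges::GRanges(genome_ref, IRanges::IRanges(position, position))
  # disjoint seqlevels (a query sequence the GFF never mentions) are a valid
  # intergenic case, not a condition worth warning about
  in_exon <- suppressWarnings(GenomicRanges::countOverlaps(q, features$exons) > 0)
  in_gene <- suppressWarnings(GenomicRanges::countOverlaps(q, features$genes) > 0)
  ifelse(in_exon, "exon", ifelse(in_gene, "intron", "intergenic"))
}

#' Annotate insertion calls with their genomic region
#'
#' @param calls A `te_calls` tibble.
#' @param features A `te_features` index.
#' @return `calls` with a `region` column added.
#' @export
annotate_calls <- function(calls, features) {
  calls$region <- classify_positions(features, calls$genome_ref, calls$position)
  calls
}

#' Permutation test for genic enrichment of insertions
#'
#' Compares the observed number of genic (exon or intron) insertions with the
#' distribution obtained by dropping the same number of positions uniformly on
#' the genome `n_perm` times. The permutation p-value uses the add-one
#' estimator `(1 + #{perm >= observed}) / (n_perm + 1)` so it can never be
#' exactly zero.
#'
#' @param features A `te_features` index.
#' @param calls A `te_calls` tibble (or tibble with `genome_ref`, `position`).
#' @param genome_lengths Named integer vector of sequence lengths.
#' @param n_perm Number of permutations (at least 100). Default 10000.
#' @param seed RNG seed.
#' @return A list of class `te_enrichment`: `observed_genic`,
#'   `expected_genic_mean`, `perm_p`, `n_calls`, `n_perm`.
#' @export
enrichment_test <- function(features, calls, genome_lengths, n_perm = 10000,
                            seed = 1) {
  stopifnot(n_perm >= 100, !is.null(names(genome_lengths)))
  n <- nrow(calls)
  stopifnot(n > 0)
  obs <- sum(classify_positions(features, calls$genome_ref, calls$position)
             != "intergenic")
  genes <- features$genes
  perm_counts <- with_seed(seed, {
    total <- n_perm * n
    chrom_idx <- sample.int(length(genome_lengths), total, replace = TRUE,
                            prob = genome_lengths)
    pos <- 1L + floor(runif(total) * genome_lengths[chrom_idx])
    q <- GenomicRanges::GRanges(names(genome_lengths)[chrom_idx],
                                IRanges::IRanges(pos, pos))
    hit <- GenomicRanges::countOverlaps(q, genes) > 0
    as.integer(rowsum(as.integer(hit), rep(seq_len(n_perm), each = n)))
  })
  structure(
    list(
      observed_genic = as.integer(obs),
      expected_genic_mean = mean(perm_counts),
      perm_p = (1 + sum(perm_counts >= obs)) / (n_perm + 1),
      n_calls = n,
      n_perm = as.integer(n_perm)
    ),
    class = "te_enrichment"
  )
}

#' @export
print.te_enrichment <- function(x, ...) {
  cat("Genic enrichment: observed", x$observed_genic, "of", x$n_calls,
      "insertions genic; expected", round(x$expected_genic_mean, 2),
      "under uniform placement; permutation p =", signif(x$perm_p, 3),
      "(", x$n_perm, "permutations )\n")
  invisible(x)
}
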