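#' Detect TE insertions end to end
#'
#' Full pipeline: build the combined genome + TE reference, align the reads
#' (or accept a pre-aligned SAM/BAM over the combined reference), classify
#' pairs, cluster and filter candidates, refine breakpoints and type zygosity;
#' optionally annotate calls against a GFF3. With `outdir` set, the call
#' table (TSV), a BED6 track and the rejected candidates are written there.
#'
#' @param genome_fasta Reference genome FASTA path.
#' @param te_fasta Single-record TE FASTA path.
#' @param fastq1,fastq2 Paired FASTQ paths (require the external `bwa`
#'   aligner), or
#' @param bam a SAM/BAM aligned to the combined reference (no aligner needed).
#' @param gff Optional GFF3 annotation for exon/intron/intergenic labels.
#' @param outdir Optional output directory.
#' @param params A [te_params()] object.
#' @param threads Aligner threads.
#' @return A `te_calls` tibble with zygosity columns; attributes `rejected`,
#'   `params` and `stats` (pair classification counts).
#' @export
detect_insertions <- function(genome_fasta, te_fasta,
                              fastq1 = NULL, fastq2 = NULL, bam = NULL,
                              gff = NULL, outdir = NULL,
                              params = te_params(), threads = 1) {
  workdir <- if (is.null(outdir)) tempfile("teloci_run_") else outdir
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  refset <- build_combined_reference(genome_fasta, te_fasta,
                                     file.path(workdir, "combined_reference.fa"))
  if (is.null(bam)) {
    if (is.null(fastq1) || is.null(fastq2)) {
      stop("supply either two FASTQ files or an aligned SAM/BAM")
    }
    bam <- align_reads(fastq1, fastq2, refset$combined_fasta,
                       file.path(workdir, "alignment.bam"),
                       threads = threads, min_score = params$min_score)
  }
  pairs <- read_pairs(bam)
  cls <- classify_pairs(pairs, refset, params)
  calls <- call_insertions(cls, refset$genome, params)
  calls <- add_zygosity(calls, cls$background, params,
                        seqnames = names(refset$genome))
  if (!is.null(gff)) {
    calls <- annotate_calls(calls, read_features(gff, seqnames = names(refset$genome)))
  }
  attr(calls, "stats") <- cls$stats
  if (!is.null(outdir)) {
    write_calls(calls,
                tsv = file.path(outdir, "insertions.tsv"),
                bed = file.path(outdir, "insertions.bed"),
                rejected = file.path(outdir, "rejected_candidates.tsv"),
                te_name = refset$te_name)
  }
  calls
}

#' Simulate a complete benchmark dataset
#'
#' Convenience wrapper producing everything needed to exercise the caller: a
#' synthetic genome, a TE-mutagenized copy with truth table, and mixed
#' heterozygous paired reads at the requested total coverage (equal read
#' amounts drawn from the mutant and reference haplotypes).
#'
#' @param n_seq,seq_len,gc,repeat_fraction Genome parameters, see
#'   [generate_genome()].
#' @param te_seq TE sequence; default a synthetic Tnt1-scale LTR element.
#' @param n_insertions,tsd_len Mutagenesis parameters, see [insert_te()].
#' @param coverage Total fold coverage of the mixed library.
#' @param zygosity `"het"` (50/50 mutant/reference mix) or `"hom"` (mutant
#'   reads only).
#' @param error_rate,read_len,insert_mean,insert_sd Read simulation
#'   parameters.
#' @param seed RNG seed; sub-seeds are derived for each stage.
#' @return A list: `genome`, `te` (named character), `mutant`, `truth`,
#'   `reads` (tibble), `te_len`.
#' @export
simulate_benchmark <- function(n_seq = 2, seq_len = 1e6, gc = 0.42,
                               repeat_fraction = 0,
                               te_seq = synthesize_te(seed = 99),
                               n_insertions = 10, tsd_len = 5,
                               coverage = 10, zygosity = "het",
                               error_rate = 0.001, read_len = 100,
                               insert_mean = 500, insert_sd = 50, seed = 1) {
  genome <- generate_genome(n_seq, seq_len, gc, repeat_fraction, seed = seed)
  mut <- insert_te(genome, te_seq, n_insertions, tsd_len = tsd_len,
                   seed = seed + 1L, zygosity = zygosity)
  hap_cov <- if (zygosity == "het") coverage / 2 else coverage
  n_pairs <- round(hap_cov * sum(nchar(genome)) / (2 * read_len))
  mut_reads <- simulate_reads(mut$mutant, coverage = hap_cov,
                              read_len = read_len, insert_mean = insert_mean,
                              insert_sd = insert_sd, error_rate = error_rate,
                              seed = seed + 2L, hap = "mut", n_pairs = n_pairs)
  if (zygosity == "het") {
    ref_reads <- simulate_reads(genome, coverage = hap_cov,
                                read_len = read_len, insert_mean = insert_mean,
                                insert_sd = insert_sd, error_rate = error_rate,
                                seed = seed + 3L, hap = "ref", n_pairs = n_pairs)
    reads <- mix_heterozygous(mut_reads, ref_reads, seed = seed + 4L)
  } else {
    reads <- mut_reads
  }
  list(genome = genome, te = te_seq, mutant = mut$mutant, truth = mut$truth,
       reads = reads, te_len = mut$te_len)
}
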