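#' Pipeline parameters
#'
#' Bundles every tunable threshold of the insertion caller into one validated
#' list. Defaults follow the published behaviour of the method: a read pair is
#' informative when at least 20 bp of it derive from the TE, a candidate locus
#' is reported when it has at least 3 supporting pairs, average mapping quality
#' of at least 1, local depth between 2 and 300, and support on both flanks.
#'
#' @param min_te_overlap Minimum TE-derived bases (bp) for a pair to count as
#'   informative. Default 20, matching the aligner's minimum output score so a
#'   20 bp segment is also alignable.
#' @param min_clip_match Minimum soft-clip length (bp) that is compared against
#'   the TE termini when looking for junction-spanning reads. Shorter clips are
#'   treated as alignment noise. Default 8.
#' @param max_mismatch_frac Maximum mismatch fraction allowed when matching a
#'   soft-clipped segment to a TE terminus. Default 0.1.
#' @param max_genome_clip Maximum incidental soft-clipping (bp) tolerated on
#'   the genome-side mate of a cross pair for it to count as completely
#'   mapped. Default 5.
#' @param min_support Minimum number of informative pairs per reported locus.
#'   Default 3.
#' @param min_avg_mapq Minimum mean mapping quality of the genome-side
#'   alignments of the informative pairs (screens out repetitive regions).
#'   Default 1.
#' @param depth_range Length-2 numeric; admissible mean sequencing depth in the
#'   window around the candidate. Default c(2, 300).
#' @param insert_mean,insert_sd Library insert size mean and standard
#'   deviation in bp. Defaults 500 and 50.
#' @param cluster_window Single-linkage clustering distance for evidence (bp).
#'   Default `insert_mean + 3 * insert_sd`.
#' @param max_tsd Largest plausible target-site duplication (bp); junction
#'   pairs implying a longer one are flagged instead. Default 20.
#' @param alpha Significance level of the one-sided binomial zygosity test.
#'   Default 0.05.
#' @param p_background Expected fraction of background pairs at a heterozygous
#'   locus; the theoretical supportive:background ratio of 2:1 gives 1/3.
#' @param min_score Minimum alignment output score passed to the external
#'   aligner (`bwa mem -T`). Default 20.
#'
#' @return A list of class `te_params`.
#' @examples
#' p <- te_params(min_support = 4)
#' p$min_support
#' @export
te_params <- function(min_te_overlap = 20,
                      min_clip_match = 8,
                      max_mismatch_frac = 0.1,
                      max_genome_clip = 5,
                      min_support = 3,
                      min_avg_mapq = 1,
                      depth_range = c(2, 300),
                      insert_mean = 500,
                      insert_sd = 50,
                      cluster_window = insert_mean + 3 * insert_sd,
                      max_tsd = 20,
                      alpha = 0.05,
                      p_background = 1 / 3,
                      min_score = 20) {
  p <- list(
    min_te_overlap = as.integer(min_te_overlap),
    min_clip_match = as.integer(min_clip_match),
    max_mismatch_frac = max_mismatch_frac,
    max_genome_clip = as.integer(max_genome_clip),
    min_support = as.integer(min_support),
    min_avg_mapq = min_avg_mapq,
    depth_range = as.numeric(depth_range),
    insert_mean = insert_mean,
    insert_sd = insert_sd,
    cluster_window = cluster_window,
    max_tsd = as.integer(max_tsd),
    alpha = alpha,
    p_background = p_background,
    min_score = as.integer(min_score)
  )
  stopifnot(
    p$min_te_overlap >= 1,
    p$min_clip_match >= 1,
    p$max_mismatch_frac >= 0, p$max_mismatch_frac < 0.5,
    p$min_support >= 1,
    length(p$depth_range) == 2, p$depth_range[1] <= p$depth_range[2],
    p$insert_mean > 0, p$insert_sd >= 0,
    p$cluster_window > 0,
    p$max_tsd >= 0,
    p$alpha > 0, p$alpha < 1,
    p$p_background > 0, p$p_background < 1
  )
  structure(p, class = "te_params")
}

#' Read or write parameters as YAML
#'
#' Round-trips a [te_params()] object through a YAML configuration file so a
#' run can be reproduced from its config.
#'
#' @param params A `te_params` object.
#' @param path File path.
#' @return `write_params()` returns `path` invisibly; `read_params()` returns
#'   a `te_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "te_params"))
  yaml::write_yaml(unclass(params), path, precision = 15)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(te_params, x)
}

# reverse complement of plain character vectors (ACGTN)
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# deterministic scoped RNG: run code under a seed without touching the
# caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
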