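# shared fixture builders; everything is generated in code at test time

# local reverse complement so oracles do not depend on package internals
revcomp <- function(x) {
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

make_refset <- function(genome, te) {
  list(genome = genome, te_name = names(te), te_sequence = unname(te))
}

# one SAM record row for write_sam()
sam_record <- function(qname, flag, rname, pos, cigar, seq, mapq = 60) {
  tibble::tibble(qname = qname, flag = as.integer(flag), rname = rname,
                 pos = as.integer(pos), mapq = as.integer(mapq),
                 cigar = cigar, seq = seq)
}

# a small deterministic genome + TE used across tests
fixture_genome <- function(seq_len = 50000, n_seq = 1, seed = 101) {
  generate_genome(n_seq = n_seq, seq_len = seq_len, seed = seed)
}

fixture_te <- function(length = 1000, ltr_len = 150, seed = 102) {
  synthesize_te(length = length, ltr_len = ltr_len, seed = seed)
}

# build a pair of plain-genome records (background-style) at a position
background_pair_records <- function(qname, genome, chrom, start,
                                    insert = 400, read_len = 100) {
  s <- genome[[chrom]]
  p1 <- start
  p2 <- start + insert - read_len
  r1 <- substr(s, p1, p1 + read_len - 1)
  r2 <- revcomp(substr(s, p2, p2 + read_len - 1))
  dplyr::bind_rows(
    sam_record(qname, 1 + 64, chrom, p1, paste0(read_len, "M"), r1),
    sam_record(qname, 1 + 128 + 16, chrom, p2, paste0(read_len, "M"), revcomp(r2))
  )
}

# write records + references to a temporary SAM and read them back as pairs
pairs_from_records <- function(records, genome, te) {
  seqlengths <- c(
    stats::setNames(nchar(genome), names(genome)),
    stats::setNames(nchar(te), names(te))
  )
  sam <- tempfile(fileext = ".sam")
  write_sam(records, seqlengths, sam)
  read_pairs(sam)
}

# simulate, project to truth SAM and run the caller without an aligner
run_projected_pipeline <- function(sim, params = te_params()) {
  sam <- tempfile(fileext = ".sam")
  project_truth_alignments(sim$reads, sim$genome, names(sim$te), sim$te_len,
                           sim$truth, sam)
  pairs <- read_pairs(sam)
  refset <- make_refset(sim$genome, sim$te)
  cls <- classify_pairs(pairs, refset, params)
  calls <- call_insertions(cls, refset$genome, params)
  add_zygosity(calls, cls$background, params, seqnames = names(sim$genome))
}

# independent oracle for the binomial lower tail: term-by-term summation on
# log scale, no calls into pbinom
binom_tail_oracle <- function(k, n, p) {
  i <- 0:k
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log(1 - p)))
}

# independent oracle for clip matching: slide the clip over both TE termini in
# both orientations and report the best Hamming distance
clip_match_oracle <- function(clip, te) {
  k <- nchar(clip)
  tlen <- nchar(te)
  cands <- c(
    substr(te, 1, k),
    substr(te, tlen - k + 1, tlen),
    revcomp(substr(te, 1, k)),
    revcomp(substr(te, tlen - k + 1, tlen))
  )
  min(vapply(cands, function(cand) {
    sum(utf8ToInt(clip) != utf8ToInt(cand))
  }, numeric(1)))
}
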