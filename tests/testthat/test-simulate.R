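kmer_dup_fraction <- function(seq, k = 100) {
  starts <- seq_len(nchar(seq) - k + 1)
  kmers <- substring(seq, starts, starts + k - 1)
  tab <- table(kmers)
  sum(tab[tab > 1]) / length(kmers)  # fraction of non-unique k-mers
}

test_that("genome generation is seeded and controls repeat content", {
  g1 <- generate_genome(n_seq = 2, seq_len = 5e4, seed = 3)
  g2 <- generate_genome(n_seq = 2, seq_len = 5e4, seed = 3)
  expect_identical(g1, g2)
  expect_identical(names(g1), c("chr1", "chr2"))
  expect_equal(nchar(g1[["chr1"]]), 5e4)

  # repeat-free: no duplicated tiling 100-mers
  expect_equal(kmer_dup_fraction(g1[["chr1"]]), 0)

  # 20% repeat fraction: a substantial share of k-mers recur
  gr <- generate_genome(n_seq = 1, seq_len = 1e5, repeat_fraction = 0.2,
                        repeat_unit_len = 500, seed = 4)
  expect_gte(kmer_dup_fraction(gr[["chr1"]], 100), 0.10)
})

test_that("TE insertion bookkeeping and splice geometry are exact", {
  g <- stats::setNames(fixture_genome(seq_len = 10000, seed = 5), "chr1")
  te <- synthesize_te(length = 1000, ltr_len = 100, seed = 6)
  mut <- insert_te(g, te, 1, tsd_len = 5, min_gap = 2000, seed = 7)
  expect_equal(nchar(mut$mutant[["chr1"]]), 10000 + 1000 + 5)

  mut0 <- insert_te(g, te, 1, tsd_len = 0, min_gap = 2000, seed = 7)
  expect_equal(nchar(mut0$mutant[["chr1"]]), 10000 + 1000)

  # string-splice oracle at the insertion site
  p <- mut$truth$position
  ref <- g[["chr1"]]
  m <- mut$mutant[["chr1"]]
  ins <- if (mut$truth$te_strand == "+") unname(te) else revcomp(unname(te))
  expect_identical(substr(m, 1, p + 4), substr(ref, 1, p + 4))
  expect_identical(substr(m, p + 5, p + 4 + 1000), ins)
  expect_identical(substr(m, p + 5 + 1000, p + 9 + 1000), substr(ref, p, p + 4))
  expect_identical(substr(m, p + 10 + 1000, nchar(m)),
                   substr(ref, p + 5, nchar(ref)))
})

test_that("multiple insertions stay apart and positions are unique", {
  g <- fixture_genome(seq_len = 2e5, seed = 8)
  te <- fixture_te()
  mut <- insert_te(g, te, 10, min_gap = 10000, seed = 9)
  tr <- mut$truth
  expect_equal(nrow(tr), 10L)
  expect_true(all(diff(tr$position) >= 10000))
  expect_equal(anyDuplicated(tr$position), 0L)
  expect_error(insert_te(g, te, 100, min_gap = 10000, seed = 9),
               "fewer insertions")
})

test_that("read simulation respects coverage, purity and error calibration", {
  g <- fixture_genome(seq_len = 1e5, seed = 10)
  reads <- simulate_reads(g, coverage = 10, error_rate = 0, seed = 11)
  expect_equal(nrow(reads), round(10 * 1e5 / 200))

  # error-free reads are exact substrings (or reverse complements)
  s <- g[["chr1"]]
  idx <- seq(1, nrow(reads), length.out = 50)
  for (i in as.integer(idx)) {
    fs <- reads$frag_start[i]; fe <- fs + reads$frag_len[i] - 1
    if (reads$strand[i] == "+") {
      expect_identical(reads$read1[i], substr(s, fs, fs + 99))
      expect_identical(reads$read2[i], revcomp(substr(s, fe - 99, fe)))
    } else {
      expect_identical(reads$read1[i], revcomp(substr(s, fe - 99, fe)))
      expect_identical(reads$read2[i], substr(s, fs, fs + 99))
    }
  }

  # empirical substitution rate within 3 standard errors of the target
  e <- 0.001
  re <- simulate_reads(g, coverage = 10, error_rate = e, seed = 11)
  mism <- sum(vapply(seq_len(nrow(re)), function(i) {
    fs <- re$frag_start[i]; fe <- fs + re$frag_len[i] - 1
    truth1 <- if (re$strand[i] == "+") substr(s, fs, fs + 99) else
      revcomp(substr(s, fe - 99, fe))
    truth2 <- if (re$strand[i] == "+") revcomp(substr(s, fe - 99, fe)) else
      substr(s, fs, fs + 99)
    sum(utf8ToInt(re$read1[i]) != utf8ToInt(truth1)) +
      sum(utf8ToInt(re$read2[i]) != utf8ToInt(truth2))
  }, numeric(1)))
  total <- 200 * nrow(re)
  se <- sqrt(e * (1 - e) / total)
  expect_lt(abs(mism / total - e), 3 * se)

  # determinism
  expect_identical(re, simulate_reads(g, coverage = 10, error_rate = e, seed = 11))

  # too-short sequences are skipped with a warning
  tiny <- c(g, stats::setNames("ACGTACGT", "mini"))
  expect_warning(simulate_reads(tiny, coverage = 2, seed = 1), "skipping")
})

test_that("heterozygous mixing interleaves both haplotypes evenly", {
  g <- fixture_genome(seq_len = 1e5, seed = 12)
  m1 <- simulate_reads(g, coverage = 4, seed = 13, hap = "mut")
  r1 <- simulate_reads(g, coverage = 4, seed = 14, hap = "ref")
  mix <- mix_heterozygous(m1, r1, seed = 15)
  expect_equal(nrow(mix), nrow(m1) + nrow(r1))
  frac_mut <- mean(mix$hap == "mut")
  expect_lt(abs(frac_mut - 0.5), 0.02)
  expect_identical(mix, mix_heterozygous(m1, r1, seed = 15))
  expect_warning(mix_heterozygous(m1, utils::head(r1, nrow(r1) - 100), seed = 1),
                 "differ")
})

test_that("truth projection places reads on the segment geometry dictates", {
  g <- stats::setNames(fixture_genome(seq_len = 20000, seed = 16), "chr1")
  te <- synthesize_te(length = 2000, ltr_len = 200, seed = 17)
  mut <- insert_te(g, te, 1, tsd_len = 5, min_gap = 5000, seed = 18,
                   positions = tibble::tibble(genome_ref = "chr1",
                                              position = 8000,
                                              te_strand = "+"))
  p <- 8000L
  # mutant coordinates: left junction ends at 8004, TE occupies 8005..10004
  frags <- tibble::tibble(
    chrom = "chr1",
    frag_start = c(8500L,              # wholly inside the TE copy
                   8004L - 69L,        # read1 straddles the left junction by 30
                   6000L),             # wholly genomic
    frag_len = 500L,
    strand = "+"
  )
  reads <- reads_from_fragments(mut$mutant, frags, seed = 19, hap = "mut")
  sam <- tempfile(fileext = ".sam")
  project_truth_alignments(reads, g, names(te), mut$te_len, mut$truth, sam)
  rec <- read_pairs(sam)
  r_te <- rec[rec$qname == reads$qname[1] & rec$mate == 1, ]
  expect_equal(r_te$rname, names(te))
  expect_equal(r_te$pos, 8500L - 8004L)  # TE coordinate of the fragment start
  r_j <- rec[rec$qname == reads$qname[2] & rec$mate == 1, ]
  expect_equal(r_j$rname, "chr1")
  expect_equal(r_j$cigar, "70M30S")
  expect_equal(r_j$ref_end, 8004L)
  r_g <- rec[rec$qname == reads$qname[3] & rec$mate == 1, ]
  expect_equal(r_g$cigar, "100M")
  expect_equal(r_g$pos, 6000L)
})

test_that("the evaluator bins matches by distance and conserves counts", {
  truth <- tibble::tibble(genome_ref = "chr1",
                          position = c(1000L, 50000L, 90000L),
                          tsd_len = 5L, te_strand = "+", zygosity = "het")
  calls <- tibble::tibble(genome_ref = "chr1",
                          position = c(1000L, 50080L, 90600L, 20000L))
  bm <- evaluate_calls(calls, truth)
  s <- glance(bm)
  expect_equal(s$n_exact, 1L)
  expect_equal(s$n_within100, 1L)
  expect_equal(s$n_within500, 0L)
  expect_equal(s$n_false_positive, 2L)
  expect_equal(s$n_missed, 1L)
  expect_equal(s$n_exact + s$n_within100 + s$n_within500 + s$n_false_positive,
               s$n_calls)
  expect_equal(s$recall, 2 / 3)

  # 101-500 bp counts as recovered but inexact
  bm2 <- evaluate_calls(tibble::tibble(genome_ref = "chr1", position = 1300L),
                        truth)
  expect_equal(glance(bm2)$n_within500, 1L)

  # each truth record is matched at most once: the second nearby call is a
  # false positive, not a second match
  bm3 <- evaluate_calls(
    tibble::tibble(genome_ref = "chr1", position = c(1000L, 1010L)), truth
  )
  expect_equal(glance(bm3)$n_exact, 1L)
  expect_equal(glance(bm3)$n_false_positive, 1L)
  expect_equal(nrow(tidy(bm3)), 1L)

  expect_error(evaluate_calls(calls, dplyr::bind_rows(truth, truth[1, ])),
               "unique")
})
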