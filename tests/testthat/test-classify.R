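# build one pair: mate1 on the genome, mate2 wholly on the TE (cross-style)
cross_pair_records <- function(qname, genome, te, gpos, te_pos = 1,
                               read_len = 100, g_strand = "+") {
  s <- genome[["chr1"]]
  r1 <- substr(s, gpos, gpos + read_len - 1)
  r2 <- substr(unname(te), te_pos, te_pos + read_len - 1)
  f1 <- 1 + 64 + if (g_strand == "-") 16 else 0
  dplyr::bind_rows(
    sam_record(qname, f1, "chr1", gpos, paste0(read_len, "M"), r1),
    sam_record(qname, 1 + 128 + 16, names(te), te_pos, paste0(read_len, "M"), r2)
  )
}

# mate1 on the genome with a terminal soft clip taken from the TE start
clipped_pair_records <- function(qname, genome, te, gend, clip_len,
                                 read_len = 100, mismatches = 0) {
  s <- genome[["chr1"]]
  m <- read_len - clip_len
  clip <- substr(unname(te), 1, clip_len)
  if (mismatches > 0) {
    for (i in seq_len(mismatches)) {
      pos <- 2 * i
      cur <- substr(clip, pos, pos)
      substr(clip, pos, pos) <- setdiff(c("A", "C", "G", "T"), cur)[1]
    }
  }
  r1 <- paste0(substr(s, gend - m + 1, gend), clip)
  r2 <- revcomp(substr(unname(te), 301, 300 + read_len))
  dplyr::bind_rows(
    sam_record(qname, 1 + 64, "chr1", gend - m + 1,
               paste0(m, "M", clip_len, "S"), r1),
    sam_record(qname, 1 + 128 + 16, names(te), 301, paste0(read_len, "M"),
               revcomp(r2))
  )
}

test_that("te_overlap_length follows the mapped / supplementary / clip cascade", {
  g <- fixture_genome()
  te <- fixture_te()
  refset <- make_refset(g, te)

  pr <- pairs_from_records(cross_pair_records("c1", g, te, 5000), g, te)
  ov <- te_overlap_length(pr[pr$qname == "c1", ], refset$te_name, refset$te_sequence)
  expect_equal(ov$bp, 100L)
  expect_equal(ov$how, "mapped_to_te")

  # 19-bp clip identical to the TE 5' terminus: measured but sub-threshold
  recs <- dplyr::bind_rows(
    clipped_pair_records("k19", g, te, 8000, 19),
    background_pair_records("bg", g, "chr1", 2000)
  )
  recs <- recs[recs$qname != "k19" | bitwAnd(recs$flag, 128L) == 0, ]
  recs <- dplyr::bind_rows(recs, {
    r2 <- substr(g[["chr1"]], 8300, 8399)
    sam_record("k19", 1 + 128 + 16, "chr1", 8300, "100M", r2)
  })
  pr <- pairs_from_records(recs, g, te)
  ov <- te_overlap_length(pr[pr$qname == "k19", ], refset$te_name, refset$te_sequence)
  expect_equal(ov$bp, 19L)
  expect_equal(ov$how, "clip_matches_te_terminus")
  cls <- classify_pairs(pr, refset)
  expect_false("k19" %in% cls$evidence$qname)  # 19 < 20: uninformative

  ovbg <- te_overlap_length(pr[pr$qname == "bg", ], refset$te_name, refset$te_sequence)
  expect_equal(ovbg$bp, 0L)
  expect_equal(ovbg$how, "none")
})

test_that("clip matching tolerates mismatches up to the configured fraction", {
  g <- fixture_genome()
  te <- fixture_te()
  refset <- make_refset(g, te)
  # 30-bp clip with 2 mismatches: 2/30 < 0.1, must match
  pr <- pairs_from_records(clipped_pair_records("m2", g, te, 9000, 30,
                                                mismatches = 2), g, te)
  ov <- te_overlap_length(pr[pr$qname == "m2", ], refset$te_name,
                          refset$te_sequence, max_mismatch_frac = 0.1)
  expect_equal(ov$bp, 100L)  # TE mate dominates the cascade
  clip <- substr(pr$seq[pr$rname == "chr1"], 71, 100)
  expect_equal(clip_match_oracle(clip, refset$te_sequence), 2)
  cls <- classify_pairs(pr, refset)
  expect_equal(cls$evidence$category, "clipped")
  # 4 mismatches in 30 bp exceeds the fraction: junction not recognized, and
  # the heavily clipped genome mate disqualifies the pair as a cross pair
  pr4 <- pairs_from_records(clipped_pair_records("m4", g, te, 9000, 30,
                                                 mismatches = 4), g, te)
  cls4 <- classify_pairs(pr4, refset)
  expect_equal(nrow(cls4$evidence), 0L)
})

test_that("pairs partition into the four categories with correct sides", {
  g <- fixture_genome()
  te <- fixture_te()
  refset <- make_refset(g, te)
  recs <- dplyr::bind_rows(
    background_pair_records("bg1", g, "chr1", 1000),
    background_pair_records("bg2", g, "chr1", 3000),
    cross_pair_records("crL", g, te, 5000, g_strand = "+"),
    clipped_pair_records("clp", g, te, 9000, 40)
  )
  pr <- pairs_from_records(recs, g, te)
  cls <- classify_pairs(pr, refset)
  st <- cls$stats
  expect_equal(st$background, 2L)
  expect_equal(st$cross, 1L)
  expect_equal(st$clipped, 1L)
  expect_equal(st$background + st$cross + st$clipped + st$uninformative, st$total)
  # + strand genome mate of a cross pair supports the left junction
  expect_equal(cls$evidence$side[cls$evidence$qname == "crL"], "left")
  # clip at the alignment end: clip_coord is the last aligned reference base
  expect_equal(cls$evidence$clip_coord[cls$evidence$qname == "clp"], 9000L)
  expect_equal(cls$evidence$side[cls$evidence$qname == "clp"], "left")
  # background index holds the outer insert interval
  expect_equal(nrow(cls$background), 2L)
  expect_true(all(cls$background$end - cls$background$start + 1 == 400))
})

test_that("both mates unmapped or TE-only pairs are uninformative", {
  g <- fixture_genome()
  te <- fixture_te()
  refset <- make_refset(g, te)
  tlen <- nchar(unname(te))
  recs <- dplyr::bind_rows(
    sam_record("uu", 1 + 64 + 4 + 8, "*", 0, "*", strrep("A", 100)),
    sam_record("uu", 1 + 128 + 4 + 8, "*", 0, "*", strrep("C", 100)),
    sam_record("tt", 1 + 64, names(te), 11, "100M", substr(unname(te), 11, 110)),
    sam_record("tt", 1 + 128 + 16, names(te), 201, "100M",
               revcomp(revcomp(substr(unname(te), 201, 300))))
  )
  pr <- pairs_from_records(recs, g, te)
  cls <- classify_pairs(pr, refset)
  expect_equal(cls$stats$uninformative, 2L)
  expect_equal(nrow(cls$evidence), 0L)
})

test_that("reverse-complementing the TE flips orientation but not categories", {
  g <- fixture_genome(seq_len = 2e5, seed = 21)
  te <- fixture_te()
  sim0 <- insert_te(g, te, 2, seed = 22)
  reads <- simulate_reads(sim0$mutant, coverage = 15, error_rate = 0,
                          seed = 23, hap = "mut")
  sam <- tempfile(fileext = ".sam")
  project_truth_alignments(reads, g, names(te), sim0$te_len, sim0$truth, sam)
  pr <- read_pairs(sam)
  fwd <- classify_pairs(pr, make_refset(g, te))
  te_rc <- stats::setNames(revcomp(unname(te)), names(te))
  rev <- classify_pairs(pr, make_refset(g, te_rc))
  # clip-matched evidence exists under both references
  f <- fwd$evidence[order(fwd$evidence$qname), ]
  r <- rev$evidence[order(rev$evidence$qname), ]
  expect_identical(f$qname, r$qname)
  expect_identical(f$category, r$category)
  expect_identical(f$clip_coord, r$clip_coord)
  clipped <- f$category == "clipped"
  expect_true(any(clipped))
  expect_true(all(f$te_strand[clipped] != r$te_strand[clipped]))
})

test_that("an insertion-free genome yields zero evidence", {
  g <- fixture_genome(seq_len = 1e5, seed = 31)
  te <- fixture_te()
  reads <- simulate_reads(g, coverage = 10, error_rate = 0.001, seed = 32,
                          hap = "ref")
  sam <- tempfile(fileext = ".sam")
  project_truth_alignments(reads, g, names(te), nchar(unname(te)),
                           tibble::tibble(genome_ref = character(0),
                                          position = integer(0),
                                          tsd_len = integer(0),
                                          te_strand = character(0)),
                           sam)
  pr <- read_pairs(sam)
  cls <- classify_pairs(pr, make_refset(g, te))
  expect_equal(nrow(cls$evidence), 0L)
  expect_equal(cls$stats$background, nrow(reads))
})

test_that("the 20-bp overlap threshold is the exact onset of informativeness", {
  g <- fixture_genome()
  te <- fixture_te()
  refset <- make_refset(g, te)
  min_informative <- integer(0)
  for (k in 10:30) {
    # variant 1: mate partially aligned on the TE for k bases
    recs1 <- dplyr::bind_rows(
      sam_record("v1", 1 + 64, "chr1", 5000, "100M",
                 substr(g[["chr1"]], 5000, 5099)),
      sam_record("v1", 1 + 128 + 16, names(te), 1,
                 paste0(k, "M", 100 - k, "S"),
                 paste0(substr(unname(te), 1, k), strrep("A", 100 - k)))
    )
    cls1 <- classify_pairs(pairs_from_records(recs1, g, te), refset)
    # variant 2: genome mate with a k-bp soft clip matching the TE start
    recs2 <- clipped_pair_records("v2", g, te, 9000, k)
    recs2 <- recs2[1, ]
    recs2 <- dplyr::bind_rows(recs2, sam_record(
      "v2", 1 + 128 + 16, "chr1", 9300, "100M",
      substr(g[["chr1"]], 9300, 9399)
    ))
    cls2 <- classify_pairs(pairs_from_records(recs2, g, te), refset)
    if (nrow(cls1$evidence) > 0) min_informative <- c(min_informative, k)
    if (nrow(cls2$evidence) > 0) min_informative <- c(min_informative, k)
  }
  expect_equal(min(min_informative), 20L)
})
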