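# random DNA string at a given GC content
.random_dna <- function(n, gc, as_vector = FALSE) {
  b <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
              prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  if (as_vector) b else paste(b, collapse = "")
}

#' Synthesize a TE sequence with the geometry of an LTR retroelement
#'
#' Generates a random element of the stated total length whose two ends are
#' identical long terminal repeats (LTRs) in the same orientation, emulating
#' the structure of the Tnt1 retrotransposon (5,334 bp with 610-bp LTRs). The
#' sequence itself is synthetic: it reproduces the element's length and repeat
#' geometry, not its composition.
#'
#' @param length Total element length in bp. Default 5334.
#' @param ltr_len Length of each terminal repeat. Default 610.
#' @param gc GC content. Default 0.42.
#' @param seed RNG seed.
#' @param name Sequence name. Default `"TE1"`.
#' @return Named character vector of length 1.
#' @export
synthesize_te <- function(length = 5334, ltr_len = 610, gc = 0.42, seed = 1,
                          name = "TE1") {
  stopifnot(length > 2 * ltr_len, ltr_len >= 0)
  with_seed(seed, {
    ltr <- if (ltr_len > 0) .random_dna(ltr_len, gc) else ""
    internal <- .random_dna(length - 2 * ltr_len, gc)
    stats::setNames(paste0(ltr, internal, ltr), name)
  })
}

#' Generate a synthetic genome
#'
#' I.i.d. bases at the given GC content, optionally with interspersed exact
#' copies of one repeat unit totalling `repeat_fraction` of each sequence, so
#' that the repeat-region failure mode of insertion calling can be exercised.
#' Deterministic given `seed`.
#'
#' @param n_seq Number of sequences (named `chr1`, `chr2`, ...).
#' @param seq_len Length of each sequence in bp.
#' @param gc GC content. Default 0.42.
#' @param repeat_fraction Fraction of each sequence overwritten with copies of
#'   the repeat unit. Default 0.
#' @param repeat_unit_len Repeat unit length in bp. Default 500.
#' @param seed RNG seed.
#' @return Named character vector of sequences.
#' @export
generate_genome <- function(n_seq = 2, seq_len = 1e6, gc = 0.42,
                            repeat_fraction = 0, repeat_unit_len = 500,
                            seed = 1) {
  stopifnot(n_seq >= 1, seq_len >= 1, gc > 0, gc < 1,
            repeat_fraction >= 0, repeat_fraction < 1)
  with_seed(seed, {
    unit <- if (repeat_fraction > 0) .random_dna(repeat_unit_len, gc) else NULL
    seqs <- vapply(seq_len(n_seq), function(i) {
      s <- .random_dna(seq_len, gc)
      if (repeat_fraction > 0) {
        n_copies <- round(seq_len * repeat_fraction / repeat_unit_len)
        starts <- sort(sample.int(seq_len - repeat_unit_len + 1, n_copies))
        for (st in starts) {
          substr(s, st, st + repeat_unit_len - 1) <- unit
        }
      }
      s
    }, character(1))
    stats::setNames(seqs, paste0("chr", seq_len(n_seq)))
  })
}

#' Insert TE copies into a genome with target-site duplications
#'
#' At each sampled position `p`, the `tsd_len` reference bases starting at `p`
#' are duplicated on both sides of the inserted element (reverse-complemented
#' element for `-` insertions), mimicking the target-site duplication created
#' during transposition. Insertion positions keep at least `min_gap` bp from
#' each other and from the sequence ends.
#'
#' @param genome Named character vector of reference sequences.
#' @param te_seq TE sequence (character scalar).
#' @param n_insertions Total number of insertions, allocated to sequences
#'   proportionally to length (ignored when `positions` is given).
#' @param tsd_len TSD length in bp. Default 5, the value characteristic of
#'   Tnt1.
#' @param min_gap Minimum spacing in bp. Default 10000.
#' @param orientation_mix Probability that an insertion is on the `+` strand.
#'   Default 0.5.
#' @param seed RNG seed.
#' @param positions Optional tibble (`genome_ref`, `position`, and optionally
#'   `te_strand`) fixing the insertion sites explicitly.
#' @param zygosity Label recorded in the truth table (`"het"` or `"hom"`);
#'   actual zygosity is realised later by read mixing.
#' @return A list: `mutant` (named character), `truth` (tibble `genome_ref`,
#'   `position` = 1-based TSD start, `tsd_len`, `te_strand`, `zygosity`),
#'   `te_len`.
#' @export
insert_te <- function(genome, te_seq, n_insertions, tsd_len = 5,
                      min_gap = 10000, orientation_mix = 0.5, seed = 1,
                      positions = NULL, zygosity = "het") {
  te_seq <- unname(te_seq)
  te_len <- nchar(te_seq)
  stopifnot(tsd_len >= 0)
  truth <- with_seed(seed, {
    if (is.null(positions)) {
      lens <- nchar(genome)
      alloc <- floor(n_insertions * lens / sum(lens))
      rem <- n_insertions - sum(alloc)
      if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
      purrr::map2_dfr(names(genome), alloc, function(chrom, k) {
        if (k == 0) return(NULL)
        len <- nchar(genome[[chrom]])
        avail <- len - 2 * min_gap - (k - 1) * min_gap - tsd_len
        if (avail < k) {
          stop("cannot place ", k, " insertions ", min_gap, " bp apart on ",
               chrom, "; try fewer insertions or a smaller min_gap")
        }
        x <- sort(sample.int(avail, k))
        tibble(genome_ref = chrom,
               position = as.integer(min_gap + x + (seq_len(k) - 1L) * min_gap))
      })
    } else {
      tibble(genome_ref = positions$genome_ref,
             position = as.integer(positions$position),
             te_strand = if ("te_strand" %in% names(positions)) {
               positions$te_strand
             } else NA_character_)
    }
  })
  truth <- truth %>% arrange(.data$genome_ref, .data$position)
  if (anyDuplicated(truth[c("genome_ref", "position")])) {
    stop("insertion positions must be unique per sequence")
  }
  if (!"te_strand" %in% names(truth)) truth$te_strand <- NA_character_
  na_idx <- is.na(truth$te_strand)
  if (any(na_idx)) {
    truth$te_strand[na_idx] <- with_seed(seed + 1L, {
      ifelse(runif(sum(na_idx)) < orientation_mix, "+", "-")
    })
  }
  truth$tsd_len <- as.integer(tsd_len)
  truth$zygosity <- zygosity

  te_rc <- revcomp(te_seq)
  mutant <- vapply(names(genome), function(chrom) {
    tr <- truth[truth$genome_ref == chrom, ]
    ref <- genome[[chrom]]
    if (nrow(tr) == 0) return(ref)
    p <- tr$position
    stopifnot(all(p >= 1), all(p + tsd_len - 1 <= nchar(ref)))
    ins <- ifelse(tr$te_strand == "+", te_seq, te_rc)
    parts <- character(2 * nrow(tr) + 1)
    prev <- 1L
    for (i in seq_len(nrow(tr))) {
      parts[2 * i - 1] <- substr(ref, prev, p[i] + tsd_len - 1L)
      parts[2 * i] <- ins[i]
      prev <- p[i]
    }
    parts[2 * nrow(tr) + 1] <- substr(ref, prev, nchar(ref))
    paste(parts, collapse = "")
  }, character(1))
  names(mutant) <- names(genome)
  list(mutant = mutant, truth = truth, te_len = te_len)
}

# substitution errors at a per-base rate, applied in place
.add_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0) return(reads)
  rl <- nchar(reads)
  total <- sum(rl)
  n_err <- rbinom(1, total, error_rate)
  if (n_err == 0) return(reads)
  stopifnot(length(unique(rl)) == 1)  # constant read length
  flat <- sample.int(total, n_err)
  ridx <- (flat - 1L) %/% rl[1] + 1L
  ppos <- (flat - 1L) %% rl[1] + 1L
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  for (j in seq_len(n_err)) {
    i <- ridx[j]; p <- ppos[j]
    cur <- substr(reads[i], p, p)
    ch <- alt[[cur]]
    substr(reads[i], p, p) <- ch[sample.int(length(ch), 1)]
  }
  reads
}

#' Turn genomic fragments into paired reads
#'
#' Extracts the two outermost `read_len` bp of each fragment as a paired-end
#' read (inner mate reverse-complemented; for `-` strand fragments the roles
#' are swapped) and applies per-base substitution errors. Read names encode
#' the origin (`haplotype:sequence:fragment_start:fragment_length:strand:i`)
#' so that truth-projected alignments can be reconstructed.
#'
#' @param seqs Named character vector of source sequences.
#' @param fragments Tibble with `chrom`, `frag_start`, `frag_len`, `strand`.
#' @param read_len Read length in bp.
#' @param error_rate Per-base substitution error rate.
#' @param seed RNG seed (errors only).
#' @param hap Haplotype tag recorded in the name (e.g. `"ref"`, `"mut"`).
#' @return Tibble `qname`, `hap`, `chrom`, `frag_start`, `frag_len`, `strand`,
#'   `read1`, `read2`.
#' @export
reads_from_fragments <- function(seqs, fragments, read_len = 100,
                                 error_rate = 0, seed = 1, hap = "ref") {
  stopifnot(all(fragments$frag_len >= 2 * read_len))
  out <- purrr::map_dfr(split(fragments, fragments$chrom), function(fr) {
    s <- seqs[[fr$chrom[1]]]
    fs <- fr$frag_start
    fe <- fs + fr$frag_len - 1L
    stopifnot(all(fs >= 1), all(fe <= nchar(s)))
    left <- substring(s, fs, fs + read_len - 1L)
    right_rc <- revcomp(substring(s, fe - read_len + 1L, fe))
    plus <- fr$strand == "+"
    tibble(
      chrom = fr$chrom, frag_start = as.integer(fs),
      frag_len = as.integer(fr$frag_len), strand = fr$strand,
      read1 = ifelse(plus, left, right_rc),
      read2 = ifelse(plus, right_rc, left)
    )
  })
  if (nrow(out) == 0) {
    return(tibble(qname = character(0), hap = character(0), chrom = character(0),
                  frag_start = integer(0), frag_len = integer(0),
                  strand = character(0), read1 = character(0), read2 = character(0)))
  }
  out <- with_seed(seed, {
    out$read1 <- .add_errors(out$read1, error_rate)
    out$read2 <- .add_errors(out$read2, error_rate)
    out
  })
  out$hap <- hap
  out$qname <- paste(hap, out$chrom, out$frag_start, out$frag_len, out$strand,
                     seq_len(nrow(out)), sep = ":")
  out[, c("qname", "hap", "chrom", "frag_start", "frag_len", "strand",
          "read1", "read2")]
}

#' Simulate paired-end reads
#'
#' Uniform fragment starts, fragment lengths from a normal distribution
#' truncated at twice the read length, inner mate reverse-complemented, and
#' per-base substitution errors — the parameter subset of the pIRS read
#' simulator used for short-insert libraries (no indel errors, no GC bias;
#' base qualities are constant Q30 and never used by the caller).
#'
#' @param seqs Named character vector of source sequences.
#' @param coverage Mean fold coverage to simulate.
#' @param read_len Read length in bp. Default 100.
#' @param insert_mean,insert_sd Fragment length distribution. Defaults 500
#'   and 50.
#' @param error_rate Per-base substitution rate. Default 0.001.
#' @param seed RNG seed.
#' @param hap Haplotype tag for read names.
#' @param n_pairs Optional explicit pair count, overriding `coverage` (used
#'   e.g. to draw equal read amounts from haplotypes of unequal length).
#' @return Read tibble as in [reads_from_fragments()].
#' @export
simulate_reads <- function(seqs, coverage, read_len = 100, insert_mean = 500,
                           insert_sd = 50, error_rate = 0.001, seed = 1,
                           hap = "ref", n_pairs = NULL) {
  stopifnot(insert_mean > 2 * read_len, error_rate >= 0, error_rate < 0.1)
  usable <- nchar(seqs) >= 2 * read_len
  if (any(!usable)) {
    warning("skipping sequences shorter than one fragment: ",
            paste(names(seqs)[!usable], collapse = ", "))
    seqs <- seqs[usable]
  }
  lens <- nchar(seqs)
  if (is.null(n_pairs)) n_pairs <- round(coverage * sum(lens) / (2 * read_len))
  alloc <- floor(n_pairs * lens / sum(lens))
  rem <- n_pairs - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
  frags <- with_seed(seed, {
    purrr::map_dfr(seq_along(seqs), function(i) {
      k <- alloc[i]
      if (k == 0) return(NULL)
      len <- lens[i]
      fl <- pmin(pmax(round(rnorm(k, insert_mean, insert_sd)), 2L * read_len), len)
      fs <- 1L + floor(runif(k) * (len - fl + 1))
      tibble(chrom = names(seqs)[i], frag_start = as.integer(fs),
             frag_len = as.integer(fl),
             strand = sample(c("+", "-"), k, replace = TRUE))
    })
  })
  reads_from_fragments(seqs, frags, read_len = read_len,
                       error_rate = error_rate, seed = seed + 1L, hap = hap)
}

#' Mix mutant and reference reads into a heterozygous library
#'
#' Interleaves two read sets (simulated at equal coverage from the mutant and
#' the unmodified reference) in random order, preserving pair integrity, to
#' emulate sequencing of a genome heterozygous for every insertion.
#'
#' @param mutant_reads,reference_reads Read tibbles from [simulate_reads()].
#' @param seed RNG seed for the interleaving order.
#' @return One combined read tibble.
#' @export
mix_heterozygous <- function(mutant_reads, reference_reads, seed = 1) {
  n1 <- nrow(mutant_reads); n2 <- nrow(reference_reads)
  if (max(n1, n2) > 0 && abs(n1 - n2) / max(n1, n2) > 0.01) {
    warning("mutant and reference pair counts differ by more than 1% (",
            n1, " vs ", n2, ")")
  }
  both <- bind_rows(mutant_reads, reference_reads)
  with_seed(seed, both[sample.int(nrow(both)), , drop = FALSE])
}

#' Keep the first fraction of a read set
#'
#' Because simulated fragments are independent draws, the leading rows of a
#' read tibble are themselves a valid lower-coverage library; nested subsets
#' give structurally monotone coverage series.
#'
#' @param reads Read tibble.
#' @param fraction Fraction of pairs to keep.
#' @return Read tibble with `round(nrow * fraction)` rows.
#' @export
downsample_reads <- function(reads, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  utils::head(reads, round(nrow(reads) * fraction))
}

#' Write paired reads to two FASTQ files
#'
#' @param reads Read tibble.
#' @param fastq1,fastq2 Output paths.
#' @return `c(fastq1, fastq2)`, invisibly.
#' @export
write_fastq <- function(reads, fastq1, fastq2) {
  q1 <- strrep("?", nchar(reads$read1))
  q2 <- strrep("?", nchar(reads$read2))
  writeLines(paste0("@", reads$qname, "\n", reads$read1, "\n+\n", q1), fastq1)
  writeLines(paste0("@", reads$qname, "\n", reads$read2, "\n+\n", q2), fastq2)
  invisible(c(fastq1, fastq2))
}
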