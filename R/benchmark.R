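# mutant-coordinate segment map for one chromosome: alternating genome and TE
# segments implied by the insertion truth table (TSD bases duplicated, so the
# genome segment before insertion i ends at position + tsd_len - 1 and the one
# after restarts at position)
.segment_map <- function(truth_chrom, ref_len, te_len) {
  k <- nrow(truth_chrom)
  segs <- vector("list", 2 * k + 1)
  mut_cursor <- 1L
  ref_cursor <- 1L
  for (i in seq_len(k)) {
    p <- truth_chrom$position[i]
    t <- truth_chrom$tsd_len[i]
    g_len <- (p + t - 1L) - ref_cursor + 1L
    segs[[2 * i - 1]] <- tibble(
      type = "genome", mut_start = mut_cursor, mut_end = mut_cursor + g_len - 1L,
      ref_start = ref_cursor, te_strand = NA_character_
    )
    mut_cursor <- mut_cursor + g_len
    segs[[2 * i]] <- tibble(
      type = "te", mut_start = mut_cursor, mut_end = mut_cursor + te_len - 1L,
      ref_start = NA_integer_, te_strand = truth_chrom$te_strand[i]
    )
    mut_cursor <- mut_cursor + te_len
    ref_cursor <- p
  }
  g_len <- ref_len - ref_cursor + 1L
  segs[[2 * k + 1]] <- tibble(
    type = "genome", mut_start = mut_cursor, mut_end = mut_cursor + g_len - 1L,
    ref_start = ref_cursor, te_strand = NA_character_
  )
  bind_rows(segs)
}

.cigar_sms <- function(lead, m, trail) {
  paste0(ifelse(lead > 0, paste0(lead, "S"), ""), m, "M",
         ifelse(trail > 0, paste0(trail, "S"), ""))
}

#' Project simulated reads to their true alignments on the combined reference
#'
#' Emits, for every read, the alignment it must have on the combined
#' genome + TE reference if alignment were perfect: reads from the reference
#' haplotype and reads wholly inside unchanged genome segments map to the
#' genome, reads wholly inside an inserted element map to the TE reference
#' (strand-flipped for `-` insertions), and junction-straddling reads map to
#' the segment carrying most of the read with the remainder soft-clipped —
#' with the CIGAR computed from the known splice geometry. This provides an
#' aligner-free oracle for the downstream caller.
#'
#' @param reads Read tibble from [simulate_reads()] /
#'   [reads_from_fragments()], with `hap` equal to `"ref"` (reference
#'   haplotype coordinates) or anything else (mutant haplotype coordinates).
#' @param genome Named character vector of reference sequences.
#' @param te_name TE reference name.
#' @param te_len TE length in bp.
#' @param truth Truth tibble from [insert_te()].
#' @param path Output SAM path.
#' @param read_len Read length. Default 100.
#' @param mapq Mapping quality written for every record. Default 60.
#' @return `path`, invisibly.
#' @export
project_truth_alignments <- function(reads, genome, te_name, te_len, truth,
                                     path, read_len = 100, mapq = 60) {
  stopifnot(nrow(reads) > 0)
  fs <- reads$frag_start
  fe <- fs + reads$frag_len - 1L
  plus <- reads$strand == "+"
  mates <- bind_rows(
    tibble(qname = reads$qname, hap = reads$hap, chrom = reads$chrom,
           mate = 1L,
           a = as.integer(ifelse(plus, fs, fe - read_len + 1L)),
           mstrand = ifelse(plus, "+", "-"),
           seq = reads$read1),
    tibble(qname = reads$qname, hap = reads$hap, chrom = reads$chrom,
           mate = 2L,
           a = as.integer(ifelse(plus, fe - read_len + 1L, fs)),
           mstrand = ifelse(plus, "-", "+"),
           seq = reads$read2)
  )
  mates$b <- mates$a + read_len - 1L
  mates$fwd_seq <- ifelse(mates$mstrand == "+", mates$seq, revcomp(mates$seq))

  out <- vector("list", 0)
  ref_rows <- mates[mates$hap == "ref", , drop = FALSE]
  if (nrow(ref_rows) > 0) {
    out <- c(out, list(tibble(
      qname = ref_rows$qname, mate = ref_rows$mate, rname = ref_rows$chrom,
      pos = ref_rows$a, aln_strand = ref_rows$mstrand,
      cigar = paste0(read_len, "M"), seq = ref_rows$fwd_seq
    )))
  }
  mut_rows <- mates[mates$hap != "ref", , drop = FALSE]
  for (chrom in unique(mut_rows$chrom)) {
    mr <- mut_rows[mut_rows$chrom == chrom, , drop = FALSE]
    segmap <- .segment_map(truth[truth$genome_ref == chrom, , drop = FALSE],
                           nchar(genome[[chrom]]), te_len)
    ia <- findInterval(mr$a, segmap$mut_start)
    ib <- findInterval(mr$b, segmap$mut_start)
    single <- ia == ib
    sg <- mr[single, , drop = FALSE]
    si <- ia[single]
    stype <- segmap$type[si]
    # fast path: read wholly inside one segment
    g <- stype == "genome"
    if (any(g)) {
      out <- c(out, list(tibble(
        qname = sg$qname[g], mate = sg$mate[g], rname = chrom,
        pos = as.integer(segmap$ref_start[si[g]] + (sg$a[g] - segmap$mut_start[si[g]])),
        aln_strand = sg$mstrand[g], cigar = paste0(read_len, "M"),
        seq = sg$fwd_seq[g]
      )))
    }
    tp <- stype == "te" & segmap$te_strand[si] == "+"
    if (any(tp)) {
      out <- c(out, list(tibble(
        qname = sg$qname[tp], mate = sg$mate[tp], rname = te_name,
        pos = as.integer(sg$a[tp] - segmap$mut_start[si[tp]] + 1L),
        aln_strand = sg$mstrand[tp], cigar = paste0(read_len, "M"),
        seq = sg$fwd_seq[tp]
      )))
    }
    tm <- stype == "te" & segmap$te_strand[si] == "-"
    if (any(tm)) {
      out <- c(out, list(tibble(
        qname = sg$qname[tm], mate = sg$mate[tm], rname = te_name,
        pos = as.integer(te_len - (sg$b[tm] - segmap$mut_start[si[tm]])),
        aln_strand = ifelse(sg$mstrand[tm] == "+", "-", "+"),
        cigar = paste0(read_len, "M"),
        seq = revcomp(sg$fwd_seq[tm])
      )))
    }
    # junction reads: decompose over segments, align the largest block
    jr <- mr[!single, , drop = FALSE]
    jia <- ia[!single]; jib <- ib[!single]
    if (nrow(jr) > 0) {
      jrec <- purrr::map_dfr(seq_len(nrow(jr)), function(i) {
        idx <- jia[i]:jib[i]
        oa <- pmax(jr$a[i], segmap$mut_start[idx])
        ob <- pmin(jr$b[i], segmap$mut_end[idx])
        w <- ob - oa + 1L
        score <- w + 0.5 * (segmap$type[idx] == "genome")
        j <- idx[which.max(score)]
        oj_a <- pmax(jr$a[i], segmap$mut_start[j])
        oj_b <- pmin(jr$b[i], segmap$mut_end[j])
        lead <- oj_a - jr$a[i]
        trail <- jr$b[i] - oj_b
        m <- oj_b - oj_a + 1L
        if (segmap$type[j] == "genome") {
          tibble(qname = jr$qname[i], mate = jr$mate[i], rname = chrom,
                 pos = as.integer(segmap$ref_start[j] + (oj_a - segmap$mut_start[j])),
                 aln_strand = jr$mstrand[i],
                 cigar = .cigar_sms(lead, m, trail), seq = jr$fwd_seq[i])
        } else if (segmap$te_strand[j] == "+") {
          tibble(qname = jr$qname[i], mate = jr$mate[i], rname = te_name,
                 pos = as.integer(oj_a - segmap$mut_start[j] + 1L),
                 aln_strand = jr$mstrand[i],
                 cigar = .cigar_sms(lead, m, trail), seq = jr$fwd_seq[i])
        } else {
          tibble(qname = jr$qname[i], mate = jr$mate[i], rname = te_name,
                 pos = as.integer(te_len - (oj_b - segmap$mut_start[j])),
                 aln_strand = ifelse(jr$mstrand[i] == "+", "-", "+"),
                 cigar = .cigar_sms(trail, m, lead), seq = revcomp(jr$fwd_seq[i]))
        }
      })
      out <- c(out, list(jrec))
    }
  }
  rec <- bind_rows(out) %>% arrange(.data$qname, .data$mate)
  stopifnot(nrow(rec) == 2 * nrow(reads))
  # mate strand for the flag: rows come in (mate1, mate2) pairs after sorting
  other_idx <- seq_len(nrow(rec)) + ifelse(rec$mate == 1L, 1L, -1L)
  mate_rev <- rec$aln_strand[other_idx] == "-"
  rec$flag <- 1L +
    ifelse(rec$mate == 1L, 64L, 128L) +
    ifelse(rec$aln_strand == "-", 16L, 0L) +
    ifelse(mate_rev, 32L, 0L)
  rec$mapq <- as.integer(mapq)
  # SEQ must be reference-oriented: fwd_seq is mutant-forward, which equals
  # reference-forward on genome and '+' TE segments; '-' TE segments were
  # already reverse-complemented above
  seqlengths <- c(stats::setNames(nchar(genome), names(genome)),
                  stats::setNames(te_len, te_name))
  write_sam(rec[, c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")],
            seqlengths, path)
  invisible(path)
}

#' Score calls against a truth table
#'
#' Greedy nearest-first matching of calls to truth records on the same
#' sequence, each truth record used at most once; only matches within
#' `fp_dist` count. Matched calls are binned by distance into exact
#' (`<= exact_tol`), within 100 bp, and within 500 bp (bins are mutually
#' exclusive, so their counts plus false positives sum to the number of
#' calls). Calls farther than `fp_dist` from every unmatched truth record are
#' false positives.
#'
#' @param calls `te_calls` tibble (or any tibble with `genome_ref`,
#'   `position`).
#' @param truth Truth tibble from [insert_te()].
#' @param exact_tol Distance treated as exact. Default 0.
#' @param near_tol Near-match bin limit. Default 100.
#' @param fp_dist Beyond this distance a call is a false positive.
#'   Default 500.
#' @return A list of class `te_benchmark`: `summary` (one-row tibble with
#'   `n_calls`, `n_truth`, `n_exact`, `n_within100`, `n_within500`,
#'   `n_false_positive`, `n_missed`, `recall`, `fp_rate`) and `matches`
#'   (per-match tibble).
#' @export
evaluate_calls <- function(calls, truth, exact_tol = 0, near_tol = 100,
                           fp_dist = 500) {
  if (anyDuplicated(truth[, c("genome_ref", "position")])) {
    stop("truth positions must be unique per sequence")
  }
  ct <- as_tibble(calls)
  tt <- as_tibble(truth)
  n_calls <- nrow(ct)
  n_truth <- nrow(tt)
  matches <- tibble(call = integer(0), truth = integer(0),
                    genome_ref = character(0), call_position = integer(0),
                    truth_position = integer(0), distance = integer(0))
  if (n_calls > 0 && n_truth > 0) {
    ct$.call <- seq_len(n_calls)
    tt$.truth <- seq_len(n_truth)
    cand <- dplyr::inner_join(
      ct[, c(".call", "genome_ref", "position")],
      tt[, c(".truth", "genome_ref", "position")],
      by = "genome_ref", suffix = c("_call", "_truth"),
      relationship = "many-to-many"
    ) %>%
      mutate(distance = abs(.data$position_call - .data$position_truth)) %>%
      filter(.data$distance <= fp_dist) %>%
      arrange(.data$distance, .data$.call, .data$.truth)
    used_c <- logical(n_calls)
    used_t <- logical(n_truth)
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      ci <- cand$.call[i]; ti <- cand$.truth[i]
      if (!used_c[ci] && !used_t[ti]) {
        used_c[ci] <- TRUE
        used_t[ti] <- TRUE
        keep[i] <- TRUE
      }
    }
    m <- cand[keep, , drop = FALSE]
    matches <- tibble(
      call = m$.call, truth = m$.truth, genome_ref = m$genome_ref,
      call_position = as.integer(m$position_call),
      truth_position = as.integer(m$position_truth),
      distance = as.integer(m$distance)
    )
  }
  d <- matches$distance
  n_exact <- sum(d <= exact_tol)
  n_within100 <- sum(d > exact_tol & d <= near_tol)
  n_within500 <- sum(d > near_tol & d <= fp_dist)
  n_matched <- nrow(matches)
  summary <- tibble(
    n_calls = n_calls, n_truth = n_truth,
    n_exact = as.integer(n_exact), n_within100 = as.integer(n_within100),
    n_within500 = as.integer(n_within500),
    n_false_positive = as.integer(n_calls - n_matched),
    n_missed = as.integer(n_truth - n_matched),
    recall = if (n_truth > 0) n_matched / n_truth else NA_real_,
    fp_rate = if (n_calls > 0) (n_calls - n_matched) / n_calls else NA_real_
  )
  structure(list(summary = summary, matches = matches), class = "te_benchmark")
}

#' @export
print.te_benchmark <- function(x, ...) {
  cat("TE insertion benchmark\n")
  print(x$summary)
  invisible(x)
}
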