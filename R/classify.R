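# hamming distance between equal-length strings (vectorized over pairs)
.hamming <- function(a, b) {
  if (length(a) == 0) return(integer(0))
  mapply(function(x, y) sum(utf8ToInt(x) != utf8ToInt(y)), a, b, USE.NAMES = FALSE)
}

# Match soft-clipped segments against the two TE termini in both orientations.
# `side` is the position of the clip on the reference ("right" = clip follows
# the aligned block, i.e. the read runs genome -> TE and supports the LEFT
# junction; "left" = clip precedes the block, RIGHT junction). A right-side
# clip must equal the first k bases of the inserted element (TE start forward
# for a '+' insertion, reverse complement of the TE end for a '-' insertion);
# a left-side clip must equal the element's last k bases.
.match_clips <- function(clip_seq, side, te_seq, max_mismatch_frac) {
  n <- length(clip_seq)
  if (n == 0) {
    return(tibble(matched = logical(0), vote = character(0),
                  te_end = character(0), mismatches = integer(0)))
  }
  k <- nchar(clip_seq)
  tlen <- nchar(te_seq)
  te_start_fwd <- substr(rep(te_seq, n), 1, pmin(k, tlen))
  te_end_fwd <- substring(rep(te_seq, n), pmax(tlen - k + 1, 1), tlen)
  cand_plus <- ifelse(side == "right", te_start_fwd, te_end_fwd)
  cand_minus <- ifelse(side == "right", revcomp(te_end_fwd), revcomp(te_start_fwd))
  end_plus <- ifelse(side == "right", "start", "end")
  end_minus <- ifelse(side == "right", "end", "start")
  usable <- k <= tlen
  mm_plus <- rep(NA_integer_, n)
  mm_minus <- rep(NA_integer_, n)
  mm_plus[usable] <- .hamming(clip_seq[usable], cand_plus[usable])
  mm_minus[usable] <- .hamming(clip_seq[usable], cand_minus[usable])
  lim <- floor(k * max_mismatch_frac)
  plus_ok <- usable & mm_plus <= lim
  minus_ok <- usable & mm_minus <= lim
  take_plus <- plus_ok & (!minus_ok | mm_plus <= mm_minus)
  matched <- plus_ok | minus_ok
  tibble(
    matched = matched,
    vote = ifelse(!matched, NA_character_, ifelse(take_plus, "+", "-")),
    te_end = ifelse(!matched, NA_character_, ifelse(take_plus, end_plus, end_minus)),
    mismatches = ifelse(!matched, NA_integer_,
                        as.integer(ifelse(take_plus, mm_plus, mm_minus)))
  )
}

#' TE-derived bases of one read pair
#'
#' Measures how many query bases of a pair are attributable to the TE:
#' (a) the aligned length of a mate whose primary alignment is on the TE
#' reference, else (b) the aligned length of a supplementary alignment on the
#' TE, else (c) the length of the longest soft-clipped segment matching either
#' TE terminus (in either orientation) within `max_mismatch_frac`, else 0.
#'
#' @param pair Rows of a [read_pairs()] tibble belonging to one query name.
#' @param te_name Name of the TE reference sequence.
#' @param te_sequence TE nucleotide sequence (character scalar).
#' @param max_mismatch_frac Maximum mismatch fraction for clip matching.
#' @param min_clip Smallest soft clip worth matching (bp). Default 5.
#' @return A list with elements `bp` (integer) and `how` (one of
#'   `"mapped_to_te"`, `"supplementary_to_te"`, `"clip_matches_te_terminus"`,
#'   `"none"`).
#' @export
te_overlap_length <- function(pair, te_name, te_sequence,
                              max_mismatch_frac = 0.1, min_clip = 5) {
  stopifnot(length(unique(pair$qname)) == 1)
  mapped <- pair[!pair$unmapped, , drop = FALSE]
  if (nrow(mapped) == 0) stop("pair has no mapped mate")
  prim_te <- mapped[!mapped$is_supp & mapped$rname == te_name, , drop = FALSE]
  if (nrow(prim_te) > 0) {
    return(list(bp = max(prim_te$aln_qlen), how = "mapped_to_te"))
  }
  supp_te <- mapped[mapped$is_supp & mapped$rname == te_name, , drop = FALSE]
  if (nrow(supp_te) > 0) {
    return(list(bp = max(supp_te$aln_qlen), how = "supplementary_to_te"))
  }
  gen <- mapped[!mapped$is_supp & mapped$rname != te_name, , drop = FALSE]
  best <- 0L
  for (i in seq_len(nrow(gen))) {
    sq <- gen$seq[i]
    if (gen$trail_clip[i] >= min_clip) {
      cs <- substr(sq, nchar(sq) - gen$trail_clip[i] + 1, nchar(sq))
      m <- .match_clips(cs, "right", te_sequence, max_mismatch_frac)
      if (m$matched && gen$trail_clip[i] > best) best <- gen$trail_clip[i]
    }
    if (gen$lead_clip[i] >= min_clip) {
      cs <- substr(sq, 1, gen$lead_clip[i])
      m <- .match_clips(cs, "left", te_sequence, max_mismatch_frac)
      if (m$matched && gen$lead_clip[i] > best) best <- gen$lead_clip[i]
    }
  }
  if (best > 0) list(bp = as.integer(best), how = "clip_matches_te_terminus")
  else list(bp = 0L, how = "none")
}

#' Classify all read pairs into background / cross / clipped / uninformative
#'
#' Partitions every pair exactly once. Background pairs have both mates on the
#' same genome sequence with no TE evidence; informative pairs carry at least
#' `min_te_overlap` TE-derived bases and a genome anchor, and are `clipped`
#' when a read spans the insertion junction (detected through a supplementary
#' alignment on the TE or a soft clip matching a TE terminus; clipped takes
#' precedence over cross) and `cross` when one mate is completely mapped to
#' the genome while its mate maps to the TE. Everything else is
#' uninformative. Evidence whose genome-side alignment points rightward
#' supports the left junction; leftward-pointing evidence the right junction.
#'
#' @param pairs A [read_pairs()] tibble.
#' @param refset A `te_reference` from [build_combined_reference()], or any
#'   list with `te_name` and `te_sequence`.
#' @param params A [te_params()] object.
#' @return A list of class `te_classified`:
#' \describe{
#'   \item{evidence}{tibble of informative pairs, sorted by
#'     (`genome_ref`, `genome_pos`): `qname`, `category`, `genome_ref`,
#'     `genome_pos` (junction-proximal anchor), `side`, `te_overlap_bp`,
#'     `clip_coord`, `te_end`, `te_strand` (per-pair orientation estimate),
#'     `mapq`.}
#'   \item{background}{tibble of background pair outer insert intervals
#'     (`qname`, `rname`, `start`, `end`) for zygosity counting.}
#'   \item{coverage}{slim tibble of all genome-side primary alignments
#'     (`rname`, `pos`, `ref_end`) for local depth computation.}
#'   \item{stats}{one-row tibble of per-category pair counts.}
#' }
#' @export
classify_pairs <- function(pairs, refset, params = te_params()) {
  te_name <- refset$te_name
  te_seq <- refset$te_sequence
  tlen <- nchar(te_seq)
  rec <- as_tibble(pairs)
  io_stats <- attr(pairs, "stats")

  empty_ev <- tibble(
    qname = character(0), category = character(0), genome_ref = character(0),
    genome_pos = integer(0), side = character(0), te_overlap_bp = integer(0),
    clip_coord = integer(0), te_end = character(0), te_strand = character(0),
    mapq = integer(0)
  )
  empty_bg <- tibble(qname = character(0), rname = character(0),
                     start = integer(0), end = integer(0))
  empty_cov <- tibble(rname = character(0), pos = integer(0), ref_end = integer(0))
  if (nrow(rec) == 0) {
    out <- list(evidence = empty_ev, background = empty_bg, coverage = empty_cov,
                stats = tibble(background = 0L, cross = 0L, clipped = 0L,
                               uninformative = 0L, total = 0L, orphan = 0L))
    class(out) <- "te_classified"
    return(out)
  }

  rec$on_te <- !rec$unmapped & !is.na(rec$rname) & rec$rname == te_name
  rec$on_gen <- !rec$unmapped & !is.na(rec$rname) & !rec$on_te
  prim <- rec[!rec$is_supp, , drop = FALSE]
  supp <- rec[rec$is_supp, , drop = FALSE]
  gp <- prim[prim$on_gen, , drop = FALSE]

  # (a) best primary-on-TE per pair
  tp <- prim %>%
    filter(.data$on_te) %>%
    group_by(.data$qname) %>%
    dplyr::slice_max(.data$aln_qlen, n = 1, with_ties = FALSE) %>%
    ungroup() %>%
    dplyr::transmute(
      qname = .data$qname, te_bp_a = .data$aln_qlen,
      te_strand_a = .data$strand,
      te_end_a = as.character(ifelse((.data$pos + .data$ref_end) / 2 <= tlen / 2,
                                     "start", "end"))
    )

  # (b) best supplementary-on-TE per pair, joined to its genome-side carrier
  sp <- supp %>%
    filter(.data$on_te) %>%
    group_by(.data$qname) %>%
    dplyr::slice_max(.data$aln_qlen, n = 1, with_ties = FALSE) %>%
    ungroup() %>%
    dplyr::transmute(
      qname = .data$qname, supp_mate = .data$mate, te_bp_b = .data$aln_qlen,
      te_supp_strand = .data$strand,
      te_end_b = as.character(ifelse((.data$pos + .data$ref_end) / 2 <= tlen / 2,
                                     "start", "end"))
    )
  spj <- sp %>%
    left_join(
      gp %>% dplyr::select("qname", "mate", g_pos = "pos", g_end = "ref_end",
                           g_strand = "strand", g_mapq = "mapq",
                           g_lead = "lead_clip", g_trail = "trail_clip"),
      by = c("qname", "supp_mate" = "mate")
    ) %>%
    filter(!is.na(.data$g_pos), .data$g_lead + .data$g_trail > 0) %>%
    mutate(
      sj_clip_side = as.character(ifelse(.data$g_trail >= .data$g_lead,
                                         "right", "left")),
      sj_coord = as.integer(ifelse(.data$sj_clip_side == "right",
                                   .data$g_end, .data$g_pos)),
      sj_vote = as.character(ifelse(.data$g_strand == .data$te_supp_strand,
                                    "+", "-")),
      sj_mapq = as.integer(.data$g_mapq)
    ) %>%
    dplyr::select("qname", "te_bp_b", "te_end_b", "sj_clip_side", "sj_coord",
                  "sj_vote", "sj_mapq")

  # junction reads dominated by the TE: primary on the TE, supplementary on
  # the genome — the supplementary provides the genome anchor and clip point
  tpm <- prim %>%
    filter(.data$on_te) %>%
    dplyr::select("qname", "mate", tp_strand = "strand")
  sgj <- supp %>%
    filter(.data$on_gen) %>%
    dplyr::inner_join(tpm, by = c("qname", "mate")) %>%
    group_by(.data$qname) %>%
    dplyr::slice_max(.data$aln_qlen, n = 1, with_ties = FALSE) %>%
    ungroup() %>%
    dplyr::transmute(
      qname = .data$qname,
      sg_ref = .data$rname,
      sg_clip_side = as.character(ifelse(.data$trail_clip >= .data$lead_clip,
                                         "right", "left")),
      sg_coord = as.integer(ifelse(.data$trail_clip >= .data$lead_clip,
                                   .data$ref_end, .data$pos)),
      sg_vote = as.character(ifelse(.data$strand == .data$tp_strand, "+", "-")),
      sg_mapq = as.integer(.data$mapq)
    )

  # (c) soft clips of genome-side primaries matched against the TE termini
  mcm <- params$min_clip_match
  cl <- bind_rows(
    gp %>%
      filter(.data$trail_clip >= mcm) %>%
      mutate(clip_side = "right",
             clip_seq = substr(.data$seq, nchar(.data$seq) - .data$trail_clip + 1,
                               nchar(.data$seq)),
             clip_len = .data$trail_clip,
             clip_coord = .data$ref_end),
    gp %>%
      filter(.data$lead_clip >= mcm) %>%
      mutate(clip_side = "left",
             clip_seq = substr(.data$seq, 1, .data$lead_clip),
             clip_len = .data$lead_clip,
             clip_coord = .data$pos)
  )
  if (nrow(cl) > 0) {
    mres <- .match_clips(cl$clip_seq, cl$clip_side, te_seq, params$max_mismatch_frac)
    cl <- dplyr::bind_cols(cl, mres)
  } else {
    cl$matched <- logical(0)
    cl$vote <- character(0)
    cl$te_end <- character(0)
  }
  clm <- cl %>%
    filter(.data$matched) %>%
    group_by(.data$qname) %>%
    dplyr::slice_max(.data$clip_len, n = 1, with_ties = FALSE) %>%
    ungroup() %>%
    dplyr::transmute(
      qname = .data$qname, cm_len = .data$clip_len,
      cm_clip_side = .data$clip_side, cm_coord = as.integer(.data$clip_coord),
      cm_vote = .data$vote, cm_te_end = .data$te_end, cm_mapq = .data$mapq
    )

  # genome-side summary per pair
  gsum <- gp %>%
    group_by(.data$qname) %>%
    summarise(
      n_gen = dplyr::n(),
      gen_ref = .data$rname[1],
      gen_same_ref = all(.data$rname == .data$rname[1]),
      bg_start = suppressWarnings(min(.data$pos)),
      bg_end = suppressWarnings(max(.data$ref_end)),
      g1_pos = .data$pos[1], g1_end = .data$ref_end[1],
      g1_strand = .data$strand[1], g1_mapq = .data$mapq[1],
      g1_totclip = .data$lead_clip[1] + .data$trail_clip[1],
      .groups = "drop"
    )

  psum <- prim %>%
    group_by(.data$qname) %>%
    summarise(
      n_te_prim = sum(.data$on_te),
      n_gen_prim = sum(.data$on_gen),
      .groups = "drop"
    )

  pd <- psum %>%
    left_join(tp, by = "qname") %>%
    left_join(spj, by = "qname") %>%
    left_join(gsum, by = "qname") %>%
    left_join(clm, by = "qname") %>%
    left_join(sgj, by = "qname")

  pd <- pd %>% mutate(
    te_bp = dplyr::case_when(
      !is.na(.data$te_bp_a) ~ .data$te_bp_a,
      !is.na(.data$te_bp_b) ~ .data$te_bp_b,
      !is.na(.data$cm_len) ~ .data$cm_len,
      TRUE ~ 0L
    ),
    use_sg = .data$n_gen_prim == 0 & !is.na(.data$sg_coord),
    informative = .data$te_bp >= params$min_te_overlap &
      (.data$n_gen_prim >= 1 | .data$use_sg),
    has_junction = !is.na(.data$cm_coord) | !is.na(.data$sj_coord) | .data$use_sg,
    is_clipped = .data$informative & .data$has_junction,
    is_cross = .data$informative & !.data$is_clipped &
      .data$n_te_prim >= 1 & .data$n_gen_prim == 1 &
      .data$g1_totclip <= params$max_genome_clip,
    category = dplyr::case_when(
      .data$is_clipped ~ "clipped",
      .data$is_cross ~ "cross",
      .data$n_gen_prim == 2 & .data$gen_same_ref & .data$te_bp == 0L ~ "background",
      TRUE ~ "uninformative"
    )
  )

  # evidence rows: clipped pairs take junction info from the clip match when
  # present, else from the supplementary alignment
  ev <- pd %>%
    filter(.data$category %in% c("clipped", "cross")) %>%
    mutate(
      use_cm = !is.na(.data$cm_coord),
      use_sj = !.data$use_cm & !is.na(.data$sj_coord),
      clip_side = dplyr::case_when(
        .data$category != "clipped" ~ NA_character_,
        .data$use_cm ~ .data$cm_clip_side,
        .data$use_sj ~ .data$sj_clip_side,
        TRUE ~ .data$sg_clip_side
      ),
      side = dplyr::case_when(
        .data$category == "clipped" & .data$clip_side == "right" ~ "left",
        .data$category == "clipped" & .data$clip_side == "left" ~ "right",
        .data$g1_strand == "+" ~ "left",
        TRUE ~ "right"
      ),
      clip_coord = dplyr::case_when(
        .data$category != "clipped" ~ NA_integer_,
        .data$use_cm ~ .data$cm_coord,
        .data$use_sj ~ .data$sj_coord,
        TRUE ~ .data$sg_coord
      ),
      genome_pos = as.integer(ifelse(
        .data$category == "clipped", .data$clip_coord,
        ifelse(.data$side == "left", .data$g1_end, .data$g1_pos)
      )),
      te_strand = dplyr::case_when(
        .data$category == "clipped" & .data$use_cm ~ .data$cm_vote,
        .data$category == "clipped" & .data$use_sj ~ .data$sj_vote,
        .data$category == "clipped" ~ .data$sg_vote,
        .data$g1_strand != .data$te_strand_a ~ "+",
        TRUE ~ "-"
      ),
      te_end = dplyr::case_when(
        .data$category == "clipped" & .data$use_cm ~ .data$cm_te_end,
        .data$category == "clipped" & .data$use_sj ~ .data$te_end_b,
        TRUE ~ .data$te_end_a
      ),
      mapq = as.integer(dplyr::case_when(
        .data$category == "clipped" & .data$use_cm ~ as.numeric(.data$cm_mapq),
        .data$category == "clipped" & .data$use_sj ~ as.numeric(.data$sj_mapq),
        .data$category == "clipped" & .data$use_sg ~ as.numeric(.data$sg_mapq),
        TRUE ~ as.numeric(.data$g1_mapq)
      ))
    ) %>%
    dplyr::transmute(
      qname = .data$qname, category = .data$category,
      genome_ref = dplyr::coalesce(.data$gen_ref, .data$sg_ref),
      genome_pos = .data$genome_pos, side = .data$side,
      te_overlap_bp = .data$te_bp, clip_coord = as.integer(.data$clip_coord),
      te_end = .data$te_end, te_strand = .data$te_strand, mapq = .data$mapq
    ) %>%
    arrange(.data$genome_ref, .data$genome_pos)

  bg <- pd %>%
    filter(.data$category == "background") %>%
    dplyr::transmute(qname = .data$qname, rname = .data$gen_ref,
                     start = as.integer(.data$bg_start),
                     end = as.integer(.data$bg_end)) %>%
    arrange(.data$rname, .data$start)

  cov <- gp %>% dplyr::select("rname", "pos", "ref_end")

  counts <- table(factor(pd$category,
                         levels = c("background", "cross", "clipped", "uninformative")))
  # pairs with no primary genome/TE record at all (e.g. both mates unmapped)
  n_unseen <- if (!is.null(io_stats)) max(0L, io_stats$n_pairs - nrow(pd)) else 0L
  stats <- tibble(
    background = as.integer(counts[["background"]]),
    cross = as.integer(counts[["cross"]]),
    clipped = as.integer(counts[["clipped"]]),
    uninformative = as.integer(counts[["uninformative"]]) + n_unseen,
    total = as.integer(nrow(pd) + n_unseen),
    orphan = if (!is.null(io_stats)) io_stats$n_orphan else NA_integer_
  )

  out <- list(evidence = ev, background = bg, coverage = cov, stats = stats)
  class(out) <- "te_classified"
  out
}

#' Classify a single read pair
#'
#' Convenience wrapper around [classify_pairs()] for one pair.
#'
#' @inheritParams classify_pairs
#' @param pair Rows of a [read_pairs()] tibble for one query name.
#' @return A list with `category` (character scalar) and `evidence` (one-row
#'   tibble, or NULL if the pair is not informative).
#' @export
classify_pair <- function(pair, refset, params = te_params()) {
  stopifnot(length(unique(pair$qname)) == 1)
  res <- classify_pairs(pair, refset, params)
  if (nrow(res$evidence) == 1) {
    list(category = res$evidence$category, evidence = res$evidence)
  } else {
    cat_ <- if (nrow(res$background) == 1) "background" else "uninformative"
    list(category = cat_, evidence = NULL)
  }
}
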