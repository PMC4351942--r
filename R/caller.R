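#' Cluster insertion evidence into candidate loci
#'
#' Single-linkage clustering along each genome sequence: consecutive evidence
#' (sorted by anchor coordinate) within `cluster_window` bp joins one cluster.
#' Each cluster is one candidate TE insertion site.
#'
#' @param evidence Evidence tibble from [classify_pairs()].
#' @param cluster_window Linking distance in bp; the default in [te_params()]
#'   is `insert_mean + 3 * insert_sd`.
#' @return A tibble with one row per cluster: `cluster`, `genome_ref`,
#'   `span_start`, `span_end`, `midpoint`, `n_support`, `n_left`, `n_right`,
#'   `n_clipped`, `avg_mapq`, and a nested `evidence` list-column.
#' @export
cluster_evidence <- function(evidence, cluster_window = 650) {
  empty <- tibble(
    cluster = integer(0), genome_ref = character(0), span_start = integer(0),
    span_end = integer(0), midpoint = integer(0), n_support = integer(0),
    n_left = integer(0), n_right = integer(0), n_clipped = integer(0),
    avg_mapq = numeric(0), evidence = list()
  )
  if (nrow(evidence) == 0) return(empty)
  ev <- evidence %>%
    arrange(.data$genome_ref, .data$genome_pos) %>%
    group_by(.data$genome_ref) %>%
    mutate(.cl = cumsum(c(1L, as.integer(diff(.data$genome_pos) > cluster_window)))) %>%
    ungroup() %>%
    mutate(cluster = as.integer(factor(paste(.data$genome_ref, .data$.cl),
                                       levels = unique(paste(.data$genome_ref, .data$.cl)))))
  ev %>%
    dplyr::select(-".cl") %>%
    tidyr::nest(evidence = -"cluster") %>%
    mutate(genome_ref = purrr::map_chr(.data$evidence, ~ .x$genome_ref[1])) %>%
    mutate(
      span_start = purrr::map_int(.data$evidence, ~ min(.x$genome_pos)),
      span_end = purrr::map_int(.data$evidence, ~ max(.x$genome_pos)),
      midpoint = as.integer(round((.data$span_start + .data$span_end) / 2)),
      n_support = purrr::map_int(.data$evidence, nrow),
      n_left = purrr::map_int(.data$evidence, ~ sum(.x$side == "left")),
      n_right = purrr::map_int(.data$evidence, ~ sum(.x$side == "right")),
      n_clipped = purrr::map_int(.data$evidence, ~ sum(.x$category == "clipped")),
      avg_mapq = purrr::map_dbl(.data$evidence, ~ mean(.x$mapq))
    ) %>%
    dplyr::select("cluster", "genome_ref", "span_start", "span_end", "midpoint",
                  "n_support", "n_left", "n_right", "n_clipped", "avg_mapq",
                  "evidence")
}

# mean per-base coverage over windows, from the slim genome-alignment table
.window_depth <- function(coverage, genome_ref, start, end) {
  n <- length(genome_ref)
  if (n == 0) return(numeric(0))
  start <- pmax(as.integer(start), 1L)
  end <- as.integer(end)
  if (nrow(coverage) == 0) return(rep(0, n))
  cov_gr <- GenomicRanges::GRanges(coverage$rname,
                                   IRanges::IRanges(coverage$pos, coverage$ref_end))
  win_gr <- GenomicRanges::GRanges(genome_ref, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(win_gr, cov_gr)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(win_gr)[S4Vectors::queryHits(hits)],
    IRanges::ranges(cov_gr)[S4Vectors::subjectHits(hits)]
  ))
  tot <- rep(0, n)
  agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
  tot[as.integer(names(agg))] <- as.numeric(agg)
  tot / (end - start + 1)
}

#' Apply the reporting filters to candidate clusters
#'
#' A candidate is reported only when it passes all four filters: average
#' mapping quality of the informative pairs at least `min_avg_mapq` (screens
#' repetitive regions), mean sequencing depth around the insertion within
#' `depth_range`, at least `min_support` supporting pairs, and both flanks of
#' the insertion supported by at least one pair.
#'
#' @param clusters Cluster tibble from [cluster_evidence()], with a `depth`
#'   column (added here from `coverage` when supplied).
#' @param params A [te_params()] object.
#' @param coverage Optional coverage tibble from [classify_pairs()]; when
#'   given, `depth` is computed over `midpoint +/- insert_mean`.
#' @return `clusters` with `depth`, `filters_failed` (list of character
#'   vectors) and `pass` columns added.
#' @export
apply_filters <- function(clusters, params = te_params(), coverage = NULL) {
  if (!is.null(coverage)) {
    clusters$depth <- .window_depth(
      coverage, clusters$genome_ref,
      clusters$midpoint - params$insert_mean,
      clusters$midpoint + params$insert_mean
    )
  }
  if (!"depth" %in% names(clusters)) {
    stop("clusters need a `depth` column; supply `coverage` to compute it")
  }
  fails <- purrr::pmap(
    list(clusters$avg_mapq, clusters$depth, clusters$n_support,
         clusters$n_left, clusters$n_right),
    function(mq, dp, ns, nl, nr) {
      f <- character(0)
      if (mq < params$min_avg_mapq) f <- c(f, "min_avg_mapq")
      if (dp < params$depth_range[1] || dp > params$depth_range[2]) {
        f <- c(f, "depth_range")
      }
      if (ns < params$min_support) f <- c(f, "min_support")
      if (nl < 1 || nr < 1) f <- c(f, "both_ends")
      f
    }
  )
  clusters$filters_failed <- fails
  clusters$pass <- lengths(fails) == 0
  clusters
}

# modal value; ties broken toward the smallest (deterministic output)
.modal <- function(x) {
  if (length(x) == 0) return(NA_integer_)
  ux <- sort(unique(x))
  cnt <- tabulate(match(x, ux))
  ux[which.max(cnt)]
}

#' Refine the breakpoint and target-site duplication of one cluster
#'
#' Clipped reads determine the exact genomic location. `L` is the modal clip
#' coordinate of the left-junction clipped reads (last reference base before
#' the TE, approached from the left) and `R` the modal clip coordinate of the
#' right-junction clipped reads (first reference base after the TE, i.e. the
#' start of the duplicated target site). When both exist and
#' `L - R + 1` lies in `[0, max_tsd]`, the insertion position is `R` and the
#' TSD is `reference[R..L]`. With clips on only one side the position is that
#' coordinate with an empty TSD; with no clipped reads the position falls back
#' to the midpoint between the innermost anchors of the two evidence sides and
#' the call is interval-precision only.
#'
#' @param evidence Evidence rows of one cluster.
#' @param reference Named character vector of genome sequences.
#' @param max_tsd Largest credible TSD (bp); larger implied duplications are
#'   flagged and reported without a TSD sequence.
#' @return A one-row tibble: `position`, `position_precision`
#'   (`"exact"`/`"interval"`), `interval_start`, `interval_end`,
#'   `tsd_sequence`, `tsd_len`, `tsd_flag`.
#' @export
refine_breakpoint <- function(evidence, reference, max_tsd = 20) {
  chrom <- evidence$genome_ref[1]
  lc <- evidence$clip_coord[evidence$side == "left" & evidence$category == "clipped"]
  rc <- evidence$clip_coord[evidence$side == "right" & evidence$category == "clipped"]
  L <- .modal(lc[!is.na(lc)])
  R <- .modal(rc[!is.na(rc)])
  left_anchor <- suppressWarnings(max(evidence$genome_pos[evidence$side == "left"]))
  right_anchor <- suppressWarnings(min(evidence$genome_pos[evidence$side == "right"]))
  pos <- NA_integer_; tsd <- ""; prec <- "exact"; flag <- FALSE
  int_s <- NA_integer_; int_e <- NA_integer_
  if (!is.na(L) && !is.na(R)) {
    tsd_len <- L - R + 1L
    pos <- R
    if (tsd_len >= 0L && tsd_len <= max_tsd) {
      tsd <- if (tsd_len > 0) substr(reference[[chrom]], R, L) else ""
    } else {
      flag <- TRUE
    }
  } else if (!is.na(L)) {
    pos <- L
  } else if (!is.na(R)) {
    pos <- R
  } else {
    prec <- "interval"
    anchors <- c(
      if (is.finite(left_anchor)) left_anchor,
      if (is.finite(right_anchor)) right_anchor
    )
    int_s <- as.integer(min(anchors))
    int_e <- as.integer(max(anchors))
    pos <- as.integer(floor(mean(anchors)))
  }
  tibble(
    position = as.integer(pos), position_precision = prec,
    interval_start = int_s, interval_end = int_e,
    tsd_sequence = tsd, tsd_len = nchar(tsd), tsd_flag = flag
  )
}

#' Vote on the orientation of the inserted element
#'
#' Majority vote over the per-evidence orientation estimates; a cluster must
#' reach an 80:20 majority, otherwise the orientation is `"unknown"`.
#'
#' @param evidence Evidence rows of one cluster.
#' @param majority Required vote fraction. Default 0.8.
#' @return `"+"`, `"-"` or `"unknown"`.
#' @export
call_orientation <- function(evidence, majority = 0.8) {
  v <- evidence$te_strand[!is.na(evidence$te_strand)]
  if (length(v) == 0) return("unknown")
  fplus <- mean(v == "+")
  if (fplus >= majority) "+" else if (fplus <= 1 - majority) "-" else "unknown"
}

#' Call TE insertions from classified read pairs
#'
#' Composes [cluster_evidence()], [apply_filters()], [refine_breakpoint()] and
#' [call_orientation()] into the final call table. Candidates failing any
#' filter are retained in the `rejected` attribute with their reasons.
#'
#' @param classified Output of [classify_pairs()].
#' @param reference Named character vector of genome sequences (e.g.
#'   `refset$genome`).
#' @param params A [te_params()] object.
#' @return A tibble of class `te_calls` (one row per reported insertion,
#'   sorted by position) with columns `genome_ref`, `position`,
#'   `position_precision`, `interval_start`, `interval_end`, `tsd_sequence`,
#'   `tsd_len`, `tsd_flag`, `te_strand`, `n_support`, `n_left`, `n_right`,
#'   `n_clipped`, `avg_mapq`, `depth`, `filters_failed`. Attributes:
#'   `rejected` (same columns for filtered-out candidates) and `params`.
#' @export
call_insertions <- function(classified, reference, params = te_params()) {
  cl <- cluster_evidence(classified$evidence, params$cluster_window)
  cl <- apply_filters(cl, params, coverage = classified$coverage)
  if (nrow(cl) > 0) {
    refined <- purrr::map(cl$evidence, refine_breakpoint,
                          reference = reference, max_tsd = params$max_tsd)
    refined <- bind_rows(refined)
    cl <- dplyr::bind_cols(cl, refined)
    cl$te_strand <- purrr::map_chr(cl$evidence, call_orientation)
  } else {
    cl <- dplyr::bind_cols(cl, refine_breakpoint(
      tibble(genome_ref = character(0), clip_coord = integer(0),
             side = character(0), category = character(0),
             genome_pos = integer(0))[0, ], reference)[0, ])
    cl$te_strand <- character(0)
  }
  cols <- c("genome_ref", "position", "position_precision", "interval_start",
            "interval_end", "tsd_sequence", "tsd_len", "tsd_flag", "te_strand",
            "n_support", "n_left", "n_right", "n_clipped", "avg_mapq", "depth")
  tab <- cl %>%
    mutate(filters_failed = purrr::map_chr(
      .data$filters_failed, ~ if (length(.x)) paste(.x, collapse = ",") else ""
    )) %>%
    arrange(.data$genome_ref, .data$position) %>%
    dplyr::select(dplyr::all_of(c(cols, "filters_failed", "pass")))
  calls <- tab %>% filter(.data$pass) %>% dplyr::select(-"pass")
  rejected <- tab %>% filter(!.data$pass) %>% dplyr::select(-"pass")
  attr(calls, "rejected") <- rejected
  attr(calls, "params") <- params
  class(calls) <- c("te_calls", class(calls))
  calls
}

#' Write call tables to disk
#'
#' Writes the calls as TSV (1-based coordinates), optionally a BED6 file
#' (0-based half-open, name = TE name, score = supporting pair count) and a
#' rejected-candidates TSV with failure reasons.
#'
#' @param calls A `te_calls` tibble.
#' @param tsv Output TSV path.
#' @param bed Optional BED6 path.
#' @param rejected Optional rejected-candidates TSV path.
#' @param te_name Name used in the BED name column.
#' @return `tsv`, invisibly.
#' @export
write_calls <- function(calls, tsv, bed = NULL, rejected = NULL, te_name = "TE") {
  readr::write_tsv(as_tibble(calls), tsv)
  if (!is.null(bed)) {
    bed_tab <- tibble(
      chrom = calls$genome_ref,
      start = calls$position - 1L,
      end = calls$position,
      name = te_name,
      score = calls$n_support,
      strand = ifelse(calls$te_strand %in% c("+", "-"), calls$te_strand, ".")
    )
    readr::write_tsv(bed_tab, bed, col_names = FALSE)
  }
  if (!is.null(rejected)) {
    readr::write_tsv(attr(calls, "rejected"), rejected)
  }
  invisible(tsv)
}
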