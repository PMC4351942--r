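#' Read a FASTA file into a named character vector
#'
#' Sequence names are the first whitespace-delimited token of each header and
#' sequences are uppercased. An empty file yields an empty vector with a
#' warning; a malformed record raises an error naming the file.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences, in file order.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 description", "acgt"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  ss <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ", conditionMessage(e), call. = FALSE)
  )
  if (length(ss) == 0) {
    warning("no records in FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70)
  invisible(path)
}

#' Build the combined genome + TE mapping reference
#'
#' Concatenates the genome records and the single TE record into one FASTA so
#' that reads are competitively aligned against both the genome and the element
#' in a single index; pairs bridging the two references then directly expose
#' insertion junctions.
#'
#' @param genome_fasta Path to the reference genome FASTA.
#' @param te_fasta Path to a single-record FASTA holding the TE sequence.
#' @param out_path Path for the combined FASTA (genome records first, TE last).
#' @return A list of class `te_reference` with elements `genome` (named
#'   character), `te_name`, `te_sequence`, and `combined_fasta`.
#' @export
build_combined_reference <- function(genome_fasta, te_fasta, out_path) {
  genome <- read_fasta(genome_fasta)
  te <- read_fasta(te_fasta)
  if (length(te) != 1) {
    stop("TE FASTA must contain exactly one record, found ", length(te))
  }
  te_name <- names(te)
  if (te_name %in% names(genome)) {
    stop("TE name '", te_name, "' collides with a genome sequence name")
  }
  write_fasta(c(genome, te), out_path)
  structure(
    list(
      genome = genome,
      te_name = te_name,
      te_sequence = unname(te),
      combined_fasta = out_path
    ),
    class = "te_reference"
  )
}

#' Align paired reads to the combined reference with bwa mem
#'
#' Thin wrapper over an external `bwa mem` invocation with minimum output
#' alignment score `-T 20` (so that at least 20 bp of a read must align for a
#' record to be emitted), followed by coordinate sorting and indexing. The
#' aligner step is optional: every downstream function equally accepts a
#' user-supplied SAM/BAM over the combined reference.
#'
#' @param fastq1,fastq2 Paths to the paired FASTQ files.
#' @param combined_ref Path to the combined FASTA from
#'   [build_combined_reference()].
#' @param out_bam Output BAM path.
#' @param threads Aligner threads.
#' @param min_score Minimum alignment output score (`bwa mem -T`). Default 20.
#' @return Path to the coordinate-sorted, indexed BAM.
#' @export
align_reads <- function(fastq1, fastq2, combined_ref, out_bam,
                        threads = 1, min_score = 20) {
  if (Sys.which("bwa") == "") {
    stop("external aligner 'bwa' not found on PATH; align the reads yourself ",
         "and supply the resulting BAM via the `bam` argument instead",
         call. = FALSE)
  }
  stopifnot(file.exists(fastq1), file.exists(fastq2), file.exists(combined_ref))
  if (!file.exists(paste0(combined_ref, ".bwt"))) {
    status <- system2("bwa", c("index", shQuote(combined_ref)),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0) stop("bwa index failed on ", combined_ref)
  }
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  status <- system2(
    "bwa",
    c("mem", "-T", min_score, "-t", threads,
      shQuote(combined_ref), shQuote(fastq1), shQuote(fastq2)),
    stdout = sam, stderr = FALSE
  )
  if (status != 0) stop("bwa mem failed")
  dest <- sub("\\.bam$", "", out_bam)
  bam <- Rsamtools::asBam(sam, dest, overwrite = TRUE, indexDestination = TRUE)
  if (Rsamtools::countBam(bam)$records == 0) {
    warning("alignment produced an empty BAM (empty FASTQ input?)")
  }
  bam
}

# regex helpers for CIGAR soft clips (hard clips stripped first)
.clip_lengths <- function(cigar) {
  c2 <- gsub("\\d+H", "", cigar)
  lead <- rep(0L, length(c2))
  m <- regmatches(c2, regexpr("^\\d+(?=S)", c2, perl = TRUE))
  has <- grepl("^\\d+S", c2)
  lead[has] <- as.integer(m)
  trail <- rep(0L, length(c2))
  m2 <- regmatches(c2, regexpr("\\d+(?=S$)", c2, perl = TRUE))
  has2 <- grepl("\\d+S$", c2)
  trail[has2] <- as.integer(m2)
  # a CIGAR that is a single soft clip would make lead == trail; treat as lead
  only_s <- grepl("^\\d+S$", c2)
  trail[only_s] <- 0L
  list(lead = lead, trail = trail)
}

#' Read a SAM/BAM file as mate-joined pair records
#'
#' Loads every primary and supplementary alignment record (secondary
#' alignments are dropped) into one tibble, one row per record, with pairs
#' grouped by query name. Works with both name-sorted and coordinate-sorted
#' input; `.sam` files are converted on the fly. Orphan mates (one side
#' unmapped or absent) are kept and counted.
#'
#' @param path Path to a BAM or SAM file.
#' @return A tibble of class `te_pairs` with columns `qname`, `mate` (1/2),
#'   `rname`, `strand`, `pos`, `mapq`, `cigar`, `seq`, `is_supp`, `unmapped`,
#'   `lead_clip`, `trail_clip`, `aln_qlen`, `ref_end`. Attribute `stats` holds
#'   pair-level counts.
#' @export
read_pairs <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE),
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar", "seq")
  )
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  n <- length(b$qname)
  if (n == 0) {
    rec <- tibble(
      qname = character(0), mate = integer(0), rname = character(0),
      strand = character(0), pos = integer(0), mapq = integer(0),
      cigar = character(0), seq = character(0), is_supp = logical(0),
      unmapped = logical(0), lead_clip = integer(0), trail_clip = integer(0),
      aln_qlen = integer(0), ref_end = integer(0)
    )
    attr(rec, "stats") <- tibble(n_records = 0L, n_pairs = 0L, n_orphan = 0L)
    class(rec) <- c("te_pairs", class(rec))
    return(rec)
  }
  flag <- b$flag
  unmapped <- bitwAnd(flag, 4L) > 0L
  is_supp <- bitwAnd(flag, 2048L) > 0L
  mate <- ifelse(bitwAnd(flag, 64L) > 0L, 1L,
                 ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L))
  cigar <- b$cigar
  cigar[is.na(cigar)] <- ""
  clips <- .clip_lengths(ifelse(cigar == "", "0M", cigar))
  aln_qlen <- integer(n)
  ref_w <- integer(n)
  ok <- cigar != ""
  aln_qlen[ok] <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cigar[ok], after.soft.clipping = TRUE)
  ref_w[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[ok])
  pos <- ifelse(is.na(b$pos), 0L, b$pos)
  rec <- tibble(
    qname = b$qname,
    mate = mate,
    rname = as.character(b$rname),
    strand = as.character(b$strand),
    pos = as.integer(pos),
    mapq = as.integer(ifelse(is.na(b$mapq), 0L, b$mapq)),
    cigar = cigar,
    seq = as.character(b$seq),
    is_supp = is_supp,
    unmapped = unmapped,
    lead_clip = ifelse(unmapped, 0L, clips$lead),
    trail_clip = ifelse(unmapped, 0L, clips$trail),
    aln_qlen = ifelse(unmapped, 0L, aln_qlen),
    ref_end = as.integer(ifelse(unmapped, 0L, pos + ref_w - 1L))
  )
  prim <- rec[!rec$is_supp, c("qname", "mate")]
  dup <- duplicated(prim)
  if (any(dup)) {
    stop("duplicate primary record for read '", prim$qname[which(dup)[1]],
         "' (name collision across libraries?)")
  }
  per_pair <- table(factor(prim$qname))
  mapped_prim <- rec[!rec$is_supp & !rec$unmapped, ]
  sides <- tapply(mapped_prim$mate, mapped_prim$qname, function(m) length(unique(m)))
  n_pairs <- length(per_pair)
  n_orphan <- sum(sides < 2) + sum(!names(per_pair) %in% names(sides))
  attr(rec, "stats") <- tibble(
    n_records = n, n_pairs = as.integer(n_pairs), n_orphan = as.integer(n_orphan)
  )
  class(rec) <- c("te_pairs", class(rec))
  rec
}

#' Write alignment records to a SAM file
#'
#' Minimal SAM writer used for truth-projected alignments and synthetic test
#' fixtures. Records must already be expressed in reference orientation.
#'
#' @param records Tibble with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `seq` and optionally `qual` (defaults to Q30).
#' @param seqlengths Named integer vector of reference sequence lengths, in
#'   header order.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, seqlengths, path) {
  stopifnot(!is.null(names(seqlengths)))
  hdr <- c(
    "@HD\tVN:1.6\tSO:unknown",
    paste0("@SQ\tSN:", names(seqlengths), "\tLN:", as.integer(seqlengths))
  )
  qual <- if ("qual" %in% names(records)) records$qual else strrep("?", nchar(records$seq))
  body <- paste(
    records$qname, records$flag, records$rname, records$pos,
    records$mapq, records$cigar, "*", 0L, 0L, records$seq, qual,
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}
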