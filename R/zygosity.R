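#' Count background pairs spanning a position
#'
#' Counts the background pairs whose outer insert interval strictly contains
#' the given position (the pair's two reads bracket the site on the allele
#' without the insertion).
#'
#' @param background Background tibble from [classify_pairs()] (`rname`,
#'   `start`, `end`).
#' @param genome_ref,position Equal-length vectors of positions to query.
#' @param seqnames Optional character vector of valid sequence names; when
#'   given, an unknown `genome_ref` raises an error.
#' @return Integer vector of counts.
#' @export
count_background <- function(background, genome_ref, position, seqnames = NULL) {
  stopifnot(length(genome_ref) == length(position))
  if (!is.null(seqnames)) {
    bad <- setdiff(unique(genome_ref), seqnames)
    if (length(bad)) {
      stop("position on unknown sequence: ", paste(bad, collapse = ", "))
    }
  }
  if (nrow(background) == 0) return(rep(0L, length(position)))
  vapply(seq_along(position), function(i) {
    sum(background$rname == genome_ref[i] &
          background$start < position[i] &
          background$end > position[i])
  }, integer(1))
}

#' Binomial zygosity test
#'
#' At a heterozygous insertion the supportive:background pair ratio is 2:1 in
#' theory (supportive pairs arise at both junctions of the inserted allele,
#' background pairs only from the intact allele), so background pairs are
#' expected with probability `p_bg = 1/3` among the pairs at the locus. A
#' deficit of background pairs indicates a homozygous insertion: the one-sided
#' exact lower-tail probability `P(X <= n_background)` for
#' `X ~ Binomial(n_support + n_background, p_bg)` is computed and the site is
#' called homozygous when it falls below `alpha`. No multiple-testing
#' correction is applied.
#'
#' @param n_support,n_background Integer vectors (recycled to equal length) of
#'   informative and spanning-background pair counts per locus.
#' @param p_bg Expected background fraction under heterozygosity. Default 1/3.
#' @param alpha Significance level for the homozygous call. Default 0.05.
#' @return A tibble with `n_support`, `n_background`, `p_value`, `zygosity`.
#' @examples
#' zygosity_test(10, 0)   # p = (2/3)^10, homozygous
#' zygosity_test(20, 10)  # p ~ 0.59, heterozygous
#' @export
zygosity_test <- function(n_support, n_background, p_bg = 1 / 3, alpha = 0.05) {
  n <- n_support + n_background
  if (any(n < 1)) {
    stop("zygosity test needs at least one informative or background pair")
  }
  p <- stats::pbinom(n_background, n, p_bg)
  tibble(
    n_support = as.integer(n_support),
    n_background = as.integer(n_background),
    p_value = p,
    zygosity = ifelse(p < alpha, "homozygous", "heterozygous")
  )
}

#' Append zygosity calls to an insertion call table
#'
#' @param calls A `te_calls` tibble.
#' @param background Background tibble from [classify_pairs()].
#' @param params A [te_params()] object (uses `p_background` and `alpha`).
#' @param seqnames Optional valid sequence names, passed to
#'   [count_background()].
#' @return `calls` with `n_background`, `p_value` and `zygosity` columns.
#' @export
add_zygosity <- function(calls, background, params = te_params(), seqnames = NULL) {
  if (nrow(calls) == 0) {
    calls$n_background <- integer(0)
    calls$p_value <- numeric(0)
    calls$zygosity <- character(0)
    return(calls)
  }
  nb <- count_background(background, calls$genome_ref, calls$position, seqnames)
  zt <- zygosity_test(calls$n_support, nb, params$p_background, params$alpha)
  calls$n_background <- zt$n_background
  calls$p_value <- zt$p_value
  calls$zygosity <- zt$zygosity
  calls
}
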