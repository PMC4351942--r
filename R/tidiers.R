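#' Summarise a call table
#'
#' One-row overview of a `te_calls` object: call counts by precision and
#' zygosity, support statistics, and the number of rejected candidates.
#'
#' @param x A `te_calls` tibble.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance te_calls
#' @export
glance.te_calls <- function(x, ...) {
  rej <- attr(x, "rejected")
  tibble(
    n_calls = nrow(x),
    n_exact = sum(x$position_precision == "exact"),
    n_interval = sum(x$position_precision == "interval"),
    n_heterozygous = if ("zygosity" %in% names(x)) {
      sum(x$zygosity == "heterozygous")
    } else NA_integer_,
    n_homozygous = if ("zygosity" %in% names(x)) {
      sum(x$zygosity == "homozygous")
    } else NA_integer_,
    median_support = stats::median(x$n_support),
    n_rejected = if (!is.null(rej)) nrow(rej) else NA_integer_
  )
}

#' Tidy a benchmark result
#'
#' @param x A `te_benchmark` object from [evaluate_calls()].
#' @param ... Unused.
#' @return The per-match tibble (`tidy`) or the one-row summary (`glance`).
#' @method tidy te_benchmark
#' @export
tidy.te_benchmark <- function(x, ...) x$matches

#' @rdname tidy.te_benchmark
#' @method glance te_benchmark
#' @export
glance.te_benchmark <- function(x, ...) x$summary

#' Plot insertion calls along the genome
#'
#' Lollipop plot of supporting-pair counts by position, faceted by sequence
#' and coloured by zygosity when available.
#'
#' @param object A `te_calls` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot te_calls
#' @export
autoplot.te_calls <- function(object, ...) {
  df <- as_tibble(object)
  col <- if ("zygosity" %in% names(df)) "zygosity" else NULL
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$n_support)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0),
                          linewidth = 0.4, colour = "grey60") +
    ggplot2::facet_wrap(~genome_ref, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "supporting pairs") +
    ggplot2::theme_minimal()
  if (!is.null(col)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$zygosity), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' Recall versus coverage curve
#'
#' @param df Tibble with columns `coverage` and `recall` (e.g. rows of
#'   `glance()` of several [evaluate_calls()] results).
#' @return A ggplot object.
#' @export
plot_recall_curve <- function(df) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coverage, y = .data$recall)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1), labels = function(x) x * 100) +
    ggplot2::labs(x = "genome coverage (fold)", y = "insertions recovered (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
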