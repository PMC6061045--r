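#' Tidy a gene-based test result
#'
#' @param x A `gates_result` from [gates_test()].
#' @param ... Unused.
#' @return A tibble with one row per SNP in sorted-p order: `snp_id`,
#'   `p`, `me_partial`, `simes_term` (the per-rank term whose minimum is
#'   the gene p-value).
#' @export
tidy.gates_result <- function(x, ...) {
  tibble(
    snp_id = x$snp_id,
    p = x$p_sorted,
    me_partial = x$me_partial,
    simes_term = pmin(1, x$me * x$p_sorted / x$me_partial)
  )
}

#' @rdname tidy.gates_result
#' @return For `glance()`: a one-row tibble with `n_snps`, `me`,
#'   `gene_p`, `pcorr_method`, `n_dropped`.
#' @export
glance.gates_result <- function(x, ...) {
  tibble(
    n_snps = x$m,
    me = x$me,
    gene_p = x$gene_p,
    pcorr_method = x$pcorr_method,
    n_dropped = x$n_dropped
  )
}

#' Tidy combined cross-species statistics
#'
#' @param x A `combined_stats` tibble from [integrate_evidence()].
#' @param ... Unused.
#' @return `tidy()` returns the underlying tibble; `glance()` a one-row
#'   summary with `n_tested`, `threshold`, `n_significant`.
#' @export
tidy.combined_stats <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "combined_stats")
  attr(out, "n_tested") <- NULL
  attr(out, "threshold") <- NULL
  as_tibble(out)
}

#' @rdname tidy.combined_stats
#' @export
glance.combined_stats <- function(x, ...) {
  tibble(
    n_tested = attr(x, "n_tested"),
    threshold = attr(x, "threshold"),
    n_significant = sum(x$significant)
  )
}

#' Evidence scatter of a combined prioritization
#'
#' Plots each gene by its mouse and human evidence on the -log10 scale;
#' genes past the combined significance threshold are highlighted and
#' labelled.
#'
#' @param object A `combined_stats` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.combined_stats <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    -log10(.data$p_human), -log10(.data$p_mouse),
    colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_text(
      data = df[df$significant, ],
      ggplot2::aes(label = .data$human_symbol),
      vjust = -0.6, size = 3, show.legend = FALSE
    ) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey55", `TRUE` = "firebrick"),
      name = sprintf("combined p < %.2g", attr(object, "threshold"))
    ) +
    ggplot2::labs(
      x = expression(-log[10] ~ "human gene-based p"),
      y = expression(-log[10] ~ "mouse correlation p")
    ) +
    ggplot2::theme_minimal()
}
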