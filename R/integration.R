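#' One-tailed z-score from a two-tailed p-value
#'
#' `z = qnorm(1 - p/2)`: the two-tailed p is halved before inversion, so
#' `z >= 0` always. This halve-then-invert convention is the one under
#' which the combined statistic reproduces published per-gene combined
#' p-values from their printed inputs. P-values below 1e-300 are capped
#' there (z approximately 37.0) with a warning.
#'
#' @param p_two_tailed Vector of two-tailed p-values in (0, 1].
#' @return Non-negative z-scores.
#' @export
#' @examples
#' one_tailed_z(c(1, 0.05, 4.2e-5))
one_tailed_z <- function(p_two_tailed) {
  if (any(is.na(p_two_tailed))) abort("p-values must not be missing")
  if (any(p_two_tailed <= 0 | p_two_tailed > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  if (any(p_two_tailed < 1e-300)) {
    warn("p-values below 1e-300 capped before inversion (z_max ~ 37.0)")
    p_two_tailed <- pmax(p_two_tailed, 1e-300)
  }
  qnorm(p_two_tailed / 2, lower.tail = FALSE)
}

#' Unweighted inverse-normal (Stouffer) combination of two p-values
#'
#' Converts the mouse-expression and human gene-based two-tailed p-values
#' to one-tailed z-scores via [one_tailed_z()], averages them as
#' `Z_C = (Z_MEXP + Z_HGWAS) / sqrt(2)`, takes the one-tailed combined
#' p-value from the standard normal upper tail and doubles it (two-tailed,
#' capped at 1). The combination is symmetric and strictly monotone in
#' both inputs. Note the mouse correlation's sign never enters: direction
#' is annotation only.
#'
#' @param p_mouse,p_human Two-tailed p-values in (0, 1]; recycled to a
#'   common length.
#' @return A tibble with `z_mexp`, `z_hgwas`, `z_c`, `p_combined`.
#' @export
#' @examples
#' combine_p(0.000042, 0.046239) # the top gene of the worked example
combine_p <- function(p_mouse, p_human) {
  n <- max(length(p_mouse), length(p_human))
  p_mouse <- rep_len(p_mouse, n)
  p_human <- rep_len(p_human, n)
  z1 <- one_tailed_z(p_mouse)
  z2 <- one_tailed_z(p_human)
  z_c <- (z1 + z2) / sqrt(2)
  tibble(
    z_mexp = z1,
    z_hgwas = z2,
    z_c = z_c,
    p_combined = pmin(1, 2 * pnorm(z_c, lower.tail = FALSE))
  )
}

#' Bonferroni-style significance threshold for the combined test
#'
#' `0.05 / n_tested / 2`: the family-wise 0.05 level divided by the number
#' of genes tested and by 2 for the doubling of the combined one-tailed
#' p-value.
#'
#' @param n_tested Number of genes tested (>= 1).
#' @return A single number.
#' @export
#' @examples
#' significance_threshold(373)
significance_threshold <- function(n_tested) {
  if (length(n_tested) != 1 || is.na(n_tested) || n_tested < 1) {
    abort("`n_tested` must be a single number >= 1")
  }
  0.05 / n_tested / 2
}

#' Join mouse and human gene-level evidence through orthologs
#'
#' Inner-joins per-gene mouse correlation statistics and human gene-based
#' statistics on an ortholog table. Symbols are matched case-insensitively
#' (mouse symbols are mixed-case, human upper-case). Pairs missing on
#' either side are dropped with a reported count. When several mouse
#' genes map to one human gene, the partner with the smallest mouse
#' p-value is kept and flagged `multi_ortholog`.
#'
#' @param mouse_stats Per-gene tibble from [collapse_probes()]
#'   (`gene_symbol`, `r`, `direction`, `p`, ...).
#' @param human_stats Per-gene tibble from [gene_based_pvalues()]
#'   (`gene_symbol`, `gates_p`, ...).
#' @param orthologs Tibble with `human_symbol`, `mouse_symbol`.
#' @return A tibble with `human_symbol`, `mouse_symbol`, `r`, `direction`,
#'   `p_mouse`, `p_human`, `multi_ortholog`.
#' @export
ortholog_join <- function(mouse_stats, human_stats, orthologs) {
  stopifnot(
    all(c("human_symbol", "mouse_symbol") %in% names(orthologs)),
    all(c("gene_symbol", "p") %in% names(mouse_stats)),
    all(c("gene_symbol", "gates_p") %in% names(human_stats))
  )
  mouse <- mouse_stats |>
    mutate(.mkey = toupper(.data$gene_symbol)) |>
    select(".mkey", dplyr::any_of(c("r", "direction")), p_mouse = "p")
  human <- human_stats |>
    mutate(.hkey = toupper(.data$gene_symbol)) |>
    select(".hkey", p_human = "gates_p")
  pairs <- orthologs |>
    mutate(
      .hkey = toupper(.data$human_symbol),
      .mkey = toupper(.data$mouse_symbol)
    )

  joined <- pairs |>
    inner_join(mouse, by = ".mkey", relationship = "many-to-many") |>
    inner_join(human, by = ".hkey", relationship = "many-to-many")
  n_dropped <- nrow(pairs) - nrow(distinct(joined, .data$.hkey, .data$.mkey))
  if (n_dropped > 0) {
    inform(paste0(n_dropped, " ortholog pair(s) without data on both sides dropped"))
  }
  if (nrow(joined) == 0) abort("ortholog join is empty")

  joined |>
    group_by(.data$.hkey) |>
    mutate(multi_ortholog = n() > 1) |>
    arrange(.data$p_mouse, .data$mouse_symbol, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(
      "human_symbol", "mouse_symbol",
      dplyr::any_of(c("r", "direction")),
      "p_mouse", "p_human", "multi_ortholog"
    )
}

#' Combined cross-species gene prioritization
#'
#' The full integration step: ortholog join, inverse-normal combination,
#' ranking by combined p-value and significance call at
#' `significance_threshold(n_tested)`.
#'
#' @inheritParams ortholog_join
#' @param n_tested Denominator of the significance threshold; defaults to
#'   the number of genes with evidence on both sides.
#' @return A tibble of class `combined_stats`, ordered by `p_combined`,
#'   with columns `human_symbol`, `mouse_symbol`, `r`, `direction`,
#'   `p_mouse`, `p_human`, `z_mexp`, `z_hgwas`, `z_c`, `p_combined`,
#'   `significant`, `multi_ortholog`, and attributes `n_tested` and
#'   `threshold`. `tidy()`, `glance()` and `autoplot()` methods are
#'   available.
#' @export
integrate_evidence <- function(mouse_stats, human_stats, orthologs,
                               n_tested = NULL) {
  joined <- ortholog_join(mouse_stats, human_stats, orthologs)
  n_tested <- n_tested %||% nrow(joined)
  threshold <- significance_threshold(n_tested)
  out <- bind_cols(joined, combine_p(joined$p_mouse, joined$p_human)) |>
    mutate(significant = .data$p_combined < threshold) |>
    arrange(.data$p_combined) |>
    relocate("multi_ortholog", .after = "significant")
  attr(out, "n_tested") <- n_tested
  attr(out, "threshold") <- threshold
  class(out) <- c("combined_stats", class(out))
  out
}

#' @export
print.combined_stats <- function(x, ...) {
  cat(sprintf(
    "# Combined cross-species statistics: %d genes tested, threshold %.3g, %d significant\n",
    attr(x, "n_tested"), attr(x, "threshold"), sum(x$significant)
  ))
  NextMethod()
}
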