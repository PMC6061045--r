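#' Normalize expression to a reference gene
#'
#' On the linear scale, the target level divided by the reference level
#' (e.g. relative to GUSB in brain qPCR); on the Ct (cycle-threshold)
#' scale, `2^-(Ct_target - Ct_reference)`, so one extra cycle halves the
#' normalized value.
#'
#' @param target_level,reference_level Numeric vectors of equal length.
#' @param scale `"linear"` or `"ct"`.
#' @return Normalized values (positive on the linear scale).
#' @export
#' @examples
#' normalize_to_reference(10, 5, "linear")
#' normalize_to_reference(24, 25, "ct") # delta-Ct of -1 doubles the level
normalize_to_reference <- function(target_level, reference_level,
                                   scale = c("linear", "ct")) {
  scale <- match.arg(scale)
  if (length(target_level) != length(reference_level)) {
    abort("target and reference vectors must have equal length")
  }
  if (anyNA(reference_level)) abort("missing reference level")
  if (scale == "linear") {
    if (any(reference_level <= 0)) {
      abort("reference level must be positive on the linear scale")
    }
    target_level / reference_level
  } else {
    2^-(target_level - reference_level)
  }
}

#' Two-group comparison of normalized expression
#'
#' Equal-variance two-sample Student t test, two-tailed; the estimate is
#' reported as the first-level mean minus the second-level mean (AD minus
#' control by default).
#'
#' @param values Numeric vector of normalized expression values.
#' @param group Group labels aligned to `values`.
#' @param levels Two group levels; the difference is `levels[1] - levels[2]`.
#' @return A one-row tibble with `estimate`, `t`, `df`, `p`.
#' @export
#' @examples
#' group_difference(c(1, 1.2, 0.9, 1.6, 1.8, 1.7),
#'                  rep(c("AD", "control"), each = 3))
group_difference <- function(values, group, levels = c("AD", "control")) {
  a <- values[group == levels[1]]
  b <- values[group == levels[2]]
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs at least 2 samples")
  }
  res <- row_t_test(matrix(a, 1), matrix(b, 1))
  tibble(estimate = mean(a) - mean(b), t = res$t, df = res$df, p = res$p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with enforced monotonicity; significance is
#' conventionally called at `q < 0.05`.
#'
#' @param p_values Vector of p-values in (0, 1].
#' @return Adjusted q-values, elementwise `>=` the input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) abort("`p_values` must be non-empty")
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Independent-cohort expression validation of prioritized genes
#'
#' Mirrors a hippocampal qPCR follow-up: per sample, the target gene's
#' level is normalized to a reference gene; per gene, the AD and control
#' groups are compared with an equal-variance t test and the p-values are
#' BH-adjusted across the genes tested. When mouse directions are
#' supplied, a per-gene concordance flag records whether the sign of the
#' AD-minus-control difference matches the mouse direction (`"Down"`
#' expects a lower AD mean); it is descriptive and never gates the
#' analysis.
#'
#' @param data Long tibble with `sample_id`, `group` (`"AD"`/`"control"`),
#'   `gene_symbol`, `target_level`, `reference_level`.
#' @param scale Passed to [normalize_to_reference()].
#' @param mouse_directions Optional tibble with `gene_symbol` and
#'   `direction` (`"Up"`/`"Down"`), matched case-insensitively.
#' @param alpha FDR level for the `significant` flag (default 0.05).
#' @return A tibble with one row per gene: `gene_symbol`, `estimate`, `t`,
#'   `df`, `p`, `q`, `significant`, and `direction_concordant` when
#'   directions were given.
#' @export
validate_expression <- function(data, scale = c("linear", "ct"),
                                mouse_directions = NULL, alpha = 0.05) {
  scale <- match.arg(scale)
  stopifnot(all(c("sample_id", "group", "gene_symbol", "target_level",
    "reference_level") %in% names(data)))
  data <- mutate(data, normalized = normalize_to_reference(
    .data$target_level, .data$reference_level, scale
  ))
  res <- data |>
    group_by(.data$gene_symbol) |>
    group_map(function(g, key) {
      bind_cols(
        tibble(gene_symbol = key$gene_symbol),
        group_difference(g$normalized, g$group)
      )
    }) |>
    bind_rows()
  res$q <- bh_adjust(res$p)
  res$significant <- res$q < alpha
  if (!is.null(mouse_directions)) {
    dir <- mouse_directions |>
      mutate(.key = toupper(.data$gene_symbol)) |>
      select(".key", "direction")
    res <- res |>
      mutate(.key = toupper(.data$gene_symbol)) |>
      left_join(dir, by = ".key") |>
      mutate(direction_concordant = dplyr::case_when(
        .data$direction == "Down" ~ .data$estimate < 0,
        .data$direction == "Up" ~ .data$estimate > 0,
        TRUE ~ NA
      )) |>
      select(-".key", -"direction")
  }
  arrange(res, .data$p)
}
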