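# Vectorized equal-variance two-sample t over the rows of two matrices.
# Zero pooled variance with equal means gives t = 0, p = 1 by convention;
# with unequal means p is clamped to the smallest positive double.
row_t_test <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  df <- na + nb - 2
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  delta <- ma - mb
  t <- ifelse(se == 0, ifelse(delta == 0, 0, sign(delta) * Inf), delta / se)
  p <- 2 * pt(-abs(t), df)
  p <- ifelse(se == 0 & delta == 0, 1, pmax(p, .Machine$double.xmin))
  list(t = unname(t), p = unname(p), df = df)
}

expr_matrix <- function(expr) {
  wide <- tidyr::pivot_wider(
    expr[c("probe_id", "sample_id", "expression")],
    names_from = "sample_id", values_from = "expression"
  )
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$probe_id
  if (anyNA(m)) abort("expression matrix has missing values; complete them upstream")
  m
}

#' Strain-differential expression screen
#'
#' First step of the two-step mouse screen: per probe, an equal-variance
#' two-sample Student t test of the target (low-susceptibility) strain
#' against each other strain, two-tailed. The per-probe summary p-value is
#' the minimum over the pairwise comparisons (`mode = "either"`, matching
#' a "different from strain A or strain B" selection), their maximum
#' (`"both"`), or a single comparison against all other strains pooled
#' (`"pooled"`).
#'
#' @param expr Long expression tibble with columns `probe_id`, `sample_id`,
#'   `strain`, `expression` (log-intensity scale, no missing values).
#' @param target_strain Strain whose difference defines the screen.
#' @param other_strains Strains compared against; defaults to all others.
#' @param mode Summary rule across comparisons; see Details.
#' @param alpha Selection threshold on the summary p-value (default 0.001).
#' @return A tibble with one row per probe: `t_<strain>` / `p_<strain>`
#'   per comparison (or `t_pooled` / `p_pooled`), `p_summary`, `selected`.
#' @export
#' @examples
#' sim <- simulate_strain_expression(sim_config(seed = 1, n_genes = 10))
#' strain_differential_test(sim$expression, "DBA")
strain_differential_test <- function(expr, target_strain,
                                     other_strains = NULL,
                                     mode = c("either", "both", "pooled"),
                                     alpha = 0.001) {
  mode <- match.arg(mode)
  stopifnot(all(c("probe_id", "sample_id", "strain", "expression")
    %in% names(expr)))
  strain_of <- distinct(expr, .data$sample_id, .data$strain)
  other_strains <- other_strains %||%
    setdiff(unique(strain_of$strain), target_strain)
  if (length(other_strains) == 0) abort("no comparison strains")
  involved <- c(target_strain, other_strains)
  n_per <- table(strain_of$strain[strain_of$strain %in% involved])
  if (!all(involved %in% names(n_per)) || any(n_per[involved] < 2)) {
    abort("invalid design: every strain involved needs at least 2 samples")
  }

  m <- expr_matrix(expr)
  cols_of <- function(s) {
    strain_of$sample_id[strain_of$strain %in% s]
  }
  a <- m[, cols_of(target_strain), drop = FALSE]

  out <- tibble(probe_id = rownames(m))
  if (mode == "pooled") {
    res <- row_t_test(a, m[, cols_of(other_strains), drop = FALSE])
    out$t_pooled <- res$t
    out$p_pooled <- res$p
    p_mat <- matrix(res$p, ncol = 1)
  } else {
    p_mat <- matrix(NA_real_, nrow(m), length(other_strains))
    for (k in seq_along(other_strains)) {
      res <- row_t_test(a, m[, cols_of(other_strains[k]), drop = FALSE])
      out[[paste0("t_", other_strains[k])]] <- res$t
      out[[paste0("p_", other_strains[k])]] <- res$p
      p_mat[, k] <- res$p
    }
  }
  out$p_summary <- switch(mode,
    either = apply(p_mat, 1, min),
    both = apply(p_mat, 1, max),
    pooled = p_mat[, 1]
  )
  out$selected <- out$p_summary < alpha
  attr(out, "mode") <- mode
  attr(out, "alpha") <- alpha
  out
}

#' Expected false-discovery proportion at a p-value threshold
#'
#' The expected-false-positives estimator `m * alpha / k`, where `m` is the
#' number of tests and `k` the number with `p < alpha`. Returns `NA` when
#' nothing is selected. The estimate may exceed 1 when fewer tests pass
#' than expected under the null.
#'
#' @param p_values Vector of p-values.
#' @param alpha Selection threshold in (0, 1).
#' @return A single number (proportion), or `NA_real_` if `k = 0`.
#' @export
#' @examples
#' fdr_at_threshold(runif(1000), 0.05)
fdr_at_threshold <- function(p_values, alpha) {
  if (length(p_values) == 0) abort("`p_values` must be non-empty")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1)")
  k <- sum(p_values < alpha)
  if (k == 0) return(NA_real_)
  length(p_values) * alpha / k
}

#' Collapse selected probes to candidate genes
#'
#' Genes with at least one probe passing the summary-p threshold become
#' candidates. Selected probes without a gene mapping are excluded with a
#' warning.
#'
#' @param diff Result of [strain_differential_test()].
#' @param probe_map Tibble mapping `probe_id` to `gene_symbol` (at most one
#'   gene per probe).
#' @param alpha Threshold on `p_summary` (default 0.001).
#' @return A tibble with one row per candidate gene: `gene_symbol`,
#'   `n_probes`, `min_p`; attributes `n_probes_selected`, `n_genes`.
#' @export
select_candidate_genes <- function(diff, probe_map, alpha = 0.001) {
  stopifnot("p_summary" %in% names(diff))
  if (anyDuplicated(probe_map$probe_id)) {
    abort("`probe_map` must map each probe to at most one gene")
  }
  hits <- filter(diff, .data$p_summary < alpha)
  mapped <- left_join(hits, probe_map, by = "probe_id")
  unmapped <- mapped$probe_id[is.na(mapped$gene_symbol)]
  if (length(unmapped) > 0) {
    warn(paste0(
      length(unmapped), " selected probe(s) without gene mapping excluded: ",
      paste(head(unmapped, 5), collapse = ", ")
    ))
    mapped <- filter(mapped, !is.na(.data$gene_symbol))
  }
  genes <- if (nrow(mapped) == 0) {
    tibble(gene_symbol = character(0), n_probes = integer(0),
      min_p = numeric(0))
  } else {
    mapped |>
      group_by(.data$gene_symbol) |>
      summarise(
        n_probes = n(),
        min_p = min(.data$p_summary),
        .groups = "drop"
      ) |>
      arrange(.data$min_p)
  }
  inform(paste0(
    "selected ", nrow(genes), " genes (", nrow(mapped), " probes) at p < ",
    format(alpha)
  ))
  attr(genes, "n_probes_selected") <- nrow(mapped)
  attr(genes, "n_genes") <- nrow(genes)
  genes
}

#' Correlation of expression with amyloid-beta accumulation
#'
#' Second step of the mouse screen: per probe, the Pearson correlation of
#' expression with the per-animal amyloid-beta level across the transgenic
#' cohort. Two-tailed p-values come from `t = r * sqrt((n - 2) / (1 - r^2))`
#' on `n - 2` degrees of freedom; direction is the sign of `r` (`"Up"` for
#' positive).
#'
#' @param expr Long expression tibble (`probe_id`, `sample_id`,
#'   `expression`) for the transgenic cohort.
#' @param abeta Tibble with `sample_id`, `abeta`, aligned to the samples of
#'   `expr`.
#' @param probes Optional subset of probe ids to test (e.g. probes of the
#'   candidate genes); default all.
#' @param on_zero_variance `"error"` (default) aborts naming any probe with
#'   zero expression variance; `"drop"` removes such probes with a warning.
#' @return A tibble with `probe_id`, `n`, `r`, `t`, `p`, `direction`.
#' @export
#' @examples
#' tg <- simulate_tg_cohort(sim_config(seed = 1, n_genes = 5, n_causal = 1))
#' abeta_correlation(tg$expression, tg$abeta)
abeta_correlation <- function(expr, abeta, probes = NULL,
                              on_zero_variance = c("error", "drop")) {
  on_zero_variance <- match.arg(on_zero_variance)
  m <- expr_matrix(expr)
  if (!is.null(probes)) {
    missing <- setdiff(probes, rownames(m))
    if (length(missing) > 0) {
      abort(paste0("probes not in expression data: ",
        paste(head(missing, 5), collapse = ", ")))
    }
    m <- m[probes, , drop = FALSE]
  }
  if (!all(colnames(m) %in% abeta$sample_id)) {
    abort("`abeta` must cover every sample of `expr`")
  }
  a <- abeta$abeta[match(colnames(m), abeta$sample_id)]
  n <- length(a)
  if (n < 4) abort("need at least 4 animals")
  if (sd(a) == 0) abort("amyloid-beta levels have zero variance")

  probe_sd <- apply(m, 1, sd)
  if (any(probe_sd == 0)) {
    flat <- rownames(m)[probe_sd == 0]
    msg <- paste0("zero expression variance for probe(s): ",
      paste(head(flat, 5), collapse = ", "))
    if (on_zero_variance == "error") abort(paste0("undefined correlation: ", msg))
    warn(paste0(msg, "; dropped"))
    m <- m[probe_sd > 0, , drop = FALSE]
  }

  r <- as.vector(cor(t(m), a))
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- pmin(1, 2 * pt(-abs(t_stat), n - 2))
  p <- pmax(p, .Machine$double.xmin) # keep p in (0, 1] even at |r| = 1
  tibble(
    probe_id = rownames(m),
    n = n,
    r = r,
    t = t_stat,
    p = p,
    direction = ifelse(r > 0, "Up", "Down")
  )
}

#' Collapse per-probe correlations to one record per gene
#'
#' Retains, per gene, the probe with the smallest two-tailed p-value; ties
#' are broken by larger `|r|`, then lexicographic probe id.
#'
#' @param corr Result of [abeta_correlation()].
#' @param probe_map Tibble mapping `probe_id` to `gene_symbol`; must cover
#'   every probe in `corr`.
#' @return A tibble with `gene_symbol`, `probe_id`, `n`, `r`, `t`, `p`,
#'   `direction`, one row per gene.
#' @export
collapse_probes <- function(corr, probe_map) {
  joined <- left_join(corr, probe_map, by = "probe_id")
  if (anyNA(joined$gene_symbol)) {
    abort("every probe in `corr` must be mapped to a gene")
  }
  joined |>
    arrange(.data$p, dplyr::desc(abs(.data$r)), .data$probe_id) |>
    group_by(.data$gene_symbol) |>
    slice(1) |>
    ungroup() |>
    select("gene_symbol", "probe_id", "n", "r", "t", "p", "direction") |>
    arrange(.data$p)
}
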