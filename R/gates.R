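#' Pairwise LD (genotype correlation) for a set of SNPs
#'
#' Signed Pearson correlation of dosages over complete pairs; square it
#' for r^2. Monomorphic SNPs are an error because their correlation is
#' undefined.
#'
#' @param panel A `genotype_panel`.
#' @param snp_ids SNPs to include (default: all, at least 2).
#' @return A symmetric correlation matrix with unit diagonal, dimnames set
#'   to the SNP ids.
#' @export
#' @examples
#' panel <- simulate_genotype_panel(sim_config(seed = 1, n_snps = 5))
#' ld_correlation(panel)
ld_correlation <- function(panel, snp_ids = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  snp_ids <- snp_ids %||% panel$snp_map$snp_id
  missing <- setdiff(snp_ids, colnames(panel$dosages))
  if (length(missing) > 0) {
    abort(paste0("SNPs not in panel: ", paste(head(missing, 5), collapse = ", ")))
  }
  if (length(snp_ids) < 2) abort("need at least 2 SNPs")
  x <- panel$dosages[, snp_ids, drop = FALSE]
  if (nrow(x) < 20) abort("need at least 20 individuals for LD estimation")
  sds <- apply(x, 2, sd, na.rm = TRUE)
  if (any(sds == 0)) {
    abort(paste0(
      "monomorphic SNP(s): ",
      paste(head(snp_ids[sds == 0], 5), collapse = ", ")
    ))
  }
  r <- cor(x, use = "pairwise.complete.obs")
  diag(r) <- 1
  r
}

# Sixth-degree polynomial mapping a genotype correlation to the
# approximate correlation between the two SNPs' two-tailed p-values,
# as used by the extended-Simes gene-based test. Evaluated on |r| so the
# function is even; pinned to 1 at |r| = 1 so perfectly duplicated tests
# collapse exactly.
.gates_poly <- c(0.2982, -0.0127, 0.0588, 0.0099, 0.6281, -0.0009)

#' Approximate correlation of two-tailed p-values from genotype LD
#'
#' Maps a signed genotype correlation `r` to the approximate Pearson
#' correlation of the corresponding two-tailed association p-values. The
#' default is the sixth-degree polynomial used with the extended-Simes
#' gene-based test, evaluated on `|r|` and clamped to `[0, 1]` with
#' `f(0) = 0` and `f(1) = 1`; `method = "r2"` uses the simpler `r^2`.
#'
#' @param r Numeric vector or matrix of genotype correlations in `[-1, 1]`.
#' @param method `"gates_poly"` (default) or `"r2"`.
#' @return Object of the same shape as `r` with entries in `[0, 1]`.
#' @export
#' @examples
#' pvalue_correlation_approx(c(0, 0.6, 1))
pvalue_correlation_approx <- function(r, method = c("gates_poly", "r2")) {
  method <- match.arg(method)
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE)) {
    abort("genotype correlations must lie in [-1, 1]")
  }
  a <- pmin(abs(r), 1)
  out <- if (method == "r2") {
    a^2
  } else {
    co <- .gates_poly
    val <- co[1] * a^6 + co[2] * a^5 + co[3] * a^4 +
      co[4] * a^3 + co[5] * a^2 + co[6] * a
    ifelse(a == 1, 1, pmin(1, pmax(0, val)))
  }
  if (is.matrix(r)) out <- matrix(out, nrow(r), ncol(r), dimnames = dimnames(r))
  out
}

#' Effective number of independent tests
#'
#' `Me = M - sum over eigenvalues lambda_i > 1 of (lambda_i - 1)` of a
#' test-statistic correlation matrix, clamped to `[1, M]`. Negative
#' eigenvalues arising from non-positive-definite approximations are
#' truncated at 0 first. `Me` equals `M` for the identity matrix and 1
#' for perfect correlation.
#'
#' @param corr_matrix Symmetric matrix with unit diagonal.
#' @return A single number in `[1, M]`.
#' @export
#' @examples
#' effective_number(diag(5))
#' effective_number(matrix(1, 4, 4))
effective_number <- function(corr_matrix) {
  corr_matrix <- as.matrix(corr_matrix)
  if (nrow(corr_matrix) != ncol(corr_matrix) ||
      !isSymmetric(unname(corr_matrix), tol = 1e-8)) {
    abort("`corr_matrix` must be symmetric")
  }
  m <- nrow(corr_matrix)
  if (m == 1) return(1)
  ev <- eigen(corr_matrix, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  me <- m - sum(pmax(ev - 1, 0))
  min(m, max(1, me))
}

#' Extended-Simes (GATES) gene-based p-value
#'
#' Combines a gene's SNP p-values into one gene-level p-value: the SNP
#' p-values are sorted ascending (ties broken by genomic position, then
#' id), the p-value correlation matrix is derived from the genotype LD
#' via [pvalue_correlation_approx()], and the gene p-value is
#' `min_j Me * p_(j) / Me(j)` where `Me` is the effective number of tests
#' of the full matrix and `Me(j)` that of the leading `j x j` submatrix in
#' sorted order, capped at 1. With identity LD this is exactly the Simes
#' combination; with perfect LD it is exactly the minimum p-value.
#'
#' @param p SNP p-values (at least one non-missing; missing ones are
#'   dropped with their matrix rows).
#' @param r_matrix Signed genotype correlation matrix matching `p`;
#'   may be omitted for a single SNP.
#' @param snp_id,pos Optional ids and genomic positions used for
#'   deterministic tie-breaking and reporting.
#' @param pcorr_method Passed to [pvalue_correlation_approx()].
#' @return An object of class `gates_result`: a list with `gene_p`, `m`,
#'   `me`, `me_partial`, `snp_id` (sorted order), `p_sorted`,
#'   `pcorr_method`, `n_dropped`. `tidy()` and `glance()` methods are
#'   available.
#' @export
#' @examples
#' gates_test(c(0.01, 0.02, 0.9), diag(3))
gates_test <- function(p, r_matrix = NULL, snp_id = NULL, pos = NULL,
                       pcorr_method = c("gates_poly", "r2")) {
  pcorr_method <- match.arg(pcorr_method)
  n_in <- length(p)
  snp_id <- snp_id %||% sprintf("snp%03d", seq_len(n_in))
  pos <- pos %||% seq_len(n_in)
  keep <- !is.na(p)
  if (!any(keep)) abort("all SNP p-values are missing")
  if (any(p[keep] <= 0 | p[keep] > 1)) abort("p-values must lie in (0, 1]")
  n_dropped <- sum(!keep)
  p <- p[keep]; snp_id <- snp_id[keep]; pos <- pos[keep]
  m <- length(p)

  if (m == 1) {
    return(structure(
      list(
        gene_p = p, m = 1L, me = 1, me_partial = 1,
        snp_id = snp_id, p_sorted = p,
        pcorr_method = pcorr_method, n_dropped = n_dropped
      ),
      class = "gates_result"
    ))
  }
  if (is.null(r_matrix)) abort("`r_matrix` is required for more than one SNP")
  r_matrix <- as.matrix(r_matrix)
  if (n_in > 1) r_matrix <- r_matrix[keep, keep, drop = FALSE]
  if (!all(dim(r_matrix) == m)) {
    abort("`r_matrix` dimensions must match the number of SNPs")
  }

  o <- order(p, pos, snp_id)
  p_sorted <- p[o]
  pcorr <- pvalue_correlation_approx(r_matrix[o, o, drop = FALSE],
    method = pcorr_method
  )
  diag(pcorr) <- 1
  me <- effective_number(pcorr)
  me_partial <- vapply(seq_len(m), function(j) {
    effective_number(pcorr[seq_len(j), seq_len(j), drop = FALSE])
  }, numeric(1))
  gene_p <- min(1, min(me * p_sorted / me_partial))

  structure(
    list(
      gene_p = gene_p, m = m, me = me, me_partial = me_partial,
      snp_id = snp_id[o], p_sorted = p_sorted,
      pcorr_method = pcorr_method, n_dropped = n_dropped
    ),
    class = "gates_result"
  )
}

#' @export
print.gates_result <- function(x, ...) {
  cat(sprintf(
    "<gates_result> %d SNPs, Me = %.2f, gene p = %.3g (%s)\n",
    x$m, x$me, x$gene_p, x$pcorr_method
  ))
  invisible(x)
}

#' Gene-based p-values for every gene of a study
#'
#' Runs [gates_test()] per gene over the SNP assignments, pulling SNP
#' p-values from an association table and LD from the genotype panel.
#' Genes whose assigned SNPs all lack a valid p-value, or with no assigned
#' SNPs, are dropped with a message.
#'
#' @param assoc Association tibble from [snp_association()] (needs
#'   `snp_id`, `pos`, `p`).
#' @param assignments SNP-to-gene assignment tibble from [assign_snps()]
#'   (needs `gene_symbol`, `snp_id`).
#' @param panel `genotype_panel` supplying LD.
#' @param pcorr_method Passed to [gates_test()].
#' @return A tibble with `gene_symbol`, `n_snps`, `me`, `gates_p`.
#' @export
gene_based_pvalues <- function(assoc, assignments, panel,
                               pcorr_method = c("gates_poly", "r2")) {
  pcorr_method <- match.arg(pcorr_method)
  merged <- inner_join(assignments, assoc[c("snp_id", "pos", "p")],
    by = "snp_id", suffix = c("", ".assoc")
  )
  if ("pos.assoc" %in% names(merged)) merged$pos <- merged$pos.assoc
  merged <- filter(merged, !is.na(.data$p))
  genes <- unique(assignments$gene_symbol)
  skipped <- setdiff(genes, unique(merged$gene_symbol))
  if (length(skipped) > 0) {
    inform(paste0(length(skipped), " gene(s) without usable SNPs dropped"))
  }
  res <- merged |>
    group_by(.data$gene_symbol) |>
    group_map(function(g, key) {
      r <- if (nrow(g) > 1) ld_correlation(panel, g$snp_id) else NULL
      fit <- gates_test(g$p, r, snp_id = g$snp_id, pos = g$pos,
        pcorr_method = pcorr_method)
      tibble(
        gene_symbol = key$gene_symbol,
        n_snps = fit$m,
        me = fit$me,
        gates_p = fit$gene_p
      )
    }) |>
    bind_rows()
  arrange(res, .data$gates_p)
}
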