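#' Per-SNP case-control association with covariate adjustment
#'
#' Additive-coding logistic regression per SNP (`status ~ dosage + age +
#' sex`) with a two-tailed Wald p-value on the dosage coefficient. Age is
#' standardized and sex coded male = 1 before fitting, for numerical
#' stability; missing dosages are dropped per SNP (complete-case).
#' Monomorphic SNPs and fits showing separation are recorded with a
#' missing p-value and a reason in `note`.
#'
#' @param panel A [simulate_genotype_panel()]-style `genotype_panel` (or
#'   one read from disk, see [read_dosage_tsv()]).
#' @param pheno Tibble with `individual_id`, `status` (0/1), `age`, `sex`
#'   (`"male"`/`"female"`); ids must match the panel.
#' @param covariates Character subset of `c("age", "sex")`.
#' @return A tibble with `snp_id`, `chrom`, `pos`, `effect` (log-odds per
#'   allele), `se`, `p`, `note`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_snps = 10, n_individuals = 300)
#' panel <- simulate_genotype_panel(cfg)
#' pheno <- simulate_case_control_study(panel, cfg)
#' snp_association(panel, pheno)
snp_association <- function(panel, pheno, covariates = c("age", "sex")) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!all(covariates %in% c("age", "sex"))) {
    abort("`covariates` must be a subset of c(\"age\", \"sex\")")
  }
  idx <- match(panel$individual_ids, pheno$individual_id)
  if (anyNA(idx)) abort("`pheno` must cover every individual of the panel")
  pheno <- pheno[idx, ]
  y <- pheno$status
  if (!all(y %in% 0:1) || length(unique(y)) < 2) {
    abort("`status` must contain both 0 (control) and 1 (case)")
  }
  if (min(table(y)) < 10) {
    abort("need at least 10 individuals per status group")
  }

  covs <- NULL
  if ("age" %in% covariates) covs <- cbind(covs, age = as.vector(scale(pheno$age)))
  if ("sex" %in% covariates) covs <- cbind(covs, sex = as.integer(pheno$sex == "male"))

  m <- ncol(panel$dosages)
  effect <- se <- p <- rep(NA_real_, m)
  note <- rep(NA_character_, m)
  X <- cbind(intercept = rep(1, length(y)), dosage = 0, covs)

  for (j in seq_len(m)) {
    x <- panel$dosages[, j]
    ok <- !is.na(x)
    if (var(x[ok]) == 0) {
      note[j] <- "monomorphic"
      next
    }
    X[, 2] <- x
    fit <- suppressWarnings(
      glm.fit(X[ok, , drop = FALSE], y[ok], family = binomial())
    )
    rk <- fit$rank
    cf <- fit$coefficients[2]
    vc <- chol2inv(fit$qr$qr[seq_len(rk), seq_len(rk), drop = FALSE])
    s <- sqrt(vc[2, 2])
    if (!fit$converged || !is.finite(cf) || abs(cf) > 15 || s > 50) {
      note[j] <- "separation"
      effect[j] <- cf
      next
    }
    effect[j] <- cf
    se[j] <- s
    p[j] <- 2 * pnorm(-abs(cf / s))
  }
  p <- ifelse(is.na(p), p, pmax(p, .Machine$double.xmin))
  tibble(
    snp_id = panel$snp_map$snp_id,
    chrom = panel$snp_map$chrom,
    pos = panel$snp_map$pos,
    effect = effect,
    se = se,
    p = p,
    note = note
  )
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, 1)) / 0.4549...`, the median of the
#' implied 1-df chi-square statistics divided by the null median
#' `qchisq(0.5, 1)`. Values near 1 indicate no systematic inflation.
#'
#' @param p_values Vector of p-values in (0, 1].
#' @return A single number.
#' @export
#' @examples
#' genomic_inflation(runif(1e4))
genomic_inflation <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0) abort("`p_values` must be non-empty")
  if (any(p_values <= 0 | p_values > 1)) abort("p-values must lie in (0, 1]")
  median(qchisq(p_values, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' Quantile-quantile coordinates for association p-values
#'
#' @param p_values Vector of p-values in (0, 1]; `NA`s are dropped.
#' @return A tibble with `expected` and `observed` `-log10(p)` coordinates.
#' @export
qq_points <- function(p_values) {
  p_values <- sort(p_values[!is.na(p_values)])
  if (length(p_values) == 0) abort("`p_values` must be non-empty")
  if (any(p_values <= 0 | p_values > 1)) abort("p-values must lie in (0, 1]")
  tibble(
    expected = -log10(ppoints(length(p_values))),
    observed = -log10(p_values)
  )
}

#' QQ plot of association p-values
#'
#' @param p_values Vector of p-values, or an association tibble with a `p`
#'   column (e.g. from [snp_association()]).
#' @return A ggplot object annotated with the genomic inflation factor.
#' @export
plot_qq <- function(p_values) {
  if (is.data.frame(p_values)) p_values <- p_values$p
  qq <- qq_points(p_values)
  lambda <- genomic_inflation(p_values[!is.na(p_values)])
  ggplot2::ggplot(qq, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p)),
      subtitle = sprintf("lambda = %.3f", lambda)
    ) +
    ggplot2::theme_minimal()
}
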