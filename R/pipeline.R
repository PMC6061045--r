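#' Run the full synthetic cross-species study
#'
#' Generates every input with the synthetic-data module and runs the whole
#' prioritization: strain-differential screen, amyloid-correlation scoring
#' in the transgenic cohort, case-control GWAS with age/sex adjustment,
#' LD-aware SNP-to-gene assignment, extended-Simes gene-based statistics,
#' and the inverse-normal combination through the ortholog table.
#'
#' @param config A [sim_config()].
#' @param screen If `TRUE`, only genes passing the strain-differential
#'   screen enter the combination (the faithful two-step design); if
#'   `FALSE` (default) every gene is carried through, which is what
#'   planted-signal recovery experiments need to rank causal against null
#'   genes.
#' @param alpha Screen threshold on the summary p-value.
#' @param pcorr_method Passed to [gene_based_pvalues()].
#' @param quiet Suppress progress messages.
#' @return A list with elements `config`, `truth`, `de`, `candidates`,
#'   `mouse` (per-gene correlation stats), `assoc` (per-SNP), `lambda`,
#'   `gene_stats` (per-gene GATES), and `combined` (a `combined_stats`
#'   tibble).
#' @export
#' @examples
#' \donttest{
#' res <- run_integrated_study(sim_config(seed = 1, n_genes = 20))
#' head(res$combined)
#' }
run_integrated_study <- function(config, screen = FALSE, alpha = 0.001,
                                 pcorr_method = c("gates_poly", "r2"),
                                 quiet = TRUE) {
  pcorr_method <- match.arg(pcorr_method)
  run <- if (quiet) suppressMessages else identity

  truth <- ground_truth(config)
  strain <- simulate_strain_expression(config, truth)
  de <- strain_differential_test(strain$expression, config$target_strain,
    alpha = alpha
  )
  candidates <- run(select_candidate_genes(de, strain$probe_map, alpha = alpha))

  tg <- simulate_tg_cohort(config, truth)
  corr <- abeta_correlation(tg$expression, tg$abeta)
  mouse <- collapse_probes(corr, tg$probe_map)
  if (screen) mouse <- filter(mouse, .data$gene_symbol %in% candidates$gene_symbol)

  panel <- simulate_genotype_panel(config)
  regions <- make_gene_regions(panel, config$n_genes)
  truth <- causal_snps_for(truth, panel)
  pheno <- simulate_case_control_study(panel, config, truth)
  assoc <- snp_association(panel, pheno)
  assignments <- run(assign_snps(regions, panel$snp_map, panel))
  gene_stats <- run(gene_based_pvalues(assoc, assignments, panel,
    pcorr_method = pcorr_method
  ))

  orthologs <- make_ortholog_table(
    human_symbols(config$n_genes), mouse_symbols(config$n_genes)
  )
  combined <- run(integrate_evidence(mouse, gene_stats, orthologs))

  list(
    config = config, truth = truth, de = de, candidates = candidates,
    mouse = mouse, assoc = assoc,
    lambda = genomic_inflation(assoc$p[!is.na(assoc$p)]),
    gene_stats = gene_stats, combined = combined
  )
}

#' Planted-gene recovery across replicate synthetic studies
#'
#' Repeats [run_integrated_study()] with per-replicate seeds derived from
#' `seed` and scores, per replicate, the fraction of null genes each
#' planted gene outranks on the combined p-value. A replicate is a
#' success when every planted gene outranks at least `beat_fraction` of
#' the null genes.
#'
#' @param config Template [sim_config()]; its seed is replaced per
#'   replicate.
#' @param n_reps Number of replicates.
#' @param seed Root seed for the replicate seeds.
#' @param beat_fraction Required fraction of null genes outranked.
#' @return A list with `success_rate`, and `per_rep` (tibble: `rep`,
#'   `min_beat`, `success`).
#' @export
recovery_experiment <- function(config, n_reps = 50, seed = 1,
                                beat_fraction = 0.95) {
  per_rep <- purrr::map_dfr(seq_len(n_reps), function(i) {
    cfg_i <- config
    cfg_i$seed <- as.integer((as.double(seed) * 1009 + i * 7717) %%
      .Machine$integer.max)
    res <- run_integrated_study(cfg_i)
    cmb <- res$combined
    causal <- cmb$human_symbol %in% res$truth$genes$human_symbol
    null_p <- cmb$p_combined[!causal]
    beat <- vapply(
      cmb$p_combined[causal],
      function(p) mean(null_p > p),
      numeric(1)
    )
    tibble(rep = i, min_beat = min(beat),
      success = min(beat) >= beat_fraction)
  })
  list(success_rate = mean(per_rep$success), per_rep = per_rep)
}

#' Null calibration of the gene-based test under LD
#'
#' Empirical type-I error of [gates_test()] on a synthetic null gene:
#' a genotype panel with one AR-1 LD block is simulated, a balanced null
#' phenotype is permuted `n_reps` times, per-SNP two-tailed p-values are
#' taken from the normal approximation of the score statistic
#' (`z = sqrt(n - 1) * cor(dosage, status)`), and the gene-based p-value
#' is computed per permutation against the panel's realized LD.
#'
#' @param n_snps SNPs in the gene (one LD block).
#' @param rho Latent AR-1 correlation of the block.
#' @param n_reps Number of phenotype permutations.
#' @param n_individuals Panel size.
#' @param maf Minor-allele frequency (equal across SNPs).
#' @param alpha Nominal level whose empirical frequency is reported.
#' @param seed Seed for panel and permutations.
#' @param pcorr_method Passed to [gates_test()].
#' @return A list with `rejection_rate`, `alpha`, `n_reps`, and the
#'   vector `gene_p`.
#' @export
gates_null_calibration <- function(n_snps = 10, rho = 0.8, n_reps = 10000,
                                   n_individuals = 2000, maf = 0.3,
                                   alpha = 0.05, seed = 1,
                                   pcorr_method = c("gates_poly", "r2")) {
  pcorr_method <- match.arg(pcorr_method)
  cfg <- sim_config(
    seed = seed, n_snps = n_snps, block_size = n_snps,
    within_block_rho = rho, maf_range = c(maf, maf),
    n_individuals = n_individuals
  )
  panel <- simulate_genotype_panel(cfg)
  r <- ld_correlation(panel)
  x <- panel$dosages
  n <- nrow(x)
  pos <- panel$snp_map$pos

  set.seed(substream_seed(seed, "case_control"))
  y <- rep(0:1, length.out = n)
  perms <- matrix(0, n, n_reps)
  for (b in seq_len(n_reps)) perms[, b] <- sample(y)
  z <- cor(x, perms) * sqrt(n - 1)
  p <- 2 * pnorm(-abs(z))
  gene_p <- vapply(seq_len(n_reps), function(b) {
    gates_test(p[, b], r, snp_id = colnames(x), pos = pos,
      pcorr_method = pcorr_method)$gene_p
  }, numeric(1))
  list(
    rejection_rate = mean(gene_p < alpha),
    alpha = alpha,
    n_reps = n_reps,
    gene_p = gene_p
  )
}
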