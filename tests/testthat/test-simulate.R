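test_that("identical configs give bit-identical outputs across all generators", {
  cfg <- tiny_config(seed = 42)
  expect_identical(
    simulate_strain_expression(cfg), simulate_strain_expression(cfg)
  )
  expect_identical(simulate_tg_cohort(cfg), simulate_tg_cohort(cfg))
  p1 <- simulate_genotype_panel(cfg)
  p2 <- simulate_genotype_panel(cfg)
  expect_identical(p1, p2)
  t1 <- causal_snps_for(ground_truth(cfg), p1)
  expect_identical(
    simulate_case_control_study(p1, cfg, t1),
    simulate_case_control_study(p2, cfg, t1)
  )
})

test_that("config validation rejects degenerate designs and parameters", {
  expect_error(sim_config(n_causal = 5, n_genes = 3), "n_causal")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(within_block_rho = 1), "within_block_rho")
  expect_error(sim_config(abeta_corr_effects = c(0.5, 1)), "magnitude")
  expect_error(sim_config(n_genes = 0), "counts")
  expect_error(
    simulate_strain_expression(tiny_config(strain_sizes = c(DBA = 1, B6 = 4, SJL = 4))),
    "invalid design"
  )
  expect_error(
    simulate_tg_cohort(tiny_config(n_tg_animals = 2)),
    "at least 4"
  )
})

test_that("non-planted genes have identical strain means; planted shift only in target", {
  cfg <- sim_config(
    seed = 3, n_genes = 2000, n_causal = 5,
    strain_sizes = c(DBA = 40, B6 = 40, SJL = 40), strain_shift = 4
  )
  sim <- simulate_strain_expression(cfg)
  means <- sim$expression |>
    dplyr::group_by(probe_id, strain) |>
    dplyr::summarise(m = mean(expression), .groups = "drop") |>
    tidyr::pivot_wider(names_from = strain, values_from = m)
  causal_probes <- sprintf("P%04d_at", sim$truth$genes$gene_index)
  null_rows <- !means$probe_id %in% causal_probes
  # null genes: strain means agree within sampling error of the noise
  se <- cfg$noise_sd * sqrt(2 / 40)
  expect_lt(max(abs(means$DBA - means$B6)[null_rows]), 6 * se)
  expect_lt(max(abs(means$B6 - means$SJL)[null_rows]), 6 * se)
  # planted genes: shifted in DBA only, by ~4 noise SD
  causal_rows <- match(causal_probes, means$probe_id)
  expect_true(all(abs(means$DBA - means$B6)[causal_rows] > 2))
  expect_lt(max(abs(means$B6 - means$SJL)[causal_rows]), 6 * se)
})

test_that("null strain design selects roughly the nominal fraction of probes", {
  cfg <- sim_config(
    seed = 11, n_genes = 5000, n_causal = 1, strain_shift = 0
  )
  sim <- simulate_strain_expression(cfg)
  de_pooled <- strain_differential_test(sim$expression, "DBA",
    mode = "pooled", alpha = 0.01
  )
  frac <- mean(de_pooled$selected)
  # binomial 99.9% band around alpha = 0.01 at n = 5000
  band <- 3.3 * sqrt(0.01 * 0.99 / 5000)
  expect_gt(frac, 0.01 - band)
  expect_lt(frac, 0.01 + band)
  # either-mode is a minimum over two comparisons, so at least alpha
  de_either <- strain_differential_test(sim$expression, "DBA",
    mode = "either", alpha = 0.01
  )
  expect_gte(mean(de_either$selected), frac * 0.8)
  expect_lt(mean(de_either$selected), 2 * 0.01 + band)
})

test_that("planted 3-SD shift is recovered at the rate the noncentral-t oracle predicts", {
  # oracle: per-comparison power at alpha = 0.001 two-tailed, 4 + 4 samples,
  # shift of 3 noise SD -> ncp = 3 / sqrt(1/4 + 1/4), df = 6
  crit <- qt(1 - 0.0005, df = 6)
  power_single <- pt(crit, df = 6, ncp = 3 / sqrt(0.5), lower.tail = FALSE)
  # either-mode takes the min of two (positively correlated) comparisons:
  # bounded by [power_single, 2 * power_single]
  hits <- 0L
  n_rep <- 200L
  for (s in seq_len(n_rep)) {
    cfg <- sim_config(seed = s, n_genes = 4, n_causal = 1, strain_shift = 3)
    sim <- simulate_strain_expression(cfg)
    de <- strain_differential_test(sim$expression, "DBA")
    causal_probe <- sprintf("P%04d_at", sim$truth$genes$gene_index)
    hits <- hits + de$selected[de$probe_id == causal_probe]
  }
  rate <- hits / n_rep
  mc <- 3 * sqrt(0.35 * 0.65 / n_rep)
  expect_gt(rate, power_single - mc)
  expect_lt(rate, 2 * power_single + mc)
})

test_that("default planted shift gives the screen >= 90% per-gene power", {
  hits <- 0L
  n_rep <- 150L
  for (s in seq_len(n_rep)) {
    cfg <- sim_config(seed = 1000 + s, n_genes = 4, n_causal = 1)
    sim <- simulate_strain_expression(cfg)
    de <- strain_differential_test(sim$expression, "DBA")
    causal_probe <- sprintf("P%04d_at", sim$truth$genes$gene_index)
    hits <- hits + de$selected[de$probe_id == causal_probe]
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("transgenic cohort hits the target correlation and its null is calibrated", {
  # mean sample r within 0.1 of the -0.7 target across 500 cohorts
  rs <- vapply(seq_len(500), function(s) {
    cfg <- sim_config(
      seed = s, n_genes = 3, n_causal = 1, abeta_corr_effects = -0.7
    )
    tg <- simulate_tg_cohort(cfg)
    probe <- sprintf("P%04d_at", tg$truth$genes$gene_index)
    abeta_correlation(tg$expression, tg$abeta, probes = probe)$r
  }, numeric(1))
  expect_lt(abs(mean(rs) + 0.7), 0.1)

  # null genes at n = 28: |r| exceeds the two-tailed 5% critical value
  # (t with 26 df => |r| ~ 0.374) about 5% of the time
  cfg <- sim_config(seed = 9, n_genes = 2000, n_causal = 1,
    abeta_corr_effects = 0)
  tg <- simulate_tg_cohort(cfg)
  cr <- abeta_correlation(tg$expression, tg$abeta)
  r_crit <- sqrt(qt(0.975, 26)^2 / (qt(0.975, 26)^2 + 26))
  frac <- mean(abs(cr$r) > r_crit)
  expect_gt(frac, 0.05 - 3.3 * sqrt(0.05 * 0.95 / 2000))
  expect_lt(frac, 0.05 + 3.3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("genotype panel respects MAF targets and the latent LD structure", {
  cfg <- sim_config(seed = 5, n_snps = 200, block_size = 5,
    n_individuals = 2000)
  panel <- simulate_genotype_panel(cfg)
  # sample allele frequency within 0.03 of target (binomial bound at n=2000)
  af <- colMeans(panel$dosages) / 2
  expect_lt(max(abs(af - panel$snp_map$maf)), 0.03)
  expect_true(all(diff(panel$snp_map$pos) > 0))

  # rho = 0: no LD anywhere
  cfg0 <- sim_config(seed = 6, n_snps = 50, within_block_rho = 0,
    n_individuals = 2000)
  r0 <- ld_correlation(simulate_genotype_panel(cfg0))
  expect_lt(mean(abs(r0[upper.tri(r0)])), 0.05)

  # thresholding attenuates the latent correlation: median adjacent
  # dosage r^2 is ~0.64 at latent rho 0.95 and exceeds 0.8 only by 0.99
  adj_r2 <- function(rho, seed) {
    cfg <- sim_config(seed = seed, n_snps = 40, block_size = 40,
      within_block_rho = rho, maf_range = c(0.3, 0.3),
      n_individuals = 2000)
    r <- ld_correlation(simulate_genotype_panel(cfg))
    median(diag(r[-1, -ncol(r)])^2)
  }
  r2_95 <- adj_r2(0.95, 7)
  r2_99 <- adj_r2(0.99, 8)
  expect_gt(r2_95, 0.5)
  expect_lt(r2_95, 0.75)
  expect_gt(r2_99, 0.8)
})

test_that("case-control generator calibrates the case fraction and plants signal", {
  cfg <- sim_config(seed = 10)
  panel <- simulate_genotype_panel(cfg)
  truth <- causal_snps_for(ground_truth(cfg), panel)
  pheno <- simulate_case_control_study(panel, cfg, truth)
  expect_true(abs(mean(pheno$status) - 0.5) <= 0.02)
  expect_true(all(c("age", "sex") %in% names(pheno)))
  expect_setequal(unique(pheno$sex), c("male", "female"))

  # skewed target fraction also calibrated
  cfg2 <- sim_config(seed = 12, case_fraction = 0.1, n_snps = 20)
  panel2 <- simulate_genotype_panel(cfg2)
  pheno2 <- simulate_case_control_study(panel2, cfg2)
  expect_true(abs(mean(pheno2$status) - 0.1) <= 0.02)

  expect_error(
    simulate_case_control_study(
      panel, cfg,
      structure(list(
        genes = truth$genes, snp_ids = "rs999999"
      ), class = "ground_truth")
    ),
    "missing from the panel"
  )
})

test_that("planted causal SNP is strongly associated (median p < 1e-4 across replicates)", {
  ps <- vapply(seq_len(40), function(s) {
    cfg <- sim_config(
      seed = 100 + s, n_genes = 2, n_causal = 1, n_snps = 10,
      block_size = 5, maf_range = c(0.3, 0.3), n_individuals = 2000
    )
    panel <- simulate_genotype_panel(cfg)
    truth <- causal_snps_for(ground_truth(cfg), panel)
    pheno <- simulate_case_control_study(panel, cfg, truth)
    assoc <- snp_association(panel, pheno)
    assoc$p[assoc$snp_id == truth$snp_ids[1]]
  }, numeric(1))
  expect_lt(median(ps), 1e-4)
})

test_that("ortholog table construction flags families and rejects bad input", {
  tbl <- make_ortholog_table(c("LBH", "SHF"), c("Lbh", "Shf"))
  expect_equal(nrow(tbl), 2)
  expect_false(any(tbl$multi))

  # a duplicated mouse symbol is allowed and flagged as a 2:1 family
  tbl2 <- make_ortholog_table(c("A1", "A2", "B1"), c("a1", "a1", "b1"))
  expect_equal(sum(tbl2$multi), 2)
  expect_false(tbl2$multi[tbl2$human_symbol == "B1"])

  expect_error(
    make_ortholog_table(c("A", "A"), c("a", "b")),
    "duplicate human symbol"
  )

  # scrambling injects flagged many-to-many rows
  tbl3 <- make_ortholog_table(paste0("G", 1:10), paste0("g", 1:10),
    scramble_fraction = 0.2, seed = 4)
  expect_equal(nrow(tbl3), 12)
  expect_gte(sum(tbl3$multi), 4)
})
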