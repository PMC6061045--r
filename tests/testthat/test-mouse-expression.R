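test_that("equal-variance t matches the textbook formula and stats::t.test", {
  a <- c(1, 2, 3, 4)
  b <- c(3, 4, 5, 6)
  m <- rbind(c(a, b))
  expr <- expr_from_matrix(
    matrix(c(a, b), 1, dimnames = list("P0001_at", NULL)),
    strain = rep(c("DBA", "B6"), each = 4)
  )
  de <- strain_differential_test(expr, "DBA", mode = "pooled")
  # textbook: pooled var = 5/3, se = sqrt(5/3 * 1/2), t = -2/se, df = 6
  se_hand <- sqrt((5 / 3) * (1 / 4 + 1 / 4))
  t_hand <- (mean(a) - mean(b)) / se_hand
  expect_equal(de$t_pooled, t_hand, tolerance = 1e-12)
  expect_equal(de$p_pooled, 2 * pt(-abs(t_hand), 6), tolerance = 1e-12)

  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(de$t_pooled, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(de$p_pooled, tt$p.value, tolerance = 1e-12)

  # random matrices agree with per-probe t.test
  set.seed(1)
  mm <- matrix(rnorm(50 * 8), 50)
  expr2 <- expr_from_matrix(mm, strain = rep(c("DBA", "B6"), each = 4))
  de2 <- strain_differential_test(expr2, "DBA", mode = "pooled")
  ref <- apply(mm, 1, function(x) {
    t.test(x[1:4], x[5:8], var.equal = TRUE)$p.value
  })
  expect_equal(de2$p_pooled, unname(ref), tolerance = 1e-10)
})

test_that("degenerate groups follow the stated conventions", {
  # identical values in both groups: t = 0, p = 1
  m <- matrix(5, 1, 8, dimnames = list("P0001_at", NULL))
  expr <- expr_from_matrix(m, strain = rep(c("DBA", "B6"), each = 4))
  de <- strain_differential_test(expr, "DBA", mode = "pooled")
  expect_equal(de$t_pooled, 0)
  expect_equal(de$p_pooled, 1)

  # zero variance with different means: p clamped into (0, 1]
  m2 <- matrix(rep(c(1, 2), each = 4), 1, 8, byrow = TRUE,
    dimnames = list("P0001_at", NULL))
  expr2 <- expr_from_matrix(m2, strain = rep(c("DBA", "B6"), each = 4))
  de2 <- strain_differential_test(expr2, "DBA", mode = "pooled")
  expect_gt(de2$p_pooled, 0)
  expect_lt(de2$p_pooled, 1e-300)

  # a strain with < 2 samples is an invalid design
  expr3 <- expr_from_matrix(matrix(rnorm(5), 1), strain = c("DBA", rep("B6", 4)))
  expect_error(strain_differential_test(expr3, "DBA"), "invalid design")
})

test_that("summary rule follows the selected mode", {
  set.seed(2)
  m <- matrix(rnorm(20 * 12), 20)
  expr <- expr_from_matrix(m, strain = rep(c("DBA", "B6", "SJL"), each = 4))
  de <- strain_differential_test(expr, "DBA", mode = "either")
  expect_equal(de$p_summary, pmin(de$p_B6, de$p_SJL))
  de_both <- strain_differential_test(expr, "DBA", mode = "both")
  expect_equal(de_both$p_summary, pmax(de$p_B6, de$p_SJL))
  # min rule: a probe with comparison p (0.0005, 0.2) is selected at 0.001
  fake <- de[1, ]
  fake$p_B6 <- 0.0005
  fake$p_SJL <- 0.2
  expect_equal(min(fake$p_B6, fake$p_SJL), 0.0005)
  expect_lt(min(fake$p_B6, fake$p_SJL), 0.001)
})

test_that("fdr_at_threshold implements the expected-false-positives estimator", {
  expect_equal(fdr_at_threshold(c(rep(0.005, 50), runif(950, 0.02, 1)), 0.01),
    1000 * 0.01 / 50)
  p_all <- runif(200, 0, 0.04)
  expect_equal(fdr_at_threshold(p_all, 0.05), 0.05)
  expect_true(is.na(fdr_at_threshold(c(0.5, 0.9), 0.001)))
  expect_error(fdr_at_threshold(numeric(0), 0.01), "non-empty")
  expect_error(fdr_at_threshold(0.5, 1.5), "alpha")
  # uniform p: estimate near 1
  set.seed(3)
  expect_equal(fdr_at_threshold(runif(2e5), 0.05), 1, tolerance = 0.05)
})

test_that("candidate selection collapses probes to genes and reports counts", {
  diff <- tibble::tibble(
    probe_id = c("p1", "p2", "p3", "p4"),
    p_summary = c(1e-4, 5e-4, 0.5, 2e-4)
  )
  map <- tibble::tibble(
    probe_id = c("p1", "p2", "p3"),
    gene_symbol = c("Lbh", "Lbh", "Shf")
  )
  expect_warning(
    genes <- suppressMessages(select_candidate_genes(diff, map)),
    "without gene mapping"
  )
  expect_equal(nrow(genes), 1)
  expect_equal(genes$gene_symbol, "Lbh")
  expect_equal(genes$n_probes, 2)
  expect_equal(attr(genes, "n_probes_selected"), 2)

  none <- suppressMessages(
    select_candidate_genes(diff[3, ], map)
  )
  expect_equal(nrow(none), 0)
})

test_that("amyloid correlation reproduces the published (r, n = 28) mapping", {
  # five candidate-gene rows: r and printed two-tailed p at n = 28
  r <- c(-0.6941, 0.5970, 0.6609, -0.6009, -0.6455)
  printed <- c(0.000042, 0.000797, 0.000129, 0.000722, 0.000208)
  t_stat <- r * sqrt(26 / (1 - r^2))
  p <- 2 * pt(-abs(t_stat), 26)
  # agreement within one unit in the last printed digit (inputs are rounded)
  expect_true(all(abs(p - printed) <= 1e-6))
  # the two anchor rows round exactly to the printed values
  expect_equal(round(p[1], 6), 0.000042)
  expect_equal(round(p[5], 6), 0.000208)
})

test_that("abeta_correlation computes Pearson r, t-based p and direction", {
  set.seed(4)
  a <- rlnorm(28, log(50), 0.5)
  x <- 2 - 0.03 * a + rnorm(28, sd = 0.2)
  m <- rbind(x, 3 + 0.02 * a, rep(1, 28))
  rownames(m) <- c("Pneg", "Ppos", "Pflat")
  colnames(m) <- sprintf("Tg_%02d", 1:28)
  expr <- expr_from_matrix(m)
  abeta <- tibble::tibble(sample_id = colnames(m), abeta = a)

  expect_error(abeta_correlation(expr, abeta), "zero expression variance")
  res <- suppressWarnings(
    abeta_correlation(expr, abeta, on_zero_variance = "drop")
  )
  expect_equal(nrow(res), 2)
  neg <- res[res$probe_id == "Pneg", ]
  expect_equal(neg$r, cor(x, a), tolerance = 1e-12)
  expect_equal(neg$direction, "Down")
  expect_equal(
    neg$p,
    cor.test(x, a)$p.value,
    tolerance = 1e-10
  )

  # exactly linear expression: r = 1, direction Up, p at the floor
  lin <- expr_from_matrix(
    matrix(2 * a + 1, 1, dimnames = list("Plin", colnames(m)))
  )
  res_lin <- abeta_correlation(lin, abeta)
  expect_equal(res_lin$r, 1, tolerance = 1e-12)
  expect_equal(res_lin$direction, "Up")
  expect_gt(res_lin$p, 0)

  expect_error(
    abeta_correlation(expr[expr$sample_id %in% colnames(m)[1:3], ], abeta),
    "at least 4"
  )
})

test_that("analytic correlation p agrees with a permutation oracle", {
  cfg <- sim_config(seed = 21, n_genes = 20, n_causal = 1,
    abeta_corr_effects = 0.5)
  tg <- simulate_tg_cohort(cfg)
  res <- abeta_correlation(tg$expression, tg$abeta)
  a <- tg$abeta$abeta
  n <- length(a)
  m <- matrix(tg$expression$expression, nrow = 20)
  rownames(m) <- tg$probe_map$probe_id

  set.seed(99)
  n_perm <- 10000
  perm_idx <- replicate(n_perm, sample.int(n))
  a_perm <- matrix(a[perm_idx], n, n_perm)
  for (probe in rownames(m)) {
    x <- m[probe, ]
    r_obs <- abs(cor(x, a))
    r_perm <- abs(as.vector(cor(x, a_perm)))
    p_perm <- (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
    p_analytic <- res$p[res$probe_id == probe]
    mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / n_perm) + 2 / n_perm
    expect_lt(abs(p_analytic - p_perm), mc_err + 0.01 * p_perm + 5e-4)
  }
})

test_that("probe collapse keeps the min-p probe with documented tie-breaks", {
  corr <- tibble::tibble(
    probe_id = c("pA", "pB", "pC", "pD", "pE"),
    n = 28,
    r = c(0.5, -0.8, 0.3, -0.3, 0.9),
    t = 0, # unused by the collapse
    p = c(0.01, 0.2, 0.05, 0.05, 0.5),
    direction = c("Up", "Down", "Up", "Down", "Up")
  )
  map <- tibble::tibble(
    probe_id = c("pA", "pB", "pC", "pD", "pE"),
    gene_symbol = c("G1", "G1", "G2", "G2", "G3")
  )
  out <- collapse_probes(corr, map)
  expect_equal(out$probe_id[out$gene_symbol == "G1"], "pA") # min p wins
  # tie on p: |r| equal -> lexicographic probe id
  expect_equal(out$probe_id[out$gene_symbol == "G2"], "pC")
  # single-probe gene passes through unchanged
  expect_equal(out$r[out$gene_symbol == "G3"], 0.9)

  # tie on p broken by larger |r| first
  corr2 <- corr
  corr2$r[3:4] <- c(0.3, -0.6)
  expect_equal(
    collapse_probes(corr2, map)$probe_id[2], "pD"
  )
  expect_error(
    collapse_probes(corr, map[-1, ]),
    "must be mapped"
  )
})
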