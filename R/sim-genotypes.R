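#' Simulate an LD-blocked diploid genotype panel
#'
#' Draws two haplotypes per individual from a latent-Gaussian threshold
#' model: within each block of `block_size` consecutive SNPs the latent
#' variables follow a stationary AR-1 process with correlation
#' `within_block_rho`, blocks are independent, and each latent value is
#' thresholded at the normal quantile of the SNP's minor-allele frequency.
#' Dosage is the sum of the two haplotypes. Thresholding attenuates the
#' dosage-scale correlation relative to the latent one (e.g. a latent
#' rho of 0.95 yields a median adjacent dosage r^2 near 0.64 at MAF 0.3).
#'
#' @param config A [sim_config()]; uses `n_individuals`, `n_snps`,
#'   `block_size`, `within_block_rho`, `maf_range` and the root seed.
#' @return An object of class `genotype_panel`: a list with `dosages`
#'   (integer matrix, individuals x SNPs), `snp_map` (tibble: `snp_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `maf`, `block`; positions strictly
#'   increasing), and `individual_ids`.
#' @export
#' @examples
#' panel <- simulate_genotype_panel(sim_config(seed = 1, n_snps = 10))
#' panel
simulate_genotype_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  m <- config$n_snps
  rho <- config$within_block_rho

  set.seed(substream_seed(config$seed, "genotype_panel"))
  maf <- runif(m, config$maf_range[1], config$maf_range[2])
  block <- rep(seq_len(ceiling(m / config$block_size)),
    each = config$block_size
  )[seq_len(m)]

  dosages <- matrix(0L, n, m)
  thresh <- qnorm(maf)
  for (b in unique(block)) {
    cols <- which(block == b)
    k <- length(cols)
    z <- matrix(rnorm(2 * n * k), 2 * n, k)
    if (k > 1 && rho > 0) {
      for (j in 2:k) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
    }
    hap <- z < rep(thresh[cols], each = 2 * n)
    dosages[, cols] <- hap[seq_len(n), , drop = FALSE] +
      hap[n + seq_len(n), , drop = FALSE]
  }

  snp_id <- sprintf("rs%06d", seq_len(m))
  individual_ids <- sprintf("I%05d", seq_len(n))
  dimnames(dosages) <- list(individual_ids, snp_id)
  structure(
    list(
      dosages = dosages,
      snp_map = tibble(
        snp_id = snp_id,
        chrom = "1",
        pos = 5000L * seq_len(m),
        ref = "A",
        alt = "G",
        maf = maf,
        block = block
      ),
      individual_ids = individual_ids
    ),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(
    "<genotype_panel>", length(x$individual_ids), "individuals x",
    nrow(x$snp_map), "SNPs in", max(x$snp_map$block), "blocks\n"
  )
  invisible(x)
}

#' Gene regions aligned to the LD blocks of a panel
#'
#' Assigns one gene per LD block: gene `i` spans the positions of block
#' `i`'s SNPs. With the default 5 kb SNP spacing and a 3 kb flank this
#' keeps neighbouring genes' SNPs out of each other's regions.
#'
#' @param panel A [simulate_genotype_panel()] result.
#' @param n_genes Number of genes; must not exceed the number of blocks.
#' @return A tibble with `gene_symbol` (human-style symbols), `chrom`,
#'   `start`, `end` (1-based inclusive).
#' @export
make_gene_regions <- function(panel, n_genes) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (n_genes > max(panel$snp_map$block)) {
    abort("`n_genes` exceeds the number of LD blocks in the panel")
  }
  panel$snp_map |>
    filter(.data$block <= n_genes) |>
    group_by(.data$block) |>
    summarise(
      chrom = .data$chrom[1],
      start = min(.data$pos),
      end = max(.data$pos),
      .groups = "drop"
    ) |>
    mutate(gene_symbol = human_symbols(n_genes)[.data$block]) |>
    select("gene_symbol", "chrom", "start", "end")
}

#' Pick the causal SNP of each planted gene
#'
#' Marks the middle SNP of each causal gene's LD block as the causal
#' variant and records it in the ground truth.
#'
#' @param truth A [ground_truth()].
#' @param panel A [simulate_genotype_panel()] result whose blocks are
#'   aligned to genes (see [make_gene_regions()]).
#' @return `truth` with `snp_ids` filled in.
#' @export
causal_snps_for <- function(truth, panel) {
  stopifnot(inherits(truth, "ground_truth"), inherits(panel, "genotype_panel"))
  ids <- vapply(truth$genes$gene_index, function(b) {
    snps <- panel$snp_map$snp_id[panel$snp_map$block == b]
    if (length(snps) == 0) {
      abort(paste0("no SNPs in block ", b, " for a causal gene"))
    }
    snps[ceiling(length(snps) / 2)]
  }, character(1))
  truth$snp_ids <- ids
  truth
}

#' Simulate case-control status with age and sex covariates
#'
#' Case status follows an additive-dosage logistic model
#' `logit(P) = b0 + sum(log(OR) * dosage_causal) + age_effect * (age -
#' age_mean) + sex_effect * male`, with age drawn normal and sex Bernoulli.
#' The intercept `b0` is calibrated by bisection against the realized
#' (sampled) case fraction, so the achieved fraction matches
#' `case_fraction` to within 0.02 deterministically.
#'
#' @param panel A [simulate_genotype_panel()] result.
#' @param config A [sim_config()].
#' @param truth A [ground_truth()] whose `snp_ids` (possibly empty, for a
#'   null study) are SNPs of the panel.
#' @return A tibble with `individual_id`, `status` (0 control / 1 case),
#'   `age` (years), `sex` (`"male"`/`"female"`).
#' @export
simulate_case_control_study <- function(panel, config,
                                        truth = ground_truth(config)) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "sim_config"))
  n <- length(panel$individual_ids)
  if (n == 0 || nrow(panel$snp_map) == 0) abort("empty genotype panel")
  if (!all(truth$snp_ids %in% panel$snp_map$snp_id)) {
    abort("causal SNPs are missing from the panel")
  }

  set.seed(substream_seed(config$seed, "case_control"))
  age <- rnorm(n, config$age_mean, config$age_sd)
  sex <- ifelse(runif(n) < 0.5, "male", "female")
  u <- runif(n)

  eta0 <- config$age_effect * (age - config$age_mean) +
    config$sex_effect * (sex == "male")
  if (length(truth$snp_ids) > 0) {
    g <- panel$dosages[, truth$snp_ids, drop = FALSE]
    eta0 <- eta0 + as.vector(g %*% rep(log(config$causal_snp_or), ncol(g)))
  }

  realized <- function(b0) mean(u < plogis(b0 + eta0))
  lo <- -25; hi <- 25
  b0 <- 0
  for (i in 1:200) {
    b0 <- (lo + hi) / 2
    r <- realized(b0)
    if (abs(r - config$case_fraction) <= 0.005) break
    if (r < config$case_fraction) lo <- b0 else hi <- b0
  }

  tibble(
    individual_id = panel$individual_ids,
    status = as.integer(u < plogis(b0 + eta0)),
    age = age,
    sex = sex
  )
}
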