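#' Configuration for the synthetic cross-species study
#'
#' Collects every size, effect and seed used by the synthetic-data
#' generators. One root `seed` drives all stages through fixed per-stage
#' substreams, so any stage can be regenerated independently and the whole
#' study is bit-reproducible.
#'
#' The defaults emulate the study design the pipeline is built around:
#' twelve non-transgenic arrays from three inbred strains (one of them,
#' DBA, with low susceptibility to amyloid pathology), a 28-animal APP
#' transgenic cohort with per-animal amyloid-beta (ELISA-like, log-normal)
#' levels, and a case-control association panel with LD-blocked diploid
#' genotypes and age/sex covariates.
#'
#' @param seed Integer root seed; all randomness flows from it.
#' @param n_genes Number of genes simulated (one LD block / probe each by
#'   default).
#' @param n_causal Number of planted causal genes (`<= n_genes`).
#' @param strain_sizes Named integer vector of arrays per non-transgenic
#'   strain; the first name is conventionally the low-susceptibility strain.
#' @param target_strain Strain whose differential expression defines the
#'   screen (default `"DBA"`).
#' @param strain_shift Planted expression shift in the target strain for
#'   causal genes, in units of the residual noise SD. The default of 6
#'   gives the two-sample t screen at `p < 0.001` better than 90% power
#'   per planted gene with four arrays per strain.
#' @param noise_sd Residual (array) noise SD on the log-intensity scale.
#' @param n_tg_animals Number of transgenic animals (default 28).
#' @param abeta_corr_effects Signed target correlations between causal-gene
#'   expression and amyloid-beta in the transgenic cohort, recycled over
#'   the causal genes; magnitudes must be `< 1`.
#' @param abeta_meanlog,abeta_sdlog Log-normal parameters of the per-animal
#'   amyloid-beta level (arbitrary ELISA-like units).
#' @param n_individuals Individuals in the genotype panel.
#' @param n_snps Number of SNPs; the last LD block may be short.
#' @param block_size SNPs per LD block.
#' @param within_block_rho Latent-Gaussian AR-1 correlation within a block,
#'   in `[0, 1)`. Note the dosage-scale r^2 is attenuated relative to this
#'   latent value by the MAF thresholding.
#' @param maf_range Minor-allele-frequency interval, within `(0, 0.5]`.
#' @param causal_snp_or Per-allele odds ratio of each planted causal SNP.
#' @param case_fraction Target fraction of cases, in `(0, 1)`; the logistic
#'   intercept is calibrated by bisection so the realized fraction matches
#'   to within 0.02.
#' @param age_mean,age_sd Age distribution (years) of simulated subjects.
#' @param age_effect Log-odds of case status per year of age.
#' @param sex_effect Log-odds shift for male subjects.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, n_genes = 20, n_causal = 2)
#' cfg$n_tg_animals
sim_config <- function(seed = 1L,
                       n_genes = 200L,
                       n_causal = 3L,
                       strain_sizes = c(DBA = 4L, B6 = 4L, SJL = 4L),
                       target_strain = "DBA",
                       strain_shift = 6,
                       noise_sd = 1,
                       n_tg_animals = 28L,
                       abeta_corr_effects = c(-0.7, 0.7, -0.7),
                       abeta_meanlog = log(50),
                       abeta_sdlog = 0.5,
                       n_individuals = 2000L,
                       n_snps = 1000L,
                       block_size = 5L,
                       within_block_rho = 0.8,
                       maf_range = c(0.1, 0.5),
                       causal_snp_or = 1.5,
                       case_fraction = 0.5,
                       age_mean = 70,
                       age_sd = 8,
                       age_effect = 0.02,
                       sex_effect = 0.25) {
  counts <- c(
    n_genes = n_genes, n_causal = n_causal, n_tg_animals = n_tg_animals,
    n_individuals = n_individuals, n_snps = n_snps, block_size = block_size
  )
  if (any(counts < 1)) {
    abort(paste0(
      "all counts must be >= 1; offending: ",
      paste(names(counts)[counts < 1], collapse = ", ")
    ))
  }
  if (n_causal > n_genes) abort("`n_causal` must not exceed `n_genes`")
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an interval within (0, 0.5]")
  }
  if (within_block_rho < 0 || within_block_rho >= 1) {
    abort("`within_block_rho` must lie in [0, 1)")
  }
  if (case_fraction <= 0 || case_fraction >= 1) {
    abort("`case_fraction` must lie in (0, 1)")
  }
  if (any(abs(abeta_corr_effects) >= 1)) {
    abort("`abeta_corr_effects` are correlations and must have magnitude < 1")
  }
  if (is.null(names(strain_sizes)) || any(!nzchar(names(strain_sizes)))) {
    abort("`strain_sizes` must be a named vector of per-strain sample counts")
  }
  if (!target_strain %in% names(strain_sizes)) {
    abort("`target_strain` must be one of the strains in `strain_sizes`")
  }
  if (causal_snp_or <= 0) abort("`causal_snp_or` must be positive")

  structure(
    list(
      seed = as.integer(seed),
      n_genes = as.integer(n_genes),
      n_causal = as.integer(n_causal),
      strain_sizes = strain_sizes,
      target_strain = target_strain,
      strain_shift = strain_shift,
      noise_sd = noise_sd,
      n_tg_animals = as.integer(n_tg_animals),
      abeta_corr_effects = abeta_corr_effects,
      abeta_meanlog = abeta_meanlog,
      abeta_sdlog = abeta_sdlog,
      n_individuals = as.integer(n_individuals),
      n_snps = as.integer(n_snps),
      block_size = as.integer(block_size),
      within_block_rho = within_block_rho,
      maf_range = maf_range,
      causal_snp_or = causal_snp_or,
      case_fraction = case_fraction,
      age_mean = age_mean,
      age_sd = age_sd,
      age_effect = age_effect,
      sex_effect = sex_effect
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, "\n")
  cat("  genes:", x$n_genes, "(", x$n_causal, "causal )\n")
  cat(
    "  strains:",
    paste(names(x$strain_sizes), x$strain_sizes, sep = "=", collapse = ", "),
    "| target:", x$target_strain, "\n"
  )
  cat("  transgenic animals:", x$n_tg_animals, "\n")
  cat(
    "  panel:", x$n_individuals, "individuals x", x$n_snps, "SNPs,",
    "blocks of", x$block_size, "(latent rho", x$within_block_rho, ")\n"
  )
  cat(
    "  causal SNP OR:", x$causal_snp_or,
    "| case fraction:", x$case_fraction, "\n"
  )
  invisible(x)
}

# Fixed per-stage offsets: every generator reseeds from the root seed plus
# its own offset, so stages are independent of call order.
.substreams <- c(
  truth = 101L,
  strain_expression = 211L,
  tg_cohort = 307L,
  genotype_panel = 401L,
  case_control = 503L,
  ortholog = 601L
)

substream_seed <- function(seed, stream) {
  offset <- .substreams[[stream]]
  as.integer((as.double(seed) * 7919 + offset) %% .Machine$integer.max)
}

#' Gene, probe and SNP identifier helpers
#'
#' Symbol conventions follow the field: human symbols are upper-case,
#' mouse symbols are capitalized mixed case, probes carry an `_at` suffix.
#'
#' @param n Number of identifiers.
#' @return Character vector of identifiers.
#' @keywords internal
#' @name synthetic_ids
NULL

human_symbols <- function(n) sprintf("GENE%04d", seq_len(n))
mouse_symbols <- function(n) sprintf("Gene%04d", seq_len(n))
probe_ids <- function(n) sprintf("P%04d_at", seq_len(n))

#' Planted ground truth of a synthetic study
#'
#' Draws which genes are causal and fixes their direction of association
#' with amyloid-beta (negative target correlation = `"Down"`). Causal SNP
#' ids are filled in once a genotype panel and gene regions exist (see
#' [causal_snps_for()]).
#'
#' @param config A [sim_config()].
#' @return A list of class `ground_truth` with elements `genes` (tibble:
#'   `gene_symbol` (mouse), `human_symbol`, `direction`, `target_r`) and
#'   `snp_ids` (character).
#' @export
#' @examples
#' ground_truth(sim_config(seed = 1, n_genes = 10, n_causal = 2))$genes
ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "truth"))
  idx <- sort(sample.int(config$n_genes, config$n_causal))
  target_r <- rep_len(config$abeta_corr_effects, config$n_causal)
  genes <- tibble(
    gene_index = idx,
    gene_symbol = mouse_symbols(config$n_genes)[idx],
    human_symbol = human_symbols(config$n_genes)[idx],
    target_r = target_r,
    direction = ifelse(target_r > 0, "Up", "Down")
  )
  structure(list(genes = genes, snp_ids = character(0)),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>", nrow(x$genes), "causal genes,",
      length(x$snp_ids), "causal SNPs\n")
  print(x$genes)
  invisible(x)
}
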