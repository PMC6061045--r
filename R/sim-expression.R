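#' Simulate the non-transgenic strain expression set
#'
#' Emulates the twelve-array design of three inbred, non-transgenic mouse
#' strains used for the first (strain-differential) step of the screen.
#' Each probe's log-intensity is a gene baseline plus i.i.d. Gaussian
#' noise; planted (causal) genes additionally receive a shift of
#' `strain_shift` noise SDs in the target strain only, signed so that
#' amyloid-suppressing (`"Down"`) genes are higher in the low-susceptibility
#' strain. Non-planted genes have identical means in every strain.
#'
#' @param config A [sim_config()].
#' @param truth Optional [ground_truth()]; regenerated from `config` when
#'   missing.
#' @return A list with `expression` (long tibble: `probe_id`, `sample_id`,
#'   `strain`, `expression`), `probe_map` (tibble: `probe_id`,
#'   `gene_symbol`), and `truth`.
#' @export
#' @examples
#' sim <- simulate_strain_expression(sim_config(seed = 1, n_genes = 5))
#' head(sim$expression)
simulate_strain_expression <- function(config, truth = ground_truth(config)) {
  stopifnot(inherits(config, "sim_config"))
  sizes <- config$strain_sizes
  if (any(sizes < 2)) {
    abort("invalid design: every strain needs at least 2 samples")
  }
  strains <- rep(names(sizes), times = sizes)
  n_samp <- length(strains)
  sample_id <- paste0(strains, "_", unlist(lapply(sizes, seq_len)))

  set.seed(substream_seed(config$seed, "strain_expression"))
  n_genes <- config$n_genes
  baseline <- rnorm(n_genes, mean = 8, sd = 1)
  values <- baseline +
    matrix(rnorm(n_genes * n_samp, sd = config$noise_sd), n_genes, n_samp)

  # "Down" genes (suppressors of amyloid accumulation) are elevated in the
  # resistant target strain; "Up" genes are lowered there.
  in_target <- strains == config$target_strain
  shift <- config$strain_shift * config$noise_sd *
    ifelse(truth$genes$direction == "Down", 1, -1)
  values[truth$genes$gene_index, in_target] <-
    values[truth$genes$gene_index, in_target] + shift

  probes <- probe_ids(n_genes)
  expression <- tibble(
    probe_id = rep(probes, times = n_samp),
    sample_id = rep(sample_id, each = n_genes),
    strain = rep(strains, each = n_genes),
    expression = as.vector(values)
  )
  probe_map <- tibble(probe_id = probes, gene_symbol = mouse_symbols(n_genes))
  list(expression = expression, probe_map = probe_map, truth = truth)
}

#' Simulate the transgenic cohort with amyloid-beta levels
#'
#' Emulates the 28-array APP transgenic cohort: per-animal amyloid-beta is
#' drawn log-normal (ELISA-like, positive and right-skewed) and causal-gene
#' expression is `baseline + r * A + sqrt(1 - r^2) * noise`, where `A` is
#' amyloid-beta standardized by its analytic (population) log-normal
#' moments, so the population expression/amyloid correlation equals the
#' signed target in `truth$genes$target_r` exactly. Non-causal genes are
#' independent of amyloid-beta.
#'
#' @inheritParams simulate_strain_expression
#' @return A list with `expression` (long tibble: `probe_id`, `sample_id`,
#'   `expression`), `abeta` (tibble: `sample_id`, `abeta`), `probe_map`,
#'   and `truth`.
#' @export
#' @examples
#' tg <- simulate_tg_cohort(sim_config(seed = 1, n_genes = 5, n_causal = 1))
#' tg$abeta
simulate_tg_cohort <- function(config, truth = ground_truth(config)) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_tg_animals
  if (n < 4) abort("invalid design: need at least 4 transgenic animals")
  if (any(abs(truth$genes$target_r) >= 1)) {
    abort("target correlations must have magnitude < 1")
  }

  set.seed(substream_seed(config$seed, "tg_cohort"))
  sample_id <- sprintf("Tg_%02d", seq_len(n))
  abeta <- rlnorm(n, meanlog = config$abeta_meanlog, sdlog = config$abeta_sdlog)

  # standardize by the analytic log-normal moments, not the sample ones,
  # so the *population* correlation hits the target
  s2 <- config$abeta_sdlog^2
  pop_mean <- exp(config$abeta_meanlog + s2 / 2)
  pop_sd <- sqrt((exp(s2) - 1) * exp(2 * config$abeta_meanlog + s2))
  a_std <- (abeta - pop_mean) / pop_sd

  n_genes <- config$n_genes
  baseline <- rnorm(n_genes, mean = 8, sd = 1)
  noise <- matrix(rnorm(n_genes * n), n_genes, n)
  loading <- numeric(n_genes)
  loading[truth$genes$gene_index] <- truth$genes$target_r
  values <- baseline + config$noise_sd *
    (loading %o% a_std + sqrt(1 - loading^2) * noise)

  probes <- probe_ids(n_genes)
  expression <- tibble(
    probe_id = rep(probes, times = n),
    sample_id = rep(sample_id, each = n_genes),
    expression = as.vector(values)
  )
  list(
    expression = expression,
    abeta = tibble(sample_id = sample_id, abeta = abeta),
    probe_map = tibble(probe_id = probes, gene_symbol = mouse_symbols(n_genes)),
    truth = truth
  )
}

#' Build a human-mouse ortholog table
#'
#' Produces 1:1 symbol pairs in the format of curated ortholog reports,
#' optionally injecting many-to-many rows (a fraction of human symbols gets
#' a second mouse partner) to exercise join policies downstream. Rows that
#' belong to a non-1:1 family are flagged in `multi`.
#'
#' @param human_symbols,mouse_symbols Equal-length character vectors;
#'   duplicated human symbols are an error (they cannot be flagged as
#'   deliberate), duplicated mouse symbols are allowed and flagged.
#' @param scramble_fraction Fraction of rows duplicated with a second,
#'   randomly chosen mouse partner.
#' @param seed Seed for the scramble draw.
#' @return A tibble with `human_symbol`, `mouse_symbol`, `multi`.
#' @export
#' @examples
#' make_ortholog_table(c("LBH", "SHF"), c("Lbh", "Shf"))
make_ortholog_table <- function(human_symbols, mouse_symbols,
                                scramble_fraction = 0, seed = 1L) {
  if (length(human_symbols) != length(mouse_symbols)) {
    abort("`human_symbols` and `mouse_symbols` must have equal length")
  }
  if (anyDuplicated(human_symbols)) {
    abort("duplicate human symbol in input; inject families via `scramble_fraction`")
  }
  if (scramble_fraction < 0 || scramble_fraction > 1) {
    abort("`scramble_fraction` must lie in [0, 1]")
  }
  tbl <- tibble(
    human_symbol = as.character(human_symbols),
    mouse_symbol = as.character(mouse_symbols)
  )
  n_extra <- floor(scramble_fraction * nrow(tbl))
  if (n_extra > 0) {
    if (nrow(tbl) < 2) abort("need at least 2 pairs to scramble")
    set.seed(substream_seed(seed, "ortholog"))
    pick <- sample.int(nrow(tbl), n_extra)
    partner <- vapply(pick, function(i) {
      sample(setdiff(seq_len(nrow(tbl)), i), 1L)
    }, integer(1))
    tbl <- bind_rows(
      tbl,
      tibble(
        human_symbol = tbl$human_symbol[pick],
        mouse_symbol = tbl$mouse_symbol[partner]
      )
    )
  }
  tbl |>
    mutate(
      multi = duplicated(.data$human_symbol) |
        duplicated(.data$human_symbol, fromLast = TRUE) |
        duplicated(.data$mouse_symbol) |
        duplicated(.data$mouse_symbol, fromLast = TRUE)
    ) |>
    arrange(.data$human_symbol, .data$mouse_symbol)
}
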