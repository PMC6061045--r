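# Small deterministic fixtures shared across test files.

tiny_config <- function(seed = 1, ...) {
  sim_config(
    seed = seed, n_genes = 10, n_causal = 2, n_snps = 50,
    n_individuals = 400, ...
  )
}

# A genotype panel whose dosage columns replicate given vectors enough
# times to satisfy the 20-individual floor, preserving all correlations.
panel_from_dosages <- function(..., reps = 4) {
  cols <- list(...)
  dos <- do.call(cbind, cols)
  dos <- dos[rep(seq_len(nrow(dos)), reps), , drop = FALSE]
  m <- ncol(dos)
  snp_id <- sprintf("rs%06d", seq_len(m))
  ind <- sprintf("I%05d", seq_len(nrow(dos)))
  dimnames(dos) <- list(ind, snp_id)
  structure(
    list(
      dosages = dos,
      snp_map = tibble::tibble(
        snp_id = snp_id, chrom = "1", pos = 5000L * seq_len(m),
        ref = "A", alt = "G"
      ),
      individual_ids = ind
    ),
    class = "genotype_panel"
  )
}

# Long expression tibble from a plain matrix plus strain labels.
expr_from_matrix <- function(m, strain = NULL) {
  probes <- rownames(m) %||% sprintf("P%04d_at", seq_len(nrow(m)))
  samples <- colnames(m) %||% sprintf("S%02d", seq_len(ncol(m)))
  out <- tibble::tibble(
    probe_id = rep(probes, times = ncol(m)),
    sample_id = rep(samples, each = nrow(m)),
    expression = as.vector(m)
  )
  if (!is.null(strain)) out$strain <- rep(strain, each = nrow(m))
  out
}

`%||%` <- rlang::`%||%`
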