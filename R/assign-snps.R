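#' Assign SNPs to genes by position and LD proxy
#'
#' A SNP belongs to a gene if it lies within the gene's mapped region
#' extended by `flank` bp on both sides (default 3 kb), or — for SNPs
#' outside that region — if its maximum r^2 with any in-region SNP is
#' strictly greater than `r2_threshold` (default 0.8). Proxy candidates
#' are searched within `proxy_window` bp of the flanked region (default
#' 1 Mb, generous relative to typical LD range while bounding
#' computation). A SNP may be assigned to several genes.
#'
#' @param genes Tibble of gene regions: `gene_symbol`, `chrom`, `start`,
#'   `end` (1-based inclusive; see [read_gene_regions()] for the BED
#'   dialect).
#' @param snp_map Tibble with `snp_id`, `chrom`, `pos`, sorted by position
#'   within chromosome.
#' @param panel Optional `genotype_panel` providing dosages for proxy r^2;
#'   without it only positional assignment is performed. Missing dosages
#'   are mean-imputed for the proxy search; monomorphic SNPs count as
#'   r^2 = 0.
#' @param flank Flanking width in bp added to both gene ends.
#' @param r2_threshold Proxies require r^2 strictly greater than this.
#' @param proxy_window Maximum distance (bp) from the flanked region in
#'   which LD proxies are searched.
#' @return A tibble with `gene_symbol`, `snp_id`, `chrom`, `pos`, `source`
#'   (`"in_region"` or `"ld_proxy"`), ordered by gene and position. Genes
#'   with no assigned SNPs contribute no rows and are reported in a
#'   message.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_snps = 20, block_size = 5)
#' panel <- simulate_genotype_panel(cfg)
#' genes <- make_gene_regions(panel, 4)
#' assign_snps(genes, panel$snp_map, panel)
assign_snps <- function(genes, snp_map, panel = NULL, flank = 3000,
                        r2_threshold = 0.8, proxy_window = 1e6) {
  stopifnot(
    all(c("gene_symbol", "chrom", "start", "end") %in% names(genes)),
    all(c("snp_id", "chrom", "pos") %in% names(snp_map))
  )
  if (flank < 0) abort("`flank` must be non-negative")
  if (any(genes$start > genes$end)) abort("gene `start` must be <= `end`")

  # standardize dosages once so per-gene r^2 is a single crossprod;
  # zero-variance (monomorphic) columns get zero weight, i.e. r = 0
  zd <- NULL
  if (!is.null(panel)) {
    zd <- scale(panel$dosages)
    zd[, attr(zd, "scaled:scale") == 0] <- 0
    zd[is.na(zd)] <- 0
    zd <- zd / sqrt(nrow(zd) - 1)
    colnames(zd) <- colnames(panel$dosages)
  }

  one_gene <- function(g) {
    on_chrom <- snp_map[snp_map$chrom == g$chrom, ]
    lo <- g$start - flank
    hi <- g$end + flank
    in_region <- on_chrom[on_chrom$pos >= lo & on_chrom$pos <= hi, ]
    rows <- NULL
    if (nrow(in_region) > 0) {
      rows <- tibble(
        gene_symbol = g$gene_symbol,
        snp_id = in_region$snp_id,
        chrom = in_region$chrom,
        pos = in_region$pos,
        source = "in_region"
      )
      if (!is.null(panel)) {
        cand <- on_chrom[
          (on_chrom$pos < lo | on_chrom$pos > hi) &
            on_chrom$pos >= lo - proxy_window &
            on_chrom$pos <= hi + proxy_window,
        ]
        if (nrow(cand) > 0) {
          r <- crossprod(
            zd[, cand$snp_id, drop = FALSE],
            zd[, in_region$snp_id, drop = FALSE]
          )
          max_r2 <- apply(r^2, 1, max)
          max_r2[!is.finite(max_r2)] <- 0
          hits <- cand[max_r2 > r2_threshold, ]
          if (nrow(hits) > 0) {
            rows <- bind_rows(rows, tibble(
              gene_symbol = g$gene_symbol,
              snp_id = hits$snp_id,
              chrom = hits$chrom,
              pos = hits$pos,
              source = "ld_proxy"
            ))
          }
        }
      }
    }
    rows
  }

  out <- bind_rows(lapply(seq_len(nrow(genes)), function(i) one_gene(genes[i, ])))
  if (nrow(out) == 0) {
    out <- tibble(
      gene_symbol = character(0), snp_id = character(0),
      chrom = character(0), pos = integer(0), source = character(0)
    )
  }
  empty <- setdiff(genes$gene_symbol, out$gene_symbol)
  if (length(empty) > 0) {
    inform(paste0(
      length(empty), " gene(s) with no assigned SNPs: ",
      paste(head(empty, 5), collapse = ", ")
    ))
  }
  arrange(out, .data$gene_symbol, .data$pos)
}
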