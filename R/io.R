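#' Read and write the pipeline's tab-separated interchange files
#'
#' Thin readr wrappers fixing the column contracts used throughout the
#' package: expression matrices travel as probe-by-sample TSV, phenotypes
#' as one row per individual, orthologs as two symbol columns (plus the
#' `multi` family flag when present), and genotype dosages as a SNP map
#' followed by one column per individual.
#'
#' @param path File path.
#' @name abprio_io
NULL

#' @rdname abprio_io
#' @param expr Long expression tibble (`probe_id`, `sample_id`,
#'   `expression`).
#' @export
write_expression_tsv <- function(expr, path) {
  wide <- tidyr::pivot_wider(expr[c("probe_id", "sample_id", "expression")],
    names_from = "sample_id", values_from = "expression"
  )
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname abprio_io
#' @export
read_expression_tsv <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  tidyr::pivot_longer(wide, -"probe_id",
    names_to = "sample_id", values_to = "expression"
  )
}

#' @rdname abprio_io
#' @param abeta Tibble with `sample_id`, `abeta`.
#' @export
write_abeta_tsv <- function(abeta, path) {
  readr::write_tsv(abeta[c("sample_id", "abeta")], path)
  invisible(path)
}

#' @rdname abprio_io
#' @export
read_abeta_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
    col_types = readr::cols(sample_id = "c", abeta = "d"))
}

#' @rdname abprio_io
#' @param pheno Tibble with `individual_id`, `status`, `age`, `sex`.
#' @export
write_phenotype_tsv <- function(pheno, path) {
  readr::write_tsv(pheno[c("individual_id", "status", "age", "sex")], path)
  invisible(path)
}

#' @rdname abprio_io
#' @export
read_phenotype_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, col_types = readr::cols(
    individual_id = "c", status = "i", age = "d", sex = "c"
  ))
}

#' @rdname abprio_io
#' @param orthologs Tibble with `human_symbol`, `mouse_symbol` (and
#'   optionally `multi`).
#' @export
write_ortholog_tsv <- function(orthologs, path) {
  readr::write_tsv(orthologs, path)
  invisible(path)
}

#' @rdname abprio_io
#' @export
read_ortholog_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("human_symbol", "mouse_symbol") %in% names(tbl)))
  if (!"multi" %in% names(tbl)) tbl$multi <- FALSE
  if (any(duplicated(tbl$human_symbol) & !tbl$multi)) {
    abort("duplicate human symbol without `multi` flag in ortholog table")
  }
  tbl
}

#' @rdname abprio_io
#' @param panel A `genotype_panel`.
#' @export
write_dosage_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  out <- bind_cols(
    panel$snp_map[c("snp_id", "chrom", "pos", "ref", "alt")],
    as_tibble(t(panel$dosages))
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname abprio_io
#' @export
read_dosage_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  meta_cols <- c("snp_id", "chrom", "pos", "ref", "alt")
  stopifnot(all(meta_cols %in% names(tbl)))
  dos <- t(as.matrix(tbl[setdiff(names(tbl), meta_cols)]))
  colnames(dos) <- tbl$snp_id
  storage.mode(dos) <- "integer"
  structure(
    list(
      dosages = dos,
      snp_map = as_tibble(tbl[meta_cols]),
      individual_ids = rownames(dos)
    ),
    class = "genotype_panel"
  )
}

#' @rdname abprio_io
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  gt <- c("0/0", "0/1", "1/1")[panel$dosages + 1L]
  gt <- matrix(gt, nrow(panel$dosages), ncol(panel$dosages))
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(panel$snp_map$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", panel$individual_ids), collapse = "\t")
  )
  body <- paste(
    panel$snp_map$chrom, panel$snp_map$pos, panel$snp_map$snp_id,
    panel$snp_map$ref, panel$snp_map$alt, ".", "PASS", ".", "GT",
    apply(gt, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' @rdname abprio_io
#' @export
read_panel_vcf <- function(path) {
  check_installed("vcfR", reason = "to read VCF genotype panels")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- t(matrix(
    vapply(strsplit(gt, "[/|]"), function(a) sum(as.integer(a)), integer(1)),
    nrow(gt), ncol(gt), dimnames = dimnames(gt)
  ))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  structure(
    list(
      dosages = dos,
      snp_map = tibble(
        snp_id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
        ref = fix$REF, alt = fix$ALT
      ),
      individual_ids = rownames(dos)
    ),
    class = "genotype_panel"
  )
}

#' @rdname abprio_io
#' @param truth A `ground_truth`.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(genes = truth$genes, snp_ids = truth$snp_ids),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname abprio_io
#' @export
read_ground_truth_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(genes = as_tibble(raw$genes),
      snp_ids = as.character(raw$snp_ids %||% character(0))),
    class = "ground_truth"
  )
}

#' Gene region annotation reader
#'
#' Reads gene regions either as 1-based inclusive TSV (`gene_symbol`,
#' `chrom`, `start`, `end`) or as 4-column BED (`chrom`, `start`, `end`,
#' `name`; 0-based half-open, converted to 1-based inclusive).
#'
#' @param path File path.
#' @param coords `"one_based"` (TSV dialect) or `"bed"`.
#' @return A tibble with `gene_symbol`, `chrom`, `start`, `end`.
#' @export
read_gene_regions <- function(path, coords = c("one_based", "bed")) {
  coords <- match.arg(coords)
  if (coords == "bed") {
    tbl <- readr::read_tsv(path,
      col_names = c("chrom", "start", "end", "gene_symbol"),
      show_col_types = FALSE
    )
    tbl |>
      mutate(chrom = as.character(.data$chrom), start = .data$start + 1L) |>
      select("gene_symbol", "chrom", "start", "end")
  } else {
    tbl <- readr::read_tsv(path, show_col_types = FALSE)
    stopifnot(all(c("gene_symbol", "chrom", "start", "end") %in% names(tbl)))
    mutate(tbl, chrom = as.character(.data$chrom))
  }
}

#' Example candidate-gene statistics
#'
#' Five amyloid-beta candidate genes (LBH, ST6GALNAC4, ARSJ, C5orf51,
#' SHF) with their mouse hippocampal expression/amyloid correlation over
#' 28 transgenic animals and their human gene-based GWAS p-values, as
#' used in the package's worked example of the combination step.
#'
#' @return A tibble with `mouse_gene`, `r`, `direction`, `p_mouse`,
#'   `human_gene`, `p_human`, `n_animals`.
#' @export
#' @examples
#' candidate_gene_stats()
candidate_gene_stats <- function() {
  readr::read_tsv(
    system.file("extdata", "candidate_genes.tsv", package = "abprio"),
    show_col_types = FALSE
  )
}
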