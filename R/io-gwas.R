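# GWAS association table IO

#' Read a GWAS association table
#'
#' Tab-separated with columns `snp`, `genes` (comma-separated mapped genes),
#' `disease`, `p_value`, `genic_flag`. SNPs mapping to multiple genes are
#' expanded to one record per mapped gene, mirroring catalogue exports where
#' all mapped genes of a locus are used.
#'
#' @param path TSV file path.
#' @return Tibble with columns `snp`, `gene`, `disease`, `p_value`, `genic`
#'   (logical), one row per SNP-gene pair.
#' @export
read_gwas_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("snp", "genes", "disease", "p_value", "genic_flag")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    abort(paste0("GWAS table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  p <- suppressWarnings(as.numeric(raw$p_value))
  bad <- which(is.na(p))
  if (length(bad)) {
    abort(sprintf("non-numeric p_value at row %d", bad[1]))
  }
  out_of_range <- which(p <= 0 | p > 1)
  if (length(out_of_range)) {
    abort(sprintf("p_value outside (0, 1] at row %d", out_of_range[1]))
  }
  genic <- raw$genic_flag %in% c("TRUE", "True", "true", "1", "genic")

  tibble(snp = raw$snp, genes = raw$genes, disease = raw$disease,
         p_value = p, genic = genic) |>
    mutate(genes = strsplit(.data$genes, ",", fixed = TRUE)) |>
    tidyr::unnest_longer("genes") |>
    mutate(gene = norm_symbols(.data$genes), .keep = "unused") |>
    filter(nzchar(.data$gene)) |>
    select("snp", "gene", "disease", "p_value", "genic")
}

#' Write a GWAS association table
#'
#' Collapses one-row-per-gene records back to comma-separated `genes` per SNP
#' record; inverse of [read_gwas_table()] up to row order.
#'
#' @param gwas Tibble as returned by [read_gwas_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gwas_table <- function(gwas, path) {
  gwas |>
    group_by(.data$snp, .data$disease, .data$p_value, .data$genic) |>
    summarise(genes = paste(.data$gene, collapse = ","), .groups = "drop") |>
    mutate(genic_flag = .data$genic) |>
    select("snp", "genes", "disease", "p_value", "genic_flag") |>
    readr::write_tsv(path)
  invisible(path)
}
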