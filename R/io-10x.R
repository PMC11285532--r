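# 10x-convention MatrixMarket triplet IO

#' Read a 10x-style MatrixMarket directory
#'
#' Expects `matrix.mtx` (genes x cells, integer), `features.tsv` (one gene
#' symbol per line, first column), `barcodes.tsv` (one barcode per line) and
#' optionally `cell_meta.tsv` (tab-separated, keyed by `barcode`). Duplicate
#' gene symbols are disambiguated deterministically in file order with
#' suffixes `.1`, `.2`, ...
#'
#' @param dir_path Directory containing the triplet.
#' @return An [count_matrix()] object.
#' @export
read_10x <- function(dir_path) {
  need <- c("matrix.mtx", "features.tsv", "barcodes.tsv")
  paths <- file.path(dir_path, need)
  missing <- need[!file.exists(paths)]
  if (length(missing)) {
    abort(paste0("missing input file(s): ",
                 paste(file.path(dir_path, missing), collapse = ", ")))
  }

  mat <- Matrix::readMM(paths[1])
  if (any(mat@x != round(mat@x))) {
    abort(paste0("non-integer values in ", paths[1]))
  }
  feats <- readr::read_tsv(paths[2], col_names = FALSE, col_types = readr::cols(),
                           progress = FALSE)
  barcodes <- readr::read_lines(paths[3])
  if (length(barcodes) == 0) abort("zero cells: empty barcode file")
  if (nrow(feats) == 0) abort("zero genes: empty features file")
  if (nrow(mat) != nrow(feats)) {
    abort(sprintf("dimension mismatch: matrix.mtx declares %d rows but %s has %d lines",
                  nrow(mat), paths[2], nrow(feats)))
  }
  if (ncol(mat) != length(barcodes)) {
    abort(sprintf("dimension mismatch: matrix.mtx declares %d columns but %s has %d lines",
                  ncol(mat), paths[3], length(barcodes)))
  }

  genes <- disambiguate_symbols(norm_symbols(feats[[1]]))
  mito <- if (ncol(feats) >= 3 && is.logical(feats[[3]])) feats[[3]] else NULL
  dimnames(mat) <- list(genes, barcodes)

  meta_path <- file.path(dir_path, "cell_meta.tsv")
  cell_meta <- if (file.exists(meta_path)) {
    readr::read_tsv(meta_path, col_types = readr::cols(), progress = FALSE)
  } else NULL

  gene_meta <- tibble(gene = genes)
  if (!is.null(mito)) gene_meta$mito <- mito
  count_matrix(mat, cell_meta = cell_meta, gene_meta = gene_meta)
}

#' Write a count matrix as a 10x-style triplet
#'
#' Inverse of [read_10x()]: writes `matrix.mtx`, `features.tsv`,
#' `barcodes.tsv` and `cell_meta.tsv` into `dir_path`.
#'
#' @param cm An `rv_counts` object.
#' @param dir_path Output directory (created if needed).
#' @return `dir_path`, invisibly.
#' @export
write_10x <- function(cm, dir_path) {
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(cm$counts, file.path(dir_path, "matrix.mtx"))
  readr::write_tsv(tibble(gene = cm$gene_meta$gene,
                          name = cm$gene_meta$gene,
                          mito = cm$gene_meta$mito),
                   file.path(dir_path, "features.tsv"), col_names = FALSE)
  readr::write_lines(colnames(cm$counts), file.path(dir_path, "barcodes.tsv"))
  meta <- cm$cell_meta[, c("barcode", "subject", "region", "major_type",
                           "subtype", "doublet")]
  readr::write_tsv(meta, file.path(dir_path, "cell_meta.tsv"))
  invisible(dir_path)
}
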