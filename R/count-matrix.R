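#' UMI count matrix with cell and gene metadata
#'
#' A light container around a sparse genes x cells UMI matrix
#' (`Matrix::dgCMatrix`) plus a per-cell metadata tibble and a per-gene
#' metadata tibble. The per-cell QC fields (`total_umi`, `n_genes_detected`,
#' `mito_fraction`) are always recomputed from the matrix so they cannot drift
#' out of sync with the counts.
#'
#' @param counts Non-negative integer matrix or sparse Matrix, genes in rows,
#'   cells in columns, with unique rownames (gene symbols) and colnames
#'   (barcodes).
#' @param cell_meta Optional tibble with one row per cell; must contain a
#'   `barcode` column. Missing annotation fields (`subject`, `region`,
#'   `major_type`, `subtype`, `doublet`) are filled with the `"unknown"`
#'   sentinel (`FALSE` for `doublet`).
#' @param gene_meta Optional tibble with one row per gene (`gene` column);
#'   a logical `mito` flag defaults to `grepl("^MT-", gene)`.
#' @return An object of class `rv_counts`: a list with elements `counts`,
#'   `cell_meta`, `gene_meta`.
#' @export
count_matrix <- function(counts, cell_meta = NULL, gene_meta = NULL) {
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have rownames (genes) and colnames (barcodes).")
  }
  if (ncol(counts) == 0) abort("zero cells")
  if (nrow(counts) == 0) abort("zero genes")
  if (any(counts@x < 0)) abort("counts must be non-negative")
  if (any(counts@x != round(counts@x))) abort("counts must be integers")
  if (anyDuplicated(colnames(counts))) abort("duplicate cell barcodes")
  if (anyDuplicated(rownames(counts))) abort("duplicate gene symbols")

  genes <- rownames(counts)
  barcodes <- colnames(counts)

  if (is.null(gene_meta)) gene_meta <- tibble(gene = genes)
  gene_meta <- as_tibble(gene_meta)
  if (!"gene" %in% names(gene_meta)) abort("`gene_meta` needs a `gene` column")
  gene_meta <- left_join(tibble(gene = genes), gene_meta, by = "gene")
  if (!"mito" %in% names(gene_meta)) {
    gene_meta$mito <- grepl("^MT-", gene_meta$gene)
  }
  gene_meta$mito[is.na(gene_meta$mito)] <- FALSE

  if (is.null(cell_meta)) cell_meta <- tibble(barcode = barcodes)
  cell_meta <- as_tibble(cell_meta)
  if (!"barcode" %in% names(cell_meta)) {
    abort("`cell_meta` needs a `barcode` column")
  }
  cell_meta <- left_join(tibble(barcode = barcodes), cell_meta, by = "barcode")
  for (col in c("subject", "region", "major_type", "subtype")) {
    if (!col %in% names(cell_meta)) cell_meta[[col]] <- "unknown"
    cell_meta[[col]][is.na(cell_meta[[col]])] <- "unknown"
  }
  if (!"doublet" %in% names(cell_meta)) cell_meta$doublet <- FALSE
  cell_meta$doublet[is.na(cell_meta$doublet)] <- FALSE
  cell_meta$doublet <- as.logical(cell_meta$doublet)

  # QC fields derived from the matrix itself
  cell_meta$total_umi <- unname(Matrix::colSums(counts))
  cell_meta$n_genes_detected <- unname(Matrix::colSums(counts > 0))
  mito_tot <- unname(Matrix::colSums(counts[gene_meta$mito, , drop = FALSE]))
  cell_meta$mito_fraction <- ifelse(cell_meta$total_umi > 0,
                                    mito_tot / cell_meta$total_umi, 0)

  structure(list(counts = counts, cell_meta = cell_meta,
                 gene_meta = gene_meta),
            class = "rv_counts")
}

#' @export
print.rv_counts <- function(x, ...) {
  cat(sprintf("<rv_counts> %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  reg <- table(x$cell_meta$region)
  cat("regions:", paste(names(reg), reg, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.rv_counts <- function(x) dim(x$counts)

# subset cells (by barcode or logical/integer index), keeping metadata aligned
subset_cells <- function(cm, idx) {
  if (is.character(idx)) idx <- match(idx, colnames(cm$counts))
  count_matrix(cm$counts[, idx, drop = FALSE],
               cell_meta = cm$cell_meta[idx, , drop = FALSE],
               gene_meta = cm$gene_meta)
}

#' Summarise a count matrix
#'
#' @param x An `rv_counts` object.
#' @param ... Unused.
#' @return One-row tibble with cell/gene counts and median QC metrics.
#' @export
glance.rv_counts <- function(x, ...) {
  tibble(n_genes = nrow(x$counts),
         n_cells = ncol(x$counts),
         median_umi = median(x$cell_meta$total_umi),
         median_genes_detected = median(x$cell_meta$n_genes_detected),
         median_mito_fraction = median(x$cell_meta$mito_fraction))
}
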