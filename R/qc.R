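# quality control and normalization

#' Filter cells by UMI depth, mitochondrial content, gene-count percentile
#' and doublet flag
#'
#' Rules are applied in a fixed order and each cell is charged to the first
#' rule it fails, so the per-rule counts in the report are well defined:
#' (1) total UMI outside `[min_umi, max_umi]` (bounds inclusive);
#' (2) mitochondrial fraction above `mito_max`;
#' (3) number of detected genes outside the `[gene_pctile]` percentile band of
#' the distribution among cells surviving rules 1-2 (linear-interpolation
#' percentiles); (4) doublet flag.
#'
#' @param cm An [count_matrix()] object.
#' @param min_umi,max_umi Inclusive UMI-depth bounds (defaults 300 and 4000).
#' @param mito_max Maximum tolerated mitochondrial fraction (default 0.10).
#' @param gene_pctile Length-2 percentile band for the detected-gene filter
#'   (default `c(5, 95)`).
#' @param gene_bounds Optional absolute detected-gene bounds; when supplied
#'   they replace the percentile computation (the realized bounds are echoed
#'   in every report, so a filter can be re-applied verbatim: percentiles of
#'   an already-truncated distribution would otherwise move inward).
#' @param drop_doublets Drop cells flagged as doublets (default TRUE).
#' @return List with `counts` (the filtered `rv_counts`) and `report`
#'   (an `rv_qc_report`, see [glance.rv_qc_report()]).
#' @export
filter_cells <- function(cm, min_umi = 300, max_umi = 4000, mito_max = 0.10,
                         gene_pctile = c(5, 95), gene_bounds = NULL,
                         drop_doublets = TRUE) {
  meta <- cm$cell_meta
  n_in <- nrow(meta)

  fail_umi <- meta$total_umi < min_umi | meta$total_umi > max_umi
  fail_mito <- !fail_umi & meta$mito_fraction > mito_max

  surviving <- !fail_umi & !fail_mito
  if (!any(surviving)) abort("empty matrix after QC")
  bounds <- gene_bounds %||%
    pctile_bounds(meta$n_genes_detected[surviving], gene_pctile)
  fail_gene <- surviving &
    (meta$n_genes_detected < bounds[1] | meta$n_genes_detected > bounds[2])

  fail_doublet <- surviving & !fail_gene &
    (if (drop_doublets) meta$doublet else FALSE)

  keep <- !(fail_umi | fail_mito | fail_gene | fail_doublet)
  if (!any(keep)) abort("empty matrix after QC")

  report <- structure(list(
    n_cells_in = n_in,
    n_removed_umi = sum(fail_umi),
    n_removed_mito = sum(fail_mito),
    n_removed_gene_pctile = sum(fail_gene),
    n_removed_doublet = sum(fail_doublet),
    n_cells_out = sum(keep),
    thresholds = list(min_umi = min_umi, max_umi = max_umi,
                      mito_max = mito_max, gene_pctile = gene_pctile,
                      gene_count_bounds = bounds)
  ), class = "rv_qc_report")

  list(counts = subset_cells(cm, which(keep)), report = report)
}

#' @export
print.rv_qc_report <- function(x, ...) {
  cat(sprintf(
    "<rv_qc_report> %d cells in -> %d out (umi %d, mito %d, gene-pctile %d, doublet %d removed)\n",
    x$n_cells_in, x$n_cells_out, x$n_removed_umi, x$n_removed_mito,
    x$n_removed_gene_pctile, x$n_removed_doublet))
  invisible(x)
}

#' One-row summary of a QC report
#'
#' @param x An `rv_qc_report`.
#' @param ... Unused.
#' @return One-row tibble of input/removed/output cell counts.
#' @export
glance.rv_qc_report <- function(x, ...) {
  tibble(n_cells_in = x$n_cells_in,
         n_removed_umi = x$n_removed_umi,
         n_removed_mito = x$n_removed_mito,
         n_removed_gene_pctile = x$n_removed_gene_pctile,
         n_removed_doublet = x$n_removed_doublet,
         n_cells_out = x$n_cells_out)
}

#' Library-size log-normalization
#'
#' `value = ln(1 + count * scale / cell_total)`, the standard single-cell
#' normalization with a fixed scale factor (default 10 000). Zeros stay zero
#' and the sparse structure is preserved.
#'
#' @param cm An `rv_counts` object (after QC).
#' @param scale Scale factor (default `1e4`).
#' @return Sparse `dgCMatrix` of normalized values, same dimnames as the
#'   counts.
#' @export
lognormalize <- function(cm, scale = 1e4) {
  counts <- if (inherits(cm, "rv_counts")) cm$counts else cm
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) abort("cannot normalize: cell with zero total count")
  norm <- counts
  # dgCMatrix: x runs column-wise; expand per-column totals over entries
  percol <- rep.int(totals, diff(norm@p))
  norm@x <- log1p(norm@x * scale / percol)
  norm
}

#' Expression-aware background gene set
#'
#' A gene is "expressed" in a scope (all cells, or one cell type/subtype) if
#' the number of cells detecting it lies inside the `[pctile]` percentile band
#' of the detection-count distribution over genes detected at least once in
#' that scope.
#'
#' @param cm An `rv_counts` object.
#' @param scope `"global"`, or a value of `major_type` or `subtype` selecting
#'   the cells to consider.
#' @param pctile Length-2 percentile band (default `c(10, 90)`).
#' @param mode `"gene_detection"` (default) applies the band to the per-gene
#'   detection-count distribution. `"cell_percentile"` is the alternative
#'   reading in which cells whose detected-gene count or UMI total falls
#'   outside the band are first discarded, and a gene is expressed if detected
#'   in at least one remaining cell.
#' @return List of class `rv_background` with `scope`, `genes` (character),
#'   `pctile`, `bounds`.
#' @export
expressed_background <- function(cm, scope = "global", pctile = c(10, 90),
                                 mode = c("gene_detection", "cell_percentile")) {
  mode <- match.arg(mode)
  if (identical(scope, "global")) {
    idx <- seq_len(ncol(cm$counts))
  } else {
    idx <- which(cm$cell_meta$major_type == scope |
                   cm$cell_meta$subtype == scope)
  }
  if (length(idx) == 0) abort(paste0("no cells in scope ", scope))
  if (mode == "cell_percentile") {
    meta <- cm$cell_meta[idx, ]
    gb <- pctile_bounds(meta$n_genes_detected, pctile)
    ub <- pctile_bounds(meta$total_umi, pctile)
    ok <- meta$n_genes_detected >= gb[1] & meta$n_genes_detected <= gb[2] &
      meta$total_umi >= ub[1] & meta$total_umi <= ub[2]
    if (!any(ok)) abort("no cells inside the percentile bands")
    det <- Matrix::rowSums(cm$counts[, idx[ok], drop = FALSE] > 0)
    return(structure(list(scope = scope,
                          genes = rownames(cm$counts)[det > 0],
                          pctile = pctile, bounds = c(NA_real_, NA_real_)),
                     class = "rv_background"))
  }
  det <- Matrix::rowSums(cm$counts[, idx, drop = FALSE] > 0)
  nz <- det[det > 0]
  if (length(nz) == 0) abort(paste0("no expressed genes in scope ", scope))
  bounds <- pctile_bounds(nz, pctile)
  keep <- det >= bounds[1] & det <= bounds[2] & det > 0
  structure(list(scope = scope,
                 genes = rownames(cm$counts)[keep],
                 pctile = pctile, bounds = bounds),
            class = "rv_background")
}

#' @export
print.rv_background <- function(x, ...) {
  cat(sprintf("<rv_background> scope=%s, %d genes, detection in [%.1f, %.1f]\n",
              x$scope, length(x$genes), x$bounds[1], x$bounds[2]))
  invisible(x)
}
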