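# one-vs-rest marker detection, region-balanced NB differential expression
# and hierarchical clustering of the regional log-FC matrix

# average log2 fold change on the de-logged normalized scale with
# pseudocount 1 (single-cell convention)
avg_log2fc <- function(norm, in_idx, out_idx) {
  m1 <- Matrix::rowSums(norm[, in_idx, drop = FALSE]) / length(in_idx)
  m2 <- Matrix::rowSums(norm[, out_idx, drop = FALSE]) / length(out_idx)
  # means of expm1(x): rowSums of expm1 on sparse entries
  e1 <- Matrix::rowSums(expm1_sparse(norm[, in_idx, drop = FALSE])) /
    length(in_idx)
  e2 <- Matrix::rowSums(expm1_sparse(norm[, out_idx, drop = FALSE])) /
    length(out_idx)
  list(lfc = log2(e1 + 1) - log2(e2 + 1), mean_in = m1, mean_out = m2)
}

expm1_sparse <- function(m) {
  m@x <- expm1(m@x)
  m
}

#' One-vs-rest marker detection by logistic regression
#'
#' For each label group, genes passing the detection and fold-change
#' pre-filters are tested by logistic regression of group membership on
#' normalized expression; the p-value is a likelihood-ratio test against the
#' intercept-only model, BH-adjusted within group. Only positive markers
#' (higher in the group) are returned.
#'
#' @param norm Normalized sparse matrix from [lognormalize()].
#' @param labels Character vector of group labels, one per cell.
#' @param min_pct Minimum detection fraction in either group (default 0.1).
#' @param logfc_min Minimum average log2 fold change in-group (default 0.25).
#' @return Tibble with `cell_type`, `gene`, `log2fc`, `p_value`, `adj_p`,
#'   `pct_in`, `pct_out`, `mean_norm`.
#' @export
find_markers <- function(norm, labels, min_pct = 0.1, logfc_min = 0.25) {
  stopifnot(length(labels) == ncol(norm))
  groups <- sort(unique(labels))
  if (length(groups) < 2) abort("need at least 2 label groups")
  small <- names(which(table(labels) < 3))
  if (length(small)) abort(paste0("group with < 3 cells: ", small[1]))

  out <- lapply(groups, function(g) {
    in_idx <- which(labels == g)
    out_idx <- which(labels != g)
    pct_in <- Matrix::rowSums(norm[, in_idx, drop = FALSE] > 0) /
      length(in_idx)
    pct_out <- Matrix::rowSums(norm[, out_idx, drop = FALSE] > 0) /
      length(out_idx)
    st <- avg_log2fc(norm, in_idx, out_idx)
    keep <- which((pct_in >= min_pct | pct_out >= min_pct) &
                    st$lfc >= logfc_min)
    if (!length(keep)) return(NULL)
    y <- as.numeric(seq_len(ncol(norm)) %in% in_idx)
    normT <- Matrix::t(norm[keep, , drop = FALSE])  # cells x tested genes
    pvals <- vapply(seq_along(keep), function(j) {
      x <- as.numeric(normT[, j])
      fit <- suppressWarnings(
        glm.fit(cbind(1, x), y, family = binomial()))
      stat <- fit$null.deviance - fit$deviance
      pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
    }, 1)
    tibble(cell_type = g, gene = rownames(norm)[keep],
           log2fc = st$lfc[keep],
           p_value = pmax(pvals, .Machine$double.xmin),
           adj_p = p.adjust(pmax(pvals, .Machine$double.xmin), "BH"),
           pct_in = pct_in[keep], pct_out = pct_out[keep],
           mean_norm = st$mean_in[keep])
  })
  bind_rows(out) |> arrange(.data$cell_type, .data$p_value)
}

#' Rank all genes by one-vs-rest average log2 fold change
#'
#' The preranked-GSEA input: every gene scored by its average log2 fold
#' change between the cells of one type and all other cells (no significance
#' filter), ranked descending downstream.
#'
#' @param norm Normalized matrix from [lognormalize()].
#' @param labels Group label per cell.
#' @param type The group to contrast against the rest.
#' @return Named numeric vector of average log2FC per gene.
#' @export
rank_genes_vs_rest <- function(norm, labels, type) {
  in_idx <- which(labels == type)
  out_idx <- which(labels != type)
  if (!length(in_idx) || !length(out_idx)) {
    abort(paste0("type ", type, " must split the cells into two groups"))
  }
  st <- avg_log2fc(norm, in_idx, out_idx)
  setNames(st$lfc, rownames(norm))
}

#' Corroborate data-driven markers against reference marker sets
#'
#' Hypergeometric upper-tail test of the overlap between each detected marker
#' set and each reference set, within an expressed background; BH-adjusted
#' across all pairs.
#'
#' @param markers Tibble from [find_markers()] (uses significant rows,
#'   `adj_p < alpha`).
#' @param reference_sets An `rv_genesets` with category `marker_reference`.
#' @param background Character vector of background genes (non-empty).
#' @param alpha Marker significance cut (default 0.05).
#' @return Enrichment tibble (see [enrich_table()]).
#' @export
marker_overlap_check <- function(markers, reference_sets, background,
                                 alpha = 0.05) {
  if (length(background) == 0) abort("empty background")
  sig <- markers |> filter(.data$adj_p < alpha)
  query <- split(sig$gene, sig$cell_type)
  enrich_table(query, reference_sets$sets, background)
}

#' Region-balanced downsampling within one cell type
#'
#' Uniform random subset without replacement so that both regions contribute
#' the same number of cells (the minimum of the two) for the given type.
#'
#' @param cm An `rv_counts` object.
#' @param celltype A `major_type` or `subtype` value.
#' @param seed Integer seed.
#' @return An `rv_counts` restricted to the balanced cells.
#' @export
downsample_balanced <- function(cm, celltype, seed = 1) {
  idx <- which(cm$cell_meta$major_type == celltype |
                 cm$cell_meta$subtype == celltype)
  regions <- cm$cell_meta$region[idx]
  tab <- table(regions)
  if (length(tab) < 2) {
    abort(paste0("both regions must be present for type ", celltype))
  }
  n_min <- min(tab)
  if (n_min < 3) abort(paste0("fewer than 3 cells in one region for type ",
                              celltype))
  set.seed(seed)
  keep <- unlist(lapply(names(tab), function(r) {
    pool <- idx[regions == r]
    if (length(pool) == n_min) pool else sort(sample(pool, n_min))
  }))
  subset_cells(cm, sort(keep))
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors for varying sequencing depth,
#' scaled to geometric mean 1.
#'
#' @param counts Integer matrix or sparse Matrix, genes x cells (>= 2
#'   columns, no zero-total column).
#' @return Numeric vector of per-cell factors.
#' @export
tmm_factors <- function(counts) {
  if (ncol(counts) < 2) abort("need at least 2 columns")
  if (any(Matrix::colSums(counts) == 0)) abort("zero-total column")
  f <- edgeR::calcNormFactors(as.matrix(counts), method = "TMM")
  unname(f)
}

#' Estimate common and tagwise NB dispersions
#'
#' Common dispersion by maximizing the pooled adjusted profile likelihood and
#' tagwise dispersions by empirical-Bayes shrinkage toward the common value
#' with a fixed prior degrees of freedom.
#'
#' @param counts Genes x cells counts.
#' @param group Two-level factor/character of group membership (>= 2 cells
#'   per group).
#' @param factors Optional TMM factors (computed if `NULL`).
#' @param prior_df Prior degrees of freedom for the shrinkage (default 10).
#' @return Object of class `rv_dispersion` with `common`, `tagwise`,
#'   `prior_df`, `genes`.
#' @export
fit_dispersion <- function(counts, group, factors = NULL, prior_df = 10) {
  group <- as.factor(group)
  if (any(table(group) < 2)) abort("need >= 2 cells per group")
  y <- edgeR::DGEList(as.matrix(counts), group = group)
  y$samples$norm.factors <- factors %||% tmm_factors(counts)
  design <- stats::model.matrix(~group)
  # min.row.sum = 0 keeps the gene set intact: the no-trend shrinkage path
  # otherwise drops low-count genes from the likelihood but not the prior
  y <- edgeR::estimateDisp(y, design, prior.df = prior_df,
                           trend.method = "none", min.row.sum = 0)
  structure(list(common = y$common.dispersion,
                 tagwise = y$tagwise.dispersion,
                 prior_df = prior_df,
                 genes = rownames(counts)),
            class = "rv_dispersion")
}

#' @export
print.rv_dispersion <- function(x, ...) {
  cat(sprintf("<rv_dispersion> common = %.4f, tagwise in [%.4f, %.4f], prior df = %s\n",
              x$common, min(x$tagwise), max(x$tagwise), format(x$prior_df)))
  invisible(x)
}

#' Tidy per-gene dispersions
#'
#' @param x An `rv_dispersion`.
#' @param ... Unused.
#' @return Tibble `gene`, `tagwise`, `common`.
#' @export
tidy.rv_dispersion <- function(x, ...) {
  tibble(gene = x$genes, tagwise = x$tagwise, common = x$common)
}

#' Two-group NB differential expression with quasi-likelihood moderation
#'
#' NB GLM with TMM offsets, quasi-likelihood F-test. The log2 fold change is
#' positive when the gene is up in `group1`. Genes with all-zero counts are
#' excluded. The DEG set is `|log2FC| > lfc_min & FDR < fdr_max`.
#'
#' @param counts Genes x cells counts.
#' @param group Group label per cell.
#' @param group1,group2 The two levels; `group1` is the first-named group of
#'   the contrast (e.g. TL in TL_vs_FL).
#' @param factors Optional TMM factors.
#' @param dispersion Optional `rv_dispersion` (refitted if `NULL`).
#' @param lfc_min,fdr_max DEG thresholds (defaults 0.5 and 0.05).
#' @param contrast Contrast label stored in the result.
#' @param celltype Cell-type label stored in the result.
#' @return Tibble `contrast`, `cell_type`, `gene`, `log2fc`, `p_value`,
#'   `adj_p`, `pct_group1`, `pct_group2`, `mean_norm`, `is_deg`.
#' @export
nb_de_test <- function(counts, group, group1, group2, factors = NULL,
                       dispersion = NULL, lfc_min = 0.5, fdr_max = 0.05,
                       contrast = paste0(group1, "_vs_", group2),
                       celltype = NA_character_) {
  counts <- as.matrix(counts)
  if (!all(group %in% c(group1, group2))) {
    abort("`group` has values outside the two contrast levels")
  }
  g <- factor(group, levels = c(group2, group1))
  if (any(table(g) < 3)) abort("each group needs >= 3 cells")

  nonzero <- Matrix::rowSums(counts) > 0
  if (!all(nonzero)) {
    inform(sprintf("excluding %d all-zero gene(s)", sum(!nonzero)))
  }
  cnt <- counts[nonzero, , drop = FALSE]

  y <- edgeR::DGEList(cnt, group = g)
  y$samples$norm.factors <- factors %||% tmm_factors(cnt)
  design <- stats::model.matrix(~g)
  if (is.null(dispersion)) {
    y <- edgeR::estimateDisp(y, design, prior.df = 10,
                             trend.method = "none", min.row.sum = 0)
  } else {
    y$common.dispersion <- dispersion$common
    y$tagwise.dispersion <- dispersion$tagwise[nonzero]
    y$trended.dispersion <- NULL
  }
  fit <- edgeR::glmQLFit(y, design)
  res <- edgeR::glmQLFTest(fit, coef = 2)$table

  idx1 <- which(group == group1)
  idx2 <- which(group == group2)
  norm <- lognormalize(Matrix::Matrix(cnt, sparse = TRUE))
  tibble(contrast = contrast, cell_type = celltype,
         gene = rownames(cnt),
         log2fc = res$logFC,
         p_value = res$PValue,
         adj_p = p.adjust(res$PValue, "BH"),
         pct_group1 = Matrix::rowSums(cnt[, idx1, drop = FALSE] > 0) /
           length(idx1),
         pct_group2 = Matrix::rowSums(cnt[, idx2, drop = FALSE] > 0) /
           length(idx2),
         mean_norm = Matrix::rowMeans(norm)) |>
    mutate(is_deg = abs(.data$log2fc) > lfc_min & .data$adj_p < fdr_max)
}

#' Regional differential expression across cell (sub)types
#'
#' For each analysed type: balance the two regions by downsampling, compute
#' TMM factors, estimate dispersions and run the quasi-likelihood NB test
#' (TL as the first-named group). Types with fewer than 3 cells in a region
#' are skipped with a warning.
#'
#' @param cm A QC-filtered `rv_counts`.
#' @param types Character vector of `major_type`/`subtype` values to analyse
#'   (default: all subtypes).
#' @param group1,group2 Region labels of the contrast (defaults TL, FL).
#' @param seed Integer seed for the downsampling.
#' @inheritParams nb_de_test
#' @return Tibble as [nb_de_test()], rows stacked over types.
#' @export
regional_de <- function(cm, types = sort(unique(cm$cell_meta$subtype)),
                        group1 = "TL", group2 = "FL", seed = 1,
                        lfc_min = 0.5, fdr_max = 0.05) {
  out <- lapply(types, function(t) {
    bal <- tryCatch(downsample_balanced(cm, t, seed = seed),
                    error = function(e) {
                      warn(paste0("skipping type ", t, ": ",
                                  conditionMessage(e)))
                      NULL
                    })
    if (is.null(bal)) return(NULL)
    nb_de_test(bal$counts, bal$cell_meta$region, group1, group2,
               lfc_min = lfc_min, fdr_max = fdr_max, celltype = t)
  })
  bind_rows(out)
}

#' Hierarchically cluster the regional log-FC matrix
#'
#' Builds the genes x types log2FC matrix for the union of DEGs (missing
#' entries zero-filled: not differentially expressed means no change),
#' clusters genes by Euclidean distance with complete linkage and cuts the
#' tree at `k` clusters.
#'
#' @param de Tibble from [regional_de()].
#' @param k Number of clusters (default 6).
#' @return List with `assignment` (tibble `gene`, `cluster`), `profiles`
#'   (tibble of per-cluster mean log2FC per type) and `tree` (hclust).
#' @export
cluster_logfc <- function(de, k = 6) {
  degs <- de |> filter(.data$is_deg)
  if (nrow(degs) == 0) abort("no DEGs to cluster")
  wide <- degs |>
    select("gene", "cell_type", "log2fc") |>
    tidyr::pivot_wider(names_from = "cell_type", values_from = "log2fc",
                       values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene
  if (k > nrow(m)) abort("k exceeds the number of DEGs")
  tree <- hclust(dist(m, method = "euclidean"), method = "complete")
  cl <- cutree(tree, k = k)
  profiles <- as_tibble(m) |>
    mutate(cluster = cl) |>
    group_by(.data$cluster) |>
    summarise(across(dplyr::everything(), mean), .groups = "drop")
  list(assignment = tibble(gene = rownames(m), cluster = unname(cl)),
       profiles = profiles, tree = tree)
}
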