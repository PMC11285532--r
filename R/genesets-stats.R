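# GWAS gene selection and set-overlap statistics

#' Select GWAS genes per disease
#'
#' Applies the catalogue selection rules: keep non-intergenic (genic) records
#' only; keep association p-values at or below `p_max`; where several SNPs
#' map to the same gene within a disease, keep the SNP with the lowest
#' p-value; finally intersect with the expressed background. Also returns the
#' all-disease union and the pan-disorder intersection.
#'
#' @param gwas Tibble from [read_gwas_table()] (or
#'   [simulate_gwas_table()]`$table`).
#' @param background Character vector of expressed genes, or an
#'   `rv_background`; `NULL` skips the expression filter.
#' @param p_max Association p-value cut (default 1e-5).
#' @return List with `genes` (tibble `disease`, `gene`, `best_p`,
#'   `best_snp`), `sets` (named list of per-disease gene vectors), `union`,
#'   `intersection`.
#' @export
gwas_select <- function(gwas, background = NULL, p_max = 1e-5) {
  if (inherits(background, "rv_background")) background <- background$genes
  kept <- gwas |>
    filter(.data$genic, .data$p_value <= p_max) |>
    group_by(.data$disease, .data$gene) |>
    slice_min(.data$p_value, n = 1, with_ties = FALSE) |>
    ungroup() |>
    rename(best_p = "p_value", best_snp = "snp") |>
    select("disease", "gene", "best_p", "best_snp")
  if (!is.null(background)) {
    kept <- kept |> filter(.data$gene %in% background)
  }
  diseases <- sort(unique(gwas$disease))
  empty <- setdiff(diseases, unique(kept$disease))
  if (length(empty)) {
    warn(paste0("no GWAS genes survive selection for: ",
                paste(empty, collapse = ", ")))
  }
  sets <- lapply(setNames(diseases, diseases),
                 function(d) sort(kept$gene[kept$disease == d]))
  list(genes = arrange(kept, .data$disease, .data$gene),
       sets = sets,
       union = sort(unique(kept$gene)),
       intersection = sort(Reduce(intersect, sets)))
}

#' Hypergeometric upper-tail overlap p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, t, q)`: the chance of at least `k`
#' of the `q` query genes falling in the `t` target genes when drawn from a
#' background of `N`. Computed in log space for stability.
#'
#' @param k Observed overlap.
#' @param q Query size.
#' @param t Target size.
#' @param N Background size.
#' @return P-value in (0, 1].
#' @export
hypergeom_upper <- function(k, q, t, N) {
  stopifnot(k >= 0, q >= 0, t >= 0, N >= 0, q <= N, t <= N)
  if (k > min(q, t)) abort("k exceeds min(q, t)")
  if (k == 0) return(1)
  # P(X >= k) = 1 - P(X <= k-1), stable via the complementary log tail
  exp(phyper(k - 1, t, N - t, q, lower.tail = FALSE, log.p = TRUE))
}

#' One-sided Fisher exact test for set overlap
#'
#' Enrichment-direction exact test on the 2x2 table
#' `(k, q-k; t-k, N-q-t+k)`; equals the hypergeometric upper tail on the
#' same margins.
#'
#' @inheritParams hypergeom_upper
#' @return P-value in (0, 1].
#' @export
fisher_overlap <- function(k, q, t, N) {
  cells <- c(k, q - k, t - k, N - q - t + k)
  if (any(cells < 0)) abort("negative cell in the derived 2x2 table")
  tab <- matrix(cells, 2, 2, byrow = TRUE)
  fisher.test(tab, alternative = "greater")$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, capped at 1, order of the input preserved.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  stopifnot(all(pvals > 0 & pvals <= 1))
  p.adjust(pvals, method = "BH")
}

#' Cross-tabulated overlap enrichment
#'
#' One hypergeometric upper-tail test per (query set, target set) pair, with
#' both sets intersected with the background first; BH adjustment across the
#' whole table. `score = -log10(adjusted p)`; `proportion = k / t`.
#'
#' @param query_sets Named list of gene vectors (or an `rv_genesets`).
#' @param target_sets Named list of gene vectors (or an `rv_genesets`).
#' @param background Character vector of background genes (the gene universe
#'   for the test).
#' @return Tibble of class `rv_enrichment` with `query`, `target`, `k`, `q`,
#'   `t`, `N`, `p_value`, `adj_p`, `score`, `proportion`.
#' @export
enrich_table <- function(query_sets, target_sets, background) {
  if (inherits(query_sets, "rv_genesets")) query_sets <- query_sets$sets
  if (inherits(target_sets, "rv_genesets")) target_sets <- target_sets$sets
  background <- unique(background)
  if (length(background) == 0) abort("empty background")
  N <- length(background)
  q_in <- lapply(query_sets, function(g) {
    g <- unique(g)
    dropped <- length(setdiff(g, background))
    if (dropped) {
      inform(sprintf("%d query gene(s) outside the background dropped",
                     dropped))
    }
    intersect(g, background)
  })
  t_in <- lapply(target_sets, function(g) intersect(unique(g), background))
  grid <- tidyr::crossing(query = names(query_sets),
                          target = names(target_sets))
  res <- purrr::pmap(grid, function(query, target) {
    qg <- q_in[[query]]
    tg <- t_in[[target]]
    k <- length(intersect(qg, tg))
    tibble(query = query, target = target, k = k,
           q = length(qg), t = length(tg), N = N,
           p_value = hypergeom_upper(k, length(qg), length(tg), N),
           proportion = if (length(tg) > 0) k / length(tg) else NA_real_)
  }) |> bind_rows()
  res$adj_p <- bh_adjust(res$p_value)
  res$score <- -log10(res$adj_p)
  class(res) <- c("rv_enrichment", class(res))
  res[, c("query", "target", "k", "q", "t", "N", "p_value", "adj_p",
          "score", "proportion")]
}

#' Over-representation analysis against pathway sets
#'
#' [enrich_table()] with a single query gene list against pathway targets.
#'
#' @param genes Character vector of query genes.
#' @param pathway_sets Named list or `rv_genesets` of pathways.
#' @param background Background gene universe.
#' @param query_name Label for the query column.
#' @return `rv_enrichment` tibble.
#' @export
ora_pathways <- function(genes, pathway_sets, background,
                         query_name = "query") {
  enrich_table(setNames(list(genes), query_name), pathway_sets, background)
}

#' Per-type chi-squared test of regional composition
#'
#' For each cell type, a 2x2 chi-squared test (type vs rest, region vs
#' region) without continuity correction; BH across types.
#'
#' @param counts Integer matrix of cell counts, types in rows, the two
#'   regions in columns.
#' @return Tibble `cell_type`, `statistic`, `p_value`, `adj_p`.
#' @export
chisq_proportions <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 2)
  if (any(colSums(counts) == 0) || any(rowSums(counts) == 0)) {
    abort("zero margin in the contingency table")
  }
  res <- lapply(rownames(counts), function(t) {
    tab <- rbind(counts[t, ], colSums(counts) - counts[t, ])
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    tibble(cell_type = t, statistic = unname(ct$statistic),
           p_value = unname(ct$p.value))
  }) |> bind_rows()
  res$adj_p <- bh_adjust(res$p_value)
  res
}

#' Pearson correlation with two-sided t-test
#'
#' @param x,y Numeric vectors, length >= 3, finite, non-constant.
#' @return List with `r` and `p_value`.
#' @export
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("zero variance input")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
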