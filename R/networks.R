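# Jaccard pathway-similarity networks and Spearman co-expression networks

#' Jaccard similarity of two gene sets
#'
#' `|A intersect B| / |A union B|`.
#'
#' @param a,b Character vectors (not both empty).
#' @return Similarity in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) abort("both sets empty")
  length(intersect(a, b)) / u
}

# light graph container: node tibble + undirected edge tibble
rv_graph <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "rv_graph")
}

#' @export
print.rv_graph <- function(x, ...) {
  cat(sprintf("<rv_graph> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Pathway similarity network
#'
#' One node per significant pathway (BH-adjusted p below `alpha` in the
#' supplied enrichment table), one edge per pathway pair with positive
#' Jaccard similarity of their gene sets; the edge weight is the similarity.
#'
#' @param enrichment `rv_enrichment` tibble whose `target` column names
#'   pathways.
#' @param pathway_sets Named list or `rv_genesets` holding the pathway gene
#'   sets.
#' @param alpha Significance cut on `adj_p` (default 0.05).
#' @param annotation Optional named character vector of high-level category
#'   labels per pathway (stored as a node attribute).
#' @return An `rv_graph`.
#' @export
pathway_network <- function(enrichment, pathway_sets, alpha = 0.05,
                            annotation = NULL) {
  if (inherits(pathway_sets, "rv_genesets")) pathway_sets <- pathway_sets$sets
  sig <- unique(enrichment$target[enrichment$adj_p < alpha])
  sig <- intersect(sig, names(pathway_sets))
  nodes <- tibble(name = sig,
                  annotation = if (is.null(annotation)) NA_character_
                               else unname(annotation[sig]))
  if (length(sig) < 2) {
    warn("fewer than 2 significant pathways; empty edge set")
    return(rv_graph(nodes, tibble(source = character(0),
                                  target = character(0),
                                  weight = numeric(0))))
  }
  pairs <- utils::combn(sig, 2)
  w <- apply(pairs, 2, function(p) {
    jaccard(pathway_sets[[p[1]]], pathway_sets[[p[2]]])
  })
  edges <- tibble(source = pairs[1, ], target = pairs[2, ], weight = w) |>
    filter(.data$weight > 0)
  rv_graph(nodes, edges)
}

#' Spearman correlation of one gene pair
#'
#' Tie-corrected rank correlation (average ranks). The two-sided p-value uses
#' the t approximation with n-2 degrees of freedom for n > 9 and the exact
#' permutation distribution for n <= 9.
#'
#' @param x,y Paired numeric vectors across >= 4 cells; neither constant.
#' @return List with `rho` and `p_value`.
#' @export
spearman_edge <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 4)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    abort("constant vector")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 9) {
    perms <- all_perms(n)
    rho_null <- apply(perms, 1, function(p) cor(rx, ry[p]))
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
  } else {
    p <- spearman_t_pvalue(rho, n)
  }
  list(rho = rho, p_value = p)
}

spearman_t_pvalue <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(t), df = n - 2)
}

#' Gene co-expression network within one cell scope
#'
#' All pairs among `genes` are tested by Spearman correlation across the
#' cells of `cell_scope` (a `major_type` or `subtype` value); edges with
#' `p < alpha` (raw, matching the source procedure; optionally BH-adjusted)
#' are retained with the correlation as weight.
#'
#' @param norm Normalized matrix from [lognormalize()].
#' @param cm The `rv_counts` the matrix came from (for cell metadata).
#' @param genes Genes to connect (subset of rownames).
#' @param cell_scope Cell type/subtype label, or `"all"`.
#' @param alpha Edge significance cut (default 0.05).
#' @param adjust Apply BH across pairs before thresholding (default FALSE).
#' @param annotation Optional named character vector of node labels.
#' @return An `rv_graph` with edge columns `source`, `target`, `weight`
#'   (rho), `p_value`.
#' @export
coexpression_network <- function(norm, cm, genes, cell_scope = "all",
                                 alpha = 0.05, adjust = FALSE,
                                 annotation = NULL) {
  genes <- intersect(unique(genes), rownames(norm))
  if (length(genes) < 2) abort("need >= 2 genes present in the matrix")
  if (identical(cell_scope, "all")) {
    idx <- seq_len(ncol(norm))
  } else {
    idx <- which(cm$cell_meta$major_type == cell_scope |
                   cm$cell_meta$subtype == cell_scope)
  }
  if (length(idx) < 4) abort("fewer than 4 cells in scope")
  m <- as.matrix(Matrix::t(norm[genes, idx, drop = FALSE]))  # cells x genes
  keep <- apply(m, 2, function(v) length(unique(v)) > 1)
  m <- m[, keep, drop = FALSE]
  ranks <- apply(m, 2, rank)
  rho <- cor(ranks)
  n <- nrow(m)
  pairs <- which(upper.tri(rho), arr.ind = TRUE)
  edges <- tibble(source = colnames(rho)[pairs[, 1]],
                  target = colnames(rho)[pairs[, 2]],
                  weight = rho[pairs])
  if (n <= 9) {
    edges$p_value <- purrr::map2_dbl(edges$source, edges$target, function(a, b) {
      spearman_edge(m[, a], m[, b])$p_value
    })
  } else {
    edges$p_value <- spearman_t_pvalue_vec(edges$weight, n)
  }
  pcol <- if (adjust) bh_adjust(edges$p_value) else edges$p_value
  edges <- edges[pcol < alpha, ]
  nodes <- tibble(name = colnames(rho),
                  annotation = if (is.null(annotation)) NA_character_
                               else unname(annotation[colnames(rho)]))
  rv_graph(nodes, edges)
}

spearman_t_pvalue_vec <- function(rho, n) {
  vapply(rho, spearman_t_pvalue, 1, n = n)
}

#' Write a graph as edge-list TSV and GraphML
#'
#' @param g An `rv_graph`.
#' @param edges_path TSV path for the edge list (`source`, `target`,
#'   `weight`, and `p_value` when present).
#' @param graphml_path Optional GraphML path (written via igraph, with node
#'   annotation attributes).
#' @return `edges_path`, invisibly.
#' @export
write_graph_files <- function(g, edges_path, graphml_path = NULL) {
  readr::write_tsv(g$edges, edges_path)
  if (!is.null(graphml_path)) {
    ig <- igraph::graph_from_data_frame(
      as.data.frame(g$edges), directed = FALSE,
      vertices = as.data.frame(g$nodes))
    igraph::write_graph(ig, graphml_path, format = "graphml")
  }
  invisible(edges_path)
}

#' Read a GraphML file back as an rv_graph
#'
#' @param path GraphML path.
#' @return An `rv_graph`.
#' @export
read_graph_file <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  nodes <- tibble(name = igraph::V(ig)$name)
  if ("annotation" %in% igraph::vertex_attr_names(ig)) {
    nodes$annotation <- igraph::V(ig)$annotation
  }
  el <- igraph::as_data_frame(ig, what = "edges")
  rv_graph(nodes, as_tibble(el) |> rename(source = "from", target = "to"))
}
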