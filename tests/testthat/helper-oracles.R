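# independent oracles and in-code fixtures shared across tests

# hypergeometric upper tail by direct summation of combinatorial mass,
# independent of phyper()
hyper_tail_oracle <- function(k, q, t, N) {
  if (k == 0) return(1)
  i <- k:min(q, t)
  sum(choose(t, i) * choose(N - t, q - i)) / choose(N, q)
}

# logistic-regression LR statistic by direct maximum likelihood (optim),
# independent of glm.fit
logistic_lr_oracle <- function(x, y) {
  nll <- function(beta) {
    eta <- beta[1] + beta[2] * x
    sum(log1p(exp(eta)) - y * eta)
  }
  nll0 <- function(b0) {
    sum(log1p(exp(b0)) - y * b0)
  }
  fit <- optim(c(0, 0), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-12))
  fit0 <- optimize(nll0, c(-20, 20), tol = 1e-10)
  2 * (fit0$objective - fit$value)
}

# weighted KS enrichment score by an explicit position-by-position walk,
# independent of the package's cumulative implementation
gsea_es_oracle <- function(ranked_stats, set, weight = 1) {
  genes <- names(ranked_stats)
  hit <- genes %in% set
  w <- abs(ranked_stats)^weight
  inc <- ifelse(hit, w / sum(w[hit]), 0)
  dec <- ifelse(hit, 0, 1 / sum(!hit))
  run <- cumsum(inc - dec)
  run[which.max(abs(run))]
}

# TMM factor for one column against a reference column: weighted trimmed
# mean of M-values (trim 30% on M, 5% on A, precision weights), written
# directly from the definition
tmm_pair_oracle <- function(obs, ref) {
  n_o <- sum(obs)
  n_r <- sum(ref)
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]
  ref <- ref[keep]
  m <- log2((obs / n_o) / (ref / n_r))
  a <- (log2(obs / n_o) + log2(ref / n_r)) / 2
  w <- (n_o - obs) / (n_o * obs) + (n_r - ref) / (n_r * ref)
  lo_m <- quantile(m, 0.3, type = 7)
  hi_m <- quantile(m, 0.7, type = 7)
  lo_a <- quantile(a, 0.05, type = 7)
  hi_a <- quantile(a, 0.95, type = 7)
  keep2 <- m >= lo_m & m <= hi_m & a >= lo_a & a <= hi_a
  2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

# small deterministic count matrix: 6 genes x 8 cells, two types, two regions
make_toy_counts <- function() {
  counts <- matrix(c(
    5, 0, 3, 0, 1, 0, 2, 0,
    0, 4, 0, 6, 0, 3, 0, 5,
    2, 2, 2, 2, 2, 2, 2, 2,
    1, 0, 0, 1, 1, 0, 0, 1,
    0, 0, 0, 0, 0, 0, 0, 0,
    3, 1, 4, 1, 3, 1, 4, 1), nrow = 6, byrow = TRUE,
    dimnames = list(paste0("G", 1:6), paste0("C", 1:8)))
  meta <- tibble::tibble(
    barcode = paste0("C", 1:8),
    subject = rep(c("S1", "S2"), each = 4),
    region = rep(c("TL", "FL"), each = 4),
    major_type = rep(c("A", "B"), 4),
    subtype = rep(c("A", "B"), 4),
    doublet = FALSE)
  count_matrix(counts, cell_meta = meta)
}

# hand-written 10x triplet: 3 genes x 4 cells with 5 nonzeros
write_toy_triplet <- function(dir, barcodes = c("AAA", "CCC", "GGG", "TTT"),
                              features = c("GENE1", "GENE2", "MT-CO1")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 4 5",
               "1 1 2", "2 1 1", "3 2 4", "1 3 3", "2 4 7"),
             file.path(dir, "matrix.mtx"))
  writeLines(features, file.path(dir, "features.tsv"))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

# direct two-group NB matrix with planted log2 fold changes
sim_nb_two_group <- function(n_genes, n_per_side, lfc = numeric(n_genes),
                             phi = 0.4, mean_count = 5, seed = 1) {
  set.seed(seed)
  base <- rgamma(n_genes, shape = 2, rate = 2 / mean_count)
  mu1 <- outer(base * 2^lfc, rep(1, n_per_side))
  mu2 <- outer(base, rep(1, n_per_side))
  mu <- cbind(mu1, mu2)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / phi),
                   n_genes, 2 * n_per_side)
  dimnames(counts) <- list(sprintf("G%04d", seq_len(n_genes)),
                           sprintf("C%04d", seq_len(2 * n_per_side)))
  list(counts = counts,
       group = rep(c("TL", "FL"), each = n_per_side))
}

# trimmed pipeline config used for multi-seed recovery runs: restrict the
# regional DE to the neuronal subtypes
neuronal_cfg <- function(seed) {
  run_config(seed = seed,
             de_types = c("EX-L2-3", "EX-L4", "EX-L5", "EX-L6",
                          "INH-PVALB", "INH-SST", "INH-LAMP5", "INH-VIP"))
}
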