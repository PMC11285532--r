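# Jaccard pathway networks and Spearman co-expression networks

test_that("jaccard similarity follows the set definition", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard(c("a", "a", "b"), c("b", "b", "a")), 1)  # dedup
  expect_error(jaccard(character(0), character(0)), "both sets empty")
})

test_that("pathway networks carry hand-computed Jaccard weights", {
  sets <- list(P1 = c("a", "b", "c", "d"),
               P2 = c("c", "d", "e", "f"),
               P3 = c("x", "y"),
               P4 = c("a", "b", "c", "d"))
  enr <- tibble::tibble(target = names(sets),
                        adj_p = c(0.01, 0.01, 0.01, 0.01))
  g <- pathway_network(enr, sets)
  w <- function(a, b) {
    e <- g$edges
    e$weight[(e$source == a & e$target == b) |
               (e$source == b & e$target == a)]
  }
  expect_equal(w("P1", "P2"), 2 / 6)
  expect_equal(w("P1", "P4"), 1)        # identical pathways
  expect_length(w("P1", "P3"), 0)       # disjoint: no edge
  expect_length(w("P3", "P2"), 0)
  # only significant pathways become nodes
  enr2 <- enr
  enr2$adj_p <- c(0.01, 0.2, 0.2, 0.2)
  expect_warning(g2 <- pathway_network(enr2, sets), "fewer than 2")
  expect_equal(nrow(g2$edges), 0L)
})

test_that("spearman edges handle monotone, reversed and tied data", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_edge(x, x * 2 + 1)$rho, 1)
  expect_equal(spearman_edge(x, rev(x))$rho, -1)
  # one tie pair: rho equals the Pearson correlation of average ranks
  y <- c(10, 12, 12, 15, 11, 18)
  res <- spearman_edge(x, y)
  expect_equal(res$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_error(spearman_edge(x, rep(3, 6)), "constant")
})

test_that("exact small-n permutation p is consistent with enumeration", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  res <- spearman_edge(x, y)
  # brute-force: all 120 permutations
  perms <- regionvuln:::all_perms(5)
  rhos <- apply(perms, 1, function(p) cor(rank(x), rank(y)[p]))
  expect_equal(res$p_value, mean(abs(rhos) >= abs(res$rho) - 1e-12))
})

test_that("a duplicated gene yields a retained rho = 1 edge", {
  set.seed(21)
  m <- matrix(rpois(6 * 30, 5), 6, 30,
              dimnames = list(paste0("G", 1:6), paste0("C", 1:30)))
  m[2, ] <- m[1, ]  # duplicate under a second name
  cm <- count_matrix(m)
  norm <- lognormalize(cm)
  g <- coexpression_network(norm, cm, paste0("G", 1:6), cell_scope = "all")
  dup <- g$edges[g$edges$source == "G1" & g$edges$target == "G2", ]
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$weight, 1)
})

test_that("a planted correlated block is recovered at the null edge rate", {
  set.seed(22)
  n_cells <- 80
  latent <- rnorm(n_cells)
  block <- sapply(1:5, function(i) 2 * latent + rnorm(n_cells, 0, 0.8))
  noise <- matrix(rnorm(n_cells * 10), n_cells, 10)
  expr <- t(cbind(block, noise)) + 5
  dimnames(expr) <- list(c(paste0("B", 1:5), paste0("N", 1:10)),
                         paste0("C", 1:n_cells))
  cm <- count_matrix(matrix(rpois(length(expr), 5), nrow(expr), ncol(expr),
                            dimnames = dimnames(expr)))
  norm <- Matrix::Matrix(expr, sparse = TRUE)
  g <- coexpression_network(norm, cm, rownames(expr), cell_scope = "all")
  in_block <- g$edges$source %in% paste0("B", 1:5) &
    g$edges$target %in% paste0("B", 1:5)
  expect_equal(sum(in_block), choose(5, 2))  # all block edges retained
  cross <- sum(xor(g$edges$source %in% paste0("B", 1:5),
                   g$edges$target %in% paste0("B", 1:5)))
  expect_lt(cross / (5 * 10), 0.2)  # cross-block near the nominal rate
})

test_that("graphs survive the GraphML round trip symmetrically", {
  sets <- list(P1 = c("a", "b", "c"), P2 = c("b", "c", "d"),
               P3 = c("c", "d", "e"))
  enr <- tibble::tibble(target = names(sets), adj_p = 0.01)
  g <- pathway_network(enr, sets, annotation = c(P1 = "synapse",
                                                 P2 = "synapse",
                                                 P3 = "signaling"))
  dir <- withr::local_tempdir()
  write_graph_files(g, file.path(dir, "edges.tsv"),
                    file.path(dir, "net.graphml"))
  back <- read_graph_file(file.path(dir, "net.graphml"))
  expect_setequal(back$nodes$name, g$nodes$name)
  expect_equal(back$nodes$annotation[match(g$nodes$name, back$nodes$name)],
               g$nodes$annotation)
  key <- function(e) paste(pmin(e$source, e$target),
                           pmax(e$source, e$target))
  expect_setequal(key(back$edges), key(g$edges))
  w_by_key <- setNames(g$edges$weight, key(g$edges))
  expect_equal(unname(w_by_key[key(back$edges)]), back$edges$weight,
               tolerance = 1e-9)
})

test_that("co-expression networks are invariant to cell and gene order", {
  set.seed(23)
  m <- matrix(rpois(8 * 40, 6), 8, 40,
              dimnames = list(paste0("G", 1:8), paste0("C", 1:40)))
  cm <- count_matrix(m)
  norm <- lognormalize(cm)
  g1 <- coexpression_network(norm, cm, paste0("G", 1:8), "all")
  cperm <- sample(40)
  gperm <- sample(8)
  cm2 <- count_matrix(m[gperm, cperm])
  norm2 <- lognormalize(cm2)
  g2 <- coexpression_network(norm2, cm2, paste0("G", 1:8), "all")
  key <- function(e) paste(pmin(e$source, e$target),
                           pmax(e$source, e$target))
  expect_setequal(key(g1$edges), key(g2$edges))
})
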