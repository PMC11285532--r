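# synthetic-data generator: determinism, planted effects, oracle identities

small_sim <- function(...) sim_config(cells_per_subject = 200, ...)

test_that("the same seed reproduces the matrix exactly", {
  a <- simulate_counts(small_sim(), seed = 11)
  b <- simulate_counts(small_sim(), seed = 11)
  expect_identical(as.matrix(a$counts$counts), as.matrix(b$counts$counts))
  expect_identical(a$truth$regional_map, b$truth$regional_map)
  c <- simulate_counts(small_sim(), seed = 12)
  expect_false(identical(as.matrix(a$counts$counts),
                         as.matrix(c$counts$counts)))
})

test_that("a planted marker shift is recovered from empirical means", {
  # one marker block with +3 log2 shift, minimal competing structure so the
  # library-size renormalization does not mask the planted effect
  cfg <- sim_config(cells_per_subject = 400, n_genes = 800,
                    marker_shift = 3, n_markers_major = 5,
                    n_markers_subtype = 2, n_regional = 20,
                    doublet_rate = 0)
  s <- simulate_counts(cfg, seed = 7)
  cm <- s$counts
  mk <- s$truth$marker_map
  g <- mk$gene[mk$cell_type == "EX"][1]
  in_ex <- cm$cell_meta$major_type == "EX"
  expect_gt(sum(in_ex), 300)
  cpm <- sweep(as.matrix(cm$counts), 2, cm$cell_meta$total_umi, "/")
  ratio <- log2(mean(cpm[g, in_ex]) / mean(cpm[g, !in_ex]))
  expect_lt(abs(ratio - 3), 0.3)
})

test_that("doublet rate zero produces no doublets; positive rate flags them", {
  s0 <- simulate_counts(small_sim(doublet_rate = 0), seed = 2)
  expect_length(s0$truth$doublets, 0L)
  expect_false(any(s0$counts$cell_meta$doublet))
  s1 <- simulate_counts(small_sim(doublet_rate = 0.1), seed = 2)
  expect_equal(sum(s1$counts$cell_meta$doublet), length(s1$truth$doublets))
  expect_gt(length(s1$truth$doublets), 0L)
})

test_that("simulated counts are overdispersed relative to Poisson", {
  s <- simulate_counts(sim_config(cells_per_subject = 400), seed = 4)
  cm <- s$counts
  # within one homogeneous group (same subject, subtype, no planted regional
  # variation across these cells) variance should exceed the mean for most
  # reasonably expressed genes
  idx <- which(cm$cell_meta$subject == "S1" &
                 cm$cell_meta$major_type == "Olig" & !cm$cell_meta$doublet)
  expect_gt(length(idx), 80)
  m <- as.matrix(cm$counts[, idx])
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  expressed <- mu > 0.5
  expect_gt(mean(v[expressed] > mu[expressed]), 0.9)
})

test_that("a composition yielding too few cells per type errors", {
  cfg <- sim_config(cells_per_subject = 20)
  expect_error(simulate_counts(cfg, seed = 1), "< 2 cells")
})

test_that("gwas_select recovers the planted GWAS truth exactly", {
  genes <- sprintf("G%03d", 1:300)
  planted <- list(BP = sample(genes, 25), SCHI = sample(genes, 30),
                  ASD = sample(genes, 10))
  for (seed in c(1, 99)) {
    sim <- simulate_gwas_table(genes, planted, seed = seed)
    sel <- gwas_select(sim$table, background = genes)
    for (d in names(planted)) {
      expect_setequal(sel$sets[[d]], planted[[d]])
    }
    # retained p is the per-gene minimum and matches the recorded truth
    joined <- dplyr::inner_join(sel$genes, sim$truth,
                                by = c("disease", "gene"))
    expect_equal(joined$best_p.x, joined$best_p.y)
    expect_equal(joined$best_snp.x, joined$best_snp.y)
  }
})

test_that("multi-SNP genes keep the lowest p and intergenic hits are dropped", {
  tab <- tibble::tibble(
    snp = c("rs1", "rs2", "rs3", "rs4"),
    gene = c("A", "A", "B", "C"),
    disease = "BP",
    p_value = c(1e-6, 1e-9, 5e-9, 2e-5),
    genic = c(TRUE, TRUE, FALSE, TRUE))
  sel <- gwas_select(tab, background = NULL)
  expect_equal(sel$genes$best_p[sel$genes$gene == "A"], 1e-9)
  expect_equal(sel$genes$best_snp[sel$genes$gene == "A"], "rs2")
  expect_false("B" %in% sel$genes$gene)  # intergenic-only
  expect_false("C" %in% sel$genes$gene)  # above threshold
})

test_that("genes planted in all diseases form the pan-disorder intersection", {
  genes <- sprintf("G%03d", 1:400)
  common <- sample(genes, 38)
  diseases <- c("BP", "ASD", "SCHI", "ADHD", "OCD", "UD", "CI")
  planted <- lapply(setNames(diseases, diseases), function(d) {
    unique(c(common, sample(genes, 10)))
  })
  sim <- simulate_gwas_table(genes, planted, seed = 5)
  sel <- gwas_select(sim$table, background = genes)
  expect_setequal(intersect(sel$intersection, common), common)
})

test_that("disease DEG concordance controls the sign-agreement fraction", {
  genes <- sprintf("G%04d", 1:2000)
  reg <- tibble::tibble(subtype = "INH-PVALB",
                        gene = genes[1:500],
                        log2fc = sample(c(-1, 1), 500, TRUE) *
                          runif(500, 0.6, 1.5))
  # extremes are deterministic
  d1 <- simulate_disease_degs(genes, reg, concordance = 1, seed = 1,
                              diseases = "BP", shared_frac = 1)
  expect_true(all(d1$truth$sign_agrees))
  d2 <- simulate_disease_degs(genes, reg, concordance = -1, seed = 1,
                              diseases = "BP", shared_frac = 1)
  expect_false(any(d2$truth$sign_agrees))
  # concordance 0.2 with 500 shared genes: agreement ~ 0.6 within binomial
  # tolerance
  d3 <- simulate_disease_degs(genes, reg, concordance = 0.2, seed = 2,
                              diseases = "BP", shared_frac = 1)
  expect_equal(nrow(d3$truth), 500L)
  expect_lt(abs(mean(d3$truth$sign_agrees) - 0.6), 0.05)
  # planted genes pass the disease-DEG thresholds
  dd <- disease_deg_filter(d3$tables$BP)
  expect_true(all(d3$truth$gene %in% c(dd$up, dd$down)))
  expect_error(simulate_disease_degs(genes, reg, concordance = 1.5),
               "concordance")
})
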