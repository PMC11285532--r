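# synthetic study generator with planted, recorded ground truth
#
# Every downstream stage (QC, markers, regional DE, GWAS selection,
# enrichment, GSEA, networks, vulnerability) has a planted signal here whose
# truth tables are returned and serialized, so recovery can be tested without
# any external download.

#' Simulation configuration
#'
#' Defaults describe the study design being emulated: three subjects (two
#' temporal-lobe, one frontal-lobe), seven major cortical cell types with
#' excitatory neurons most abundant (38.3%), inhibitory neurons (23.6%) and
#' oligodendrocytes (22.1%) next, neuronal subtypes (EX layers L2-3 to L6;
#' INH PVALB/SST/LAMP5/VIP), negative-binomial UMI counts with log-normal
#' library sizes and per-gene dispersions, planted cell-type markers, and
#' region-specific (TL vs FL) log2 fold changes concentrated in a designated
#' vulnerable subtype (PVALB by default).
#'
#' @param n_genes Number of non-mitochondrial genes.
#' @param n_mito_genes Number of mitochondrial genes (symbols `MT-...`).
#' @param cells_per_subject Cells drawn per subject.
#' @param subjects Tibble with columns `subject`, `region` (two regions,
#'   default 2 TL + 1 FL).
#' @param composition Named fractions over the 7 major types (must sum to 1).
#' @param subtype_split Named list: for EX and INH, fractions over subtypes.
#' @param libsize_meanlog,libsize_sdlog Log-normal library-size parameters.
#' @param dispersion_meanlog,dispersion_sdlog Log-normal per-gene NB
#'   dispersion parameters (`Var = mu + phi mu^2`).
#' @param mito_mean Mean per-cell mitochondrial fraction (Beta-distributed;
#'   a tail of cells exceeds the 10% QC cut).
#' @param doublet_rate Fraction of cells simulated as averaged parent pairs.
#' @param n_markers_major,n_markers_subtype Planted markers per major type /
#'   neuronal subtype.
#' @param marker_shift Log2 mean shift of a marker in its own type.
#' @param n_regional Total planted regional (TL vs FL) genes.
#' @param vulnerable_subtype Subtype receiving `vulnerable_frac` of the
#'   regional genes.
#' @param vulnerable_frac Fraction of regional genes planted in the
#'   vulnerable subtype.
#' @param regional_lfc Log2 fold change (TL over FL) of planted regional
#'   genes.
#' @param regional_down_frac Fraction of planted regional genes down (not up)
#'   in TL.
#' @return A list of class `rv_sim_config`.
#' @export
sim_config <- function(n_genes = 1000,
                       n_mito_genes = 10,
                       cells_per_subject = 1000,
                       subjects = tibble(subject = c("S1", "S2", "S3"),
                                         region = c("TL", "TL", "FL")),
                       composition = c(EX = 0.383, INH = 0.236, Olig = 0.221,
                                       Astro = 0.07, OPC = 0.04, Micro = 0.03,
                                       Endo = 0.02),
                       subtype_split = list(
                         EX = c("EX-L2-3" = 0.4, "EX-L4" = 0.2,
                                "EX-L5" = 0.2, "EX-L6" = 0.2),
                         INH = c("INH-PVALB" = 0.3, "INH-SST" = 0.3,
                                 "INH-LAMP5" = 0.2, "INH-VIP" = 0.2)),
                       libsize_meanlog = log(2000), libsize_sdlog = 0.35,
                       dispersion_meanlog = log(0.4), dispersion_sdlog = 0.5,
                       mito_mean = 0.05,
                       doublet_rate = 0.05,
                       n_markers_major = 25, n_markers_subtype = 12,
                       marker_shift = 2,
                       n_regional = 160,
                       vulnerable_subtype = "INH-PVALB",
                       vulnerable_frac = 0.5,
                       regional_lfc = 1,
                       regional_down_frac = 0.15) {
  stopifnot(abs(sum(composition) - 1) < 1e-8,
            all(vapply(subtype_split, function(s) abs(sum(s) - 1) < 1e-8,
                       TRUE)),
            doublet_rate >= 0, doublet_rate <= 1,
            mito_mean > 0, mito_mean < 1,
            vulnerable_frac >= 0, vulnerable_frac <= 1,
            regional_down_frac >= 0, regional_down_frac <= 1)
  structure(as.list(environment()), class = "rv_sim_config")
}

# expand (major type, subtype) cell labels for one subject, largest-remainder
# apportionment so counts are deterministic and sum exactly
apportion_cells <- function(cfg) {
  major <- cfg$composition
  out <- list()
  for (t in names(major)) {
    split <- cfg$subtype_split[[t]]
    if (is.null(split)) split <- setNames(1, t)
    for (s in names(split)) {
      out[[s]] <- c(major_type = t, subtype = s,
                    frac = unname(major[t] * split[s]))
    }
  }
  tab <- as_tibble(do.call(rbind, out)) |>
    mutate(frac = as.numeric(.data$frac))
  raw <- tab$frac * cfg$cells_per_subject
  n <- floor(raw)
  rem <- cfg$cells_per_subject - sum(n)
  if (rem > 0) {
    extra <- order(raw - n, decreasing = TRUE)[seq_len(rem)]
    n[extra] <- n[extra] + 1
  }
  tab$n <- as.integer(n)
  tab
}

#' Simulate a UMI count matrix with planted truth
#'
#' Per cell: library size is log-normal; for gene g in cell c of subtype s,
#' `count ~ NB(mean = baseline_g * 2^(marker shift if g marks s or its major
#' type) * 2^(regional log2FC if region(c) = TL and g planted in s) *
#' libsize_c, dispersion phi_g)`. Mitochondrial counts are allocated to the
#' designated `MT-` genes to hit a Beta-distributed per-cell target fraction.
#' Doublets are averaged parent pairs, re-sampled from the NB and flagged.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the same seed reproduces the matrix exactly.
#' @return List with `counts` (an [count_matrix()]) and `truth` (list with
#'   `marker_map`, `regional_map`, `mito_genes`, `doublets`, `dispersion`).
#' @export
simulate_counts <- function(cfg = sim_config(), seed = 1) {
  set.seed(seed)
  plan <- apportion_cells(cfg)
  if (any(plan$n < 2)) {
    abort(sprintf("cell type %s has < 2 cells per subject; downstream DE undefined",
                  plan$subtype[which.min(plan$n)]))
  }

  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  mito_genes <- sprintf("MT-G%02d", seq_len(cfg$n_mito_genes))
  all_genes <- c(genes, mito_genes)
  n_all <- length(all_genes)

  # per-gene baseline relative abundance and dispersion
  w <- rlnorm(cfg$n_genes, 0, 1)
  w <- w / sum(w)
  wm <- rlnorm(cfg$n_mito_genes, 0, 0.5)
  wm <- wm / sum(wm)
  phi <- rlnorm(n_all, cfg$dispersion_meanlog, cfg$dispersion_sdlog)

  # planted markers: disjoint gene blocks per major type then per subtype
  pool <- sample(genes)
  take <- function(k) {
    picked <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    picked
  }
  marker_map <- list()
  for (t in names(cfg$composition)) {
    marker_map[[t]] <- take(cfg$n_markers_major)
  }
  for (s in unlist(lapply(cfg$subtype_split, names))) {
    marker_map[[s]] <- take(cfg$n_markers_subtype)
  }

  # planted regional (TL vs FL) effects, concentrated in the vulnerable
  # subtype; remaining genes spread over the other subtypes
  subtypes <- plan$subtype
  n_vuln <- round(cfg$n_regional * cfg$vulnerable_frac)
  others <- setdiff(subtypes, cfg$vulnerable_subtype)
  regional <- tibble(subtype = c(rep(cfg$vulnerable_subtype, n_vuln),
                                 sample(others, cfg$n_regional - n_vuln,
                                        replace = TRUE)),
                     gene = sample(pool, cfg$n_regional))
  regional$log2fc <- cfg$regional_lfc *
    ifelse(runif(nrow(regional)) < cfg$regional_down_frac, -1, 1)

  # cell table
  cells <- tidyr::crossing(cfg$subjects, plan) |>
    mutate(n = .data$n) |>
    tidyr::uncount(.data$n) |>
    select("subject", "region", "major_type", "subtype")
  n_cells <- nrow(cells)
  cells$barcode <- sprintf("C%05d", seq_len(n_cells))

  lib <- rlnorm(n_cells, cfg$libsize_meanlog, cfg$libsize_sdlog)
  # Beta with mean mito_mean; concentration chosen so a tail crosses 10%
  m_frac <- stats::rbeta(n_cells, 2, 2 * (1 - cfg$mito_mean) / cfg$mito_mean)

  # expected means: rows = genes (non-mito then mito), cols = cells
  mu <- matrix(w, cfg$n_genes, n_cells)
  idx_of <- setNames(seq_len(cfg$n_genes), genes)
  for (lab in names(marker_map)) {
    cols <- which(cells$major_type == lab | cells$subtype == lab)
    mu[idx_of[marker_map[[lab]]], cols] <-
      mu[idx_of[marker_map[[lab]]], cols] * 2^cfg$marker_shift
  }
  for (s in unique(regional$subtype)) {
    rows <- regional[regional$subtype == s, ]
    cols <- which(cells$subtype == s & cells$region == "TL")
    if (length(cols)) {
      mu[idx_of[rows$gene], cols] <-
        mu[idx_of[rows$gene], cols] * 2^rows$log2fc
    }
  }
  # renormalize per cell, then split the budget between nuclear and mito
  mu <- sweep(mu, 2, colSums(mu), "/")
  mu <- sweep(mu, 2, lib * (1 - m_frac), "*")
  mu_mito <- outer(wm, lib * m_frac)
  mu <- rbind(mu, mu_mito)

  counts <- matrix(rnbinom(n_all * n_cells, mu = mu, size = rep(1 / phi, n_cells)),
                   n_all, n_cells)

  # doublets: averaged parent pairs within subject, resampled and appended
  n_doub <- round(cfg$doublet_rate * n_cells)
  doub_barcodes <- character(0)
  if (n_doub > 0) {
    pa <- sample(n_cells, n_doub)
    pb <- vapply(pa, function(i) {
      sample(setdiff(which(cells$subject == cells$subject[i]), i), 1)
    }, 1L)
    mu_d <- (mu[, pa, drop = FALSE] + mu[, pb, drop = FALSE]) / 2
    cd <- matrix(rnbinom(n_all * n_doub, mu = mu_d,
                         size = rep(1 / phi, n_doub)), n_all, n_doub)
    doub_barcodes <- sprintf("D%05d", seq_len(n_doub))
    counts <- cbind(counts, cd)
    cells <- bind_rows(cells,
                       cells[pa, ] |>
                         mutate(barcode = doub_barcodes))
  }
  cells$doublet <- cells$barcode %in% doub_barcodes

  dimnames(counts) <- list(all_genes, cells$barcode)
  cm <- count_matrix(Matrix::Matrix(counts, sparse = TRUE),
                     cell_meta = cells,
                     gene_meta = tibble(gene = all_genes,
                                        mito = all_genes %in% mito_genes))

  truth <- list(
    marker_map = tibble(cell_type = rep(names(marker_map),
                                        lengths(marker_map)),
                        gene = unlist(marker_map, use.names = FALSE),
                        log2_shift = cfg$marker_shift),
    regional_map = regional,
    mito_genes = mito_genes,
    doublets = doub_barcodes,
    dispersion = tibble(gene = all_genes, phi = phi)
  )
  list(counts = cm, truth = truth)
}

#' Simulate a GWAS association table around a planted gene map
#'
#' Planted genes get genic SNPs with p below the genome-wide-suggestive cut
#' (1e-5), a stated fraction below the strict 1e-8 tier; background SNPs get
#' p ~ Uniform(1e-5, 1); a fraction of records is intergenic (including some
#' low-p intergenic records that the selection rules must drop); some planted
#' genes carry multiple SNPs so the lowest-p rule is exercised. By
#' construction, applying [gwas_select()] to the table recovers `planted_map`
#' exactly.
#'
#' @param gene_ids Universe of gene symbols.
#' @param planted_map Named list (per disease) of planted gene vectors.
#' @param seed Integer seed.
#' @param strict_frac Fraction of planted genes below p = 1e-8.
#' @param n_background_snps Background SNPs per disease.
#' @param intergenic_frac Fraction of background SNPs flagged intergenic.
#' @param multi_snp_frac Fraction of planted genes receiving a second SNP.
#' @return List with `table` (tibble as from [read_gwas_table()]) and
#'   `truth` (tibble `disease`, `gene`, `best_p`, `best_snp`).
#' @export
simulate_gwas_table <- function(gene_ids, planted_map, seed = 1,
                                strict_frac = 0.5, n_background_snps = 150,
                                intergenic_frac = 0.3, multi_snp_frac = 0.3) {
  set.seed(seed)
  missing <- setdiff(unlist(planted_map), gene_ids)
  if (length(missing)) {
    abort(paste0("planted gene absent from gene_ids: ", missing[1]))
  }
  snp_i <- 0L
  new_snp <- function(n = 1) {
    snp_i <<- snp_i + n
    sprintf("rs%06d", snp_i - n + seq_len(n))
  }
  rows <- list()
  truth <- list()
  for (d in names(planted_map)) {
    pg <- planted_map[[d]]
    strict <- runif(length(pg)) < strict_frac
    best_p <- ifelse(strict, 10^-runif(length(pg), 8.05, 12),
                     10^-runif(length(pg), 5.05, 8))
    best_snp <- new_snp(length(pg))
    rows[[paste0(d, "_planted")]] <- tibble(
      snp = best_snp, genes = pg, disease = d, p_value = best_p,
      genic_flag = TRUE)
    # secondary, weaker SNPs on a fraction of planted genes
    extra <- which(runif(length(pg)) < multi_snp_frac)
    if (length(extra)) {
      rows[[paste0(d, "_second")]] <- tibble(
        snp = new_snp(length(extra)), genes = pg[extra], disease = d,
        p_value = pmin(1, best_p[extra] * 10^runif(length(extra), 1, 4)),
        genic_flag = TRUE)
    }
    # background: genic high-p (dropped by threshold) and intergenic low-p
    # (dropped by the genic rule); intergenic genes never overlap the planted
    bg_genes <- sample(gene_ids, n_background_snps, replace = TRUE)
    inter <- runif(n_background_snps) < intergenic_frac
    p_bg <- runif(n_background_snps, 1e-5, 1)
    non_planted <- setdiff(gene_ids, pg)
    low_inter_genes <- sample(non_planted, 5)
    rows[[paste0(d, "_bg")]] <- bind_rows(
      tibble(snp = new_snp(n_background_snps), genes = bg_genes, disease = d,
             p_value = p_bg, genic_flag = !inter),
      tibble(snp = new_snp(5), genes = low_inter_genes, disease = d,
             p_value = 10^-runif(5, 5.05, 9), genic_flag = FALSE))
    truth[[d]] <- tibble(disease = d, gene = pg, best_p = best_p,
                         best_snp = best_snp)
  }
  tab <- bind_rows(rows) |>
    mutate(gene = .data$genes, genic = .data$genic_flag) |>
    select("snp", "gene", "disease", "p_value", "genic")
  list(table = tab, truth = bind_rows(truth))
}

#' Simulate disease case-control DEG tables with controlled concordance
#'
#' For each disease, a table of (gene, log2FC, adjusted p) is produced in
#' which planted genes pass the disease-DEG thresholds (|log2FC| > 0.25,
#' adjusted p < 0.05). Genes shared with the regional truth agree in sign
#' with the regional TL/FL log2FC with probability `(1 + concordance)/2`.
#'
#' @param gene_ids Gene universe.
#' @param regional_truth Tibble (`subtype`, `gene`, `log2fc`) as produced by
#'   [simulate_counts()].
#' @param concordance Sign-agreement control in `[-1, 1]`.
#' @param seed Integer seed.
#' @param diseases Disease labels.
#' @param vulnerable_subtype Which subtype's regional genes are shared.
#' @param shared_frac Fraction of that subtype's regional genes included per
#'   disease.
#' @param n_other Additional non-regional disease DEGs per disease.
#' @param n_null Filler genes failing the thresholds per disease.
#' @return List with `tables` (named list of tibbles `gene`, `log2fc`,
#'   `adj_p`), `sets` (an `rv_genesets` of passing genes) and `truth`
#'   (tibble `disease`, `gene`, `log2fc`, `sign_agrees`).
#' @export
simulate_disease_degs <- function(gene_ids, regional_truth, concordance = 0.6,
                                  seed = 1,
                                  diseases = c("BP", "OCD", "SCHI"),
                                  vulnerable_subtype = "INH-PVALB",
                                  shared_frac = 0.6, n_other = 40,
                                  n_null = 100) {
  if (concordance < -1 || concordance > 1) {
    abort("`concordance` must lie in [-1, 1]")
  }
  set.seed(seed)
  reg <- regional_truth[regional_truth$subtype == vulnerable_subtype, ]
  tables <- list()
  truth <- list()
  for (d in diseases) {
    shared <- reg[runif(nrow(reg)) < shared_frac, ]
    agree <- runif(nrow(shared)) < (1 + concordance) / 2
    sgn <- ifelse(agree, sign(shared$log2fc), -sign(shared$log2fc))
    shared_tbl <- tibble(gene = shared$gene,
                         log2fc = sgn * runif(nrow(shared), 0.3, 1.5),
                         adj_p = runif(nrow(shared), 1e-6, 0.049))
    other_genes <- sample(setdiff(gene_ids, regional_truth$gene), n_other)
    other_tbl <- tibble(gene = other_genes,
                        log2fc = sample(c(-1, 1), n_other, TRUE) *
                          runif(n_other, 0.3, 1.5),
                        adj_p = runif(n_other, 1e-6, 0.049))
    null_genes <- sample(setdiff(gene_ids, c(shared$gene, other_genes)),
                         n_null)
    null_tbl <- tibble(gene = null_genes,
                       log2fc = runif(n_null, -0.2, 0.2),
                       adj_p = runif(n_null, 0.06, 1))
    tables[[d]] <- bind_rows(shared_tbl, other_tbl, null_tbl)
    truth[[d]] <- tibble(disease = d, gene = shared$gene,
                         log2fc = shared_tbl$log2fc, sign_agrees = agree)
  }
  passing <- lapply(tables, function(t) {
    t$gene[abs(t$log2fc) > 0.25 & t$adj_p < 0.05]
  })
  list(tables = tables,
       sets = gene_sets(passing, category = "disease_deg"),
       truth = bind_rows(truth))
}
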