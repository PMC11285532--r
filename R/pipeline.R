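# pipeline configuration, study simulation wiring and stage runners
#
# All stages operate inside one working directory:
#   <dir>/inputs/   simulated or user-supplied inputs
#   <dir>/truth/    planted ground truth (simulate only)
#   <dir>/results/  stage outputs + manifest.json

#' Pipeline run configuration
#'
#' Houses every printed threshold of the analysis: QC cuts (UMI 300-4000,
#' mito 10%, detected-gene 5th-95th percentile), marker-test settings
#' (min.pct 0.1, log2FC 0.25), regional DEG thresholds (|log2FC| > 0.5,
#' FDR < 0.05), GWAS p-value tiers (1e-5 suggestive, 1e-8 strict), disease
#' DEG thresholds (|log2FC| > 0.25, adj p < 0.05), expressed-background
#' percentiles (10-90), GSEA permutations and the co-expression edge alpha.
#'
#' @param seed Integer master seed.
#' @param ... Named overrides of any default threshold.
#' @return List of class `rv_config`.
#' @export
run_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    min_umi = 300, max_umi = 4000, mito_max = 0.10,
    gene_pctile = c(5, 95),
    marker_min_pct = 0.1, marker_logfc = 0.25,
    de_logfc = 0.5, de_fdr = 0.05,
    gwas_p = 1e-5, gwas_strict_p = 1e-8,
    disease_logfc = 0.25, disease_fdr = 0.05,
    expr_pctile = c(10, 90),
    expr_filter_mode = "gene_detection",
    gsea_nperm = 1000, gsea_weight = 1,
    spearman_alpha = 0.05,
    cluster_k = 6,
    de_types = NULL
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) abort(paste0("unknown config field(s): ",
                                paste(bad, collapse = ", ")))
  cfg <- modifyList(cfg, over)
  stopifnot(cfg$min_umi > 0, cfg$max_umi > cfg$min_umi,
            cfg$mito_max > 0,
            cfg$gene_pctile[1] < cfg$gene_pctile[2],
            all(cfg$gene_pctile >= 0 & cfg$gene_pctile <= 100),
            cfg$expr_pctile[1] < cfg$expr_pctile[2],
            all(cfg$expr_pctile >= 0 & cfg$expr_pctile <= 100),
            cfg$gwas_p > 0, cfg$gwas_strict_p > 0,
            cfg$gsea_nperm > 0)
  structure(cfg, class = c("rv_config", "list"))
}

#' Simulate a complete study into a working directory
#'
#' Generates the count matrix (with planted markers and regional effects),
#' the GWAS table (planted per-disease gene sets, including a pan-disorder
#' common set and a block overlapping the vulnerable subtype's TL-upregulated
#' genes), drug-target classes with a planted 2:1 drug:GWAS overlap into
#' those genes, pathway and reference-marker collections, and disease DEG
#' tables; writes everything plus the truth tables under `dir`.
#'
#' @param dir Working directory.
#' @param seed Integer seed.
#' @param sim A [sim_config()].
#' @param n_gwas_overlap Planted GWAS genes among the vulnerable subtype's
#'   TL-up genes (default 20).
#' @param drug_gwas_ratio Drug:GWAS planted overlap ratio (default 2).
#' @param n_common Pan-disorder genes planted in all seven diseases.
#' @param concordance_level Sign-agreement control for the disease DEG
#'   tables (default 0.6).
#' @return Invisibly, a list with the simulated objects and truth.
#' @export
simulate_study <- function(dir, seed = 1, sim = sim_config(),
                           n_gwas_overlap = 20, drug_gwas_ratio = 2,
                           n_common = 10, concordance_level = 0.6) {
  inputs <- file.path(dir, "inputs")
  truth_dir <- file.path(dir, "truth")
  dir.create(inputs, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(inputs, "disease_degs"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(truth_dir, recursive = TRUE, showWarnings = FALSE)

  counts_sim <- simulate_counts(sim, seed = seed)
  cm <- counts_sim$counts
  truth <- counts_sim$truth
  genes <- cm$gene_meta$gene
  reg <- truth$regional_map
  vuln_up <- reg$gene[reg$subtype == sim$vulnerable_subtype & reg$log2fc > 0]

  set.seed(seed + 1000L)
  diseases <- c("BP", "ASD", "SCHI", "ADHD", "OCD", "UD", "CI")
  n_gwas_overlap <- min(n_gwas_overlap, length(vuln_up))
  gwas_vuln <- sample(vuln_up, n_gwas_overlap)
  nonregional <- setdiff(genes, c(reg$gene, truth$mito_genes))
  common <- c(sample(gwas_vuln, min(4, n_gwas_overlap)),
              sample(nonregional, max(0, n_common - 4)))
  planted_map <- lapply(setNames(diseases, diseases), function(d) {
    extra <- sample(setdiff(nonregional, common), 15)
    vuln_share <- sample(gwas_vuln, ceiling(n_gwas_overlap / 2))
    unique(c(common, vuln_share, extra))
  })
  # every vulnerable-overlap gene must appear in at least one disease
  leftover <- setdiff(gwas_vuln, unique(unlist(planted_map)))
  if (length(leftover)) {
    planted_map[[1]] <- unique(c(planted_map[[1]], leftover))
  }
  gwas_sim <- simulate_gwas_table(genes, planted_map, seed = seed + 2000L)

  # drug classes: planted block in the vulnerable subtype's TL-up genes at
  # drug_gwas_ratio times the GWAS overlap, split across seven classes
  set.seed(seed + 3000L)
  classes <- c("SSRI", "DA", "TCA", "BZD", "MAOI", "GABA", "ARA")
  n_drug <- min(round(drug_gwas_ratio * n_gwas_overlap), length(vuln_up))
  drug_vuln <- sample(vuln_up, n_drug)
  split_idx <- rep_len(seq_along(classes), n_drug)
  drug_sets <- lapply(setNames(seq_along(classes), classes), function(i) {
    unique(c(drug_vuln[split_idx == i], sample(nonregional, 15)))
  })
  drugs <- gene_sets(drug_sets, category = "drug")

  # pathways: planted sets enriched in markers / regional genes plus nulls
  set.seed(seed + 4000L)
  mk <- truth$marker_map
  # three synapse-flavoured pathways sampled from the vulnerable subtype's
  # TL-up genes so they overlap one another (Jaccard edges) and the GWAS
  # selection (ORA signal); two identity pathways follow the marker blocks
  synapse_pick <- function() {
    unique(c(sample(gwas_vuln, min(10, length(gwas_vuln))),
             sample(vuln_up, min(8, length(vuln_up))),
             sample(nonregional, 6)))
  }
  pw <- list(
    SYNAPSE_VESICLE_CYCLE = synapse_pick(),
    SYNAPSE_GABAERGIC = synapse_pick(),
    SIGNALING_CALCIUM = synapse_pick(),
    NEURO_EX_IDENTITY = unique(c(mk$gene[mk$cell_type == "EX"],
                                 sample(nonregional, 5))),
    NEURO_INH_IDENTITY = unique(c(mk$gene[mk$cell_type == "INH"],
                                  sample(nonregional, 5)))
  )
  for (i in seq_len(17)) {
    pw[[sprintf("NULL_PATHWAY_%02d", i)]] <- sample(genes, sample(15:40, 1))
  }
  pathways <- gene_sets(pw, category = "pathway")

  refs <- split(mk$gene, mk$cell_type)
  refs <- lapply(refs, function(g) {
    unique(c(sample(g, min(15, length(g))), sample(nonregional, 5)))
  })
  reference <- gene_sets(refs, category = "marker_reference")

  degs <- simulate_disease_degs(genes, reg, concordance = concordance_level,
                                seed = seed + 5000L,
                                diseases = c("BP", "OCD", "SCHI"),
                                vulnerable_subtype = sim$vulnerable_subtype)

  # write inputs
  write_10x(cm, file.path(inputs, "counts"))
  write_gwas_table(gwas_sim$table, file.path(inputs, "gwas.tsv"))
  write_gmt(drugs, file.path(inputs, "drugs.gmt"))
  write_gmt(pathways, file.path(inputs, "pathways.gmt"))
  write_gmt(reference, file.path(inputs, "reference_markers.gmt"))
  for (d in names(degs$tables)) {
    readr::write_tsv(degs$tables[[d]],
                     file.path(inputs, "disease_degs", paste0(d, ".tsv")))
  }

  # write truth
  readr::write_tsv(truth$marker_map, file.path(truth_dir, "marker_map.tsv"))
  readr::write_tsv(truth$regional_map,
                   file.path(truth_dir, "regional_map.tsv"))
  readr::write_tsv(gwas_sim$truth, file.path(truth_dir, "gwas_truth.tsv"))
  readr::write_tsv(degs$truth, file.path(truth_dir, "disease_deg_truth.tsv"))
  readr::write_tsv(tibble(gene = drug_vuln),
                   file.path(truth_dir, "drug_overlap_truth.tsv"))
  readr::write_lines(truth$doublets, file.path(truth_dir, "doublets.txt"))
  readr::write_tsv(tibble(vulnerable_subtype = sim$vulnerable_subtype,
                          n_gwas_overlap = n_gwas_overlap,
                          n_drug_overlap = n_drug),
                   file.path(truth_dir, "design.tsv"))

  invisible(list(counts = cm, truth = truth, gwas = gwas_sim,
                 drugs = drugs, pathways = pathways, reference = reference,
                 disease_degs = degs))
}

# ---- stage runners -------------------------------------------------------

res_path <- function(dir, ...) {
  p <- file.path(dir, "results", ...)
  dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
  p
}

require_input <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("missing input: ", path), class = "rv_missing_input")
  }
  path
}

stage_qc <- function(dir, cfg) {
  cm <- read_10x(require_input(file.path(dir, "inputs", "counts")))
  qc <- filter_cells(cm, min_umi = cfg$min_umi, max_umi = cfg$max_umi,
                     mito_max = cfg$mito_max, gene_pctile = cfg$gene_pctile)
  write_10x(qc$counts, res_path(dir, "filtered"))
  jsonlite::write_json(
    c(glance(qc$report), list(thresholds = qc$report$thresholds)),
    res_path(dir, "qc_report.json"), auto_unbox = TRUE, digits = NA)
  scopes <- unique(c("global", qc$counts$cell_meta$major_type,
                     qc$counts$cell_meta$subtype))
  bg_dir <- res_path(dir, "backgrounds")
  dir.create(bg_dir, showWarnings = FALSE)
  for (s in scopes) {
    bg <- expressed_background(qc$counts, s, pctile = cfg$expr_pctile,
                               mode = cfg$expr_filter_mode)
    readr::write_lines(bg$genes, file.path(bg_dir, paste0(s, ".txt")))
  }
  invisible(qc)
}

read_filtered <- function(dir) {
  read_10x(require_input(file.path(dir, "results", "filtered")))
}

read_background <- function(dir, scope) {
  readr::read_lines(require_input(
    file.path(dir, "results", "backgrounds", paste0(scope, ".txt"))))
}

stage_markers <- function(dir, cfg) {
  cm <- read_filtered(dir)
  norm <- lognormalize(cm)
  mk <- find_markers(norm, cm$cell_meta$major_type,
                     min_pct = cfg$marker_min_pct,
                     logfc_min = cfg$marker_logfc)
  readr::write_tsv(mk, res_path(dir, "markers.tsv"))
  ref_path <- file.path(dir, "inputs", "reference_markers.gmt")
  if (file.exists(ref_path)) {
    refs <- read_gmt(ref_path, category = "marker_reference")
    ov <- marker_overlap_check(mk, refs, read_background(dir, "global"))
    readr::write_tsv(ov, res_path(dir, "marker_overlap.tsv"))
  }
  invisible(mk)
}

stage_regional_de <- function(dir, cfg, types = NULL) {
  cm <- read_filtered(dir)
  types <- types %||% cfg$de_types %||%
    sort(unique(c(cm$cell_meta$major_type, cm$cell_meta$subtype)))
  de <- regional_de(cm, types = types, seed = cfg$seed,
                    lfc_min = cfg$de_logfc, fdr_max = cfg$de_fdr)
  readr::write_tsv(de, res_path(dir, "regional_de.tsv"))
  cl <- tryCatch(cluster_logfc(de, k = cfg$cluster_k),
                 error = function(e) NULL)
  if (!is.null(cl)) {
    readr::write_tsv(cl$assignment, res_path(dir, "logfc_clusters.tsv"))
  }
  # regional cell-composition test
  tab <- table(cm$cell_meta$major_type, cm$cell_meta$region)
  if (ncol(tab) == 2) {
    readr::write_tsv(chisq_proportions(unclass(tab)),
                     res_path(dir, "composition_chisq.tsv"))
  }
  invisible(de)
}

read_regional_de <- function(dir) {
  readr::read_tsv(require_input(file.path(dir, "results", "regional_de.tsv")),
                  col_types = readr::cols(), progress = FALSE)
}

stage_gwas_select <- function(dir, cfg) {
  gwas <- read_gwas_table(require_input(file.path(dir, "inputs", "gwas.tsv")))
  bg <- read_background(dir, "global")
  sel <- gwas_select(gwas, bg, p_max = cfg$gwas_p)
  strict <- gwas_select(gwas, bg, p_max = cfg$gwas_strict_p)
  readr::write_tsv(sel$genes, res_path(dir, "gwas_genes.tsv"))
  readr::write_tsv(strict$genes, res_path(dir, "gwas_genes_strict.tsv"))
  jsonlite::write_json(
    list(per_disease = lapply(sel$sets, length),
         union = length(sel$union),
         intersection = length(sel$intersection)),
    res_path(dir, "gwas_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(sel)
}

read_gwas_sets <- function(dir, strict = FALSE) {
  f <- if (strict) "gwas_genes_strict.tsv" else "gwas_genes.tsv"
  g <- readr::read_tsv(require_input(file.path(dir, "results", f)),
                       col_types = readr::cols(), progress = FALSE)
  split(g$gene, g$disease)
}

# TL-upregulated DEG lists per analysed type
tl_up_sets <- function(de, lfc_min = 0.5) {
  degs <- de[de$is_deg & de$log2fc > lfc_min, ]
  split(degs$gene, degs$cell_type)
}

# per-type enrichment against per-type expressed backgrounds, BH within the
# combined family table
enrich_family <- function(dir, query_sets, sets_by_type, family) {
  rows <- lapply(names(sets_by_type), function(ct) {
    bg <- tryCatch(read_background(dir, ct), error = function(e) NULL)
    if (is.null(bg)) return(NULL)
    et <- enrich_table(query_sets,
                       setNames(list(sets_by_type[[ct]]), "tl_up"), bg)
    et$cell_type <- ct
    et
  })
  fam <- bind_rows(rows)
  if (nrow(fam)) {
    fam$adj_p <- bh_adjust(fam$p_value)
    fam$score <- -log10(fam$adj_p)
    fam$family <- family
  }
  fam
}

stage_enrich <- function(dir, cfg) {
  de <- read_regional_de(dir)
  up <- tl_up_sets(de, lfc_min = cfg$de_logfc)
  gwas_sets <- read_gwas_sets(dir)
  out <- list()

  # GWAS x markers (per major type, global background)
  mk_path <- file.path(dir, "results", "markers.tsv")
  if (file.exists(mk_path)) {
    mk <- readr::read_tsv(mk_path, col_types = readr::cols(),
                          progress = FALSE)
    sig <- mk[mk$adj_p < 0.05, ]
    marker_sets <- split(sig$gene, sig$cell_type)
    em <- enrich_table(gwas_sets, marker_sets, read_background(dir, "global"))
    em$cell_type <- em$target
    em$family <- "gwas_markers"
    out$markers <- em
  }

  # GWAS / drug / disease-DEG sets x TL-up DEGs per type
  out$gwas <- enrich_family(dir, gwas_sets, up, "gwas_tl_up")
  drugs <- read_gmt(require_input(file.path(dir, "inputs", "drugs.gmt")),
                    category = "drug")
  out$drugs <- enrich_family(dir, drugs$sets, up, "drug_tl_up")

  deg_dir <- file.path(dir, "inputs", "disease_degs")
  if (dir.exists(deg_dir)) {
    tabs <- read_disease_tables(deg_dir)
    dis_sets <- lapply(tabs, function(t) {
      dd <- disease_deg_filter(t, cfg$disease_logfc, cfg$disease_fdr)
      c(dd$up, dd$down)
    })
    out$disease <- enrich_family(dir, dis_sets, up, "disease_tl_up")
  }
  enr <- bind_rows(out)
  readr::write_tsv(enr, res_path(dir, "enrichment.tsv"))
  invisible(enr)
}

read_disease_tables <- function(deg_dir) {
  files <- list.files(deg_dir, pattern = "\\.tsv$", full.names = TRUE)
  tabs <- lapply(files, readr::read_tsv, col_types = readr::cols(),
                 progress = FALSE)
  names(tabs) <- sub("\\.tsv$", "", basename(files))
  tabs
}

stage_gsea <- function(dir, cfg) {
  cm <- read_filtered(dir)
  norm <- lognormalize(cm)
  labels <- cm$cell_meta$major_type
  pathways <- read_gmt(require_input(
    file.path(dir, "inputs", "pathways.gmt")))
  out <- lapply(intersect(c("EX", "INH"), unique(labels)), function(ct) {
    stats <- rank_genes_vs_rest(norm, labels, ct)
    g <- gsea_preranked(stats, pathways, nperm = cfg$gsea_nperm,
                        weight = cfg$gsea_weight, seed = cfg$seed)
    if (nrow(g)) g$cell_type <- ct
    g
  })
  g <- bind_rows(out)
  if (nrow(g)) {
    g$leading_edge <- vapply(g$leading_edge, paste, "", collapse = ",")
  }
  readr::write_tsv(g, res_path(dir, "gsea.tsv"))
  invisible(g)
}

stage_network <- function(dir, cfg) {
  # pathway similarity network from ORA of the GWAS union
  gwas_sets <- read_gwas_sets(dir)
  pathways <- read_gmt(require_input(
    file.path(dir, "inputs", "pathways.gmt")))
  bg <- read_background(dir, "global")
  ora <- ora_pathways(unique(unlist(gwas_sets)), pathways, bg,
                      query_name = "gwas_union")
  readr::write_tsv(ora, res_path(dir, "pathway_ora.tsv"))
  annot <- setNames(sub("_.*$", "", names(pathways$sets)),
                    names(pathways$sets))
  pn <- pathway_network(ora, pathways, annotation = annot)
  write_graph_files(pn, res_path(dir, "network_edges.tsv"),
                    res_path(dir, "network.graphml"))

  # co-expression network of GWAS genes inside the most vulnerable subtype
  de <- read_regional_de(dir)
  up <- tl_up_sets(de, lfc_min = cfg$de_logfc)
  if (length(up)) {
    cm <- read_filtered(dir)
    norm <- lognormalize(cm)
    focus <- names(which.max(vapply(up, function(g) {
      length(intersect(g, unique(unlist(gwas_sets))))
    }, 1)))
    genes <- intersect(up[[focus]], unique(unlist(gwas_sets)))
    if (length(genes) >= 2) {
      cx <- coexpression_network(norm, cm, genes, cell_scope = focus,
                                 alpha = cfg$spearman_alpha)
      write_graph_files(cx, res_path(dir, "coexpression_edges.tsv"),
                        res_path(dir, "coexpression.graphml"))
    }
  }
  invisible(pn)
}

stage_concordance <- function(dir, cfg) {
  de <- read_regional_de(dir)
  tabs <- read_disease_tables(require_input(
    file.path(dir, "inputs", "disease_degs")))
  types <- unique(de$cell_type)
  bgs <- lapply(setNames(types, types), function(ct) {
    tryCatch(read_background(dir, ct),
             error = function(e) read_background(dir, "global"))
  })
  strict <- read_gwas_sets(dir, strict = TRUE)
  drugs <- read_gmt(require_input(file.path(dir, "inputs", "drugs.gmt")),
                    category = "drug")
  cc <- concordance(de, tabs, bgs,
                    lfc_min = cfg$disease_logfc, fdr_max = cfg$disease_fdr,
                    flag_sets = list(gwas_strict = unique(unlist(strict)),
                                     drug_target = unique(unlist(drugs$sets))))
  readr::write_tsv(cc$summary, res_path(dir, "concordance.tsv"))
  readr::write_tsv(cc$shared, res_path(dir, "concordance_genes.tsv"))
  invisible(cc)
}

stage_vulnerability <- function(dir, cfg) {
  de <- read_regional_de(dir)
  up <- tl_up_sets(de, lfc_min = cfg$de_logfc)
  gwas_sets <- read_gwas_sets(dir)
  drugs <- read_gmt(require_input(file.path(dir, "inputs", "drugs.gmt")),
                    category = "drug")
  # drug targets pass through the same expressed-gene filter as the GWAS
  # selection so the two overlap fractions are comparable
  bg <- read_background(dir, "global")
  drug_sets <- lapply(drugs$sets, intersect, bg)
  vc <- vulnerability_contrast(up, gwas_sets, drug_sets)
  readr::write_tsv(vc$summary, res_path(dir, "vulnerability.tsv"))
  readr::write_tsv(vc$per_set, res_path(dir, "vulnerability_per_set.tsv"))
  # rank types by the GWAS enrichment score of their TL-up genes
  top_by_score <- NA_character_
  enr_path <- file.path(dir, "results", "enrichment.tsv")
  if (file.exists(enr_path)) {
    enr <- readr::read_tsv(enr_path, col_types = readr::cols(),
                           progress = FALSE)
    fam <- enr[enr$family == "gwas_tl_up", ]
    if (nrow(fam)) {
      sc <- fam |>
        group_by(.data$cell_type) |>
        summarise(score = max(.data$score), .groups = "drop") |>
        arrange(dplyr::desc(.data$score))
      top_by_score <- sc$cell_type[1]
    }
  }
  jsonlite::write_json(
    list(summary = vc$summary,
         top_gwas_enriched_type = top_by_score),
    res_path(dir, "vulnerability.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(vc)
}

write_manifest <- function(dir, cfg) {
  dir.create(file.path(dir, "results"), recursive = TRUE,
             showWarnings = FALSE)
  files <- sort(list.files(file.path(dir, c("inputs", "results")),
                           recursive = TRUE, full.names = TRUE))
  files <- files[!grepl("manifest\\.json$", files)]
  sums <- tools::md5sum(files)
  dirn <- normalizePath(dir)
  rel <- substring(normalizePath(files), nchar(dirn) + 2)
  jsonlite::write_json(
    list(seed = cfg$seed,
         config = unclass(cfg),
         package_version = as.character(utils::packageVersion("regionvuln")),
         r_version = R.version.string,
         files = setNames(as.list(unname(sums)), rel)),
    file.path(dir, "results", "manifest.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "results", "manifest.json"))
}

#' Run pipeline stages in a working directory
#'
#' @param dir Working directory (created if needed).
#' @param stages Character vector of stage names, in the order
#'   `simulate`, `qc`, `markers`, `regional-de`, `gwas-select`, `enrich`,
#'   `gsea`, `network`, `concordance`, `vulnerability`; `"all"` runs the
#'   full sequence.
#' @param cfg A [run_config()].
#' @param sim A [sim_config()] used by the `simulate` stage.
#' @return Invisibly, `dir`.
#' @export
run_pipeline <- function(dir, stages = "all", cfg = run_config(),
                         sim = sim_config()) {
  order <- c("simulate", "qc", "markers", "regional-de", "gwas-select",
             "enrich", "gsea", "network", "concordance", "vulnerability")
  if (identical(stages, "all")) stages <- order
  bad <- setdiff(stages, order)
  if (length(bad)) abort(paste0("unknown stage: ", bad[1]))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in intersect(order, stages)) {
    t0 <- Sys.time()
    message(sprintf("[regionvuln] stage %s ...", s))
    switch(s,
      "simulate" = simulate_study(dir, seed = cfg$seed, sim = sim),
      "qc" = stage_qc(dir, cfg),
      "markers" = stage_markers(dir, cfg),
      "regional-de" = stage_regional_de(dir, cfg),
      "gwas-select" = stage_gwas_select(dir, cfg),
      "enrich" = stage_enrich(dir, cfg),
      "gsea" = stage_gsea(dir, cfg),
      "network" = stage_network(dir, cfg),
      "concordance" = stage_concordance(dir, cfg),
      "vulnerability" = stage_vulnerability(dir, cfg))
    message(sprintf("[regionvuln] stage %s done in %.1fs", s,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  write_manifest(dir, cfg)
  invisible(dir)
}
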