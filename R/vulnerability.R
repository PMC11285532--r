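# concordance quadrants and the GWAS-vs-drug vulnerability contrast

#' Threshold a disease DEG table into up/down gene sets
#'
#' Keeps genes with `|log2FC| > lfc_min` and `adjusted p < fdr_max`, split by
#' sign of the fold change.
#'
#' @param table Tibble with columns `gene`, `log2fc`, `adj_p`.
#' @param lfc_min Absolute log2FC cut (default 0.25).
#' @param fdr_max Adjusted-p cut (default 0.05).
#' @return List with `up`, `down` (character vectors) and `n_in`, `n_kept`.
#' @export
disease_deg_filter <- function(table, lfc_min = 0.25, fdr_max = 0.05) {
  need <- c("gene", "log2fc", "adj_p")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    abort(paste0("DEG table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  kept <- table |> filter(abs(.data$log2fc) > lfc_min,
                          .data$adj_p < fdr_max)
  list(up = sort(kept$gene[kept$log2fc > 0]),
       down = sort(kept$gene[kept$log2fc < 0]),
       n_in = nrow(table), n_kept = nrow(kept))
}

#' Concordance of regional and disease differential expression
#'
#' For each (cell type, disease) pair: tests the overlap of the regional DEG
#' set with the disease DEG set (hypergeometric upper tail against the
#' expressed background, BH across pairs), and splits the shared genes into
#' sign quadrants of (regional log2FC, disease log2FC). Shared genes with a
#' zero fold change on either axis cannot be signed and are excluded from
#' the quadrant denominators. Genes also present in `flag_sets` (e.g. a
#' strict GWAS tier or the drug-target union) are flagged.
#'
#' @param regional Tibble from [regional_de()].
#' @param disease_tables Named list of disease DEG tibbles (`gene`, `log2fc`,
#'   `adj_p`).
#' @param background Character vector (or `rv_background`) of expressed
#'   genes, or a named list of such vectors keyed by cell type (per-type
#'   backgrounds, the convention used for the enrichment tests).
#' @param lfc_min,fdr_max Disease DEG thresholds passed to
#'   [disease_deg_filter()].
#' @param flag_sets Optional named list of gene sets used to flag shared
#'   genes.
#' @return List with `summary` (tibble `cell_type`, `disease`, overlap
#'   margins, p-values and quadrant fractions) and `shared` (tibble of
#'   per-gene records with both fold changes and flags).
#' @export
concordance <- function(regional, disease_tables, background,
                        lfc_min = 0.25, fdr_max = 0.05, flag_sets = NULL) {
  bg_for <- function(ct) {
    bg <- if (is.list(background) && !inherits(background, "rv_background")) {
      background[[ct]] %||% abort(paste0("no background for type ", ct))
    } else background
    if (inherits(bg, "rv_background")) bg <- bg$genes
    unique(bg)
  }
  types <- sort(unique(regional$cell_type))
  rows <- list()
  shared_rows <- list()
  for (ct in types) {
    bg <- bg_for(ct)
    reg <- regional |> filter(.data$cell_type == ct, .data$is_deg)
    reg_genes <- intersect(reg$gene, bg)
    for (d in names(disease_tables)) {
      dd <- disease_deg_filter(disease_tables[[d]], lfc_min, fdr_max)
      dis_genes <- intersect(c(dd$up, dd$down), bg)
      if (length(dis_genes) == 0) {
        warn(paste0("empty disease DEG set for ", d))
        rows[[paste(ct, d)]] <- tibble(
          cell_type = ct, disease = d, k = NA_integer_,
          q = length(reg_genes), t = 0L, N = length(bg),
          p_value = NA_real_, up_up = NA_real_, up_down = NA_real_,
          down_up = NA_real_, down_down = NA_real_)
        next
      }
      sh <- intersect(reg_genes, dis_genes)
      dtab <- disease_tables[[d]]
      sh_tbl <- tibble(cell_type = ct, disease = d, gene = sh,
                       log2fc_region = reg$log2fc[match(sh, reg$gene)],
                       log2fc_disease = dtab$log2fc[match(sh, dtab$gene)])
      if (!is.null(flag_sets)) {
        for (fs in names(flag_sets)) {
          sh_tbl[[paste0("in_", fs)]] <- sh %in% flag_sets[[fs]]
        }
      }
      shared_rows[[paste(ct, d)]] <- sh_tbl
      signed <- sh_tbl |> filter(.data$log2fc_region != 0,
                                 .data$log2fc_disease != 0)
      nsigned <- nrow(signed)
      quad <- function(sr, sd) {
        if (nsigned == 0) return(NA_real_)
        sum(sign(signed$log2fc_region) == sr &
              sign(signed$log2fc_disease) == sd) / nsigned
      }
      rows[[paste(ct, d)]] <- tibble(
        cell_type = ct, disease = d, k = length(sh),
        q = length(reg_genes), t = length(dis_genes),
        N = length(bg),
        p_value = hypergeom_upper(length(sh), length(reg_genes),
                                  length(dis_genes), length(bg)),
        up_up = quad(1, 1), up_down = quad(1, -1),
        down_up = quad(-1, 1), down_down = quad(-1, -1))
    }
  }
  summary <- bind_rows(rows)
  summary$adj_p <- NA_real_
  ok <- !is.na(summary$p_value)
  summary$adj_p[ok] <- bh_adjust(summary$p_value[ok])
  list(summary = summary, shared = bind_rows(shared_rows))
}

#' GWAS-vs-drug vulnerability contrast per cell (sub)type
#'
#' For each type's TL-upregulated DEG list: the fraction overlapping the
#' GWAS gene union, the fraction overlapping the drug-target union, the fold
#' contrast (drug fraction over GWAS fraction, defined only when the GWAS
#' fraction is positive), and per-disease / per-class breakdowns.
#'
#' @param up_genes_by_type Named list: TL-upregulated genes per (sub)type.
#' @param gwas_sets Named list of per-disease GWAS gene vectors (unioned
#'   internally; duplicates across sets are deduplicated).
#' @param drug_sets Named list of per-class drug-target vectors.
#' @return List with `summary` (tibble per type) and `per_set` (tibble per
#'   type x set with class/disease-level overlaps).
#' @export
vulnerability_contrast <- function(up_genes_by_type, gwas_sets, drug_sets) {
  gwas_union <- unique(unlist(gwas_sets))
  drug_union <- unique(unlist(drug_sets))
  per_set <- list()
  rows <- lapply(names(up_genes_by_type), function(ct) {
    up <- unique(up_genes_by_type[[ct]])
    n_up <- length(up)
    if (n_up == 0) {
      return(tibble(cell_type = ct, n_up = 0L, n_gwas = NA_integer_,
                    frac_gwas = NA_real_, n_drug = NA_integer_,
                    frac_drug = NA_real_, fold_contrast = NA_real_))
    }
    n_g <- length(intersect(up, gwas_union))
    n_d <- length(intersect(up, drug_union))
    fg <- n_g / n_up
    fd <- n_d / n_up
    per_set[[ct]] <<- bind_rows(
      tibble(cell_type = ct, family = "gwas", set = names(gwas_sets),
             k = vapply(gwas_sets, function(s) length(intersect(up, s)), 1L),
             n_up = n_up),
      tibble(cell_type = ct, family = "drug", set = names(drug_sets),
             k = vapply(drug_sets, function(s) length(intersect(up, s)), 1L),
             n_up = n_up))
    tibble(cell_type = ct, n_up = n_up, n_gwas = n_g, frac_gwas = fg,
           n_drug = n_d, frac_drug = fd,
           fold_contrast = if (fg > 0) fd / fg else NA_real_)
  })
  list(summary = bind_rows(rows),
       per_set = bind_rows(per_set) |> mutate(frac = .data$k / .data$n_up))
}
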