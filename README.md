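# regionvuln

Mapping which brain cell types are vulnerable to neuropsychiatric disease
genes and to psychoactive drugs, from regional single-nucleus RNA-seq.

Cortical regions differ: the temporal lobe (TL) and frontal lobe (FL) carry
distinct cell-type-resolved expression programs, and those differences shape
how strongly each cell population is exposed to genetic risk and to drug
action. `regionvuln` implements the full integrative analysis as a tested,
reusable pipeline:

1. **QC and normalization** of a genes × cells UMI matrix: cells kept with
   total UMI in \[300, 4000\], mitochondrial fraction ≤ 10%, detected-gene
   count inside the 5th–95th percentile band, doublets dropped; counts
   log-normalized as `ln(1 + 10^4 · c/total)`.
2. **Markers**: one-vs-rest logistic regression with a likelihood-ratio test
   (`min.pct = 0.1`, avg log2FC ≥ 0.25, positive only), corroborated against
   reference marker sets by a hypergeometric overlap test.
3. **Regional differential expression**: per cell (sub)type, regions are
   balanced by downsampling, then a negative-binomial GLM with TMM offsets,
   empirical-Bayes dispersion shrinkage and quasi-likelihood F-tests (edgeR)
   calls DEGs at |log2FC| > 0.5 and FDR < 0.05; the union of DEG log-FC
   profiles is hierarchically clustered (Euclidean, complete linkage, k = 6).
4. **GWAS gene selection**: genic records only, association p ≤ 1e-5 (strict
   tier 1e-8), lowest-p SNP per gene per disease, intersected with an
   expression-aware background — genes whose detection count lies inside the
   10th–90th percentile of the detection-count distribution.
5. **Enrichment**: hypergeometric upper-tail tests of GWAS, drug-target and
   disease-DEG sets against each (sub)type's TL-upregulated genes, with
   per-type expressed backgrounds and BH adjustment; the *enrichment score*
   is `-log10(adjusted p)`.
6. **Preranked GSEA** (weighted Kolmogorov–Smirnov running sum, gene-label
   permutation null, `NES = ES / mean |null ES| of matching sign`).
7. **Networks**: Jaccard similarity network over significant pathways, and
   Spearman co-expression networks within a cell scope (edges at p < 0.05).
8. **Vulnerability contrast**: per (sub)type, the fraction of TL-upregulated
   genes overlapping the GWAS union versus the drug-target union, and their
   ratio (the drug-vs-GWAS fold contrast).

Because raw tissue data cannot ship with a package, a first-class
synthetic-data module generates NB-distributed UMI matrices with planted
marker structure, region-specific fold changes concentrated in a designated
vulnerable subtype (PVALB interneurons by default), GWAS tables whose
post-selection gene sets equal a planted map exactly, drug-target classes
with a planted 2:1 drug:GWAS overlap, and disease DEG tables with controlled
sign concordance — so every stage has a recovery test against recorded truth.

## Worked example

```r
library(regionvuln)

study <- simulate_study(tempfile(), seed = 42)   # writes inputs + truth
qc    <- filter_cells(study$counts)
glance(qc$report)
#> # A tibble: 1 x 6
#>   n_cells_in n_removed_umi n_removed_mito n_removed_gene_pctile ...
#> 1       3150            70            299                   273

expressed_background(qc$counts, "INH-PVALB")
#> <rv_background> scope=INH-PVALB, 812 genes, detection in [40.9, 153.0]
```

Or run everything at once and read the integrated result:

```r
d <- tempfile()
run_pipeline(d, cfg = run_config(seed = 42))
readr::read_tsv(file.path(d, "results", "vulnerability.tsv"))
#>   cell_type  n_up n_gwas frac_gwas n_drug frac_drug fold_contrast
#> 1 INH-PVALB    31      8     0.258     13     0.419          1.62
#> 2 EX-L2-3       7      0     0          0     0             NA
#> ...
```

Here 31 genes are significantly TL-upregulated in PVALB interneurons; 25.8%
of them are selected GWAS genes and 41.9% are psychoactive-drug targets, a
1.62-fold larger drug contribution in this single run (the planted
generating ratio is 2:1; single-seed estimates scatter around it). PVALB is
ranked top among all subtypes by the GWAS enrichment score, recovering the
planted vulnerable subtype.

The same stages are available from a shell:

```sh
exec/regionvuln all --seed 7 --out run1        # full pipeline
exec/regionvuln qc --out run1 --min_umi 200    # one stage, threshold override
```

All outputs are TSV/JSON (plus GraphML for networks) under
`<out>/results/`, with a `manifest.json` listing every file with its
checksum; runs with the same seed and inputs are byte-identical.

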