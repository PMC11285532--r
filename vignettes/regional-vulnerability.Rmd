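---
title: "Methods: regional cell-type vulnerability to disease genes and drug targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional cell-type vulnerability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regionvuln)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the parameters that matter, what the
synthetic data emulate and do not, and the numerical choices made where the
design was genuinely open.

## The scientific question

Single-nucleus RNA-seq of two cortical regions — temporal lobe (TL) and
frontal lobe (FL) — resolves, per cell type and neuronal subtype, which genes
are regionally regulated. Intersecting each subtype's TL-upregulated genes
with (i) GWAS genes for neuropsychiatric disorders, (ii) genes dysregulated
in diseased brain tissue, and (iii) psychoactive drug-target sets quantifies
how exposed each cell population is to genetic risk and to pharmacology, and
whether that exposure is regional. The package's headline output is the
**vulnerability contrast**: per subtype, the fraction of TL-upregulated genes
that are GWAS genes, the fraction that are drug targets, and their ratio.

## Quality control and normalization

Cells are kept when total UMI lies in `[min_umi, max_umi]` (defaults 300 and
4000, inclusive), mitochondrial fraction is at most 10%, and the number of
detected genes falls inside the 5th–95th percentile band of the distribution
among cells passing the first two rules; flagged doublets are then dropped.
Rules apply in that fixed order and each removed cell is charged to the first
rule it fails, so the QC report's categories are additive. Percentiles use
linear interpolation between order statistics (type 7) throughout the
package: a stated, reproducible convention.

One subtlety: re-applying a percentile rule to its own output is not a
no-op, because the percentile band of a truncated distribution moves inward.
The report therefore echoes the *realized* absolute detected-gene bounds,
and `filter_cells(gene_bounds =)` re-applies the filter at those bounds
verbatim — that is the operational sense in which the filter is idempotent.

Normalization is `ln(1 + count × 10^4 / cell_total)`. Natural log is the
single-cell toolchain convention; the base only rescales log-FC units
uniformly. Zero stays zero and sparsity is preserved.

**Expressed backgrounds.** Enrichment tests need an expression-aware gene
universe. A gene is "expressed" in a scope (all cells, or one (sub)type)
when its detection count lies inside the 10th–90th percentile of the
detection-count distribution over genes detected at least once in that
scope. The description of the source procedure admits a second reading —
restrict to *cells* inside per-cell percentile bands of detected genes and
total UMI, then require one count — and `expressed_background(mode =
"cell_percentile")` implements it; the gene-detection reading is the default
because it is the one stated operationally. Widening the band never removes
genes (monotonicity), which the tests assert.

## Markers and the marker cross-check

One-vs-rest markers use logistic regression of group membership on the
normalized expression of each gene passing two pre-filters: detected in at
least `min.pct = 0.1` of either group, and average log2 fold change at
least 0.25 in the group. The p-value is the likelihood-ratio test against
the intercept-only model; BH adjustment is within cell type; only positive
markers are reported. The average log2FC is computed on `expm1` of the
normalized values with pseudocount 1 — the single-cell convention — stated
explicitly because conventions differ. An independent Newton/BFGS
maximum-likelihood oracle in the tests pins the LR statistic to 1e-6.

Detected marker sets are corroborated against reference marker collections
by the hypergeometric upper tail within an expressed background.

## Regional differential expression

Region imbalance (two TL subjects, one FL) would bias per-type comparisons,
so each analysed type is first balanced by uniform, seeded downsampling to
the smaller region count. The test is a negative-binomial GLM with
`Var = μ + φμ²`: TMM normalization factors as offsets, common dispersion by
the pooled adjusted profile likelihood, tagwise dispersions shrunk toward
the common value by empirical Bayes with prior df 10, and a
quasi-likelihood F-test for the region coefficient. These steps are
standard and delegated to edgeR behind the package's function surface
(`tmm_factors()`, `fit_dispersion()`, `nb_de_test()`); dispersion shrinkage
uses no abundance trend so that the prior-df → ∞ limit collapses tagwise
onto the common value, and the internal likelihood grid keeps every gene so
the no-trend path is dimensionally consistent. DEGs are `|log2FC| > 0.5`
and `FDR < 0.05`; the log2FC sign convention is fixed (positive = up in the
first-named group, TL). Label swap negates every log2FC and leaves p-values
unchanged; null simulations verify calibration (KS distance to uniform,
type-I error) and planted 2-fold changes are recovered with median absolute
log2FC error below 0.2 at 200 cells per side.

The union of DEGs forms a genes × types log2FC matrix (gene not DE in a
type = 0, i.e. "no change"), clustered hierarchically with Euclidean
distance and complete linkage, cut at k = 6 — the number of coherent
regional programs the source analysis reports.

## GWAS gene selection and enrichment machinery

Selection rules, in order: genic records only; association p ≤ 1e-5 (a
strict tier at 1e-8 is re-run over the same machinery); per (disease, gene)
the SNP with the lowest p; intersection with the expressed background. The
per-disease sets, their union and the pan-disorder intersection are all
emitted. On simulated tables the selection recovers the planted map
*exactly* for any seed — an oracle identity the tests enforce.

All overlap statistics flow through one hypergeometric upper tail
`P(X ≥ k)` computed via the complementary log-tail for stability;
one-sided Fisher tests are the same quantity on the same margins (asserted
by an exhaustive enumeration sweep over every margin with N ≤ 25). BH
adjustment is applied within one analysis family (one table) at a time,
matching the reporting units. The *enrichment score* reported in result
tables is `-log10(BH-adjusted p)` — the raw fields (k, q, t, N, p) are
always emitted so any monotone rescaling can be reproduced; proportions are
`k/t`.

## Preranked GSEA

Genes are ranked by one-vs-rest average log2FC in descending order, ties
broken deterministically by symbol. The enrichment score is the signed
extremum of the weighted Kolmogorov–Smirnov running sum (hit increments
proportional to `|stat|^weight`, default weight 1; misses decrement
uniformly); `weight = 0` reduces to the classic KS statistic. The null
permutes gene labels (`nperm = 1000` by default) because the input is a
preranked list — there are no sample phenotypes to permute. `NES = ES /
mean(|null ES| of matching sign)`; the permutation p has +1 smoothing, so
its floor is `1/(nperm + 1)` (in very small universes the null can tie a
perfect score, which is why the floor is only *attainable*, not
guaranteed). The pipeline stage ranks **all** genes rather than only the
significant markers: at desk-scale gene universes, restricting the ranking
to a few hundred markers empties most pathway intersections below the
minimum set size, leaving nothing to test, while the full ranking preserves
set sizes and the identical statistic.

## Networks

Significant pathways (BH-adjusted p < 0.05 in the over-representation
table) become nodes; each pair is joined by an edge weighted by the Jaccard
similarity of their gene sets, zero-weight pairs dropped and no further
threshold applied. Co-expression networks use tie-corrected Spearman
correlation across the cells of one scope; edges are kept at raw p < 0.05
(a BH switch exists but is off by default, matching the source procedure),
with the t approximation on n − 2 df for n > 9 and the exact permutation
distribution for n ≤ 9. Both signs of correlation are retained. Graphs are
written as edge-list TSV and GraphML with node annotations.

## Concordance and the vulnerability contrast

Disease DEG tables are thresholded at `|log2FC| > 0.25`, adjusted p < 0.05
and split by sign. For each (subtype, disease) pair the overlap of regional
and disease DEGs is tested hypergeometrically against the subtype's
expressed background, and shared genes fall into sign quadrants of
(regional log2FC, disease log2FC); genes with an exactly zero fold change
on either axis cannot be signed and are excluded from quadrant
denominators. Shared genes carried by the strict GWAS tier or by drug
classes are flagged.

The vulnerability contrast takes, per subtype, the TL-upregulated DEGs
(log2FC > +0.5, FDR < 0.05) and reports fractions overlapping the GWAS
union and the drug union, with per-disease and per-class breakdowns. Drug
target sets are intersected with the same global expressed background that
filtered the GWAS genes before fractions are formed — the two families must
pass the same expression filter for their ratio to be meaningful; without
this symmetry the background filter shrinks only the GWAS side and biases
the fold upward. The fold contrast is defined only when the GWAS fraction
is positive. Subtypes are ranked by the enrichment score of their TL-up
genes against the GWAS union.

## The synthetic study and what it does (not) show

The generator emulates the study design: three subjects (two TL, one FL),
roughly 1000 cells each; seven major types with excitatory neurons most
abundant (38.3%), inhibitory neurons 23.6%, oligodendrocytes 22.1%; EX
layer subtypes L2-3–L6 and INH subtypes PVALB/SST/LAMP5/VIP. Counts are
negative binomial with per-gene dispersion drawn log-normally around 0.4,
library sizes log-normal (median ≈ 2000 UMI), per-cell mitochondrial
fractions Beta-distributed around 5% with a tail crossing the 10% QC cut,
and doublets as averaged, re-sampled parent pairs (average, not sum, keeps
the library-size distribution realistic; detection is out of scope — flags
are carried as input). Markers are disjoint planted blocks (+2 log2 by
default); 160 regional genes at ±1 log2 (15% down in TL) are planted, half
concentrated in the designated vulnerable subtype (PVALB). GWAS tables
plant per-disease gene sets (including a pan-disorder common block and 20
genes inside PVALB's TL-up set), drug classes plant a 2:1 drug:GWAS overlap
into the same genes, and disease DEG tables control sign concordance at
`(1 + c)/2` agreement. Where the source states no value (noise magnitudes,
set sizes), defaults are conventional choices fixed once.

Multi-seed recovery runs use roughly 3000 cells and 1000 genes with the
regional test restricted to the eight neuronal subtypes — sizes chosen so a
20-seed recovery study completes in minutes on one core while each subtype
still retains ~50–100 balanced cells per region after QC. Because detected
TL-up sets are then a few dozen genes, the planted 2:1 drug:GWAS ratio is
checked on overlap counts pooled across seeds (per-seed ratios of ~10
GWAS hits have a standard deviation near 0.5 and would test nothing), while
the PVALB-top ranking is asserted per seed.

What passing these tests shows: the statistics are implemented correctly,
calibrated under their own nulls, and recover planted truths of realistic
magnitude through the full pipeline. What they do not show: robustness to
ambient RNA, batch chemistry, alignment artefacts, subject-level
confounding (the DE model, like the source procedure, has no subject
covariate — subjects are recorded so users can test this), or gene-symbol
alias mismatch between catalogues and expression data (symbols are simply
uppercased; no alias table is used).

## Degenerate inputs and tie-breaks

Empty barcode files, all-zero genes, zero-total cells, constant vectors,
empty gene sets, zero contingency margins and empty disease sets all raise
informative errors or logged NA rows rather than propagating nonsense.
Duplicate gene symbols are disambiguated deterministically in file order
(`.1`, `.2`, …). All randomness (simulation, downsampling, GSEA
permutations) flows from explicit seeds; two runs of the full pipeline with
the same seed are byte-identical, manifest included — the manifest records
config, seed, versions and per-file checksums, and deliberately no
timestamps.

## Known limitations

The expression filter's double condition (genes detected / UMIs) is
ambiguous in the source; both readings are implemented and the default is
the operationally stated one. The figure-level "enrichment score" is not
defined in the source methods; `-log10(adjusted p)` is used and all raw
fields are emitted. The co-expression edge rule (raw p < 0.05) is kept as
stated even though it is anti-conservative at scale; the BH switch is one
flag away. Printed fold-contrast figures from tissue data are not
arithmetically recoverable from their own published fractions; this package
reports the raw fractions and their ratio and lets them speak.
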