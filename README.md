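# caflineage

Cancer-associated fibroblasts (CAFs) are not one cell population: tumors
carry several fibroblast subtypes, and one of them — marked by exclusively
high *GJB2* (connexin 26) expression, sitting at the terminal end of the
fibroblast differentiation trajectory, and loaded with collagen/ECM
genes — tracks stromal fibrosis and poor prognosis. `caflineage`
re-implements, as a tested R package, the complete multi-sample single-cell
workflow for discovering such a lineage-specific CAF subtype and measuring
its clinical relevance, together with a seeded synthetic-data generator
that plants every piece of structure the analysis is supposed to find, so
the whole pipeline is testable end-to-end without any external download.

The package is written for computational biologists who want either the
workflow itself (on their own 10x-style data) or its individual, reusable
stages. All result tables are tibbles; fitted survival objects support
`tidy()`, `glance()` and `autoplot()`.

## The method

Per discovery sample *s*:

1. **QC & normalization.** Cells with ≤ 200 or ≥ 6000 detected genes, ≤
   1000 UMIs, or ≥ 20% mitochondrial reads are removed;
   `x₍gc₎ = ln(1 + sf·count₍gc₎/total₍c₎)`.
2. **Annotation.** Cells are typed by maximum Spearman correlation against
   reference profiles; a cell is a fibroblast iff it is classified
   `Fibroblast` *and* expresses ≥ 1 of DCN/COL3A1/THY1. Tumor- and
   border-tissue fibroblasts are CAFs, normal-tissue fibroblasts NFs.
3. **Subtype matching.** CAFs are subclustered per sample (SNN graph +
   Louvain) on the *intersected* variable features. For every cross-sample
   cluster pair, canonical correlation analysis is run with the common
   variable features as observations and cells as variables
   (ridge-regularized whitened SVD); pairs are merged greedily by
   descending first canonical correlation, ties broken by deeper canonical
   correlations, giving shared subtypes with a full audit trail.
4. **Robust markers.** Per sample, Wilcoxon rank-sum DE of the
   marker-bearing subtype vs the other CAFs; the 75 lowest-p genes per
   sample are intersected and genes with inconsistent log2 fold-change
   signs are dropped; mean p and mean log2FC are reported.
5. **Lineage genes.** Kruskal–Wallis ordering genes → a lightweight
   principal-curve pseudotime anchored at the NF centroid → per-gene mean
   Spearman ρ(pseudotime, expression) across samples → genes commonly
   expressed in CAFs (≥ 25% positive), rare in NFs (≤ 5%), and rising
   along pseudotime (mean ρ ≥ 0.3), ranked by ρ.
6. **Cross-talk.** Ligand–receptor scores
   `mean(expm1 ligand | senders) · mean(expm1 receptor | receivers)` with
   permutation p-values, BH within sample, then cross-sample intersection
   of interaction identities; incoming/outgoing interaction counts of the
   marker-positive vs marker-negative CAFs are compared with a paired
   Wilcoxon signed-rank test.
7. **Enrichment.** Preranked GSEA (weighted Kolmogorov–Smirnov running
   sum, gene-label permutation NES and nominal p) of marker-positive vs
   marker-negative CAFs, averaged across samples.
8. **Clinical.** Bulk signature score = mean z-scored log(1+expression) of
   the robust markers; CAF abundance from a marker panel; stage binning
   (Stage 1/2/LOW vs Stage 3/4/HIGH); Kaplan–Meier + log-rank at the
   median split; Cox proportional hazards (Efron ties) adjusted for stage,
   age and sex.

## Worked example

```r
library(caflineage)

cfg <- caf_sim_config(seed = 1)   # 3 samples x 1000 cells, 6 CAF subtypes
res <- run_caf_pipeline(cfg)
res
#> <caf_pipeline>
#>   lineage subtype: ST3 (GJB2+), marker rank 1
#>   robust markers: 32; lineage genes: 31; common interactions: 13
#>   paired frequency p = 0.125; log-rank p = 6.44e-39; Cox HR = 3.23

head(res$lineage_genes, 5)
#> # A tibble: 5 x 4
#>   gene   mean_rho caf_frac nf_frac
#> 1 GJB2      0.739    0.349 0.00403
#> 2 COL8A1    0.711    0.328 0.00403
#> 3 NOTCH3    0.710    0.333 0.00806
#> 4 PDGFRB    0.708    0.334 0.0202
#> 5 ECM12     0.707    0.332 0.0161

res$stage_proportions
#> # A tibble: 2 x 4
#>   stage_bin n_caf n_lineage proportion
#> 1 high        489       196      0.401
#> 2 low         265        63      0.238
```

Reading the output: the six CAF subclusters found per sample were matched
across samples into six shared subtypes; the subtype with 98% marker
positivity was flagged as the lineage subtype and its cross-sample robust
markers recovered the planted collagen/ECM program. The marker gene ranks
first among lineage-specific genes by mean pseudotime correlation (ρ =
0.74, positive in 35% of CAFs and 0.4% of NFs). The lineage subtype
receives the planted endothelial ligand–receptor signals in every sample,
makes up 40% of CAFs in high-stage vs 24% in low-stage samples, and its
bulk signature score carries the planted survival hazard (adjusted Cox HR
3.2 per score unit, log-rank p < 1e-38 at the median split).

`autoplot(res$correspondence)` draws the cluster-to-subtype matching;
`autoplot(res$survival)` the Kaplan–Meier curves; `tidy(res$survival)` the
adjusted Cox table.

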