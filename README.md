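# pgcna — Parsimonious Gene Correlation Network Analysis

Bulk transcriptomic cohorts of the same disease rarely agree in detail, but
they do agree on which genes rise and fall together. `pgcna` is an R package
for distilling that shared co-expression structure out of **multiple
expression datasets at once**, resolving it into gene modules, and scoring
every patient sample against those modules. It is aimed at computational
biologists who have several genes × samples matrices (microarray or RNA-seq,
log2, quantile-normalizable) and want interpretable modules plus per-sample
module scores they can relate to survival and mutation data.

## The method

1. **Correlate, then merge.** Within each dataset *d*, Spearman rank
   correlations ρ<sub>ij</sub><sup>(d)</sup> are computed between the 80%
   most variant genes. Across datasets, each gene pair is summarised by the
   **median** ρ and median p-value over the datasets containing both genes;
   genes present in too few datasets are dropped, and any correlation with
   median p > 0.05 is set to 0.
2. **Edge-per-gene (EPG) reduction.** Instead of a soft threshold, each gene
   keeps only its *N* strongest correlations (default **EPG3**); retention is
   symmetrised as the union of nominations (m<sub>ij</sub> = m<sub>ji</sub>).
   This collapses ~G²/2 correlations to ≤ N·G weighted edges while keeping
   every gene contextualised, and the resulting graphs are scale-free.
3. **Repeated modularity clustering.** The sparse network is clustered many
   times with the Louvain (FastUnfold) algorithm under different seeds; each
   partition is scored by weighted Newman–Girvan modularity
   Q = Σ<sub>c</sub>[w<sub>in,c</sub>/m − (s<sub>c</sub>/2m)²] and the best
   runs retained.
4. **Clustering selection by SCES.** Given a gene-signature collection
   (GMT), each module's signatures are tested by the one-sided
   hypergeometric test with BH-FDR control. A clustering's **scaled cluster
   enrichment score** is
   `SCES = ZScoreMS · MFC · H_n`, where ZScoreMS sums each enriched
   signature's best per-module z-score, MFC (median fractional contribution,
   row-max z / row-sum z) rewards signatures confined to a single module,
   and H<sub>n</sub> (normalized Shannon entropy of module sizes) rewards
   balanced modules.
5. **ModCon hubs and MEVs.** Genes are ranked within each module by
   `ModCon = connectivity² · percentileExpression · VarWithin · (100 − VarAcross)/100`
   — well-connected genes that vary across patients (median QCOD) but are
   stable across datasets (MAD of percentile expression). Each module's
   **Module Expression Value** per sample is the sum of the z-scored
   expression of its top-25 ModCon genes, usable on entirely unseen cohorts
   via `predict()`.
6. **Downstream.** Size-weighted fixed-effect meta-analysis of per-gene Cox
   hazard ratios, module–module correlation maps, mutation–module
   association z-matrices (with coordinate-window splitting of a gene's
   mutations), and gene/signature-level overlap between two module sets.

A seeded synthetic-study generator with planted modules, module-aligned
signatures, module-driven survival and module-correlated mutations makes the
whole pipeline testable end-to-end without any external data.

## Worked example

```r
library(pgcna)

sim  <- generate_expression(pgcna_sim_config(n_genes = 300, n_modules = 5,
                                             n_datasets = 3,
                                             samples_per_dataset = 80,
                                             seed = 42))
sigs <- generate_signatures(sim$truth)
surv <- generate_survival(sim$truth, beta_per_module = c(0.6, 0, 0, 0, 0))

fit <- pgcna(sim$datasets, signatures = sigs, survival_tables = surv,
             n_runs = 50, n_keep = 10, seed = 7)
fit
#> Parsimonious gene correlation network
#>   cohorts: 3 (synth01, synth02, synth03)
#>   merged genes: 273; EPG3 network: 653 edges (0 isolated genes)
#>   best clustering: 5 modules, Q = 0.7991, SCES = 177.28

summary(fit)
#> PGCNA fit: 273 genes, 653 edges (EPG3), 5 modules, Q = 0.7991
#> SCES = 177.280 (ZScoreMS 177.31, MFC 1.000, entropy 1.000)
#>  module size hub_gene top_signature
#>       1   56    g0034     sig_M3_05
#>       2   56    g0146     sig_M5_02
#>       3   54    g0014     sig_M1_01
#>       4   54    g0079     sig_M2_04
#>       5   53    g0064     sig_M4_04

adjusted_rand_index(fit$best$assignment, sim$truth$assignment)
#> [1] 0.9810756
```

Reading the output: the three cohorts agree on 273 genes after the merge;
EPG3 keeps 653 of ~37k possible edges; Louvain finds five modules at
modularity 0.80 that match the five planted modules almost perfectly
(ARI 0.98). MFC = 1 means every enriched signature is confined to a single
module, and entropy = 1 means the modules are evenly sized — together the
maximal SCES regime. Per-sample module scores for any cohort:

```r
mev <- predict(fit, sim$datasets[[1]])
round(mev$values[, 1:4], 2)
#>   d1_s001 d1_s002 d1_s003 d1_s004
#> 1   22.57  -31.94  -29.05    3.17
#> 2  -24.12  -15.20   -4.71   -7.63
#> 3    2.31    6.43   24.09   24.51
#> 4  -21.82   23.72   -8.36   -6.44
#> 5    8.28   18.57   28.59   -8.22
```

Each entry sums 25 per-gene z-scores, so sample d1_s001 is a strong
module-1-high, module-2/4-low patient. `export_network()` writes
GraphML + TSVs for Gephi; `associate()` builds the mutation–module z-matrix.

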