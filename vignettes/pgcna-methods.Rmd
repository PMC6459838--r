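---
title: "Methods and design notes for pgcna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for pgcna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgcna)
```

# The model

`pgcna` treats a collection of expression cohorts as noisy draws from one
shared co-expression structure. The object being estimated is a partition of
genes into modules; everything else — the merged correlation matrix, the
sparse network, the per-sample module scores — is either an intermediate or
a read-out of that partition.

The assumptions worth stating explicitly:

* **Co-expression is rank-shaped and reproducible.** Spearman correlation is
  used throughout, so any per-cohort monotone distortion of expression is
  irrelevant; what must replicate across cohorts is the rank relationship.
  The cross-cohort **median** of ρ and of its p-value is the estimator of
  the shared signal — robust to a minority of discordant cohorts, and
  requiring no variance model for the cohorts themselves.
* **Module structure lives in the strongest few edges per gene.** The
  edge-per-gene (EPG) reduction keeps, for each gene, only its `n_edges`
  largest correlations (default 3) and then re-symmetrises by the union of
  nominations. This is deliberately not a global threshold: a hub and a
  quiet gene each keep their best partners, so the network stays fully
  connected at radically reduced edge counts.
* **Positive co-expression defines modules.** Partners are ranked by signed
  correlation, not absolute value: modules are groups of genes that go up
  and down together, and modularity is undefined for negative weights.
  Ranking by `|rho|` is available (`rank_by = "absolute"`); any negative
  edges that then survive are dropped, with a message, before clustering.

# Pipeline parameters

| parameter | default | units / range | why |
|---|---|---|---|
| `variant_fraction` | 0.8 | fraction of genes per cohort | correlating the flattest 20% of genes mostly adds noise-driven pairs; selection is per cohort, by plain variance, ties broken by gene id |
| `min_datasets` | ⌈D/3⌉ | cohorts | a pair's median correlation over very few cohorts is fragile; roughly one-third of the cohorts is required before a gene enters the merged matrix |
| `p_noise_cutoff` | 0.05 | median p | correlations not distinguishable from zero are set to exactly 0 so they can never be nominated as edges |
| `epg` (`n_edges`) | 3 | edges/gene, 3–10 sensible | below 3 modules fragment into orphans; above ~10 the parsimony advantage erodes; edge count is bounded by `n_edges × G` |
| `n_runs`, `n_keep` | 100, ≤100 | Louvain runs | desk-scale default; the procedure is insensitive to this once the best retained Q plateaus, and both are plain arguments for larger studies |
| `fdr_cutoff`, `top_n` | 0.05, 15 | per-module enrichment filter | only confidently enriched signatures enter the SCES z-matrix; 15 per module keeps one module from flooding the global list |
| signature size bounds | [5, 1000] | genes, after intersecting with the population | tiny signatures are unstable, giant ones uninformative; the bound is applied to the signature's overlap with the gene universe actually tested, which is also the universe of the hypergeometric test |
| `top_hub_genes` | 25 | genes per module | MEV sums exactly this many z-scores (fewer only if the cohort lacks genes), so MEVs are comparable across modules |
| mutation `min_freq` | 0.05 | fraction of cohort, strict `>` | genes mutated in almost no samples cannot support a rank correlation |

# Numerical choices

* **Spearman p-values** use the t approximation
  `t = ρ√((n−2)/(1−ρ²))` with average ranks for ties; `|ρ| = 1` maps to
  p = 0. Exact permutation tests add nothing at cohort sizes where the
  pipeline is meaningful (the code warns below 5 samples).
* **Hypergeometric tails** are evaluated in log space
  (`phyper(..., log.p = TRUE)`) and z-scores taken as the standard-normal
  quantile of the one-sided log-p, so extreme enrichments neither underflow
  nor saturate. Enrichment gives positive z, depletion negative.
* **Modularity** is the weighted Newman–Girvan quantity
  `Q = Σ_c [w_in,c/m − (s_c/2m)²]`, recomputed directly from the edge list
  for every returned partition rather than trusted from the clustering
  backend; for two disjoint unit triangles the optimal bipartition gives
  exactly Q = 0.5.
* **Determinism.** Louvain stochasticity comes from a seeded permutation of
  the vertex processing order; per-run seeds are spawned from one base seed
  and recorded on each result, so any single run is replayable. Module
  labels are canonical (1..K by decreasing size, ties by smallest member
  gene id), EPG nomination ties break by partner gene id, and ModCon ties
  by gene id — re-running with permuted inputs yields identical objects.
* **Quartiles are type 7** (linear interpolation), which QCOD and hence
  ModCon inherit; **MEV z-scores use the population standard deviation**
  (ddof 0); **MAD is raw** (no 1.4826 consistency factor) because it only
  acts as a relative weight on the 0–100 percentile scale.
* **Normalized entropy** `H_n = −Σ p_i log p_i / log K` is base-invariant;
  natural logs are used. A single-module clustering has no defined `H_n`
  (log 1 = 0) and is assigned 0, i.e. maximal skew — such a clustering
  should never win selection.
* **Degenerate inputs**: zero-variance genes get missing correlations and
  are excluded from the merge; modules with no eligible signatures score
  SCES 0 with a warning; constant mutation indicators give z = 0; Cox fits
  are skipped when a cohort has no events.

# Open design points and how they were settled

* **Multi-probe merge rule.** The median-vs-maximum rule needs a
  correlation statistic for probe sets larger than two; the mean of all
  pairwise Pearson correlations is used because it is symmetric and reduces
  to the pair case. Threshold configurable (`corr_threshold`).
* **"Most variant" genes.** Plain variance of the normalized log2 values is
  the least surprising reading and is what is implemented; because the
  selection is per cohort, cross-cohort scale differences do not matter.
* **Connectivity in ModCon** sums a gene's **retained** intra-module edge
  weights, not the dense merged correlations: the network is the object the
  module was derived from, and hub-ness within the pruned graph is what the
  visualised module shows. Negative connectivity (possible only under
  absolute ranking) is floored at 0 before squaring so ModCon stays
  monotone.
* **Depletion z-scores and MFC.** Fractional contributions are computed
  over positive z entries only, and rows with no positive entry are dropped
  from the MFC median; this keeps MFC in (0, 1] and prevents sign
  cancellation from manufacturing spurious "specificity".
* **Stability matching is not a bijection**: each reference module matches
  its maximum-overlap module per run independently, so two reference
  modules may match the same target — the natural behaviour when a run has
  merged them.
* **Mutation association z** uses the two-sided p signed by ρ, so the
  association heatmap carries direction and significance symmetrically;
  a one-sided variant is a trivial configuration change.
* **Overlap populations.** Gene-level module overlap is tested on the
  intersection of the two gene universes (overlap is only observable
  there); signature-level overlap on the union of signatures passing the
  pre-filter (p < 0.001, size 5–1000) in either analysis.
* **Meta-analysis weights are cohort sizes**, not inverse variances — the
  fixed-effect combination is `β = Σ wᵢβᵢ/Σ wᵢ`,
  `se² = Σ wᵢ²seᵢ²/(Σ wᵢ)²`. This is a deliberate weighting choice (big
  cohorts dominate regardless of their standard errors) and is implemented
  directly; the test suite cross-checks it against `metafor::rma(...,
  weights = n, method = "FE")`.
* **Intermediate store.** Pipeline intermediates persist in a
  directory-backed binary store (`pgcna_store()`), one entry per object,
  with bit-identical round-trips.

# What the synthetic generator emulates — and what it does not

`generate_expression()` plants K modules in G genes across D cohorts. Each
cohort redraws its own per-sample latent factor per module; a module gene is
`baseline + loading·f + √(1−loading²)·ε`, so the within-module correlation
target is `loading²` (0.56 at the default loading 0.75) and the marginal
variance is 1 on a log2-like scale (baselines uniform in [4, 12], so
quantile normalization and percentile expression are exercised
non-trivially). A `null_fraction` of genes is pure noise.
`generate_signatures()` draws signatures from planted modules with a
contamination fraction; `generate_survival()` makes event times exponential
with log-hazard `Σ β_k f_k` plus independent exponential censoring;
`generate_mutations()` makes per-sample Bernoulli indicators with logit
`logit(base_rate) + effect_k·f_k` and toy chr1 coordinates.

This emulates the features the method's claims rest on: shared module
structure with cohort-level heterogeneity, module-aligned biology, and
module-driven outcomes. It deliberately does **not** emulate probe-level
artefacts, within-cohort batch effects, heavy-tailed count noise,
correlated module factors, or gene-length/GC biases. Passing tests
therefore demonstrate that the estimator recovers the structure it is
defined to recover under honest noise — not that any particular biological
dataset contains such structure.

# Validation scale

The validation suite runs the full pipeline at the generator defaults
(1000 genes, 8 modules, 4 cohorts × 120 samples, loading 0.75, EPG3,
best of 100 Louvain runs), where recovery against the planted truth reaches
ARI ≥ 0.9; survival recovery uses 3 cohorts × 200 samples with β = 0.5 on
one module, clustering-selection preference uses 20 independent seeds at
200 genes, and all exact identities (hypergeometric tails, modularity,
entropy, MFC) are checked against independent closed-form or enumeration
oracles at small n.

# Known limitations

* Louvain is a local optimiser; the multi-run/best-of protocol controls
  but does not eliminate its variance, and the resolution parameter is
  fixed at 1 (very small or very large modules at extreme G may need a
  different clustering back-end).
* The median merge assumes cohorts are exchangeable; a systematically
  different cohort (e.g. a different tissue) is down-weighted only insofar
  as it is a minority.
* Quantile normalization with missing values is handled by the standard
  within-column ranking dialect, which is exactly idempotent only on
  complete matrices.
* MEVs are sums of z-scores, so they are comparable across samples within
  a cohort but only loosely across cohorts with very different sample
  sizes.
* The mutation association treats mutation status as binary per gene (or
  per coordinate window); mutation type is not modelled.
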