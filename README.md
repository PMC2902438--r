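# icemod

Co-expression module discovery by iterative clique enumeration, for
module-level analysis of bulk gene expression data.

Single-gene expression signatures of a clinical phenotype tend to replicate
poorly across cohorts and are hard to interpret. `icemod` instead treats
**co-expression modules** — sets of genes that are *pairwise* highly
correlated across samples, i.e. cliques of a thresholded correlation
network — as the units of analysis: a module's overall expression is
screened against an ordered phenotype such as tumor grade, and its gene
content is interpreted by gene-set enrichment. It is aimed at
transcriptomics analysts who want a strict, reproducible alternative to
soft clustering for biomarker and co-regulation work.

## What it computes

Given a standardized gene × sample matrix `X`:

1. **Network.** All pairwise Pearson correlations `r_ij`; an unweighted
   graph with an edge where `r_ij ≥ t`. Candidate thresholds: the
   Bonferroni-corrected correlation-test cut (p ≤ 0.01), and the top 1% /
   top 0.1% quantiles of the signed correlation distribution. A
   correlation-binned curve of mean Resnik GO semantic similarity per
   0.1-wide correlation interval shows where co-expression starts to imply
   shared function, guiding the final (user) choice.
2. **Modules (the core algorithm).** Iterative clique enumeration: repeat
   { find the *maximum clique* `C_i` of the residual graph (exact branch
   and bound with greedy-coloring bounds, deterministic lexicographic
   tie-break); expand it to the largest maximal clique `C_i' ⊇ C_i` of the
   original graph; emit `C_i'` and delete its nodes from the residual }
   until the residual maximum clique is smaller than `c_min` (default 10).
   Cores are disjoint, so every module brings ≥ `c_min` new genes, while
   expansion permits restrained overlap between modules.
3. **Trend screening.** Module overall expression = mean of member genes'
   z-scores per sample. Jonckheere–Terpstra test against ordered
   categories: `W = Σ_{i<j} #{X_iα < X_jβ}` (ties 0.5), with
   `E₀(W) = (N² − Σn_i²)/4`,
   `Var₀(W) = [N²(2N+3) − Σn_i²(2n_i+3)]/72`, normal approximation
   two-sided p (exact permutation option for small N), and
   Benjamini–Hochberg FDR across the module family.
4. **Enrichment and reproducibility.** Upper-tail hypergeometric
   `P(X ≥ k)` of module/set overlaps against GMT collections (GO, motif
   sets merged per transcription factor, positional sets), Bonferroni
   adjusted; and the reproducibility of a biomarker set as the percentage
   of discovery-significant modules that stay significant in an independent
   cohort.

A synthetic-data generator (`simulate_expression()`) plants correlated,
trend-bearing modules with known ground truth so the whole pipeline is
testable without any external download.

## Worked example

```r
library(icemod)

sim <- simulate_expression(simulation_spec(
  n_background = 150, module_sizes = c(10, 10), rho = 0.9,
  n_per_category = c(20, 20, 20), delta = c(0.6, -0.6), seed = 11))

fit <- ice_fit(sim$expression, quantile = 0.01, c_min = 8)
fit
#> Co-expression modules by iterative clique enumeration
#>   input: 170 genes x 60 samples
#>   threshold: r >= 0.3384; network: 90 nodes, 144 edges
#>   modules: 2 (c_min = 8)

screen_modules(sim$expression, fit, sim$phenotype)[
  , c("module", "n_genes", "z", "fdr", "direction", "significant")]
#>     module n_genes         z          fdr direction significant
#> 1 module_1      10  5.006027 1.111299e-06        up        TRUE
#> 2 module_2      10 -3.323785 8.880467e-04      down        TRUE
```

Both planted 10-gene modules are recovered exactly from the top-1% network
(threshold r ≥ 0.34 here), and the trend screen flags the rising module
(z > 0) and the falling one (z < 0) at FDR < 0.01 while the 150 background
genes contribute nothing. `summary(fit)` additionally reports the network's
mean clustering coefficient and per-module core/expanded sizes; `plot(fit)`
shows the degree distribution and module sizes.

A command-line front end over the same functions lives in
`inst/cli/icemod.R` (subcommands `preprocess`, `simcurve`, `network`,
`ice`, `trend`, `enrich`, `synth`).

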