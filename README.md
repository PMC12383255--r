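# scquiesce

Consensus clustering and activation statistics for quiescent neural stem
cell (NSC) transcriptomics.

Adult pallial NSCs in zebrafish sit in graded depths of quiescence
maintained by Notch signalling. When Notch is blocked pharmacologically
(γ-secretase inhibition, e.g. LY411575, against a DMSO control), some
quiescent subpopulations re-enter the cell cycle and others resist.
Linking the transcriptomic subtypes of quiescent NSCs to this behaviour
requires a chain of bespoke statistics around standard droplet scRNA-seq
processing. `scquiesce` implements that chain as tested, reusable R
functions, exercised end-to-end on a synthetic two-condition data
generator with known ground truth:

- **QC filtering** — loess residual filter on the nGene ~ nUMI
  relationship (span 0.5, gaussian family, ±3 SD), detected-gene floor
  (nGene ≥ 200), mitochondrial ceiling (percent.mito ≤ 10%), joint
  upper-quantile rule for abnormally high complexity, and removal of
  genes detected in fewer than 10 cells.
- **Consensus clustering (CSPA)** — an ensemble of base clusterers
  (graph community detection on SNN graphs with SNN-Cliq-style rank or
  Phenograph-style Jaccard edge weights, a Gaussian mixture, density
  peaks) is pooled into a consensus matrix `C[i,j] = `fraction of
  partitions co-clustering cells *i* and *j*; an average-linkage tree on
  `1 − C` is cut conservatively (height 0.2), neighbouring clusters that
  lack discriminating genes (pairwise rank-sum + BH) are merged, and
  doublets are screened with an artificial-doublet kNN score and a
  convex-mixture test for whole doublet clusters.
- **Differential cluster abundance** — bootstrapped
  difference-of-proportion test: per cluster, `B = 10,000` simulated
  differences `Binom(n_t, p̂_t)/n_t − Binom(n_c, p̂_c)/n_c`, two-sided
  tail at zero with a `1/(B+1)` floor, Bonferroni across clusters.
- **Cell-cycle scoring** — genes binned into 24 average-expression bins;
  per set gene, 100 expression-matched controls drawn from its bin;
  score = mean(set) − mean(controls) per cell.
- **Regulator inference refinement** — transcription-factor → target
  weight matrices (imported from external inference, or the built-in
  |Spearman| fallback) are cut at the elbow of the sorted weight curve
  (max distance to chord), signed by correlation, and intersected across
  conditions to find consensus regulators.
- **Response rate** — for each population,
  `RR = (p_treated − p_control) / (1 − p_control)`: cells recruited by
  the treatment over cells at risk of recruitment. The difference in RR
  between two populations is tested against a Monte-Carlo null that
  pools activation rates within each condition (50 bootstraps × 1,000
  samples, p = max over bootstraps of the one-sided tail).

## Worked example

Simulate a two-condition experiment (5 clusters of unequal size, 1,000
cells per condition, 10% doublets) in which cluster 1 doubles its share
under treatment and cluster 5 halves; run QC, consensus clustering and
the abundance test:

```r
library(scquiesce)
design <- simulation_design(
  treated_abundance_multipliers = c(2, 1, 1, 1, 0.5),
  doublet_rate = 0.1, seed = 42)
run <- run_pipeline(default_config(seed = 42), design = design,
                    stages = c("simulate", "qc", "cluster", "abundance"))
summary(run$results$cluster$consensus)
print(run$results$abundance)
```

```
Consensus clustering of 1974 cells
  base partitions: 6
  clusters: 5
  sizes: 708, 428, 361, 297, 180
  merge rounds: 2 pairs tested, 1 merged
Bootstrapped difference-of-proportion test (B = 10000, Bonferroni over 5 clusters)
 cluster prop_control prop_treated    diff  p_raw  p_adj direction sig
       1       0.2667       0.4504  0.1837 0.0001 0.0005  enriched   *
       2       0.2373       0.1964 -0.0410 0.0266 0.1330  depleted
       3       0.2018       0.1640 -0.0379 0.0260 0.1300  depleted
       4       0.1653       0.1356 -0.0297 0.0600 0.3000  depleted
       5       0.1288       0.0536 -0.0752 0.0001 0.0005  depleted   *
```

The five planted clusters are recovered, the planted enrichment
(cluster 1) and depletion (cluster 5) are the two significant calls, and
the proportional bystander shifts in clusters 2–4 (forced because
proportions sum to one) correctly stay below the Bonferroni threshold.

The response-rate statistic on simulated in-situ counts — a
marker-positive population that barely responds to treatment (5% → 7%
activated) next to a marker-negative population that responds strongly
(5% → 25%):

```r
inp <- simulate_cell_counts(0.05, 0.07, 0.05, 0.25,
                            n = c(600, 600, 700, 700), seed = 7)
response_rate_difference_test(inp, seed = 7)
```

```
Response-rate difference test (50 repeats x 1000 samples)
  response rate [pos]: 0.0141
  response rate [neg]: 0.2057
  observed difference: -0.1916
  p-value (max over repeats): 0.000999
```

About 21% of the at-risk marker-negative cells were recruited versus
1.4% of the marker-positive ones; the difference is significant at the
resolution floor of the Monte-Carlo null (1/1001).

## Documentation

The methods vignette (`vignettes/quiescent-nsc-methods.Rmd`) describes
the models, the synthetic-data generator and its limits, parameter
defaults, and the numerical design choices.
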