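# coexmod

Consensus gene co-expression modules and eigengene-network preservation
across paired cohorts.

## The problem

Two related cancers — say HPV16-positive head-and-neck and cervical
squamous carcinomas, each profiled against its own normal tissue — often
share co-expression structure that single-cohort differential expression
misses. `coexmod` finds the **consensus modules**: groups of genes that are
co-expressed in *both* cohorts, and then asks how faithfully the
relationships among those modules carry over from one cohort to the other.

The pipeline, for cohorts A and B with log-scale expression matrices:

1. **Screening.** Per cohort, a two-sided Mann–Whitney U test of cancer vs
   normal per gene (exact p when the smaller group has ≤ 8 samples and no
   ties); the common significant genes are intersected, then ranked by
   soft-threshold network connectivity `k_i = Σ_j a_ij` with consensus
   connectivity `min(k_i^A, k_i^B)`, keeping the top hub genes.
2. **Consensus network.** Per cohort, Pearson correlation → soft-threshold
   adjacency `a_ij = |cor_ij|^β` (default β = 6) → topological overlap
   `TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)`. The
   consensus dissimilarity is `1 − min(TOM^A, TOM^B)` elementwise.
3. **Module detection.** Average-linkage (UPGMA) clustering of the
   consensus dissimilarity, cut at a fixed height (default 0.95) with a
   minimum module size (default 25); modules get the conventional color
   labels in decreasing size order (turquoise, blue, brown, …), with grey
   for unassigned genes.
4. **Eigengenes.** Each module is summarized by its eigengene — the first
   principal component `E = C₁g₁ + C₂g₂ + … + C_n g_n` of the standardized
   member genes — with its variance explained, and the per-cohort eigengene
   network `cor(E_i, E_j)`.
5. **Preservation.** For modules i, j the cross-cohort preservation is

   `preserv_ij(A,B) = 1 − |cor(E_i(A), E_j(A)) − cor(E_i(B), E_j(B))| / 2`

   with per-module `D_i = mean_{j≠i} preserv_ij` and overall preservation
   `D = mean_i D_i`. D = 1 means the eigengene relationships are identical
   in both cohorts.
6. **Enrichment.** Per-module over-representation of user-supplied gene
   sets (GMT) with the conservative EASE score (hypergeometric upper tail
   with the overlap decremented by one) and Benjamini–Hochberg adjustment.

A synthetic-data generator plants known module structure in paired cohorts
(latent factor per module, optional correlated meta-branches, per-group
mean shifts, and a rewiring knob that degrades cohort B), so every step can
be validated against ground truth.

## Worked example

```r
library(coexmod)

cfg <- sim_config(seed = 1)        # 8 planted modules of 40 genes,
sim <- simulate_pair(cfg)          # cohorts of 13+14 and 8+8 samples
fit <- run_consensus_pipeline(sim$study_a, sim$study_b)
fit
#> <consensus_fit>  400 genes -> 8 modules (grey: 80)
#>   overall preservation D = 0.870
tidy(fit)
#> # A tibble: 8 x 5
#>   module     size var_explained_a var_explained_b     d
#>   <chr>     <int>           <dbl>           <dbl> <dbl>
#> 1 turquoise    40           0.812           0.753 0.856
#> 2 blue         40           0.781           0.689 0.896
#> 3 brown        40           0.791           0.766 0.853
#> 4 yellow       40           0.771           0.790 0.919
#> 5 green        40           0.735           0.828 0.804
#> 6 red          40           0.789           0.792 0.895
#> 7 black        40           0.799           0.787 0.904
#> 8 pink         40           0.772           0.786 0.829
```

All eight planted modules are recovered (adjusted Rand index 1.0 against
the simulation truth at this seed); the 80 background genes land in grey.
Each module's eigengene explains ~70–80% of its genes' variance in both
cohorts, and the overall preservation D ≈ 0.87 says the module
relationships transfer well between the two (independent) cohorts.
`autoplot(fit$assignment)`, `autoplot(fit$preservation)` and
`plot_preservation_d(fit$preservation)` draw the standard figures.

As a reference point, the per-module preservation indices reported for the
eight consensus modules of an HPV16-positive head-and-neck / cervical
cancer comparison average to the published overall value:

```r
overall_preservation(c(0.811, 0.938, 0.933, 0.92, 0.835, 0.963, 0.92, 0.919))
#> $value
#> [1] 0.904875
#> $rounded
#> [1] 0.9
```

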