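# vdrfun

Functional profiling and cluster-stability analysis of vitamin D
receptor (VDR) orthologs and paralogs.

## What this package is for

The VDR binds its native hormone 1α,25-dihydroxyvitamin D₃ with high
affinity, and in mammals it is also activated by lithocholic acid (LCA),
a toxic secondary bile acid. Comparing VDRs from species spanning
vertebrate evolution — lamprey, skate, bichir, zebrafish α/β, medaka
α/β, human — on ligand binding, transcriptional activation, and
coregulator recruitment asks whether the VDR–LCA partnership is a recent
adaptation or an ancient by-product. `vdrfun` implements the
quantitative workflow of such a comparison for R users in nuclear
receptor pharmacology:

* **Competitive binding** (`specific_binding()`, `fit_competition()`,
  `cheng_prusoff()`): specific binding by subtraction, a one-site
  competition fit S(c) = bottom + (top − bottom)/(1 + c/IC₅₀) with Hill
  slope −1, and the Cheng–Prusoff conversion Kᵢ = IC₅₀/(1 + L/K_d).
* **Dual-luciferase normalization** (`normalize_to_control()`,
  `fold_activation()`, `summarize_fold()`,
  `assemble_assay_matrix()`): control-normalised ratios, fold
  activation/interaction against the design's reference construct,
  per-experiment averaging with SEM, and assembly of the
  coregulator-annotated assay × species response matrix.
* **Clustering** (`row_normalize()`, `species_distance()`,
  `complete_linkage()`, `cut_partition()`, `is_clade()`,
  `to_newick()`): per-assay row normalization, Manhattan distance
  between species profiles, complete-linkage trees with a deterministic
  tie rule, and Newick export.
* **Bootstrap recapitulation** (`bootstrap_recapitulation()`,
  `coregulator_importance()`): resample assays, re-cluster, count how
  often the reference partition and named subclusters reappear, and
  rank coregulators by how much the rate drops when their assays are
  left out.
* **Synthetic data** (`simulate_assay_matrix()`,
  `simulate_competition_curve()`, `simulate_luciferase()`): every
  pipeline input with planted ground truth, so the full analysis is
  exercisable and testable with no external data.

`run_pipeline()` composes all stages end to end with full determinism
under one seed; `exec/vdrfun` is a thin command-line wrapper.

## Worked example

```r
library(vdrfun)

## binding: simulate the reference design (Ki = 9.5 uM, Kd = 1 nM,
## L = 4 nM, 0-1 mM series, 3 experiments x 2 replicates) and refit
sim <- simulate_competition_curve(true_ki_uM = 9.5, kd_nM = 1,
                                  cv = 0.05, seed = 1)
fit_competition(sim$curve, kd_nM = 1)
#> one-site competition fit
#>   IC50 = 46.79 uM  [41.7, 52.51]
#>   Ki   = 9.358 uM  (Kd = 1 nM)
#>   top = 1004, bottom = 15.97, SSE = 1847, converged: TRUE
```

The fitted IC₅₀ of ~47 µM is the competitor concentration displacing
half the specific binding; corrected for hot-ligand occupancy it gives
Kᵢ ≈ 9.4 µM against the planted 9.5 µM.

```r
## clustering + stability on a synthetic assay matrix (8 receptors in
## two planted groups, 14 annotated assays, effect 6, noise 1)
sim2 <- simulate_assay_matrix(default_species_groups(), seed = 1)
m <- row_normalize(sim2$matrix)
tree <- complete_linkage(species_distance(m))
cut_partition(tree, 2)
#> [[1]]
#> [1] "lVDR"   "bVDR"   "sVDR"   "zfVDRb" "mVDRb"
#> [[2]]
#> [1] "zfVDRa" "mVDRa"  "hVDR"

pattern <- cluster_pattern(sim2$truth$true_partition)
bootstrap_recapitulation(m, pattern, B = 1000, seed = 1)
#> stability_report (B = 1000, seed = 1, mode = stratified)
#>   overall recapitulation:   0.9620
#>   partition recapitulation: 0.9620
#>   subcluster C1:             0.9620
#>   subcluster C2:             0.9620

coregulator_importance(m, pattern, B = 500, seed = 1)
#> coregulator importance (leave-out, B = 500, seed = 1)
#>   full-matrix recapitulation: 0.9740
#>   RXR_WT   importance +0.6160 (leave-out rate 0.3580)
#>   SRC1     importance +0.4560 (leave-out rate 0.5180)
#>   GRIP1    importance -0.0120 (leave-out rate 0.9860)
#>   RXR_AF2  importance -0.0160 (leave-out rate 0.9900)
#>   ACTR     importance -0.0260 (leave-out rate 1.0000)
```

The k = 2 cut recovers the planted partition; the bootstrap says the
pattern reappears in ~96% of stratified assay resamples of this
particular noise realization; and leaving out the assays of either
planted driver (RXR_WT, SRC1) collapses the rate, while removing
non-driver assays changes nothing — the leave-out importances identify
the drivers.

See `vignettes/vdr-functional-clustering.Rmd` for the models, the
normalization choices, the two resampling modes and their rationale, and
the generators' scope.

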