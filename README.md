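# compshift

Composition-aware differential expression for bulk RNA-seq.

Bulk RNA-seq measures a mixture of cell types. When an intervention shifts
the tissue's cellular makeup — cardiomyocyte loss with fibroblast and
macrophage gain at an infarct border zone is the motivating example — every
gene expressed unevenly across cell types moves in the bulk signal, and a
standard per-gene analysis reports those shifts as differential expression
even when no cell changed its program. `compshift` is for analysts of bulk
RNA-seq from heterogeneous tissue who have (or can borrow) a clustered
single-cell/single-nucleus reference and want their condition contrasts to
reflect regulation, not composition.

## What it does

* **Reference building** — resolve duplicate symbols, intersect gene
  universes, select top-`k` one-vs-rest markers per cluster (Welch t on
  log1p CP10K, BH-adjusted), and assemble a signature: per-type relative
  expression θ<sub>gk</sub>, cross-subject variance σ²<sub>gk</sub>, and
  cell-size factors S<sub>k</sub>.
* **Deconvolution** — per sample, solve
  y<sub>g</sub> ≈ Σ<sub>k</sub> c<sub>k</sub> S<sub>k</sub> θ<sub>gk</sub>
  (c<sub>k</sub> ≥ 0) over the marker panel by iteratively re-weighted
  NNLS with weights
  1 / (r<sub>g</sub>² + Σ<sub>k</sub> ĉ<sub>k</sub>² σ²<sub>gk</sub> S<sub>k</sub>² + ε),
  and report RNA fractions
  p<sub>k</sub> = c<sub>k</sub>S<sub>k</sub> / Σ<sub>j</sub> c<sub>j</sub>S<sub>j</sub>.
* **Compositional statistics** — CLR and PCA covariate representations of
  proportions, and Dirichlet regression
  α<sub>ic</sub> = exp(x<sub>i</sub>ᵀβ<sub>c</sub>) with Wald inference.
* **Differential expression** — per-gene NB GLM with log link and
  median-of-ratios size-factor offsets, per-gene ML dispersion, Wald
  contrasts, BH-FDR; compositional covariates enter as additive terms.
* **Simulation & benchmark** — synthetic clustered references,
  multinomial pseudo-bulk mixtures over a 30–70% major-type sweep with
  anti-correlated minor-type shifts and log-normally spiked true
  positives (log2FC mean 0.58 ≈ 1.5×, sd 0.5), scored by
  precision/recall/F1 per covariate representation.

## Worked example

```r
library(compshift)

ref <- make_fixture_reference(seed = 42)    # 2,000 genes, 5 cardiac types
#> ClusteredReference: 2000 genes x 600 nuclei | 5 clusters, 3 subjects

panel <- select_markers(ref, k = 15, min_cluster_size = 2)
#> MarkerPanel: 5 clusters, 75 markers total (k = 15)
sig <- build_signature(ref, panel)

# two groups: 40% vs 50% cardiomyocyte RNA fraction, 1e5 reads, 4 reps
des <- mixture_design(cm_grid = c(0.40, 0.50), n_replicates = 4,
                      total_reads = 1e5, seed = 1)
sim <- simulate_experiment(ref, des)
#> SimTruth: 2000 genes x 8 samples (2 conditions x 4 replicates), 200 spiked genes

props <- deconvolve_cohort(sim$bulk_counts, sig)
round(head(props$proportions, 3), 3)
#>                CM    EC    FB   Mac  Peri
#> cm_0.400_r1 0.404 0.126 0.190 0.155 0.125
#> cm_0.400_r2 0.407 0.123 0.182 0.153 0.135
#> cm_0.400_r3 0.402 0.122 0.190 0.160 0.127
```

The deconvolved cardiomyocyte fractions sit within half a point of the
40% truth. Fitting the unadjusted NB GLM on this two-group design calls
287 of 960 tested genes (30%) at BH-FDR 0.05 — three times the 10% of
genes actually spiked — which is the compositional artifact.

Correction needs the multi-condition sweep (the abundance coefficient is
identified by within-group composition variation pooled across groups, so
the two model families are fit jointly over all conditions):

```r
des  <- mixture_design(seed = 1)            # 81 conditions, 30-70% sweep
bench <- run_benchmark(ref, des, representations = c("none", "clr"), seeds = 1)
summarize_benchmark(bench)$by_shift_class
#>   shift_class representation mean_F1 sd_F1 mean_frac_called  n
#> 1       major            clr    0.38 0.108            0.101 80
#> 3       major           none    0.27 0.052            0.368 80
#> 2       minor            clr    0.54 0.100            0.071 80
#> 4       minor           none    0.47 0.121            0.136 80
```

With CLR covariates the model calls far fewer genes (10% vs 37% under
major shifts — close to the spiked truth rate) and scores a higher F1
against the spiked ground truth in both shift regimes.

See `vignettes/composition-aware-de.Rmd` for the models, parameter
meanings, simulator assumptions, and numerical choices.

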