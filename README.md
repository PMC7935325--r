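# sepnet

Immune gene co-expression network analysis for sepsis transcriptomes.

Sepsis is a dysregulated host response to infection, and its immune
signature is a property of a *system*, not of single genes: adaptive
immunity, antigen presentation, complement and coagulation, platelet
activity and cytokine signaling move together — or stop moving together.
`sepnet` is for computational biologists who want to study that structure
from whole-blood expression profiles of control and sepsis samples (or
sepsis survivors vs nonsurvivors): it builds a co-expression graph per
condition, measures its topology, and asks which immune functional
categories cluster, which detach into isolated components, and how the two
conditions differ.

## What it computes

* **Annotation** — each gene is assigned one of ten immune functional
  categories (adaptive immunity, antigen presentation,
  complement-coagulation, cytokines-chemokines, hematopoiesis, innate
  immunity, leukocyte migration, NK cell activity, platelet activity,
  signaling) by majority vote over its KEGG / GO / Reactome pathway
  memberships, with defined tie rules (a tie mixing specific categories
  with the broad trio cytokines-chemokines/signaling/hematopoiesis drops
  the trio; unresolved ties are `U`).
* **Differential expression** — per-gene two-sided Welch t between groups,
  Benjamini–Hochberg FDR (default threshold 0.01).
* **Gene set enrichment** — a GAGE-style competitive statistic: per case
  sample, fold changes against the control mean; per set, a two-sample t
  of the set vs the background; per-sample one-sided p-values combined by
  covariance-corrected Stouffer, Z = Σz / √(m + m(m−1)ρ) with
  ρ = (1/n_c)/(1 + 1/n_c), reported separately for up and down (global
  p < 0.05).
* **Network** — nodes are annotated immune genes; an undirected edge joins
  genes with Spearman ρ ≥ 0.8 (inclusive, signed) and p < 0.05 within a
  group's samples; degree-0 genes are dropped.
* **Topology** — clustering coefficient, density, heterogeneity
  (CV of degree), components, diameter, centralization, shortest-path
  count, characteristic path length, average degree, node count, degree
  assortativity, greedy (CNM) modularity, plus per-node degree, clustering,
  betweenness, closeness, stress, eccentricity and topological coefficient.
* **Comparison** — per-parameter percent difference
  (case − control)/control × 100, hypergeometric detection of prominent
  isolated category clusters, and cross-dataset consensus tallies.
* **Synthetic data** — an equicorrelated-block Gaussian simulator with
  planted group-specific correlation blocks and mean shifts, so every stage
  is testable with known ground truth.

## Worked example

```r
library(sepnet)

d   <- generate_dataset(synthetic_config(seed = 42))
d$matrix
#> <expr_matrix> 320 genes x 50 samples (25 control, 25 case)

cm  <- spearman_matrix(d$matrix, "case")
net <- build_network(cm, d$truth$category_map)   # rho >= 0.8, p < 0.05
topology_report(net)
#> <topology_report>
#>                   parameter       value
#>      Clustering coefficient   0.9401552
#>             Network density   0.4677419
#>       Network heterogeneity   0.2345081
#>        Connected components   2.0000000
#>            Network diameter   2.0000000
#>      Network centralization   0.1548387
#>               Shortest path 512.0000000
#>  Characteristic path length   1.0937500
#>         Average degree, <k>  14.5000000
#>          Number of nodes, N  32.0000000
#>      Degree correlation, mu   0.6877356
#>              Modularity, Mc   0.4033517

detect_isolated_clusters(net, d$truth$category_map)[, c(2, 3, 6, 8)]
#>   size dominant_category     p_enrich is_isolated
#> 1   20 adaptive immunity 5.888899e-19       FALSE
#> 2   12 platelet activity 4.043489e-12        TRUE

deg <- welch_t(d$matrix)
sum(deg$significant)   # planted 20-gene shift recovered at FDR < 0.01
#> [1] 20
```

The case-group network contains exactly the two planted structures: the
20-gene adaptive-immunity block (the dense main component, category
enrichment p ≈ 6 × 10⁻¹⁹ against the 320-gene annotated universe) and the
12-gene platelet block as an isolated component. The remaining 288
independent genes form no edges at ρ ≥ 0.8 and are dropped. In the control
group only the shared platelet block appears, so the percent-difference
report (`compare_reports`, `run_pipeline`) contrasts a 12-node control
network with a 32-node case network.

The whole analysis runs as one call:

```r
bundle <- run_pipeline(pipeline_config(seed = 42), "out/")
```

writing the expression matrix, annotation, DEG and enrichment tables,
per-group GraphML networks, topology reports, cluster findings, the
comparison table and a manifest; identical config + seed reruns are
bit-identical. A thin CLI over the same functions ships in
`inst/scripts/sepnet` (subcommands `simulate`, `run-all`, `annotate`,
`topology`, `compare`).

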