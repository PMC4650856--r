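# grnpath

Network-guided discovery of disease genes and differential-diagnosis
biomarkers from paired mRNA/miRNA expression profiles.

`grnpath` is written for the setting where a rare tumour entity (the
motivating case is the solid pseudopapillary neoplasm of the pancreas, SPN)
must be told apart from malignant look-alikes (PanNET, PDAC) using small
microarray cohorts, a handful of literature-reported disease genes, and
large noisy catalogues of predicted TF and miRNA target regulations. It
provides the full analysis chain as tested, composable R functions:

1. **Preprocessing** — log2 transform and quantile normalization of the
   mRNA and miRNA matrices (each platform normalized independently).
2. **Candidate network** — merge predicted and experimentally validated
   regulation lists (TF→gene, TF→miRNA, miRNA→gene) with provenance.
3. **Tissue-specific GRN** — score every candidate edge by the Pearson
   correlation α of its endpoints across the disease samples; choose the
   |α| cutoff by the power-law fitness of the degree distribution
   (p(k) = k^−λ, fit by least squares on the log–log scale; scale-free
   regulatory networks show 2 < λ < 3) and keep edges with |α| ≥ cutoff
   (default 0.8).
4. **Shortest-path candidates** — weight each retained edge by
   β = 1 − |α| (small β = strong regulation) and run Dijkstra between all
   pairs of seed genes; interior nodes of the shortest paths are new
   disease-gene candidates by guilt-by-association.
5. **DE + enrichment** — call differential expression with Student's
   t-test (P < 0.01) plus median-ratio fold change (≥ 2 or ≤ 0.5) and
   test the path genes for DE enrichment with Fisher's exact test.
6. **Biomarker selection** — evaluate candidate genes with a KNN
   classifier (Euclidean distance, Chou's cumulative voting over
   K = 1..k_max) under jackknife (leave-one-out) validation
   (accuracy = 100 · correct / total), and assemble gene sets that
   discriminate the disease from its malignant mimics.

A synthetic-data generator (`synthetic_config()` / `simulate_study()`)
plants co-expressed regulations with known α, decoy edges, DE genes and
class-separating biomarkers at the study's sample sizes (14 SPN / 6
PanNET / 6 PDAC / 5 normal), so every stage can be validated against
ground truth.

## Worked example

```r
library(grnpath)
report <- run_pipeline(list(simulate = list(), rng_seed = 1))
print(report)
```

```
grn pipeline report
  config hash   ede21211f8beea065d4176728814e093
  GRN           57 nodes, 41 edges
  DE SPN_vs_normal      16 features
  DE PanNET_vs_normal   0 features
  DE PDAC_vs_normal     0 features
  DE SPN_vs_PanNET      16 features
  DE SPN_vs_PDAC        16 features
  paths         42 (unreachable pairs: 168)
  path genes    2
  biomarkers SPN_vs_malignant 1 gene(s), 100.0% accuracy
  biomarkers SPN_vs_PanNET    1 gene(s), 100.0% accuracy
  biomarkers SPN_vs_PDAC      1 gene(s), 100.0% accuracy
```

Reading this: from the simulated cohort the pipeline retained 41 of the
candidate regulations at |α| ≥ 0.8 (57 network nodes), found 16
differentially expressed features for SPN versus normal (the 10 planted
DE genes plus the 6 planted biomarkers, which are shifted in SPN by
construction), computed 42 seed-pair shortest paths (most of the 26 × 25/2
seed pairs are unreachable, as expected when seeds sit in different
network components), recovered the 2 planted path-intermediate regulators
as new candidates, and for each diagnostic contrast selected a biomarker
set reaching 100 % jackknife accuracy. Individual stages are available as
plain functions (`score_edges()`, `fit_power_law()`, `seed_pair_paths()`,
`call_de()`, `fisher_enrichment()`, `jackknife_accuracy()`, ...) and
accept file inputs in plain TSV formats; see the vignette in
`vignettes/grnpath-methods.Rmd`.

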