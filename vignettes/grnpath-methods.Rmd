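---
title: "grnpath: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{grnpath: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnpath)
```

## The problem and the model

`grnpath` implements a network-guided strategy for finding disease genes
and differential-diagnosis biomarkers when cohorts are small. The
motivating setting is a rare, mostly benign pancreatic tumour (SPN) that
must be distinguished from malignant mimics (PanNET, PDAC) with roughly a
dozen samples per class. Direct genome-wide differential expression at
this scale is noisy; the strategy instead narrows the search space in
three steps.

**Step 1: a tissue-specific gene regulatory network (GRN).** Candidate
regulations come from target-prediction tools and curated interaction
databases, as plain regulator→target lists in three categories: TF→gene,
TF→miRNA, miRNA→gene. These catalogues are tissue-agnostic and noisy, so
each candidate edge is scored by the Pearson correlation $\alpha$ of its
endpoints' log2 expression across the disease samples, and only edges
with $|\alpha| \ge c$ are kept. The cutoff $c$ is chosen so the network
is approximately scale-free: for each candidate cutoff the degree
distribution of each regulator-class sub-network is fit by
$p(k) = k^{-\lambda}$, estimated by ordinary least squares of
$\log_{10} p(k)$ on $\log_{10} k$, and the fit's $R^2$ is the fitness
criterion. Hierarchical biological networks typically show
$2 < \lambda < 3$; raising the cutoff improves fitness but shrinks the
network, so the final cutoff is an explicit, user-visible compromise
(default $0.8$ for both regulator classes, where the underlying analysis
was also robust from 0.6 to 0.8).

**Step 2: shortest-path candidates.** Known disease genes ("seeds",
literature-derived) are mapped into the GRN, each edge is weighted
$\beta = 1 - |\alpha|$ so that strong co-expression means short
distance, and Dijkstra's algorithm finds the minimum-total-$\beta$ path
between every seed pair. Genes interior to these paths are new
candidates under guilt-by-association: a gene that transmits regulation
between two disease genes plausibly shares their biology. The candidates
are sanity-checked by asking whether they are enriched in differentially
expressed features (Fisher's exact test), since genes involved in the
disease should tend to be deregulated in it.

**Step 3: biomarker sets.** The pooled candidate list (seeds plus path
genes) is screened with a K-nearest-neighbour classifier on log2
expression (Euclidean distance). Instead of committing to one K, Chou's
cumulative voting scores each class $m$ by
$Y_m = \sum_{K=1}^{k_{\max}} |\{ \text{class-}m \text{ samples among the
} K \text{ nearest} \}|$, i.e. the neighbour at rank $r$ contributes
$k_{\max} - r + 1$ votes; $k_{\max} = 1$ reduces to plain 1-NN.
Performance is assessed by the jackknife (leave-one-out): every sample is
predicted from all others and accuracy is $100 \cdot
\text{correct}/\text{total}$, the least arbitrary of the standard
cross-validation schemes at these sample sizes.

## Differential expression

Two groups are compared per contrast (disease vs normal and the
disease-vs-disease contrasts used for differential diagnosis). A feature
is called DE when the two-sided equal-variance Student's t-test gives
$P < 0.01$ (strict) *and* the median-ratio fold change — computed on
log2 data as $2^{\mathrm{median}(A) - \mathrm{median}(B)}$ — is $\ge 2$
or $\le 0.5$ (inclusive). No multiple-testing correction enters the
call, matching the procedure the pipeline reproduces; a
Benjamini–Hochberg FDR column is emitted for information. A Welch
variant is available behind `var_equal = FALSE`. Degenerate inputs
follow explicit conventions: two constant groups give $p = 1$ when their
means agree and $p = 0$ otherwise; groups of size one are an error.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `cutoff_tf`, `cutoff_mirna` | 0.8 | minimum \|α\| per regulator class; ties retained |
| correlation samples | disease class only | the GRN is tissue-specific; `"all"` uses every shared sample |
| `p_threshold` | 0.01 | strict t-test gate |
| `fc_threshold` | 2 | fold change ≥ 2 or ≤ 0.5, inclusive |
| `path_mode` | undirected | see below |
| `k_max` | 3 | Chou voting horizon; the smallest class keeps 4–5 same-class neighbours under leave-one-out |
| selection strategy | greedy | forward selection by singleton accuracy; `threshold` keeps all genes at/above a singleton-accuracy bar |

The default correlation sample set is the disease class (n = 14 at the
default design). Correlations estimated from 14 samples are noisy
(`atanh`-scale standard error $\approx 0.30$), which is why edge
retention at the 0.8 cutoff is imperfect even for strongly co-expressed
pairs; this is a property of the study design, not of the
implementation.

## The synthetic-data generator

`synthetic_config()` defines a simulated study; defaults mirror the
motivating cohort: 14/6/6/5 samples over SPN/PanNET/PDAC/normal, a
26-feature seed list composed of 4 TFs, 7 miRNAs and 15 genes, and log2
expression with baseline 8 and within-class standard deviation 0.5.

Co-expression is planted through shared latent signals rather than by
simulating regulation kinetics: each feature has a standardized latent
signal; a true edge's target mixes its regulator's signal with fresh
noise as $u_t = s\,\alpha\, u_r + \sqrt{1-\alpha^2}\,\varepsilon$, so the
population correlation along the edge is exactly `alpha_true` (default
0.9), with sign $s = -1$ for miRNA regulators (miRNAs repress their
targets; the pipeline uses $|\alpha|$, so the sign only tests the
absolute-value handling). Each target has exactly one true regulator, so
planted correlations are analytic. Decoy edges (default half of the
candidate set) connect features with independent latent roots,
emulating false target predictions. Planted DE genes receive a
class-mean shift of `de_log2fc` (default 2 log2 units) in SPN; planted
biomarkers a shift of `biomarker_shift` (default 3) separating SPN from
every other class.

**Path-structure redundancy.** Two designated "hub" regulators (one
miRNA, one TF) each regulate seven of the seed genes, so seed pairs are
connected through them and the hubs are the ground-truth path
intermediates. The redundancy (2 hubs × 7 targets, the maximum under the
26-seed composition) is a deliberate identifiability choice: all edges
at one hub share the hub's realized sample signal, so their estimated
correlations rise and fall together, and recovery of a hub requires at
least two of its edges to survive the cutoff. Under the default design
(n = 14, $\alpha$ = 0.9, cutoff 0.8) per-edge retention is around 0.9
(the acceptance script measures the realized recall) and these
correlated failures would make small hubs unreliable; seven targets per
hub keep the planted structure recoverable in nearly every simulated
cohort.

Biomarker genes are drawn from the hub-target seed genes. A
class-constant shift leaves within-class correlations untouched, so this
does not interfere with edge recovery, and it places the planted
discriminative genes inside the seed-plus-path candidate pool that the
classifier actually searches — as literature seeds are in the real
analysis.

**What the generator does not emulate.** Probe-level microarray noise,
batch effects, cross-platform intensity differences, genome-scale
feature counts, and — importantly — realistic in-degree structure:
because every target has exactly one true regulator, the in-degree
distribution of the synthetic GRN collapses toward 1 at high cutoffs and
the in-degree power-law fit is frequently undefined there (the scan
flags these rows with `fit_ok = FALSE`). On real catalogues, where
targets have many candidate regulators, the in-degree fit is the
informative one; on synthetic data the out-degree fits carry the signal.
For the same reason the qualitative "fitness rises with the cutoff"
behaviour seen on real data is not reliably reproduced by the generator,
and passing tests on synthetic data say nothing about it. The cutoff
scan is therefore advisory everywhere: selection is an explicit
configuration choice.

## Numerical choices and conventions

* **Quantile normalization** maps each column's ranks to per-rank means
  across columns; ties receive the mean of the reference values at the
  occupied ranks, so results do not depend on sort stability. Each
  platform (mRNA, miRNA) is normalized independently and no
  cross-platform rescaling is applied before correlation; Pearson
  correlation is location/scale invariant per feature, so this mainly
  matters for the classifier, which uses features on their own log2
  scales without re-standardization (an explicit design choice; a z-score
  flag would be a sensitivity analysis, not a default).
* **Missing values** are rejected outright rather than imputed.
* **Power-law fit**: unbinned empirical density over distinct degrees
  $k \ge 1$; zero-frequency bins are excluded (log undefined); at least
  three distinct degrees are required, otherwise the fit is flagged
  undefined. A flat distribution has slope 0 by the closed-form OLS
  estimate. Maximum-likelihood (Clauset-style) fitting with $x_{\min}$
  estimation is intentionally out of scope: the log–log $R^2$ *is* the
  selection criterion being reproduced.
* **Path graph**: undirected by default — many seeds are pure targets
  with zero out-degree, and paths between such pairs exist only in the
  undirected view; directed mode is available for sensitivity analysis.
  Antiparallel duplicates merge keeping the smaller β. Zero-weight edges
  ($|\alpha| = 1$) are legal and traversed at no cost.
* **Path tie-breaking** among equal-β shortest paths is deterministic:
  fewest hops, then lexicographically smallest node sequence;
  `all_co_optimal = TRUE` enumerates all tied paths so their interior
  nodes can be pooled.
* **Seeds absent from the GRN** are skipped with a warning, and seed
  pairs in different components are counted, not errors — with real
  catalogues not every literature gene participates.
* **Fisher's exact test** is the conditional hypergeometric test;
  two-sided p sums all tables at most as likely as the observed one.
  Degenerate margins give $p = 1$. Both background conventions are
  reported: `disjoint` removes the candidate set from the background row
  (standard enrichment practice); `overlapping` keeps the printed
  background totals. The enrichment conclusion should be — and in the
  motivating overlap counts is — stable across both.
* **KNN determinism**: equidistant neighbours rank by sample id; tied
  class scores resolve to the nearest neighbour's class when it is among
  the tied classes, then lexicographically. The cumulative-voting form
  of the classifier score is implemented as stated above; it reduces
  exactly to 1-NN at $k_{\max} = 1$, which the test suite checks
  exhaustively on random data.
* **Jackknife under permuted labels** averages slightly *below* 50 % on
  balanced two-class data (≈ 47 % at 10 + 10): leaving out the test
  sample makes its own class the minority among the training samples.
  This is a property of leave-one-out, not a bias in the
  implementation.

## Problem sizes used by the test suite

The suite validates the stages on simulated cohorts at the study's
sample sizes with 80 genes, 12 TFs and 12 miRNAs per cohort (edge
recovery, path-intermediate recovery, DE sensitivity/specificity and
biomarker selection are measured over 20 cohorts), checks the Dijkstra
implementation against exhaustive simple-path enumeration on random
graphs of up to 8 nodes, the Fisher p-value against hypergeometric
enumeration on all 2×2 tables with total ≤ 30, and power-law exponent
recovery both on exact $k^{-2.5}$ input and on preferential-attachment
graphs of 3000 nodes. Feature counts are configurable; nothing in the
implementation depends on these sizes.

## Known limitations

* The published analyses this pipeline operationalizes do not state the
  rule by which final biomarker sets were assembled from per-gene
  accuracies; the selection strategy is therefore pluggable (greedy
  forward selection by default), and no claim is made to reproduce
  specific published gene lists.
* Headline counts of the motivating study (network size, number of
  paths and path genes) depend on external target-prediction catalogues
  and the original cohort and are not reproducible from this package
  alone; the package reproduces the *procedure* and validates it on
  planted ground truth.
* Union semantics between predicted and validated regulation sources are
  a plain provenance-preserving union; no priority rule is applied.
* Equal-variance Student's t is the default deliberately (it is the
  named test of the reproduced procedure); with strongly unequal group
  variances the Welch flag is the statistically safer choice.
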