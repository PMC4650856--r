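Package: grnpath
Title: Gene Regulatory Network Construction, Shortest-Path Gene Discovery
    and KNN Biomarker Selection from Paired mRNA/miRNA Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds tissue-specific gene regulatory networks from candidate
    TF and miRNA regulations by Pearson co-expression filtering with a
    scale-free (power-law fitness) correlation cutoff, discovers new
    disease-gene candidates as intermediates on beta-weighted (beta = 1 -
    |alpha|) shortest paths between known seed genes, tests candidates for
    enrichment in differentially expressed features (Student's t-test plus
    median-ratio fold change, Fisher's exact test), and selects
    differential-diagnosis biomarker gene sets with a K-nearest-neighbour
    classifier using Chou's cumulative voting, evaluated by jackknife
    (leave-one-out) accuracy. Includes a synthetic-data generator that
    plants co-expressed regulations, differentially expressed genes and
    class-separating biomarkers so every stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
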