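Package: utr3scape
Title: Comparative Analysis of 3' UTR Length Evolution Across Metazoan Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of mRNA 3' untranslated region (UTR)
    lengths across fruit fly, zebrafish, mouse and human. Provides curation of
    mRNA records (RefSeq-style NM_ prefix, completeness and minimum-length
    filters, longest-transcript selection), per-region length summaries and
    pairwise log2 length correlations, 3'/5' UTR length-ratio distributions,
    k-means clustering of ortholog-group 3' UTR length trajectories across the
    four species, a GO-term frequency-matrix PCA of length-quartile gene sets
    with a permutation test for functional divergence, and notched-boxplot
    median comparisons across tissue-expression and subcellular-localization
    categories. A synthetic-cohort generator with recorded ground truth
    emulates every input so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, graphics, grDevices, tools, Matrix, jsonlite
Suggests: testthat (>= 3.0.0), mclust, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
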