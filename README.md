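# utr3scape

Comparative analysis of mRNA 3' untranslated region (UTR) lengths across
four metazoan species — fruit fly (Dme), zebrafish (Dre), mouse (Mmu) and
human (Hsa) — for researchers studying the evolution and functional load of
untranslated regions.

The pipeline:

1. **Curation** — parse mRNA records (minimal GenBank-style flat file or
   length TSV), keep curated `NM_` records that are complete on both ends
   with 5'UTR ≥ 30 nt and 3'UTR ≥ 50 nt, and select the longest transcript
   per gene. With 1-based closed CDS coordinates,
   `len5 = cds_start − 1`, `len3 = seq_length − cds_end`.
2. **Length statistics** — per-species summaries of the three regions,
   pairwise Pearson correlations on log2 lengths, and the per-gene ratio
   `len3/len5` summarized by its survival fractions at thresholds 2 and 5.
3. **Ortholog trajectories** — per ortholog group the ordered 4-vector of
   3'UTR lengths (within-species co-orthologs averaged), clustered by Lloyd
   k-means (Euclidean, log2 space, best of 25 starts, k = 4 by default).
4. **Functional divergence** — genes cut into length quarters Q1..Q4; the
   GO frequency matrix *M* (m terms × n sets, m\_ij = distinct genes of set
   j carrying term i) is scaled by centered PCA, and the dispersion of the
   set profiles — Σ\_j ‖x\_j − x̄‖² / (n − 1) in the full feature space — is
   compared with B random equal-sized partitions:
   p = (1 + #{null ≥ observed}) / (B + 1).
5. **Expression categories** — per human tissue/subcellular category the
   median 3'UTR length with the McGill notch interval
   median ± 1.57 · IQR / √n, plus a descriptive notch-overlap matrix.

A synthetic-cohort generator (`CohortConfig()` / `generateCohort()`)
emulates every input with recorded ground truth — planted filter
violations, trajectory archetypes, GO–length association, category median
shifts — so each stage is testable against an oracle.

## Worked example

```r
library(utr3scape)

cohort <- generateCohort(CohortConfig(seed = 1L, nGenesPerSpecies = 4000L,
                                      nOrthologGroups = 800L))
runPipeline(cohort, "demo", B = 199L)

lengths <- readTable("demo/lengths.tsv")
tapply(lengths$len3, lengths$species, median)
#>    Dme    Dre    Hsa    Mmu
#>  430.0  613.5 1204.0  893.0
```

Median 3'UTR length lengthens from 430 nt in fly to 1204 nt in human while
the CDS median stays within 2% across the two species
(`median(hsa$len_cds)/median(dme$len_cds)` = 0.98): the 3'UTR, not the
coding region, carries the inter-species length signal. The ratio table
(`demo/ratios.tsv`) shows 74% of fly genes with 3'UTR at least twice the
5'UTR, and 77% of human genes with the ratio at least five.

```r
clusters <- readTable("demo/clusters.tsv")
readTable("demo/centers.tsv")[c("cluster", "size", "pct", "pattern")]
#>   cluster size       pct    pattern
#> 1       1  126 53.389831 increasing
#> 2       2   57 24.152542 increasing
#> 3       3   31 13.135593 increasing
#> 4       4   22  9.322034      mixed
```

The dominant trajectory cluster (53% of ortholog groups) increases
steadily across the species order, recovering the planted archetype mixture
(adjusted Rand index 0.96 against ground truth). `demo/divergence.json`
holds the permutation p-values of the quartile-vs-random gene-set
comparison, and `demo/category_medians.tsv` the notched category medians —
in this cohort the "Mixed" tissue category has the longest human 3'UTRs
(median 1497 nt, 1.37× the "Tissue enriched" median), as planted.

## Documentation

The methods vignette (`vignettes/utr3scape-methods.Rmd`) documents the
models, the generator's defaults and what they do and do not emulate, the
numerical conventions (quantile type, tie-breaks, PCA centering, the
add-one permutation estimator) and known limitations.
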