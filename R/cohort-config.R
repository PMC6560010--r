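#' Build a synthetic-cohort configuration
#'
#' Constructor for [CohortConfig-class]. Defaults describe a cohort that
#' mirrors the qualitative landscape seen in curated metazoan mRNA sets:
#' 3'UTR medians lengthen from fruit fly to human while CDS lengths stay
#' near constant, a majority trajectory archetype increases steadily across
#' the four species with a minority archetype longest in fly, ubiquitously
#' expressed human genes ("Mixed") carry longer 3'UTRs, and a mild GO-term /
#' length association is planted. All lengths are drawn log-normally (log2
#' scale) because empirical UTR lengths are heavy-tailed.
#'
#' Clean records are truncated at the curation thresholds (5'UTR >= 30 nt,
#' 3'UTR >= 50 nt) so that filter violations exist if and only if they are
#' planted; the sub-threshold tail mass of the untruncated distributions is
#' negligible (~5e-4).
#'
#' @param seed integer RNG seed.
#' @param nGenesPerSpecies genes per species.
#' @param utr3Log2Median per-species log2 medians of 3'UTR length, species
#'   order Dme, Dre, Mmu, Hsa. Defaults to c(8.8, 9.3, 9.7, 9.8), i.e.
#'   medians of about 445, 630, 830 and 890 nt.
#' @param utr3Log2Sd sd of log2 3'UTR length (default 1.0).
#' @param utr5Log2Median,utr5Log2Sd log2 5'UTR length distribution; default
#'   median 2^7 = 128 nt, within the 100-200 nt band typical of metazoan
#'   5'UTRs.
#' @param cdsLog2Median,cdsLog2Sd log2 CDS length distribution; default
#'   median 2^10.5 ~ 1448 nt, shared by all species.
#' @param regionLog2Correlation planted pairwise correlation of the log2
#'   scores of the three regions (default 0 = independent).
#' @param fracViolating named violation rates for the four curation filters.
#' @param transcriptsPerGeneMean Poisson mean of extra transcripts per gene.
#' @param nOrthologGroups planted ortholog groups (members are drawn from the
#'   head of each species' gene list).
#' @param trajectoryArchetypes k x 4 matrix of archetype log2 means; defaults
#'   to four patterns: steady increase (dominant), longest-in-fly, late
#'   expansion in the mammal lineage, and an early jump after fly.
#' @param archetypeWeights mixing weights, summing to 1.
#' @param trajectoryLog2Sd noise sd around archetype coordinates.
#' @param coOrthologProb probability of a second within-species co-ortholog.
#' @param nGoTerms GO vocabulary size.
#' @param goTermsPerGeneMean Poisson mean of annotations per gene.
#' @param fracAssociatedTerms fraction of terms flagged length-associated.
#' @param goAssociationStrength additive log2 shift of 3'UTR length for genes
#'   carrying an associated term (0 disables the planted association).
#' @param categoryMedianShifts named multiplicative 3'UTR shifts per tissue
#'   category for human genes.
#' @param subcellularFrac fraction of human genes assigned a subcellular
#'   category.
#' @return A validated [CohortConfig-class] object.
#' @examples
#' cfg <- CohortConfig(seed = 1L, nGenesPerSpecies = 200L)
#' cfg
#' @export
CohortConfig <- function(seed = 1L,
                         nGenesPerSpecies = 1000L,
                         utr3Log2Median = c(8.8, 9.3, 9.7, 9.8),
                         utr3Log2Sd = 1.0,
                         utr5Log2Median = 7.0,
                         utr5Log2Sd = 0.7,
                         cdsLog2Median = 10.5,
                         cdsLog2Sd = 0.5,
                         regionLog2Correlation = 0,
                         fracViolating = c(nonNM = 0.30, incomplete = 0.05,
                                           shortUtr5 = 0.03, shortUtr3 = 0.03),
                         transcriptsPerGeneMean = 0.4,
                         nOrthologGroups = 300L,
                         trajectoryArchetypes = defaultArchetypes(),
                         archetypeWeights = c(0.55, 0.10, 0.20, 0.15),
                         trajectoryLog2Sd = 0.3,
                         coOrthologProb = 0.15,
                         nGoTerms = 300L,
                         goTermsPerGeneMean = 5,
                         fracAssociatedTerms = 0.1,
                         goAssociationStrength = 0.5,
                         categoryMedianShifts = c("Mixed" = 1.5,
                                                  "Expressed in all" = 1.2),
                         subcellularFrac = 0.4) {
  new("CohortConfig",
      seed = as.integer(seed),
      nGenesPerSpecies = as.integer(nGenesPerSpecies),
      speciesOrder = SPECIES_ORDER,
      utr3Log2Median = as.numeric(utr3Log2Median),
      utr3Log2Sd = as.numeric(utr3Log2Sd),
      utr5Log2Median = as.numeric(utr5Log2Median),
      utr5Log2Sd = as.numeric(utr5Log2Sd),
      cdsLog2Median = as.numeric(cdsLog2Median),
      cdsLog2Sd = as.numeric(cdsLog2Sd),
      regionLog2Correlation = as.numeric(regionLog2Correlation),
      fracViolating = fracViolating[c("nonNM", "incomplete", "shortUtr5", "shortUtr3")],
      transcriptsPerGeneMean = as.numeric(transcriptsPerGeneMean),
      nOrthologGroups = as.integer(nOrthologGroups),
      trajectoryArchetypes = trajectoryArchetypes,
      archetypeWeights = as.numeric(archetypeWeights),
      trajectoryLog2Sd = as.numeric(trajectoryLog2Sd),
      coOrthologProb = as.numeric(coOrthologProb),
      nGoTerms = as.integer(nGoTerms),
      goTermsPerGeneMean = as.numeric(goTermsPerGeneMean),
      fracAssociatedTerms = as.numeric(fracAssociatedTerms),
      goAssociationStrength = as.numeric(goAssociationStrength),
      categoryMedianShifts = categoryMedianShifts,
      subcellularFrac = as.numeric(subcellularFrac))
}

#' Default trajectory archetypes
#'
#' Four log2-mean 3'UTR trajectory archetypes across (Dme, Dre, Mmu, Hsa):
#' steady increase, longest in fruit fly, late expansion in the mammalian
#' lineage, and an early jump after fly. Pairwise Euclidean separation of the
#' centers exceeds 1.5 log2 units.
#'
#' @return A 4 x 4 numeric matrix (archetype x species).
#' @export
defaultArchetypes <- function() {
  m <- rbind(
    steady_increase = c(8.2, 8.8, 9.4, 9.9),
    fly_longest     = c(10.8, 8.4, 8.6, 8.8),
    late_expansion  = c(8.2, 8.2, 10.6, 11.0),
    early_jump      = c(8.2, 10.4, 10.5, 10.6)
  )
  colnames(m) <- SPECIES_ORDER
  m
}
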