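#' @import methods
#' @importFrom stats median quantile var rnorm runif rpois rbinom sd setNames
#' @importFrom utils head
NULL

SPECIES_ORDER <- c("Dme", "Dre", "Mmu", "Hsa")

TISSUE_CATEGORIES <- c("Tissue enriched", "Group enriched", "Tissue enhanced",
                       "Expressed in all", "Mixed")
SUBCELLULAR_CATEGORIES <- c("Secreted", "Membrane", "Cytoplasm", "Mitochondria")

#' CohortConfig: parameters of the synthetic cohort generator
#'
#' Holds every knob of the synthetic-data generator: per-species log2 3'UTR
#' length distributions, a species-independent CDS length distribution,
#' planted curation-filter violation rates, ortholog trajectory archetypes,
#' GO-term/length association strength and expression-category median shifts.
#' Construct with [CohortConfig()].
#'
#' @slot seed integer RNG seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @slot nGenesPerSpecies number of genes generated per species.
#' @slot speciesOrder fixed species code order, always
#'   \code{c("Dme","Dre","Mmu","Hsa")} (fruit fly, zebrafish, mouse, human).
#' @slot utr3Log2Median per-species median of log2 3'UTR length (length 4).
#' @slot utr3Log2Sd common sd of log2 3'UTR length.
#' @slot utr5Log2Median,utr5Log2Sd log2 5'UTR length distribution (shared by
#'   all species).
#' @slot cdsLog2Median,cdsLog2Sd log2 CDS length distribution (shared by all
#'   species; CDS lengths are near constant across these taxa).
#' @slot regionLog2Correlation pairwise correlation planted between the log2
#'   scores of the three regions (equicorrelated latent factor), in [0, 1).
#' @slot fracViolating named proportions of records planted to violate each
#'   curation filter: \code{nonNM}, \code{incomplete}, \code{shortUtr5},
#'   \code{shortUtr3}.
#' @slot transcriptsPerGeneMean Poisson mean of extra (shorter) transcripts
#'   per gene beyond the primary one.
#' @slot nOrthologGroups number of planted ortholog groups.
#' @slot trajectoryArchetypes k x 4 matrix of archetype log2-mean 3'UTR
#'   lengths in species order.
#' @slot archetypeWeights mixing weights over archetypes (sum to 1).
#' @slot trajectoryLog2Sd per-coordinate noise sd around the archetype.
#' @slot coOrthologProb probability that a group carries a second co-ortholog
#'   in a given species.
#' @slot nGoTerms size of the flat GO term vocabulary.
#' @slot goTermsPerGeneMean Poisson mean of GO annotations per gene (before
#'   de-duplication).
#' @slot fracAssociatedTerms fraction of terms flagged as length-associated.
#' @slot goAssociationStrength additive log2 3'UTR shift for genes annotated
#'   with at least one associated term (0 = null).
#' @slot categoryMedianShifts named multiplicative 3'UTR length shifts per
#'   tissue category (applied to human genes).
#' @slot subcellularFrac fraction of human genes given a subcellular
#'   localization category.
#' @export
setClass("CohortConfig",
  slots = c(
    seed = "integer",
    nGenesPerSpecies = "integer",
    speciesOrder = "character",
    utr3Log2Median = "numeric",
    utr3Log2Sd = "numeric",
    utr5Log2Median = "numeric",
    utr5Log2Sd = "numeric",
    cdsLog2Median = "numeric",
    cdsLog2Sd = "numeric",
    regionLog2Correlation = "numeric",
    fracViolating = "numeric",
    transcriptsPerGeneMean = "numeric",
    nOrthologGroups = "integer",
    trajectoryArchetypes = "matrix",
    archetypeWeights = "numeric",
    trajectoryLog2Sd = "numeric",
    coOrthologProb = "numeric",
    nGoTerms = "integer",
    goTermsPerGeneMean = "numeric",
    fracAssociatedTerms = "numeric",
    goAssociationStrength = "numeric",
    categoryMedianShifts = "numeric",
    subcellularFrac = "numeric"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (!identical(object@speciesOrder, SPECIES_ORDER))
    msg <- c(msg, "speciesOrder must be exactly c(\"Dme\", \"Dre\", \"Mmu\", \"Hsa\")")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single non-missing integer")
  if (length(object@nGenesPerSpecies) != 1L || object@nGenesPerSpecies < 1L)
    msg <- c(msg, "nGenesPerSpecies must be a positive integer")
  if (length(object@utr3Log2Median) != 4L)
    msg <- c(msg, "utr3Log2Median must have one value per species (length 4)")
  for (s in c("utr3Log2Sd", "utr5Log2Sd", "cdsLog2Sd", "trajectoryLog2Sd")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, paste(s, "must be a single value > 0"))
  }
  if (length(object@regionLog2Correlation) != 1L ||
      object@regionLog2Correlation < 0 || object@regionLog2Correlation >= 1)
    msg <- c(msg, "regionLog2Correlation must lie in [0, 1)")
  need <- c("nonNM", "incomplete", "shortUtr5", "shortUtr3")
  if (!identical(sort(names(object@fracViolating)), sort(need)))
    msg <- c(msg, "fracViolating must be named nonNM, incomplete, shortUtr5, shortUtr3")
  if (any(object@fracViolating < 0 | object@fracViolating > 1))
    msg <- c(msg, "fracViolating proportions must lie in [0, 1]")
  if (object@nOrthologGroups < 0L)
    msg <- c(msg, "nOrthologGroups must be >= 0")
  if (ncol(object@trajectoryArchetypes) != 4L)
    msg <- c(msg, "trajectoryArchetypes must have 4 columns (species order)")
  if (nrow(object@trajectoryArchetypes) != length(object@archetypeWeights))
    msg <- c(msg, "one mixing weight per archetype is required")
  if (abs(sum(object@archetypeWeights) - 1) > 1e-8 || any(object@archetypeWeights < 0))
    msg <- c(msg, "archetypeWeights must be non-negative and sum to 1")
  if (object@coOrthologProb < 0 || object@coOrthologProb > 1)
    msg <- c(msg, "coOrthologProb must lie in [0, 1]")
  if (object@nGoTerms < 1L)
    msg <- c(msg, "nGoTerms must be >= 1")
  if (object@fracAssociatedTerms < 0 || object@fracAssociatedTerms > 1)
    msg <- c(msg, "fracAssociatedTerms must lie in [0, 1]")
  if (object@goAssociationStrength < 0)
    msg <- c(msg, "goAssociationStrength must be >= 0")
  if (any(object@categoryMedianShifts <= 0))
    msg <- c(msg, "categoryMedianShifts must be positive multiplicative factors")
  if (!all(names(object@categoryMedianShifts) %in% TISSUE_CATEGORIES))
    msg <- c(msg, "categoryMedianShifts names must be tissue categories")
  if (object@subcellularFrac < 0 || object@subcellularFrac > 1)
    msg <- c(msg, "subcellularFrac must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' UTRCohort: a generated synthetic cohort with ground truth
#'
#' Container returned by [generateCohort()]: the mRNA record table, the three
#' annotation tables the pipeline consumes, the generator's ground-truth
#' bookkeeping and the configuration that produced it all.
#'
#' @slot records data.frame of mRNA records (accession, gene_id, species,
#'   seq_length, cds_start, cds_end, incomplete_5p, incomplete_3p).
#' @slot goTable data.frame (gene_id, go_term), de-duplicated.
#' @slot orthologTable data.frame (group_id, species, gene_id).
#' @slot categoryTable data.frame (gene_id, tissue_category,
#'   subcellular_category), human genes only.
#' @slot truth list of ground-truth tables: \code{recordViolations},
#'   \code{geneLengths}, \code{groupArchetypes}, \code{termAssociation}.
#' @slot config the [CohortConfig-class] used.
#' @export
setClass("UTRCohort",
  slots = c(records = "data.frame", goTable = "data.frame",
            orthologTable = "data.frame", categoryTable = "data.frame",
            truth = "list", config = "CohortConfig")
)

setValidity("UTRCohort", function(object) {
  msg <- character()
  needRec <- c("accession", "gene_id", "species", "seq_length", "cds_start",
               "cds_end", "incomplete_5p", "incomplete_3p")
  if (!all(needRec %in% names(object@records)))
    msg <- c(msg, "records is missing required columns")
  needTruth <- c("recordViolations", "geneLengths", "groupArchetypes",
                 "termAssociation")
  if (!all(needTruth %in% names(object@truth)))
    msg <- c(msg, "truth must carry recordViolations, geneLengths, groupArchetypes, termAssociation")
  if (length(msg)) msg else TRUE
})

#' GeneSetPartition: labelled, disjoint, (near-)equal gene sets
#'
#' A partition of a gene universe into n ordered sets: either length quartiles
#' Q1 (shortest 3'UTRs) ... Qn (longest), or random sets R1 ... Rn serving as
#' the null contrast. Set sizes differ by at most one.
#'
#' @slot kind "length_quartile" or "random".
#' @slot sets named list of character vectors of gene ids.
#' @slot seed RNG seed for random partitions (NA for length partitions).
#' @export
setClass("GeneSetPartition",
  slots = c(kind = "character", sets = "list", seed = "integer")
)

setValidity("GeneSetPartition", function(object) {
  msg <- character()
  if (!object@kind %in% c("length_quartile", "random"))
    msg <- c(msg, "kind must be 'length_quartile' or 'random'")
  all_genes <- unlist(object@sets, use.names = FALSE)
  if (anyDuplicated(all_genes))
    msg <- c(msg, "sets must be pairwise disjoint")
  sizes <- lengths(object@sets)
  if (length(sizes) && diff(range(sizes)) > 1L)
    msg <- c(msg, "set sizes must differ by at most 1")
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "sets must carry unique labels")
  if (length(msg)) msg else TRUE
})

#' ClusteringResult: k-means clustering of ortholog trajectories
#'
#' @slot k number of clusters.
#' @slot assignments named integer vector, group_id -> cluster index; clusters
#'   are relabelled by decreasing size (cluster 1 is the largest).
#' @slot centers k x 4 matrix of cluster centers in clustering space.
#' @slot inertia total within-cluster sum of squares of the accepted solution.
#' @slot seed RNG seed used.
#' @slot transform "log2" or "identity": the space the clustering ran in.
#' @slot sizes cluster sizes.
#' @export
setClass("ClusteringResult",
  slots = c(k = "integer", assignments = "integer", centers = "matrix",
            inertia = "numeric", seed = "integer", transform = "character",
            sizes = "integer")
)

setValidity("ClusteringResult", function(object) {
  msg <- character()
  if (nrow(object@centers) != object@k)
    msg <- c(msg, "centers must have k rows")
  if (length(object@sizes) != object@k)
    msg <- c(msg, "sizes must have length k")
  if (sum(object@sizes) != length(object@assignments))
    msg <- c(msg, "cluster sizes must sum to the number of groups")
  if (length(object@assignments) &&
      (any(object@assignments < 1L) || any(object@assignments > object@k)))
    msg <- c(msg, "assignments must map every group to one of the k clusters")
  if (is.null(names(object@assignments)))
    msg <- c(msg, "assignments must be named by group_id")
  if (length(msg)) msg else TRUE
})

#' SetScaling: PCA coordinates of gene sets in GO-term frequency space
#'
#' Gene sets are the observations, GO-term frequencies the features; features
#' are centered but not variance-scaled. Coordinates are the projections on
#' the first two principal components.
#'
#' @slot coordinates n x 2 matrix of set coordinates (rownames = set labels).
#' @slot explainedVariance fractions of variance per component, non-increasing.
#' @slot degenerate TRUE when the matrix had no between-set variance (all sets
#'   map to the origin and explained variance is undefined).
#' @export
setClass("SetScaling",
  slots = c(coordinates = "matrix", explainedVariance = "numeric",
            degenerate = "logical")
)

setValidity("SetScaling", function(object) {
  msg <- character()
  if (ncol(object@coordinates) != 2L)
    msg <- c(msg, "coordinates must have 2 columns")
  ev <- object@explainedVariance
  if (!object@degenerate && length(ev)) {
    if (any(ev < -1e-12 | ev > 1 + 1e-12))
      msg <- c(msg, "explained-variance fractions must lie in [0, 1]")
    if (is.unsorted(rev(ev), strictly = FALSE))
      msg <- c(msg, "explained-variance fractions must be non-increasing")
  }
  if (length(msg)) msg else TRUE
})

#' DivergenceResult: permutation test of gene-set functional divergence
#'
#' Observed dispersion of the length-quartile partition's GO frequency matrix
#' against B random partitions of the same universe; empirical p-value with
#' the (1 + x) / (B + 1) estimator.
#'
#' @slot observed dispersion of the length-based partition.
#' @slot null dispersions of the B random partitions.
#' @slot pValue empirical p-value, in (0, 1].
#' @slot B number of random partitions.
#' @slot seed RNG seed.
#' @slot nParts number of sets per partition.
#' @export
setClass("DivergenceResult",
  slots = c(observed = "numeric", null = "numeric", pValue = "numeric",
            B = "integer", seed = "integer", nParts = "integer")
)

setValidity("DivergenceResult", function(object) {
  msg <- character()
  if (length(object@null) != object@B)
    msg <- c(msg, "null must hold exactly B dispersions")
  p <- (1 + sum(object@null >= object@observed)) / (object@B + 1)
  if (abs(p - object@pValue) > 1e-12)
    msg <- c(msg, "pValue must equal (1 + #{null >= observed}) / (B + 1)")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})
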