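#' Accessors for utr3scape S4 containers
#'
#' Small accessor family following Bioconductor conventions: slots are never
#' reached into directly by user code.
#'
#' @param object an S4 object from this package.
#' @return The corresponding component; see each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cohortRecords", function(object) standardGeneric("cohortRecords"))
#' @rdname accessors
#' @export
setGeneric("cohortTruth", function(object) standardGeneric("cohortTruth"))
#' @rdname accessors
#' @export
setGeneric("cohortConfig", function(object) standardGeneric("cohortConfig"))
#' @rdname accessors
#' @export
setGeneric("goAnnotations", function(object) standardGeneric("goAnnotations"))
#' @rdname accessors
#' @export
setGeneric("orthologGroups", function(object) standardGeneric("orthologGroups"))
#' @rdname accessors
#' @export
setGeneric("geneCategories", function(object) standardGeneric("geneCategories"))
#' @rdname accessors
#' @export
setGeneric("partitionSets", function(object) standardGeneric("partitionSets"))
#' @rdname accessors
#' @export
setGeneric("partitionKind", function(object) standardGeneric("partitionKind"))
#' @rdname accessors
#' @export
setGeneric("clusterAssignments", function(object) standardGeneric("clusterAssignments"))
#' @rdname accessors
#' @export
setGeneric("clusterCenters", function(object) standardGeneric("clusterCenters"))
#' @rdname accessors
#' @export
setGeneric("clusterInertia", function(object) standardGeneric("clusterInertia"))
#' @rdname accessors
#' @export
setGeneric("clusterSizes", function(object) standardGeneric("clusterSizes"))
#' @rdname accessors
#' @export
setGeneric("scalingCoordinates", function(object) standardGeneric("scalingCoordinates"))
#' @rdname accessors
#' @export
setGeneric("explainedVariance", function(object) standardGeneric("explainedVariance"))
#' @rdname accessors
#' @export
setGeneric("observedDispersion", function(object) standardGeneric("observedDispersion"))
#' @rdname accessors
#' @export
setGeneric("nullDispersions", function(object) standardGeneric("nullDispersions"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setMethod("cohortRecords", "UTRCohort", function(object) object@records)
#' @rdname accessors
#' @export
setMethod("cohortTruth", "UTRCohort", function(object) object@truth)
#' @rdname accessors
#' @export
setMethod("cohortConfig", "UTRCohort", function(object) object@config)
#' @rdname accessors
#' @export
setMethod("goAnnotations", "UTRCohort", function(object) object@goTable)
#' @rdname accessors
#' @export
setMethod("orthologGroups", "UTRCohort", function(object) object@orthologTable)
#' @rdname accessors
#' @export
setMethod("geneCategories", "UTRCohort", function(object) object@categoryTable)
#' @rdname accessors
#' @export
setMethod("partitionSets", "GeneSetPartition", function(object) object@sets)
#' @rdname accessors
#' @export
setMethod("partitionKind", "GeneSetPartition", function(object) object@kind)
#' @rdname accessors
#' @export
setMethod("clusterAssignments", "ClusteringResult", function(object) object@assignments)
#' @rdname accessors
#' @export
setMethod("clusterCenters", "ClusteringResult", function(object) object@centers)
#' @rdname accessors
#' @export
setMethod("clusterInertia", "ClusteringResult", function(object) object@inertia)
#' @rdname accessors
#' @export
setMethod("clusterSizes", "ClusteringResult", function(object) object@sizes)
#' @rdname accessors
#' @export
setMethod("scalingCoordinates", "SetScaling", function(object) object@coordinates)
#' @rdname accessors
#' @export
setMethod("explainedVariance", "SetScaling", function(object) object@explainedVariance)
#' @rdname accessors
#' @export
setMethod("observedDispersion", "DivergenceResult", function(object) object@observed)
#' @rdname accessors
#' @export
setMethod("nullDispersions", "DivergenceResult", function(object) object@null)
#' @rdname accessors
#' @export
setMethod("pValue", "DivergenceResult", function(object) object@pValue)

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig (seed ", object@seed, ")\n", sep = "")
  cat("  genes/species:", object@nGenesPerSpecies,
      " species:", paste(object@speciesOrder, collapse = " > "), "\n")
  cat("  3'UTR log2 medians:",
      paste(format(object@utr3Log2Median), collapse = ", "),
      " (sd ", object@utr3Log2Sd, ")\n", sep = "")
  cat("  ortholog groups:", object@nOrthologGroups,
      " archetypes:", nrow(object@trajectoryArchetypes), "\n")
  cat("  GO terms:", object@nGoTerms,
      " association strength:", object@goAssociationStrength, "\n")
})

setMethod("show", "UTRCohort", function(object) {
  cat("UTRCohort:", nrow(object@records), "mRNA records,",
      length(unique(object@records$gene_id)), "genes,",
      length(unique(object@orthologTable$group_id)), "ortholog groups\n")
  cat("  GO annotation pairs:", nrow(object@goTable),
      " categorized genes:", nrow(object@categoryTable), "\n")
})

setMethod("show", "GeneSetPartition", function(object) {
  cat("GeneSetPartition (", object@kind, "): ",
      length(object@sets), " sets, sizes ",
      paste(lengths(object@sets), collapse = "/"), "\n", sep = "")
})

setMethod("show", "ClusteringResult", function(object) {
  cat("ClusteringResult: k =", object@k, "on", length(object@assignments),
      "trajectories (", object@transform, "space )\n")
  cat("  sizes:", paste(object@sizes, collapse = ", "),
      " inertia:", format(object@inertia), "\n")
})

setMethod("show", "SetScaling", function(object) {
  cat("SetScaling of", nrow(object@coordinates), "gene sets")
  if (object@degenerate) {
    cat(" [degenerate: no between-set variance]\n")
  } else {
    cat("; PC1/PC2 explain",
        paste(sprintf("%.1f%%", 100 * object@explainedVariance[1:2]),
              collapse = " / "), "\n")
  }
})

setMethod("show", "DivergenceResult", function(object) {
  cat("DivergenceResult: observed dispersion", format(object@observed),
      "vs", object@B, "random partitions\n")
  cat("  empirical p =", format(object@pValue), "\n")
})
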