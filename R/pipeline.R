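#' Run the whole 3'UTR length analysis pipeline
#'
#' Orchestrates: synthesize (or ingest) -> curate -> length statistics ->
#' ortholog trajectory clustering -> functional divergence -> expression
#' categories, writing every stage output as TSV (plus a divergence JSON)
#' into \code{outDir}, and a reproducibility manifest recording package
#' version, configuration, every seed, output paths and md5 digests, and the
#' filter report. Stage outputs are pure functions of (inputs, config):
#' re-running with the same configuration reproduces byte-identical files,
#' so the manifest carries no timestamps.
#'
#' @param config a [CohortConfig-class] describing the synthetic cohort, or a
#'   [UTRCohort-class] already generated (e.g. read back from files).
#' @param outDir output directory, created if needed.
#' @param minUtr5,minUtr3 curation thresholds in nt.
#' @param k,nInit,clusterSeed k-means parameters.
#' @param B,divergenceSeed permutation-test parameters.
#' @param thresholds ratio thresholds reported.
#' @param divergenceSpecies species whose gene universes get a divergence
#'   test (default all four).
#' @return the manifest, invisibly (a list; also written as manifest.json).
#' @export
runPipeline <- function(config, outDir,
                        minUtr5 = 30L, minUtr3 = 50L,
                        k = 4L, nInit = 25L,
                        clusterSeed = NULL,
                        B = 199L, divergenceSeed = NULL,
                        thresholds = c(2, 5),
                        divergenceSpecies = SPECIES_ORDER) {
  if (is(config, "UTRCohort")) {
    cohort <- config
    config <- cohortConfig(cohort)
  } else {
    stopifnot(is(config, "CohortConfig"))
    cohort <- generateCohort(config)
  }
  if (is.null(clusterSeed)) clusterSeed <- config@seed + 101L
  if (is.null(divergenceSeed)) divergenceSeed <- config@seed + 202L
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  path <- function(f) file.path(outDir, f)

  ## curation
  filt <- filterCurated(cohortRecords(cohort), minUtr5 = minUtr5,
                        minUtr3 = minUtr3)
  representative <- selectLongestPerGene(filt$records)
  lengths <- suppressWarnings(toLengthTable(representative))
  report <- rbind(filt$report,
                  data.frame(step = "longest_per_gene",
                             n = nrow(representative)))
  writeTable(lengths, path("lengths.tsv"))
  writeTable(report, path("filter_report.tsv"))

  ## length statistics
  writeTable(summarizeLengths(lengths), path("summary.tsv"))
  writeTable(pairwiseCorrelation(lengths), path("correlations.tsv"))
  ratio <- ratioDistribution(lengths, thresholds = thresholds)
  writeTable(ratio$fractions, path("ratios.tsv"))

  ## trajectories
  traj <- suppressMessages(
    buildTrajectories(orthologGroups(cohort), lengths, onMissing = "drop"))
  clusters <- NULL
  if (nrow(traj) >= k) {
    clusters <- clusterTrajectories(traj, k = k, seed = clusterSeed,
                                    nInit = nInit)
    writeTable(traj, path("trajectories.tsv"))
    writeTable(data.frame(group_id = names(clusterAssignments(clusters)),
                          cluster = unname(clusterAssignments(clusters))),
               path("clusters.tsv"))
    writeTable(clusterSummary(clusters), path("centers.tsv"))
  }

  ## functional divergence, per species
  divergence <- list()
  for (s in divergenceSpecies) {
    sub <- lengths[lengths$species == s, , drop = FALSE]
    if (nrow(sub) < 4L * 2L) next
    dt <- divergenceTest(sub, goAnnotations(cohort), nParts = 4L, B = B,
                         seed = divergenceSeed)
    part <- partitionByLength(sub)
    M <- buildGoMatrix(part, goAnnotations(cohort))
    sc <- scaleSets(M)
    divergence[[s]] <- list(observed = observedDispersion(dt),
                            p = pValue(dt), B = dt@B, seed = dt@seed,
                            explained_variance = explainedVariance(sc)[1:2])
  }
  jsonlite::write_json(divergence, path("divergence.json"),
                       auto_unbox = TRUE, digits = NA)

  ## expression categories (human)
  hsaLengths <- lengths[lengths$species == "Hsa", , drop = FALSE]
  catComparison <- compareCategories(hsaLengths, geneCategories(cohort),
                                     axis = "tissue")
  writeTable(catComparison$medians, path("category_medians.tsv"))
  writeTable(as.data.frame(catComparison$overlap), path("overlap.tsv"))

  files <- list.files(outDir, full.names = TRUE)
  manifest <- list(
    package = as.character(utils::packageVersion("utr3scape")),
    seeds = list(cohort = config@seed, cluster = clusterSeed,
                 divergence = divergenceSeed),
    parameters = list(minUtr5 = minUtr5, minUtr3 = minUtr3, k = k,
                      nInit = nInit, B = B, thresholds = thresholds),
    filter_report = report,
    outputs = as.list(setNames(unname(tools::md5sum(files)),
                               basename(files)))
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
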