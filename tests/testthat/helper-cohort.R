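# Shared fixture factories: everything is generated in code, nothing stored.

noViolations <- c(nonNM = 0, incomplete = 0, shortUtr5 = 0, shortUtr3 = 0)

# Small cohort with planted violations and all annotation tables.
smallConfig <- function(seed = 1L, ...) {
  CohortConfig(seed = seed, nGenesPerSpecies = 120L, nOrthologGroups = 20L, ...)
}

# Cohort stripped of every planted effect: no violations, single transcript
# per gene, null GO association, no category shifts. Any of those can be
# re-planted explicitly through ...
cleanConfig <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(fracViolating = noViolations,
                   transcriptsPerGeneMean = 0,
                   goAssociationStrength = 0,
                   categoryMedianShifts = c(Mixed = 1))
  defaults <- defaults[!names(defaults) %in% names(args)]
  do.call(CohortConfig, c(list(seed = seed), defaults, args))
}

# Curation chain: records -> filtered -> representative -> length table.
curatedLengths <- function(cohort) {
  filt <- filterCurated(cohortRecords(cohort))
  suppressWarnings(toLengthTable(selectLongestPerGene(filt$records)))
}

# Minimal hand-built record table.
makeRecords <- function(accession, len5, len_cds, len3,
                        gene_id = paste0("g", seq_along(accession)),
                        species = "Hsa",
                        incomplete_5p = FALSE, incomplete_3p = FALSE) {
  data.frame(accession = accession, gene_id = gene_id, species = species,
             seq_length = len5 + len_cds + len3,
             cds_start = len5 + 1L, cds_end = len5 + len_cds,
             incomplete_5p = incomplete_5p, incomplete_3p = incomplete_3p,
             stringsAsFactors = FALSE)
}

makeLengthTable <- function(len3, len5 = 100L, len_cds = 900L,
                            gene_id = sprintf("g%03d", seq_along(len3)),
                            species = "Hsa") {
  data.frame(gene_id = gene_id, species = species,
             accession = paste0("NM_", seq_along(len3), ".1"),
             len5 = len5, len_cds = len_cds, len3 = len3,
             stringsAsFactors = FALSE)
}
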