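#' Generate a synthetic mRNA cohort with ground truth
#'
#' Draws a complete set of pipeline inputs — mRNA records, GO annotations,
#' ortholog groups and human expression categories — from the generative
#' model described by a [CohortConfig-class], and records the ground truth of
#' every planted effect so downstream operations can be tested against an
#' oracle.
#'
#' The model, in order:
#' \enumerate{
#'   \item one gene universe per species (\code{nGenesPerSpecies} each);
#'   \item GO annotations: a Poisson(\code{goTermsPerGeneMean}) number of
#'     draws from a flat term vocabulary per gene, de-duplicated; the first
#'     \code{fracAssociatedTerms} of the vocabulary is flagged "associated";
#'   \item human tissue / subcellular categories with Protein-Atlas-like
#'     marginal frequencies;
#'   \item ortholog groups: each group picks an archetype by mixing weight;
#'     members (one per species, occasionally two co-orthologs) receive log2
#'     3'UTR means equal to the archetype coordinate plus
#'     Normal(0, \code{trajectoryLog2Sd}) noise; members are consumed from
#'     the head of each species' gene list;
#'   \item region lengths: log2 lengths are Normal with the configured
#'     medians/sds; the three regions share an equicorrelated latent factor
#'     (\code{regionLog2Correlation}); a gene carrying an associated GO term
#'     gains \code{goAssociationStrength} log2 units of 3'UTR, and human
#'     genes gain \code{log2(categoryMedianShifts[category])}; CDS lengths
#'     are rounded to codon multiples; clean lengths are truncated at the
#'     curation thresholds (30 / 50 nt);
#'   \item transcripts: each gene has a primary transcript plus
#'     Poisson(\code{transcriptsPerGeneMean}) shorter secondaries (3'UTR
#'     scaled by Uniform(0.5, 0.9)); accessions are assigned in generation
#'     order so the primary always has the lexicographically smallest;
#'   \item filter violations, planted independently per record: non-NM
#'     accession prefix (XM_), incompleteness flags on the 5' and/or 3' end,
#'     and resampled sub-threshold 5'UTR (0-29 nt) or 3'UTR (0-49 nt)
#'     lengths. A record may violate several filters; all are recorded.
#' }
#'
#' The output is a deterministic function of the configuration (including its
#' seed).
#'
#' @param config a [CohortConfig-class].
#' @return A [UTRCohort-class] with records, goTable, orthologTable,
#'   categoryTable, and a \code{truth} list holding \code{recordViolations}
#'   (per-record planted violation labels), \code{geneLengths} (per-gene
#'   intended primary lengths, association flag, archetype and categories),
#'   \code{groupArchetypes} and \code{termAssociation}.
#' @examples
#' cohort <- generateCohort(CohortConfig(seed = 7L, nGenesPerSpecies = 50L,
#'                                       nOrthologGroups = 10L))
#' cohort
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  set.seed(config@seed)

  sp <- config@speciesOrder
  nG <- config@nGenesPerSpecies
  genes <- data.frame(
    gene_id = unlist(lapply(sp, function(s) sprintf("%s_g%05d", s, seq_len(nG)))),
    species = rep(sp, each = nG),
    stringsAsFactors = FALSE
  )
  ng <- nrow(genes)
  spIdx <- match(genes$species, sp)

  ## --- GO annotations over the whole universe -----------------------------
  terms <- sprintf("GO:%07d", seq_len(config@nGoTerms))
  nAssoc <- round(config@fracAssociatedTerms * config@nGoTerms)
  assocTerms <- terms[seq_len(nAssoc)]
  cnt <- rpois(ng, config@goTermsPerGeneMean)
  goTable <- data.frame(
    gene_id = rep(genes$gene_id, cnt),
    go_term = if (sum(cnt)) sample(terms, sum(cnt), replace = TRUE) else character(),
    stringsAsFactors = FALSE
  )
  goTable <- unique(goTable)
  goTable <- goTable[order(goTable$gene_id, goTable$go_term), , drop = FALSE]
  rownames(goTable) <- NULL
  assocFlag <- genes$gene_id %in%
    unique(goTable$gene_id[goTable$go_term %in% assocTerms])

  ## --- human expression categories ----------------------------------------
  hsa <- genes$species == "Hsa"
  tissue <- rep(NA_character_, ng)
  tissue[hsa] <- sample(TISSUE_CATEGORIES, sum(hsa), replace = TRUE,
                        prob = c(1843, 950, 2907, 8375, 2300))
  subc <- rep(NA_character_, ng)
  hasSub <- hsa & runif(ng) < config@subcellularFrac
  subc[hasSub] <- sample(SUBCELLULAR_CATEGORIES, sum(hasSub), replace = TRUE,
                         prob = c(1779, 3543, 867, 403))
  catShiftLog2 <- rep(0, ng)
  known <- !is.na(tissue) & tissue %in% names(config@categoryMedianShifts)
  catShiftLog2[known] <- log2(config@categoryMedianShifts[tissue[known]])

  ## --- ortholog groups and archetype-driven 3'UTR means -------------------
  nGrp <- config@nOrthologGroups
  mu3 <- config@utr3Log2Median[spIdx]
  archOverride <- rep(NA_real_, ng)
  geneArch <- rep(NA_integer_, ng)
  orthologTable <- data.frame(group_id = character(), species = character(),
                              gene_id = character(), stringsAsFactors = FALSE)
  groupArchetypes <- data.frame(group_id = character(),
                                archetype = integer(),
                                archetype_name = character(),
                                stringsAsFactors = FALSE)
  if (nGrp > 0L) {
    kArch <- nrow(config@trajectoryArchetypes)
    arch <- sample.int(kArch, nGrp, replace = TRUE,
                       prob = config@archetypeWeights)
    groupIds <- sprintf("OG%05d", seq_len(nGrp))
    extra <- matrix(rbinom(nGrp * 4L, 1L, config@coOrthologProb), nGrp, 4L)
    members <- 1L + extra
    if (any(colSums(members) > nG))
      stop("nGenesPerSpecies too small for the requested ortholog groups")
    rows <- vector("list", 4L)
    for (s in seq_along(sp)) {
      m <- members[, s]
      idx <- seq_len(sum(m)) + (s - 1L) * nG   # head of this species' genes
      gid <- rep(seq_len(nGrp), m)
      archMean <- config@trajectoryArchetypes[arch[gid], s]
      archOverride[idx] <- archMean + rnorm(length(idx), 0, config@trajectoryLog2Sd)
      geneArch[idx] <- arch[gid]
      rows[[s]] <- data.frame(group_id = groupIds[gid], species = sp[s],
                              gene_id = genes$gene_id[idx],
                              stringsAsFactors = FALSE)
    }
    orthologTable <- do.call(rbind, rows)
    orthologTable <- orthologTable[order(orthologTable$group_id,
                                         match(orthologTable$species, sp),
                                         orthologTable$gene_id), , drop = FALSE]
    rownames(orthologTable) <- NULL
    groupArchetypes <- data.frame(
      group_id = groupIds, archetype = arch,
      archetype_name = rownames(config@trajectoryArchetypes)[arch],
      stringsAsFactors = FALSE)
  }

  ## --- region lengths ------------------------------------------------------
  rho <- config@regionLog2Correlation
  w <- rnorm(ng)
  zr <- function() sqrt(rho) * w + sqrt(1 - rho) * rnorm(ng)
  z5 <- zr(); zc <- zr(); z3 <- zr()
  log2len5 <- config@utr5Log2Median + config@utr5Log2Sd * z5
  log2cds <- config@cdsLog2Median + config@cdsLog2Sd * zc
  log2len3 <- mu3 + config@utr3Log2Sd * z3
  log2len3[!is.na(archOverride)] <- archOverride[!is.na(archOverride)]
  log2len3 <- log2len3 + config@goAssociationStrength * assocFlag + catShiftLog2

  len5 <- pmax(30L, as.integer(round(2^log2len5)))
  lenCds <- pmax(90L, as.integer(round(2^log2cds)))
  lenCds <- lenCds + (3L - lenCds %% 3L) %% 3L     # codon multiples
  len3 <- pmax(50L, as.integer(round(2^log2len3)))

  ## --- transcripts ---------------------------------------------------------
  extraTr <- rpois(ng, config@transcriptsPerGeneMean)
  recIdx <- rep(seq_len(ng), extraTr + 1L)
  nR <- length(recIdx)
  primary <- !duplicated(recIdx)
  r5 <- len5[recIdx]
  rc <- lenCds[recIdx]
  shrink <- runif(nR, 0.5, 0.9)
  r3 <- ifelse(primary, len3[recIdx],
               pmax(50L, as.integer(floor(len3[recIdx] * shrink))))

  ## --- planted filter violations ------------------------------------------
  f <- config@fracViolating
  vNonNM <- runif(nR) < f[["nonNM"]]
  vIncomplete <- runif(nR) < f[["incomplete"]]
  vShort5 <- runif(nR) < f[["shortUtr5"]]
  vShort3 <- runif(nR) < f[["shortUtr3"]]
  if (any(vShort5)) r5[vShort5] <- sample(0:29, sum(vShort5), replace = TRUE)
  if (any(vShort3)) r3[vShort3] <- sample(0:49, sum(vShort3), replace = TRUE)
  inc5 <- inc3 <- rep(FALSE, nR)
  if (any(vIncomplete)) {
    side <- sample.int(3L, sum(vIncomplete), replace = TRUE)  # 5', 3', both
    inc5[vIncomplete] <- side != 2L
    inc3[vIncomplete] <- side != 1L
  }
  accession <- sprintf("%s_%06d.1", ifelse(vNonNM, "XM", "NM"), seq_len(nR))

  records <- data.frame(
    accession = accession,
    gene_id = genes$gene_id[recIdx],
    species = genes$species[recIdx],
    seq_length = r5 + rc + r3,
    cds_start = r5 + 1L,
    cds_end = r5 + rc,
    incomplete_5p = inc5,
    incomplete_3p = inc3,
    stringsAsFactors = FALSE
  )

  truth <- list(
    recordViolations = data.frame(
      accession = accession,
      non_nm = vNonNM, incomplete = vIncomplete,
      short_utr5 = vShort5, short_utr3 = vShort3,
      clean = !(vNonNM | vIncomplete | vShort5 | vShort3),
      stringsAsFactors = FALSE),
    geneLengths = data.frame(
      gene_id = genes$gene_id, species = genes$species,
      len5 = len5, len_cds = lenCds, len3 = len3,
      associated = assocFlag, archetype = geneArch,
      tissue_category = tissue, subcellular_category = subc,
      stringsAsFactors = FALSE),
    groupArchetypes = groupArchetypes,
    termAssociation = data.frame(
      go_term = terms, associated = terms %in% assocTerms,
      stringsAsFactors = FALSE)
  )

  new("UTRCohort",
      records = records,
      goTable = goTable,
      orthologTable = orthologTable,
      categoryTable = data.frame(gene_id = genes$gene_id[hsa],
                                 tissue_category = tissue[hsa],
                                 subcellular_category = subc[hsa],
                                 stringsAsFactors = FALSE),
      truth = truth,
      config = config)
}
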