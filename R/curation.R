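#' Derived UTR lengths of mRNA records
#'
#' With 1-based, fully closed CDS coordinates (GenBank convention), the
#' 5'UTR occupies [1, cds_start - 1] and the 3'UTR
#' [cds_end + 1, seq_length], so len5 = cds_start - 1 and
#' len3 = seq_length - cds_end.
#'
#' @param records data.frame of mRNA records.
#' @return \code{records} with numeric columns \code{len5}, \code{len_cds},
#'   \code{len3} appended.
#' @export
utrLengths <- function(records) {
  records$len5 <- records$cds_start - 1L
  records$len_cds <- records$cds_end - records$cds_start + 1L
  records$len3 <- records$seq_length - records$cds_end
  records
}

#' Apply the curation filters to mRNA records
#'
#' Retains records that pass, in order: (1) accession prefix "NM_" (manually
#' curated protein-coding RefSeq records); (2) no incompleteness annotation
#' on either end AND 5'UTR length >= \code{minUtr5} AND 3'UTR length >=
#' \code{minUtr3}. The default thresholds (30 nt and 50 nt) guard the 3'/5'
#' length-ratio statistics against near-zero denominators. The step counts
#' are reported in this fixed order so they are comparable across runs.
#'
#' @param records data.frame of parsed mRNA records.
#' @param minUtr5 minimum 5'UTR length in nt (records strictly shorter are
#'   discarded).
#' @param minUtr3 minimum 3'UTR length in nt.
#' @return list with \code{records} (the kept rows) and \code{report}, a
#'   data.frame of step counts (\code{raw}, \code{nm_prefix},
#'   \code{complete_and_length}) that is non-increasing by construction.
#' @examples
#' rec <- data.frame(accession = c("NM_1.1", "XM_2.1"),
#'                   gene_id = "g", species = "Hsa",
#'                   seq_length = 1000L, cds_start = 31L, cds_end = 950L,
#'                   incomplete_5p = FALSE, incomplete_3p = FALSE)
#' filterCurated(rec)$report
#' @export
filterCurated <- function(records, minUtr5 = 30L, minUtr3 = 50L) {
  raw <- nrow(records)
  nm <- records[startsWith(records$accession, "NM_"), , drop = FALSE]
  lens <- utrLengths(nm)
  keep <- !nm$incomplete_5p & !nm$incomplete_3p &
    lens$len5 >= minUtr5 & lens$len3 >= minUtr3
  kept <- nm[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(
    records = kept,
    report = data.frame(
      step = c("raw", "nm_prefix", "complete_and_length"),
      n = c(raw, nrow(nm), nrow(kept)),
      stringsAsFactors = FALSE)
  )
}

#' Select the longest transcript per gene
#'
#' Keeps exactly one record per (gene_id, species): the one with the
#' greatest sequence length, ties broken by the lexicographically smallest
#' accession. The result is invariant to the input row order.
#'
#' @param records data.frame of (already filtered) mRNA records.
#' @return data.frame with one representative record per gene, ordered by
#'   species then gene_id.
#' @export
selectLongestPerGene <- function(records) {
  ord <- order(records$species, records$gene_id,
               -records$seq_length, records$accession)
  r <- records[ord, , drop = FALSE]
  r <- r[!duplicated(r[c("gene_id", "species")]), , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' Build the per-gene length table
#'
#' One row per representative transcript with the recorded lengths of the
#' three mRNA regions. The lengths always satisfy
#' len5 + len_cds + len3 = seq_length. A CDS length that is not a codon
#' multiple is tolerated (real records vary in stop-codon conventions) but
#' counted in a warning.
#'
#' @param records data.frame with one record per (gene_id, species).
#' @return data.frame (gene_id, species, accession, len5, len_cds, len3).
#' @export
toLengthTable <- function(records) {
  if (anyDuplicated(records[c("gene_id", "species")]))
    stop("records must hold one representative transcript per gene; ",
         "run selectLongestPerGene() first")
  r <- utrLengths(records)
  nonCodon <- sum(r$len_cds %% 3L != 0L)
  if (nonCodon > 0L)
    warning(nonCodon, " CDS length(s) are not a multiple of 3")
  out <- r[c("gene_id", "species", "accession", "len5", "len_cds", "len3")]
  rownames(out) <- NULL
  out
}
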