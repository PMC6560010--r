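INCOMPLETE_5P_TOKEN <- "incomplete on the 5' end"
INCOMPLETE_3P_TOKEN <- "incomplete on the 3' end"

#' Write mRNA records as a minimal GenBank-style flat file
#'
#' Emits one entry per record in a minimal GenBank-flavored dialect: LOCUS
#' (name + length + "bp mRNA"), SOURCE (species code, so species round-trips),
#' ACCESSION/VERSION, an optional COMMENT carrying the incompleteness tokens
#' ("incomplete on the 5' end" / "incomplete on the 3' end"), and a FEATURES
#' block with a single \code{CDS start..end} feature plus a
#' \code{/gene="..."} qualifier, terminated by \code{//}. Coordinates are
#' 1-based and fully closed, the GenBank convention. Only lengths and
#' coordinates are modelled; no nucleotide sequence is written.
#'
#' @param records data.frame of mRNA records as produced by
#'   [generateCohort()] / [parseGenBank()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso [parseGenBank()] for the reader; \code{parse(write(x))} is an
#'   exact round trip.
#' @export
writeGenBank <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data.frame")
  entry <- function(i) {
    r <- records[i, ]
    name <- sub("\\.\\d+$", "", r$accession)
    lines <- c(
      sprintf("LOCUS       %-18s %d bp    mRNA", name, r$seq_length),
      sprintf("SOURCE      %s", r$species),
      sprintf("ACCESSION   %s", name),
      sprintf("VERSION     %s", r$accession)
    )
    flags <- c(if (r$incomplete_5p) INCOMPLETE_5P_TOKEN,
               if (r$incomplete_3p) INCOMPLETE_3P_TOKEN)
    if (length(flags))
      lines <- c(lines, sprintf("COMMENT     Sequence is %s.",
                                paste(flags, collapse = " and ")))
    c(lines,
      "FEATURES             Location/Qualifiers",
      sprintf("     CDS             %d..%d", r$cds_start, r$cds_end),
      sprintf("                     /gene=\"%s\"", r$gene_id),
      "//")
  }
  out <- unlist(lapply(seq_len(nrow(records)), entry))
  writeLines(out, path)
  invisible(path)
}

#' Parse a minimal GenBank-style flat file of mRNA records
#'
#' Reads the dialect written by [writeGenBank()]: one record per LOCUS entry,
#' CDS coordinates from the first CDS feature, incompleteness flags set iff
#' the COMMENT contains the dialect tokens. Entries without a CDS feature or
#' with malformed coordinates are skipped; their identities and reasons are
#' collected in the \code{"errors"} attribute (a data.frame with columns
#' \code{entry} and \code{message}) and reported via [message()].
#'
#' @param path path to the flat file.
#' @return data.frame of mRNA records (accession, gene_id, species,
#'   seq_length, cds_start, cds_end, incomplete_5p, incomplete_3p) with an
#'   \code{"errors"} attribute.
#' @export
parseGenBank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  ends <- which(lines == "//")
  starts <- c(1L, head(ends, -1L) + 1L)
  errors <- data.frame(entry = character(), message = character(),
                       stringsAsFactors = FALSE)
  recs <- vector("list", length(ends))
  for (i in seq_along(ends)) {
    block <- lines[starts[i]:ends[i]]
    locus <- grep("^LOCUS", block, value = TRUE)
    name <- if (length(locus)) sub("^LOCUS\\s+(\\S+).*$", "\\1", locus[1]) else
      sprintf("<entry %d>", i)
    fail <- function(why) {
      errors[nrow(errors) + 1L, ] <<- list(name, why)
      NULL
    }
    lenMatch <- regmatches(locus[1], regexpr("\\d+(?= bp)", locus[1], perl = TRUE))
    if (!length(locus) || !length(lenMatch)) {
      recs[i] <- list(fail("missing or malformed LOCUS length")); next
    }
    seqLen <- as.integer(lenMatch)
    version <- grep("^VERSION", block, value = TRUE)
    acc <- if (length(version)) sub("^VERSION\\s+(\\S+).*$", "\\1", version[1]) else NA
    src <- grep("^SOURCE", block, value = TRUE)
    species <- if (length(src)) sub("^SOURCE\\s+(\\S+).*$", "\\1", src[1]) else NA
    if (is.na(acc) || is.na(species)) {
      recs[i] <- list(fail("missing VERSION or SOURCE line")); next
    }
    cds <- grep("^\\s+CDS\\s", block, value = TRUE)
    if (!length(cds)) {
      recs[i] <- list(fail("no CDS feature")); next
    }
    m <- regmatches(cds[1], regexec("(\\d+)\\.\\.(\\d+)", cds[1]))[[1]]
    if (length(m) != 3L) {
      recs[i] <- list(fail("malformed CDS coordinates")); next
    }
    cdsStart <- as.integer(m[2]); cdsEnd <- as.integer(m[3])
    if (!(cdsStart >= 1L && cdsStart < cdsEnd && cdsEnd <= seqLen)) {
      recs[i] <- list(fail("CDS coordinates outside 1 <= start < end <= length")); next
    }
    gq <- grep("/gene=\"", block, value = TRUE)
    gene <- if (length(gq)) sub('^.*?/gene="([^"]*)".*$', "\\1", gq[1]) else NA
    if (is.na(gene)) {
      recs[i] <- list(fail("missing /gene qualifier")); next
    }
    comment <- paste(grep("^COMMENT", block, value = TRUE), collapse = " ")
    recs[[i]] <- data.frame(
      accession = acc, gene_id = gene, species = species,
      seq_length = seqLen, cds_start = cdsStart, cds_end = cdsEnd,
      incomplete_5p = grepl(INCOMPLETE_5P_TOKEN, comment, fixed = TRUE),
      incomplete_3p = grepl(INCOMPLETE_3P_TOKEN, comment, fixed = TRUE),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(accession = character(), gene_id = character(),
                      species = character(), seq_length = integer(),
                      cds_start = integer(), cds_end = integer(),
                      incomplete_5p = logical(), incomplete_3p = logical(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (nrow(errors))
    message(nrow(errors), " entr", if (nrow(errors) == 1L) "y" else "ies",
            " skipped while parsing ", path)
  attr(out, "errors") <- errors
  out
}

#' Read and write the pipeline's TSV tables
#'
#' Plain TSV with a header row. \code{writeCohortTables()} writes all four
#' input tables of a cohort (plus the ground-truth sidecars) into a
#' directory; the single-table readers/writers are exposed for piecemeal use.
#' Round trips are exact.
#'
#' @param table a data.frame.
#' @param path file path (single tables) .
#' @param cohort a [UTRCohort-class].
#' @param dir output directory for \code{writeCohortTables()}.
#' @return Readers return a data.frame; writers return the path(s) invisibly.
#' @name table-io
NULL

#' @rdname table-io
#' @export
writeTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname table-io
#' @export
readTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @rdname table-io
#' @export
writeCohortTables <- function(cohort, dir) {
  stopifnot(is(cohort, "UTRCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    genbank = file.path(dir, "records.gb"),
    go = file.path(dir, "go_annotations.tsv"),
    orthologs = file.path(dir, "orthologs.tsv"),
    categories = file.path(dir, "categories.tsv"),
    truth = file.path(dir, "ground_truth.tsv")
  )
  writeGenBank(cohortRecords(cohort), paths[["genbank"]])
  writeTable(goAnnotations(cohort), paths[["go"]])
  writeTable(orthologGroups(cohort), paths[["orthologs"]])
  writeTable(geneCategories(cohort), paths[["categories"]])
  writeTable(cohortTruth(cohort)$geneLengths, paths[["truth"]])
  invisible(paths)
}
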