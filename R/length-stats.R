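REGIONS <- c("utr5", "cds", "utr3")

.lengthColumn <- c(utr5 = "len5", cds = "len_cds", utr3 = "len3")

#' Summary statistics of region lengths
#'
#' Per-(group, region) mean, min, quartiles, median, max and n of the 5'UTR,
#' CDS and 3'UTR lengths. Quartiles use the linear-interpolation convention
#' (\code{quantile()} type 7); summary tables depend on this choice, so it is
#' fixed and documented rather than configurable.
#'
#' @param lengthTable data.frame with columns gene_id, species, len5,
#'   len_cds, len3 (see [toLengthTable()]).
#' @param groupBy column name(s) of \code{lengthTable} to group on
#'   (default "species").
#' @return data.frame with one row per group x region and columns n, mean,
#'   min, q1, median, q3, max. Empty groups are omitted.
#' @export
summarizeLengths <- function(lengthTable, groupBy = "species") {
  if (!is.data.frame(lengthTable) || nrow(lengthTable) == 0L)
    stop("lengthTable must be a non-empty data.frame")
  stopifnot(all(groupBy %in% names(lengthTable)))
  key <- interaction(lengthTable[groupBy], drop = TRUE, sep = ":")
  rows <- list()
  for (g in levels(key)) {
    sub <- lengthTable[key == g, , drop = FALSE]
    for (region in REGIONS) {
      v <- sub[[.lengthColumn[[region]]]]
      q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, region = region, n = length(v),
        mean = mean(v), min = min(v), q1 = q[1], median = q[2], q3 = q[3],
        max = max(v), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise Pearson correlations of region lengths
#'
#' For each species, Pearson's r (with a two-sided p-value) between the
#' lengths of each pair of mRNA regions, computed on log2-transformed
#' lengths by default, matching how the lengths are usually displayed; raw
#' scale is available via \code{transform = "identity"}. A zero-variance
#' vector leaves the correlation undefined: it is reported as NA with
#' \code{undefined = TRUE}, never coerced to 0.
#'
#' @param lengthTable per-gene length table (post-filter, so all lengths are
#'   positive and log2 is safe).
#' @param transform "log2" (default) or "identity".
#' @return data.frame with columns species, region1, region2, n, r, p,
#'   undefined.
#' @export
pairwiseCorrelation <- function(lengthTable, transform = c("log2", "identity")) {
  transform <- match.arg(transform)
  pairs <- list(c("utr5", "cds"), c("utr5", "utr3"), c("cds", "utr3"))
  rows <- list()
  for (s in unique(lengthTable$species)) {
    sub <- lengthTable[lengthTable$species == s, , drop = FALSE]
    if (nrow(sub) < 3L)
      stop("need at least 3 genes per species for correlation (", s, ")")
    for (p in pairs) {
      x <- sub[[.lengthColumn[[p[1]]]]]
      y <- sub[[.lengthColumn[[p[2]]]]]
      if (transform == "log2") {
        if (any(x <= 0) || any(y <= 0))
          stop("log2 transform requires strictly positive lengths")
        x <- log2(x); y <- log2(y)
      }
      if (sd(x) == 0 || sd(y) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          species = s, region1 = p[1], region2 = p[2], n = length(x),
          r = NA_real_, p = NA_real_, undefined = TRUE,
          stringsAsFactors = FALSE)
      } else {
        ct <- stats::cor.test(x, y, method = "pearson",
                              alternative = "two.sided")
        rows[[length(rows) + 1L]] <- data.frame(
          species = s, region1 = p[1], region2 = p[2], n = length(x),
          r = unname(ct$estimate), p = ct$p.value, undefined = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Distribution of the 3'/5' UTR length ratio
#'
#' Per-gene ratio len3/len5 and, per species, the fraction of genes whose
#' ratio is at least t for each reported threshold. Defaults report t = 2
#' and t = 5, the two ratios most often quoted when contrasting fly-like and
#' mammalian transcriptomes. The input must be post-filter (len5 >= 30), so
#' every ratio is finite and positive.
#'
#' @param lengthTable per-gene length table.
#' @param thresholds ratio thresholds to report.
#' @return list with \code{ratios} (gene_id, species, ratio) and
#'   \code{fractions} (species, threshold, fraction, n).
#' @export
ratioDistribution <- function(lengthTable, thresholds = c(2, 5)) {
  if (any(lengthTable$len5 <= 0))
    stop("ratio requires len5 > 0; run filterCurated() first")
  ratios <- data.frame(gene_id = lengthTable$gene_id,
                       species = lengthTable$species,
                       ratio = lengthTable$len3 / lengthTable$len5,
                       stringsAsFactors = FALSE)
  rows <- list()
  for (s in unique(ratios$species)) {
    r <- ratios$ratio[ratios$species == s]
    for (t in thresholds) {
      rows[[length(rows) + 1L]] <- data.frame(
        species = s, threshold = t, fraction = fractionAtLeast(r, t),
        n = length(r), stringsAsFactors = FALSE)
    }
  }
  fractions <- do.call(rbind, rows)
  rownames(fractions) <- NULL
  list(ratios = ratios, fractions = fractions)
}

#' Fraction of values at or above a threshold
#'
#' \code{fractionAtLeast(x, 0)} is 1 for positive data, and the fraction is
#' non-increasing in t (the survival function of the empirical distribution).
#'
#' @param x numeric vector.
#' @param t threshold.
#' @return the proportion of \code{x} with \code{x >= t}.
#' @export
fractionAtLeast <- function(x, t) {
  if (!length(x)) stop("empty vector")
  mean(x >= t)
}
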