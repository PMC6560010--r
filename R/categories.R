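#' Notched-boxplot confidence interval for a median
#'
#' The McGill notch convention: median +/- 1.57 x IQR / sqrt(n), an
#' approximate 95% confidence interval for the median. IQR uses the
#' linear-interpolation quantile convention. The notch width shrinks as
#' 1/sqrt(n) and collapses to the median when all values are equal.
#'
#' @param values numeric vector, n >= 2 (positive lengths in this package's
#'   use, but any numeric sample is accepted).
#' @return one-row data.frame: n, median, lower, upper.
#' @examples
#' notchCI(c(90, 95, 100, 105, 110))
#' @export
notchCI <- function(values) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values for a notch interval")
  med <- median(values)
  iqr <- stats::IQR(values, type = 7)
  half <- 1.57 * iqr / sqrt(n)
  data.frame(n = n, median = med, lower = med - half, upper = med + half)
}

#' Compare 3'UTR lengths across expression categories
#'
#' Joins the length table with the category table on gene_id and reports,
#' per category along the chosen axis, the median 3'UTR length with its
#' notch interval, plus a pairwise notch-overlap matrix (TRUE where the
#' intervals intersect) and the ranking of categories by median. Overlap of
#' notches is reported descriptively; no formal multiple-testing procedure
#' is attached, because non-overlap of notches is an informal criterion, not
#' a calibrated test.
#'
#' Genes without a category on the chosen axis are excluded and counted;
#' categories with fewer than 2 genes are excluded with a warning.
#'
#' @param lengthTable per-gene length table (human genes, in the intended
#'   use).
#' @param categoryTable data.frame (gene_id, tissue_category,
#'   subcellular_category).
#' @param axis "tissue" or "subcellular".
#' @return list with \code{medians} (category, n, median, lower, upper,
#'   ordered by decreasing median), \code{overlap} (logical matrix),
#'   \code{nUncategorized}, and \code{excluded} (categories dropped for
#'   n < 2).
#' @export
compareCategories <- function(lengthTable, categoryTable,
                              axis = c("tissue", "subcellular")) {
  axis <- match.arg(axis)
  col <- paste0(axis, "_category")
  if (!col %in% names(categoryTable))
    stop("category table lacks column ", col)
  merged <- merge(lengthTable[c("gene_id", "len3")],
                  categoryTable[c("gene_id", col)], by = "gene_id")
  if (nrow(merged) == 0L)
    stop("length table and category table share no genes")
  uncategorized <- sum(is.na(merged[[col]]))
  merged <- merged[!is.na(merged[[col]]), , drop = FALSE]
  if (nrow(merged) == 0L) stop("no categorized genes on axis ", axis)
  counts <- table(merged[[col]])
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    warning("excluding categor", if (length(small) == 1L) "y" else "ies",
            " with n < 2: ", paste(small, collapse = ", "))
    merged <- merged[!merged[[col]] %in% small, , drop = FALSE]
  }
  cats <- sort(unique(merged[[col]]))
  medians <- do.call(rbind, lapply(cats, function(cc) {
    ci <- notchCI(merged$len3[merged[[col]] == cc])
    cbind(data.frame(category = cc, stringsAsFactors = FALSE), ci)
  }))
  medians <- medians[order(-medians$median), , drop = FALSE]
  rownames(medians) <- NULL
  k <- nrow(medians)
  overlap <- matrix(TRUE, k, k,
                    dimnames = list(medians$category, medians$category))
  for (i in seq_len(k)) for (j in seq_len(k))
    overlap[i, j] <- medians$lower[i] <= medians$upper[j] &&
      medians$lower[j] <= medians$upper[i]
  list(medians = medians, overlap = overlap,
       nUncategorized = uncategorized, excluded = small)
}
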