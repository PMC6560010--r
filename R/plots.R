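#' Plot clustered ortholog trajectories
#'
#' One panel per cluster: gray lines for member trajectories, a bold black
#' line for the cluster center, on the log2 length scale, species in fixed
#' order on the x axis. Cluster sizes appear in the panel titles.
#'
#' @param trajectories data.frame from [buildTrajectories()].
#' @param result matching [ClusteringResult-class].
#' @return invisibly, NULL; draws on the active device.
#' @export
plotTrajectoryClusters <- function(trajectories, result) {
  stopifnot(is(result, "ClusteringResult"))
  x <- log2(as.matrix(trajectories[SPECIES_ORDER]))
  rownames(x) <- trajectories$group_id
  assign <- clusterAssignments(result)[rownames(x)]
  centers <- clusterCenters(result)
  if (result@transform != "log2") centers <- log2(centers)
  k <- result@k
  old <- graphics::par(mfrow = c(ceiling(k / 2), min(k, 2)),
                       mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old))
  for (cl in seq_len(k)) {
    member <- x[assign == cl, , drop = FALSE]
    graphics::matplot(t(member), type = "l", lty = 1,
                      col = grDevices::grey(0.75), xaxt = "n",
                      xlab = "", ylab = "log2 3'UTR length (nt)",
                      main = sprintf("Cluster %d (n = %d)", cl, nrow(member)))
    graphics::lines(centers[cl, ], lwd = 3, col = "black")
    graphics::axis(1, at = seq_along(SPECIES_ORDER), labels = SPECIES_ORDER)
  }
  invisible(NULL)
}

#' Plot gene-set PCA scalings
#'
#' Scatter of set coordinates on the first two principal components:
#' length-quartile sets (Q) in colour with labels, random sets (R) in gray.
#'
#' @param qScaling [SetScaling-class] of the length-quartile partition.
#' @param rScaling optional [SetScaling-class] of a random partition, drawn
#'   in gray for contrast.
#' @param main plot title.
#' @return invisibly, NULL.
#' @export
plotSetScaling <- function(qScaling, rScaling = NULL, main = "Gene-set scaling") {
  q <- scalingCoordinates(qScaling)
  pts <- if (is.null(rScaling)) q else rbind(q, scalingCoordinates(rScaling))
  graphics::plot(pts, type = "n", xlab = "PC1", ylab = "PC2", main = main)
  graphics::abline(h = 0, v = 0, col = "grey90")
  if (!is.null(rScaling)) {
    r <- scalingCoordinates(rScaling)
    graphics::points(r, pch = 19, col = grDevices::grey(0.6))
    graphics::text(r, labels = rownames(r), pos = 3,
                   col = grDevices::grey(0.6))
  }
  graphics::points(q, pch = 19, col = seq_len(nrow(q)) + 1L)
  graphics::text(q, labels = rownames(q), pos = 3)
  invisible(NULL)
}

#' Notched boxplots of 3'UTR length by expression category
#'
#' Standard notched box-and-whisker display of log2 3'UTR lengths per
#' category; non-overlapping notches informally flag differing medians.
#'
#' @param lengthTable per-gene length table.
#' @param categoryTable category table.
#' @param axis "tissue" or "subcellular".
#' @return invisibly, NULL.
#' @export
plotCategoryNotches <- function(lengthTable, categoryTable,
                                axis = c("tissue", "subcellular")) {
  axis <- match.arg(axis)
  col <- paste0(axis, "_category")
  merged <- merge(lengthTable[c("gene_id", "len3")],
                  categoryTable[c("gene_id", col)], by = "gene_id")
  merged <- merged[!is.na(merged[[col]]), , drop = FALSE]
  graphics::boxplot(log2(len3) ~ merged[[col]], data = merged, notch = TRUE,
                    xlab = "", ylab = "log2 3'UTR length (nt)", las = 2)
  invisible(NULL)
}
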