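#' Build ortholog 3'UTR length trajectories
#'
#' For each ortholog group, the ordered 4-vector of 3'UTR lengths across
#' (Dme, Dre, Mmu, Hsa). When a species contributes several co-orthologous
#' genes, their arithmetic mean 3'UTR length is used. Groups missing any of
#' the four species are dropped and counted (no imputation): the trajectory
#' analysis is defined only on groups represented in all four species.
#'
#' @param orthologTable data.frame (group_id, species, gene_id).
#' @param lengthTable per-gene length table.
#' @param onMissing what to do with ortholog members absent from the length
#'   table: \code{"error"} (default) aborts listing the offending gene ids;
#'   \code{"drop"} silently removes them first, which is what a pipeline
#'   wants after curation has legitimately discarded records.
#' @return data.frame (group_id, Dme, Dre, Mmu, Hsa) with attribute
#'   \code{"dropped"} = number of groups missing at least one species.
#' @export
buildTrajectories <- function(orthologTable, lengthTable,
                              onMissing = c("error", "drop")) {
  onMissing <- match.arg(onMissing)
  unknown <- setdiff(orthologTable$gene_id, lengthTable$gene_id)
  if (length(unknown)) {
    if (onMissing == "error")
      stop("ortholog table references gene ids absent from the length table: ",
           paste(head(unknown, 10L), collapse = ", "),
           if (length(unknown) > 10L) sprintf(" ... (%d total)", length(unknown)))
    orthologTable <- orthologTable[!orthologTable$gene_id %in% unknown, ,
                                   drop = FALSE]
  }
  bad <- !orthologTable$species %in% SPECIES_ORDER
  if (any(bad))
    stop("invalid species codes in ortholog table: ",
         paste(unique(orthologTable$species[bad]), collapse = ", "))
  len3 <- lengthTable$len3[match(orthologTable$gene_id, lengthTable$gene_id)]
  agg <- stats::aggregate(
    len3,
    by = list(group_id = orthologTable$group_id,
              species = orthologTable$species),
    FUN = mean)
  wide <- stats::reshape(agg, idvar = "group_id", timevar = "species",
                         direction = "wide")
  names(wide) <- sub("^x\\.", "", names(wide))
  missingCols <- setdiff(SPECIES_ORDER, names(wide))
  for (m in missingCols) wide[[m]] <- NA_real_
  wide <- wide[c("group_id", SPECIES_ORDER)]
  complete <- stats::complete.cases(wide[SPECIES_ORDER])
  dropped <- sum(!complete)
  if (dropped > 0L)
    message(dropped, " ortholog group(s) dropped: not represented in all four species")
  out <- wide[complete, , drop = FALSE]
  out <- out[order(out$group_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Cluster ortholog trajectories with k-means
#'
#' Lloyd k-means with Euclidean distance on the (by default log2-transformed)
#' 4-vectors, taking the best of \code{nInit} random initializations by total
#' within-cluster sum of squares. log2 space is the default because raw UTR
#' lengths span orders of magnitude and Euclidean distance on raw nucleotides
#' would be dominated by the longest UTRs. Deterministic given \code{seed};
#' an initialization that produces an empty cluster is re-drawn (standard
#' Lloyd re-seeding practice), still under the seeded RNG stream. Clusters
#' are relabelled by decreasing size, so cluster 1 is always the largest.
#'
#' @param trajectories data.frame from [buildTrajectories()].
#' @param k number of clusters (default 4).
#' @param transform "log2" (default) or "identity".
#' @param seed RNG seed.
#' @param nInit number of random initializations (default 25).
#' @return A [ClusteringResult-class].
#' @export
clusterTrajectories <- function(trajectories, k = 4L,
                                transform = c("log2", "identity"),
                                seed = 1L, nInit = 25L) {
  transform <- match.arg(transform)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  x <- as.matrix(trajectories[SPECIES_ORDER])
  rownames(x) <- trajectories$group_id
  if (k > nrow(x)) stop("k exceeds the number of ortholog groups")
  if (any(x <= 0) && transform == "log2")
    stop("log2 transform requires positive trajectory values")
  if (transform == "log2") x <- log2(x)
  set.seed(seed)
  fit <- NULL
  for (attempt in seq_len(50L)) {
    fit <- tryCatch(
      withCallingHandlers(
        stats::kmeans(x, centers = k, iter.max = 100L, nstart = nInit,
                      algorithm = "Lloyd"),
        warning = function(w) {
          if (grepl("empty cluster", conditionMessage(w)))
            invokeRestart("muffleWarning")
        }),
      error = function(e) e)
    if (!inherits(fit, "error")) break
    if (!grepl("empty cluster", conditionMessage(fit)))
      stop(fit)
  }
  if (inherits(fit, "error"))
    stop("k-means failed: ", conditionMessage(fit))
  ord <- order(-fit$size, fit$centers[, 1])
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  assignments <- relabel[fit$cluster]
  names(assignments) <- rownames(x)
  centers <- fit$centers[ord, , drop = FALSE]
  rownames(centers) <- seq_len(k)
  new("ClusteringResult",
      k = k,
      assignments = assignments,
      centers = centers,
      inertia = fit$tot.withinss,
      seed = as.integer(seed),
      transform = transform,
      sizes = as.integer(fit$size[ord]))
}

#' Summarize a trajectory clustering
#'
#' Cluster sizes and percentages, back-transformed center profiles (nt), and
#' a monotonicity classification of each center across the species order:
#' strictly increasing, strictly decreasing, or mixed.
#'
#' @param result a [ClusteringResult-class].
#' @return data.frame with one row per cluster: cluster, size, pct, the
#'   four center coordinates in nt, and \code{pattern}.
#' @export
clusterSummary <- function(result) {
  stopifnot(is(result, "ClusteringResult"))
  centers <- clusterCenters(result)
  profile <- if (result@transform == "log2") 2^centers else centers
  colnames(profile) <- SPECIES_ORDER
  pattern <- apply(centers, 1L, function(v) {
    d <- diff(v)
    if (all(d > 0)) "increasing" else if (all(d < 0)) "decreasing" else "mixed"
  })
  out <- data.frame(
    cluster = seq_len(result@k),
    size = clusterSizes(result),
    pct = 100 * clusterSizes(result) / sum(clusterSizes(result)),
    profile,
    pattern = pattern,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Inertia across a range of k
#'
#' Best-of-\code{nInit} total within-cluster sum of squares for each k, the
#' programmatic replacement for choosing k by eye: inertia is non-increasing
#' in k and an elbow marks the parsimonious choice.
#'
#' @param trajectories data.frame from [buildTrajectories()].
#' @param ks integer vector of cluster counts to evaluate.
#' @inheritParams clusterTrajectories
#' @return data.frame (k, inertia).
#' @export
inertiaProfile <- function(trajectories, ks = 1:8,
                           transform = c("log2", "identity"),
                           seed = 1L, nInit = 25L) {
  transform <- match.arg(transform)
  data.frame(
    k = ks,
    inertia = vapply(ks, function(k) {
      clusterInertia(clusterTrajectories(trajectories, k = k,
                                         transform = transform,
                                         seed = seed, nInit = nInit))
    }, numeric(1)))
}
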