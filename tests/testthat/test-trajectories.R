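trajFixture <- function() {
  ot <- data.frame(
    group_id = c("OG1", "OG1", "OG1", "OG1", "OG1",
                 "OG2", "OG2", "OG2"),
    species = c("Dme", "Dre", "Mmu", "Hsa", "Hsa",
                "Dme", "Dre", "Mmu"),
    gene_id = c("d1", "z1", "m1", "h1", "h2", "d2", "z2", "m2"),
    stringsAsFactors = FALSE)
  lt <- data.frame(
    gene_id = c("d1", "z1", "m1", "h1", "h2", "d2", "z2", "m2"),
    species = ot$species,
    accession = paste0("NM_", 1:8, ".1"),
    len5 = 100L, len_cds = 900L,
    len3 = c(100L, 200L, 300L, 400L, 600L, 100L, 150L, 200L),
    stringsAsFactors = FALSE)
  list(ot = ot, lt = lt)
}

test_that("co-orthologs are averaged and incomplete groups are dropped with a count", {
  fx <- trajFixture()
  expect_message(traj <- buildTrajectories(fx$ot, fx$lt), "dropped")
  expect_identical(traj$group_id, "OG1")     # OG2 misses human
  expect_equal(traj$Hsa, 500)                # mean of 400 and 600
  expect_equal(unlist(traj[1, SPECIES_ORDER], use.names = FALSE),
               c(100, 200, 300, 500))
  expect_identical(attr(traj, "dropped"), 1L)
})

test_that("unknown gene ids abort with the offending ids unless dropping is requested", {
  fx <- trajFixture()
  fx$ot$gene_id[1] <- "ghost"
  expect_error(buildTrajectories(fx$ot, fx$lt), "ghost")
  expect_message(traj <- buildTrajectories(fx$ot, fx$lt, onMissing = "drop"))
  expect_identical(nrow(traj), 0L)           # OG1 lost its only Dme member
})

test_that("k = 1 yields the coordinate-wise mean and identical points have zero inertia", {
  cohort <- generateCohort(cleanConfig(seed = 41L, nGenesPerSpecies = 300L,
                                       nOrthologGroups = 80L))
  traj <- buildTrajectories(orthologGroups(cohort), curatedLengths(cohort))
  one <- clusterTrajectories(traj, k = 1, seed = 3L)
  expect_equal(unname(clusterCenters(one)[1, ]),
               unname(colMeans(log2(as.matrix(traj[SPECIES_ORDER])))))
  dup <- traj[rep(1L, 10L), ]
  dup$group_id <- sprintf("OG%02d", 1:10)
  flat <- clusterTrajectories(dup, k = 1, seed = 3L)
  expect_equal(clusterInertia(flat), 0)
})

test_that("clustering errors on impossible k", {
  fx <- trajFixture()
  traj <- suppressMessages(buildTrajectories(fx$ot, fx$lt))
  expect_error(clusterTrajectories(traj, k = 0), "k must be >= 1")
  expect_error(clusterTrajectories(traj, k = 5), "exceeds")
})

test_that("same seed reproduces the clustering exactly", {
  cohort <- generateCohort(cleanConfig(seed = 42L, nGenesPerSpecies = 600L,
                                       nOrthologGroups = 150L))
  traj <- buildTrajectories(orthologGroups(cohort), curatedLengths(cohort))
  a <- clusterTrajectories(traj, k = 4, seed = 17L)
  b <- clusterTrajectories(traj, k = 4, seed = 17L)
  expect_identical(clusterAssignments(a), clusterAssignments(b))
  expect_equal(clusterCenters(a), clusterCenters(b))
})

test_that("centers equal the mean of their members in clustering space", {
  cohort <- generateCohort(cleanConfig(seed = 43L, nGenesPerSpecies = 600L,
                                       nOrthologGroups = 150L))
  traj <- buildTrajectories(orthologGroups(cohort), curatedLengths(cohort))
  cl <- clusterTrajectories(traj, k = 4, seed = 7L)
  x <- log2(as.matrix(traj[SPECIES_ORDER]))
  rownames(x) <- traj$group_id
  for (i in seq_len(cl@k)) {
    member <- x[clusterAssignments(cl)[rownames(x)] == i, , drop = FALSE]
    expect_equal(unname(clusterCenters(cl)[i, ]), unname(colMeans(member)),
                 tolerance = 1e-8)
  }
})

test_that("planted archetypes are recovered and labels are compared label-invariantly", {
  skip_if_not_installed("mclust")
  cohort <- generateCohort(cleanConfig(seed = 44L, nGenesPerSpecies = 700L,
                                       nOrthologGroups = 400L))
  traj <- buildTrajectories(orthologGroups(cohort), curatedLengths(cohort))
  cl <- clusterTrajectories(traj, k = 4, seed = 5L)
  truthArch <- cohortTruth(cohort)$groupArchetypes
  planted <- truthArch$archetype[match(names(clusterAssignments(cl)),
                                       truthArch$group_id)]
  ari <- mclust::adjustedRandIndex(clusterAssignments(cl), planted)
  expect_gt(ari, 0.9)
})

test_that("cluster summaries report sizes, percentages and monotonicity classes", {
  assignments <- setNames(rep(1:3, c(60L, 30L, 10L)), sprintf("OG%03d", 1:100))
  centers <- rbind(log2(c(100, 200, 400, 800)),
                   log2(c(800, 400, 200, 100)),
                   log2(c(100, 800, 200, 400)))
  res <- new("ClusteringResult", k = 3L, assignments = assignments,
             centers = centers, inertia = 1, seed = 1L, transform = "log2",
             sizes = c(60L, 30L, 10L))
  s <- clusterSummary(res)
  expect_equal(s$pct, c(60, 30, 10))
  expect_equal(s$pattern, c("increasing", "decreasing", "mixed"))
  expect_equal(unname(unlist(s[1, SPECIES_ORDER])), c(100, 200, 400, 800))
})

test_that("best-of-restarts inertia is non-increasing in k", {
  cohort <- generateCohort(cleanConfig(seed = 45L, nGenesPerSpecies = 600L,
                                       nOrthologGroups = 150L))
  traj <- buildTrajectories(orthologGroups(cohort), curatedLengths(cohort))
  prof <- inertiaProfile(traj, ks = 1:6, seed = 2L, nInit = 10L)
  expect_true(all(diff(prof$inertia) <= 1e-8))
})
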