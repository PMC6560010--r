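test_that("length partition is forced by the sort and the remainder rule", {
  lt <- makeLengthTable(len3 = c(60L, 70L, 80L, 90L, 100L, 110L, 120L, 130L))
  p <- partitionByLength(lt)
  sets <- partitionSets(p)
  len3Of <- function(g) lt$len3[match(g, lt$gene_id)]
  expect_equal(lapply(sets, len3Of),
               list(Q1 = c(60L, 70L), Q2 = c(80L, 90L),
                    Q3 = c(100L, 110L), Q4 = c(120L, 130L)))
  p10 <- partitionByLength(makeLengthTable(len3 = 101:110))
  expect_equal(unname(lengths(partitionSets(p10))), c(3L, 3L, 2L, 2L))
  expect_error(partitionByLength(makeLengthTable(len3 = c(1L, 2L, 3L))),
               "fewer genes")
})

test_that("length quartiles are ordered blocks of the full sort", {
  # brute-force oracle on random tables: Q_i max <= Q_{i+1} min, and the
  # partition equals cutting the (len3, gene_id)-sorted gene list
  set.seed(88)
  for (i in 1:50) {
    n <- sample(4:60, 1)
    lt <- makeLengthTable(len3 = sample(50:500, n, replace = TRUE))
    p <- partitionByLength(lt)
    sets <- partitionSets(p)
    len3Of <- function(g) lt$len3[match(g, lt$gene_id)]
    maxs <- vapply(sets, function(g) max(len3Of(g)), numeric(1))
    mins <- vapply(sets, function(g) min(len3Of(g)), numeric(1))
    expect_true(all(head(maxs, -1) <= tail(mins, -1)))
    sorted <- lt$gene_id[order(lt$len3, lt$gene_id)]
    expect_identical(unname(unlist(sets)), sorted)
  }
})

test_that("random partitions are uniform, disjoint, seed-deterministic blocks", {
  genes <- sprintf("g%02d", 1:10)
  p <- randomPartition(genes, seed = 5L)
  sets <- partitionSets(p)
  expect_setequal(unlist(sets), genes)
  expect_false(anyDuplicated(unlist(sets)) > 0)
  expect_equal(unname(lengths(sets)), c(3L, 3L, 2L, 2L))
  expect_identical(partitionSets(randomPartition(genes, seed = 5L)), sets)
  expect_false(identical(partitionSets(randomPartition(genes, seed = 6L)), sets))
  # exact uniform-permutation probabilities: each of 4 genes lands in part 1
  # of a 2-part split with probability 1/2
  hits <- vapply(1:4000, function(s) {
    "g1" %in% partitionSets(randomPartition(paste0("g", 1:4), nParts = 2L,
                                            seed = s))$R1
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.5), 0.03)
})

test_that("the GO frequency matrix counts distinct annotated genes per set", {
  part <- new("GeneSetPartition", kind = "random",
              sets = list(S1 = c("g1", "g2"), S2 = "g3"), seed = 1L)
  go <- data.frame(gene_id = c("g1", "g1", "g2", "g3", "g3"),
                   go_term = c("A", "B", "A", "B", "B"),  # g3/B duplicated
                   stringsAsFactors = FALSE)
  M <- buildGoMatrix(part, go)
  expect_equal(M, matrix(c(2L, 0L, 1L, 1L), 2, 2, byrow = TRUE,
                         dimnames = list(c("A", "B"), c("S1", "S2"))))
})

test_that("matrix column sums equal the generator's per-set annotation-pair counts", {
  cohort <- generateCohort(smallConfig(seed = 51L))
  lt <- curatedLengths(cohort)
  lt <- lt[lt$species == "Dme", ]
  part <- partitionByLength(lt)
  go <- goAnnotations(cohort)
  M <- buildGoMatrix(part, go)
  for (lab in names(partitionSets(part))) {
    inSet <- go$gene_id %in% partitionSets(part)[[lab]]
    expect_equal(unname(colSums(M)[lab]), sum(inSet))
  }
  # annotation-free partitions produce an empty matrix
  none <- buildGoMatrix(part, go[0, ])
  expect_identical(nrow(none), 0L)
  expect_error(setDispersion(none), "empty")
})

test_that("set scaling matches an independent eigen-decomposition", {
  M <- matrix(c(5, 1, 0, 2, 3, 4,
                4, 2, 1, 2, 2, 5,
                1, 6, 2, 3, 1, 0,
                0, 5, 4, 4, 0, 1), nrow = 6,
              dimnames = list(paste0("GO:", 1:6), paste0("Q", 1:4)))
  sc <- scaleSets(M)
  X <- t(M)
  Xc <- sweep(X, 2, colMeans(X))
  eig <- eigen(stats::cov(Xc))
  oracleCoords <- Xc %*% eig$vectors[, 1:2]
  got <- scalingCoordinates(sc)
  for (j in 1:2)  # eigenvectors are sign-ambiguous
    expect_true(max(abs(got[, j] - oracleCoords[, j])) < 1e-10 ||
                max(abs(got[, j] + oracleCoords[, j])) < 1e-10)
  oracleEv <- eig$values / sum(eig$values)
  expect_equal(explainedVariance(sc)[1:2], oracleEv[1:2], tolerance = 1e-10)
  # centroid of the scaled sets sits at the origin
  expect_equal(unname(colMeans(got)), c(0, 0), tolerance = 1e-12)
})

test_that("degenerate and two-set scalings behave geometrically", {
  same <- matrix(3L, 4, 3, dimnames = list(paste0("t", 1:4), paste0("S", 1:3)))
  sc <- scaleSets(same)
  expect_true(sc@degenerate)
  expect_true(all(scalingCoordinates(sc) == 0))
  two <- matrix(c(4, 0, 1, 0, 2, 3), nrow = 3,
                dimnames = list(paste0("t", 1:3), c("A", "B")))
  sc2 <- scaleSets(two)
  co <- scalingCoordinates(sc2)
  expect_equal(co["A", "PC1"], -co["B", "PC1"])   # symmetric about origin
  expect_equal(unname(co[, "PC2"]), c(0, 0))
  expect_error(scaleSets(two[, 1, drop = FALSE]), "at least 2")
})

test_that("dispersion follows the variance decomposition and is label-invariant", {
  two <- matrix(c(4, 0, 1, 0, 2, 3), nrow = 3)
  d <- sum((two[, 1] - two[, 2])^2)
  expect_equal(setDispersion(two), d / 2)          # half the squared distance
  same <- matrix(7, 5, 4)
  expect_equal(setDispersion(same), 0)
  M <- matrix(rpois(24, 5), 6, 4)
  expect_equal(setDispersion(M), sum(apply(M, 1, var)))  # sum of term variances
  expect_equal(setDispersion(M[, c(3, 1, 4, 2)]), setDispersion(M))
  expect_equal(setDispersion(M[sample(6), ]), setDispersion(M))
})

test_that("the divergence test applies the add-one permutation estimator", {
  cohort <- generateCohort(cleanConfig(seed = 52L, nGenesPerSpecies = 1200L,
                                       nOrthologGroups = 0L,
                                       goAssociationStrength = 1.5))
  lt <- curatedLengths(cohort)
  lt <- lt[lt$species == "Hsa", ]
  res <- divergenceTest(lt, goAnnotations(cohort), B = 99L, seed = 1L)
  expect_identical(length(nullDispersions(res)), 99L)
  expect_equal(pValue(res),
               (1 + sum(nullDispersions(res) >= observedDispersion(res))) / 100)
  # a strongly planted association clears every random partition
  expect_equal(pValue(res), 0.01)
  # observed statistic equals the explicit buildGoMatrix route
  M <- buildGoMatrix(partitionByLength(lt), goAnnotations(cohort))
  expect_equal(observedDispersion(res), setDispersion(M))
})

test_that("divergence test rejects bad inputs", {
  lt <- makeLengthTable(len3 = 101:120)
  go <- data.frame(gene_id = "not_there", go_term = "A")
  expect_error(divergenceTest(lt, go, B = 19L), "no GO annotations")
  goOk <- data.frame(gene_id = lt$gene_id, go_term = "A")
  expect_error(divergenceTest(lt, goOk, B = 5L), "B must be >= 19")
  expect_error(divergenceTest(rbind(lt, lt), goOk, B = 19L), "one row per gene")
})

test_that("reproducibility: the same seed gives identical null dispersions", {
  cohort <- generateCohort(smallConfig(seed = 53L))
  lt <- curatedLengths(cohort)
  lt <- lt[lt$species == "Mmu", ]
  a <- divergenceTest(lt, goAnnotations(cohort), B = 29L, seed = 4L)
  b <- divergenceTest(lt, goAnnotations(cohort), B = 29L, seed = 4L)
  expect_identical(nullDispersions(a), nullDispersions(b))
})
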