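test_that("the notch interval follows median +/- 1.57 IQR / sqrt(n)", {
  # an evenly spaced sample from 60 to 140 has median 100 and IQR 40 under
  # the linear-interpolation quantile convention
  v <- seq(60, 140, length.out = 100)
  ci <- notchCI(v)
  expect_equal(ci$median, 100)
  expect_equal(ci$lower, 100 - 1.57 * 40 / 10)
  expect_equal(ci$upper, 100 + 1.57 * 40 / 10)
  flat <- notchCI(rep(80, 20))
  expect_equal(flat$lower, 80)
  expect_equal(flat$upper, 80)
  expect_error(notchCI(5), "at least 2")
})

test_that("notch width shrinks monotonically with n at fixed IQR", {
  widths <- vapply(c(10, 40, 160, 640), function(n) {
    ci <- notchCI(seq(60, 140, length.out = n))
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("interval coverage of the true median is near nominal for log-normal data", {
  set.seed(101)
  trueMedian <- 2^9.5
  hits <- replicate(300, {
    ci <- notchCI(2^rnorm(500, 9.5, 1.0))
    ci$lower <= trueMedian && trueMedian <= ci$upper
  })
  expect_gte(mean(hits), 0.88)
  expect_lte(mean(hits), 0.99)
})

test_that("identical categories give identical intervals and overlap", {
  lt <- makeLengthTable(len3 = rep(c(100L, 200L, 300L, 400L), 2),
                        gene_id = sprintf("g%02d", 1:8))
  cats <- data.frame(gene_id = lt$gene_id,
                     tissue_category = rep(c("Mixed", "Tissue enriched"), each = 4),
                     subcellular_category = NA_character_,
                     stringsAsFactors = FALSE)
  cmp <- compareCategories(lt, cats, axis = "tissue")
  m <- cmp$medians
  expect_equal(m$median[1], m$median[2])
  expect_equal(m$lower[1], m$lower[2])
  expect_true(all(cmp$overlap))
})

test_that("singleton categories are excluded with a warning, others untouched", {
  lt <- makeLengthTable(len3 = c(100L, 120L, 140L, 999L),
                        gene_id = sprintf("g%02d", 1:4))
  cats <- data.frame(gene_id = lt$gene_id,
                     tissue_category = c(rep("Mixed", 3), "Group enriched"),
                     subcellular_category = NA_character_,
                     stringsAsFactors = FALSE)
  expect_warning(cmp <- compareCategories(lt, cats, axis = "tissue"), "n < 2")
  expect_identical(cmp$medians$category, "Mixed")
  expect_identical(cmp$excluded, "Group enriched")
  full <- suppressWarnings(compareCategories(lt[1:3, ], cats, axis = "tissue"))
  expect_equal(cmp$medians, full$medians)
})

test_that("uncategorized genes are excluded and counted without touching the rest", {
  cohort <- generateCohort(smallConfig(seed = 61L))
  lt <- curatedLengths(cohort)
  hsa <- lt[lt$species == "Hsa", ]
  cmp <- compareCategories(hsa, geneCategories(cohort), axis = "subcellular")
  expect_gt(cmp$nUncategorized, 0)
  expect_true(all(cmp$medians$lower <= cmp$medians$median &
                  cmp$medians$median <= cmp$medians$upper))
})

test_that("a planted Mixed shift yields the largest, notch-separated median", {
  cfg <- cleanConfig(seed = 62L, nGenesPerSpecies = 2500L,
                     nOrthologGroups = 0L,
                     categoryMedianShifts = c(Mixed = 1.5))
  cohort <- generateCohort(cfg)
  lt <- curatedLengths(cohort)
  hsa <- lt[lt$species == "Hsa", ]
  cmp <- compareCategories(hsa, geneCategories(cohort), axis = "tissue")
  expect_identical(cmp$medians$category[1], "Mixed")
  others <- setdiff(cmp$medians$category, "Mixed")
  expect_true(all(!cmp$overlap["Mixed", others]))
})

test_that("with no planted shifts all tissue notches overlap", {
  cohort <- generateCohort(cleanConfig(seed = 63L, nGenesPerSpecies = 2500L,
                                       nOrthologGroups = 0L))
  lt <- curatedLengths(cohort)
  hsa <- lt[lt$species == "Hsa", ]
  cmp <- compareCategories(hsa, geneCategories(cohort), axis = "tissue")
  expect_true(all(cmp$overlap))
})

test_that("tables with no shared genes are rejected", {
  lt <- makeLengthTable(len3 = c(100L, 200L))
  cats <- data.frame(gene_id = c("x1", "x2"), tissue_category = "Mixed",
                     subcellular_category = NA_character_)
  expect_error(compareCategories(lt, cats, axis = "tissue"), "share no genes")
})
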