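test_that("sampleSpecimenPercent follows the zero-inflated Beta law", {
  # degenerate law: always fully negative
  allNeg <- markerDistribution("p53", zeroInflation = 1)
  expect_identical(sampleSpecimenPercent(allNeg, 50), rep(0, 50))

  # symmetric Beta with no zero inflation: mean near 50
  sym <- markerDistribution("p16", zeroInflation = 0, alpha = 2, beta = 2)
  set.seed(808)
  draws <- sampleSpecimenPercent(sym, 2000)
  expect_true(all(draws >= 0 & draws <= 100))
  expect_lt(abs(mean(draws) - 50), 2)

  # determinism under a fixed seed
  set.seed(9); a <- sampleSpecimenPercent(sym, 10)
  set.seed(9); b <- sampleSpecimenPercent(sym, 10)
  expect_identical(a, b)

  expect_error(markerDistribution("p53", zeroInflation = 1.2), "probability")
  expect_error(markerDistribution("p53", 0.5, alpha = 0), "alpha")
  expect_error(markerDistribution("p53", 0.5, beta = -1), "beta")
})

test_that("generatePair implements the clonal and independent mechanisms", {
  # zero drift: the clonal twin bins identically, total D-value 0
  set.seed(11)
  for (i in 1:10) {
    pair <- generatePair("clonal", driftSd = 0)
    expect_identical(totalD(totalDValue(pair$t1, pair$t2)), 0L)
    expect_identical(pair$label, "metastatic-like")
  }
  set.seed(12)
  indep <- generatePair("independent")
  expect_identical(indep$label, "MPLC-like")
  expect_identical(lesionRole(indep$t1), "primary")
  expect_identical(lesionRole(indep$t2), "second_lesion")

  # degenerate laws on both sides: no signal, labels unrecoverable by design
  degen <- lapply(stats::setNames(nm = markerPanel()),
                  function(m) markerDistribution(m, zeroInflation = 1))
  pair <- generatePair("independent", markerDists = degen)
  expect_identical(totalD(totalDValue(pair$t1, pair$t2)), 0L)

  expect_error(generatePair("clonal", driftSd = -1), "non-negative")
})

test_that("generateCohort is seeded, sized and byte-reproducible", {
  ch <- generateCohort(3, 2, seed = 21)
  expect_identical(nrow(ch$specimens), 5L * 8L)
  expect_identical(table(ch$labels$label)[["metastatic-like"]], 3L)
  expect_identical(table(ch$labels$label)[["MPLC-like"]], 2L)

  onlyIndep <- generateCohort(0, 5, seed = 3)
  expect_identical(unique(onlyIndep$labels$label), "MPLC-like")
  expect_error(generateCohort(0, 0), "> 0")

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeCohort(generateCohort(4, 4, seed = 77), f1)
  writeCohort(generateCohort(4, 4, seed = 77), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))

  # the ambient RNG stream is left untouched by a seeded call
  set.seed(99); before <- .Random.seed
  invisible(generateCohort(2, 2, seed = 55))
  expect_identical(.Random.seed, before)
})

test_that("clonal D-values grow with drift and stay below independent pairs", {
  meanClonalTotal <- function(sd) {
    ch <- generateCohort(60, 0, driftSd = sd, seed = 31)
    mean(vapply(pairDValues(specimenProfiles(readSpecimenTable(ch$specimens))),
                totalD, integer(1)))
  }
  m <- vapply(c(0, 5, 15, 40), meanClonalTotal, numeric(1))
  expect_true(all(diff(m) >= 0))

  # separation at small drift and dispersed marker laws
  ch <- generateCohort(60, 60, driftSd = 5, seed = 32)
  pairs <- pairDValues(specimenProfiles(readSpecimenTable(ch$specimens)))
  totals <- vapply(pairs, totalD, integer(1))
  clonal <- ch$labels$label == "metastatic-like"
  expect_gt(mean(totals[!clonal]), mean(totals[clonal]))
})

test_that("the cut-off-90 rule recovers synthetic labels above chance", {
  md <- defaultMarkerDistributions(alpha = 0.5, beta = 0.5)
  ch <- generateCohort(100, 100, driftSd = 5, markerDists = md, seed = 41)
  pairs <- pairDValues(specimenProfiles(readSpecimenTable(ch$specimens)))
  calls <- vapply(pairs, function(p) modelCall(classifyPair(p)),
                  character(1))
  truth <- ifelse(ch$labels$label == "metastatic-like", "metastatic", "MPLC")
  hits <- sum(calls == truth)
  expect_lt(binom.test(hits, length(truth), p = 0.5,
                       alternative = "greater")$p.value, 0.01)
})
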