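test_that("buildReclassification cross-tabulates and conserves counts", {
  calls <- c("MPLC", "metastatic", "MPLC", "metastatic", "metastatic")
  clin <- c("MPLC", "MPLC", "IPM", "IPM", "IPM")
  tab <- buildReclassification(calls, clin)
  expect_identical(sum(counts(tab)), 5L)
  expect_identical(counts(tab)["MPLC", "MPLC"], 1L)
  expect_identical(counts(tab)["IPM", "IPM"], 2L)

  # empty input gives the all-zero table
  expect_identical(sum(counts(buildReclassification(character(), character()))),
                   0L)
  # perfectly concordant input has zero off-diagonals
  off <- counts(buildReclassification(c("MPLC", "IPM"), c("MPLC", "IPM")))
  expect_identical(off["MPLC", "IPM"] + off["IPM", "MPLC"], 0L)

  expect_error(buildReclassification("MPLC", c("MPLC", "IPM")),
               "differ in length")
  expect_error(buildReclassification("MPLC", "benign"), "unknown clinical")
  expect_error(buildReclassification("maybe", "MPLC"), "unknown model call")
})

test_that("counts are invariant under permutations of input order", {
  set.seed(505)
  calls <- sample(c("MPLC", "metastatic"), 40, replace = TRUE)
  clin <- sample(c("MPLC", "IPM"), 40, replace = TRUE)
  ref <- counts(buildReclassification(calls, clin))
  for (i in 1:5) {
    perm <- sample(40)
    expect_identical(counts(buildReclassification(calls[perm], clin[perm])),
                     ref)
  }
})

test_that("buildReclassification accepts Classification objects", {
  calls <- list(classifyPair(120), classifyPair(20))
  tab <- buildReclassification(calls, c("MPLC", "IPM"))
  expect_identical(counts(tab)["MPLC", "MPLC"], 1L)
  expect_identical(counts(tab)["IPM", "IPM"], 1L)
})

test_that("agreement on the published counts gives the known fractions", {
  rep <- agreement(reclassificationCounts())
  expect_equal(perGroupFractions(rep)[["IPM"]], 14 / 20)   # 70.0%
  expect_equal(perGroupFractions(rep)[["MPLC"]], 29 / 36)
  expect_equal(percentAgreement(rep), (29 + 14) / 56 * 100)
  expect_gt(cohenKappa(rep), 0)
  expect_error(agreement(ReclassificationTable(0, 0, 0, 0)), "empty table")
})

test_that("kappa matches its closed form and an independent implementation", {
  # perfectly concordant table
  expect_equal(cohenKappa(agreement(ReclassificationTable(10, 0, 0, 10))), 1)

  closedForm <- function(cts) {
    n <- sum(cts)
    po <- sum(diag(cts)) / n
    pe <- sum(rowSums(cts) * colSums(cts)) / n^2
    (po - pe) / (1 - pe)
  }
  set.seed(606)
  for (i in 1:25) {
    cells <- rpois(4, 8) + 1
    tab <- ReclassificationTable(cells[1], cells[2], cells[3], cells[4])
    k <- cohenKappa(agreement(tab))
    expect_equal(k, closedForm(counts(tab)))
    expect_equal(k, e1071::classAgreement(counts(tab))$kappa)
  }
})

test_that("threshold sweep reproduces the control operating points", {
  ctrl <- controlPairDValues()
  mplc <- list(pairFromD(p53 = 60, p16 = 40, p27 = 30, cerbB2 = 20),   # 150
               pairFromD(p53 = 100, p16 = 60, p27 = 40, cerbB2 = 20))  # 220
  sw <- thresholdSweep(ctrl, mplc)
  at <- function(th) sw[sw$threshold == th, ]
  # all 30 recomputed control totals are <= 90
  expect_equal(at(90)$sensitivity_metastatic, 1.0)
  expect_equal(at(90)$specificity_metastatic, 1.0)
  expect_equal(at(400)$sensitivity_metastatic, 1.0)
  expect_equal(at(400)$specificity_metastatic, 0.0)
  # every control total is >= 10, so a threshold below 10 catches none
  expect_equal(at(0)$sensitivity_metastatic, 0.0)

  expect_error(thresholdSweep(list(), mplc), "empty")
  expect_error(thresholdSweep(ctrl, list()), "empty")
})

test_that("sweep rates are monotone in the threshold", {
  set.seed(707)
  for (i in 1:10) {
    met <- as.numeric(sample(seq(0, 400, 10), 15, replace = TRUE))
    mplc <- as.numeric(sample(seq(0, 400, 10), 15, replace = TRUE))
    sw <- thresholdSweep(met, mplc)
    expect_true(all(diff(sw$sensitivity_metastatic) >= 0))
    expect_true(all(diff(sw$specificity_metastatic) <= 0))
  }
})
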