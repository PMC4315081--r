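test_that("markerDValue is the absolute score difference, same marker only", {
  expect_identical(markerDValue(MarkerScore("p16", 40),
                                MarkerScore("p16", 10)), 30L)
  expect_identical(markerDValue(MarkerScore("p16", 10),
                                MarkerScore("p16", 40)), 30L)
  expect_identical(markerDValue(MarkerScore("p53", 50),
                                MarkerScore("p53", 50)), 0L)
  expect_error(markerDValue(MarkerScore("p53", 50), MarkerScore("p16", 50)),
               "marker mismatch")
})

test_that("totalDValue sums the four per-marker absolute differences", {
  # control-table style rows: per-marker Ds (p16=40, erbB2=10, p27=20,
  # p53=20) sum to 90; (10, 10, 0, 0) sum to 20
  t1 <- profile(p16 = 40, cerbB2 = 10, p27 = 20, p53 = 20)
  t2 <- profile()
  p <- totalDValue(t1, t2)
  expect_identical(totalD(p), 90L)
  expect_identical(perMarkerD(p)[["p16"]], 40L)

  expect_identical(totalD(totalDValue(profile(p16 = 10, cerbB2 = 10),
                                      profile())), 20L)
  expect_identical(totalD(totalDValue(t1, t1)), 0L)
})

test_that("totalDValue enforces patient identity unless overridden", {
  a <- profile(id = "A", p53 = 50)
  b <- profile(id = "B", role = "second_lesion", p53 = 10)
  expect_error(totalDValue(a, b), "patient mismatch")
  expect_identical(totalD(totalDValue(a, b, checkPatient = FALSE)), 40L)
})

test_that("totalDValue is symmetric and obeys the triangle inequality", {
  set.seed(303)
  for (i in 1:50) {
    s1 <- profile(p53 = randomDeciles(1), p16 = randomDeciles(1),
                  p27 = randomDeciles(1), cerbB2 = randomDeciles(1))
    s2 <- profile(role = "second_lesion", p53 = randomDeciles(1),
                  p16 = randomDeciles(1), p27 = randomDeciles(1),
                  cerbB2 = randomDeciles(1))
    expect_identical(totalD(totalDValue(s1, s2)),
                     totalD(totalDValue(s2, s1)))
  }
  # per-marker triangle inequality on random decile triples
  for (i in 1:200) {
    tri <- randomDeciles(3)
    a <- MarkerScore("p27", tri[1]); b <- MarkerScore("p27", tri[2])
    c <- MarkerScore("p27", tri[3])
    expect_lte(markerDValue(a, c), markerDValue(a, b) + markerDValue(b, c))
  }
})

test_that("classifyPair puts the boundary total in the metastatic class", {
  expect_identical(modelCall(classifyPair(90)), "metastatic")
  expect_identical(modelCall(classifyPair(100)), "MPLC")
  expect_identical(modelCall(classifyPair(0)), "metastatic")
  expect_identical(threshold(classifyPair(0)), 90L)
  # the alternative boundary convention flips only the boundary value
  expect_identical(modelCall(classifyPair(90, boundary = "lt_is_metastatic")),
                   "MPLC")
  expect_identical(modelCall(classifyPair(80, boundary = "lt_is_metastatic")),
                   "metastatic")
  expect_error(classifyPair(90, threshold = -10), "non-negative")
  expect_error(classifyPair(500), "\\[0, 400\\]")

  p <- pairFromD(p53 = 40, p16 = 30, p27 = 20)
  expect_identical(modelCall(classifyPair(p)), "metastatic")
  expect_identical(totalD(classifyPair(p)), 90L)
})

test_that("raising the threshold never converts metastatic to MPLC", {
  set.seed(404)
  totals <- sample(seq(0L, 400L, 10L), 40, replace = TRUE)
  thresholds <- seq(0L, 400L, 10L)
  for (tot in totals) {
    calls <- vapply(thresholds,
                    function(th) modelCall(classifyPair(tot, th)),
                    character(1))
    # once metastatic, metastatic for all higher thresholds
    met <- calls == "metastatic"
    expect_true(all(met[which(met)[1]:length(met)]) || !any(met))
  }
})

test_that("brute-force enumeration: MPLC calls are exactly totals > 90", {
  grid <- expand.grid(rep(list(seq(0L, 100L, 10L)), 4))
  totals <- rowSums(grid)
  expect_identical(nrow(grid), 14641L)
  calls <- vapply(sort(unique(totals)), function(tot)
    modelCall(classifyPair(tot)), character(1))
  names(calls) <- sort(unique(totals))
  callPerCombo <- calls[as.character(totals)]
  expect_identical(unname(callPerCombo == "MPLC"), unname(totals > 90))
})

test_that("minMplcTotal finds the smallest achievable MPLC total", {
  expect_identical(minMplcTotal(), 100L)
  expect_identical(minMplcTotal(0), 10L)
  expect_identical(minMplcTotal(85), 90L)
  expect_warning(res <- minMplcTotal(400), "no achievable total")
  expect_identical(res, NA_integer_)
  # agrees with 10 * (floor(t/10) + 1) for decile-multiple thresholds
  for (th in seq(0L, 390L, 10L))
    expect_identical(minMplcTotal(th), 10L * (th %/% 10L + 1L))
})
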