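# The differential-expression (D-value) model and the cut-off-90 rule.
#
# Per marker, the D-value of a lesion pair is the absolute difference of the
# two decile staining scores; the model statistic is the unweighted sum over
# the four markers (range 0..400). With the default rule a pair is called
# metastatic when the total does not exceed the reference value of 90 and
# MPLC when it does. The boundary convention and the threshold are
# configurable; "le_is_metastatic" is the default because the published
# control group contains a metastatic pair with total exactly 90.

#' Per-marker D-value of two staining scores
#'
#' The absolute difference of the two lesions' decile scores for one marker.
#' Symmetric in its arguments; both readings must be of the same marker.
#'
#' @param s1,s2 [MarkerScore-class] objects for the same marker.
#' @return Integer D-value, a multiple of 10 in \[0, 100\].
#' @examples
#' markerDValue(MarkerScore("p16", 40), MarkerScore("p16", 10))  # 30
#' @export
markerDValue <- function(s1, s2) {
  stopifnot(is(s1, "MarkerScore"), is(s2, "MarkerScore"))
  if (marker(s1) != marker(s2))
    stop("marker mismatch: ", marker(s1), " vs ", marker(s2))
  abs(score(s1) - score(s2))
}

#' Total D-value of a lesion pair
#'
#' Computes the four per-marker absolute score differences between two
#' lesions of the same patient and their sum, the model's diagnostic
#' statistic.
#'
#' @param t1,t2 [SpecimenProfile-class] objects, conventionally the primary
#'   tumor and the second lesion / metastasis. The statistic is symmetric,
#'   so the order does not matter.
#' @param checkPatient If `TRUE` (default), require both profiles to carry
#'   the same `patientId`; set `FALSE` for exploratory cross-patient
#'   comparisons.
#' @return A [PairDValue-class].
#' @examples
#' t1 <- SpecimenProfile("P01", "primary",
#'                       c(p53 = 40, p16 = 50, p27 = 20, cerbB2 = 10))
#' t2 <- SpecimenProfile("P01", "lymph_node_met",
#'                       c(p53 = 20, p16 = 10, p27 = 0, cerbB2 = 20))
#' totalDValue(t1, t2)
#' @export
totalDValue <- function(t1, t2, checkPatient = TRUE) {
  stopifnot(is(t1, "SpecimenProfile"), is(t2, "SpecimenProfile"))
  if (checkPatient && patientId(t1) != patientId(t2))
    stop("patient mismatch: '", patientId(t1), "' vs '", patientId(t2),
         "' (use checkPatient = FALSE to override)")
  PairDValue(patientId(t1), abs(markerScores(t1) - markerScores(t2)))
}

#' Classify a lesion pair by its total D-value
#'
#' Applies the cut-off rule: under the default boundary convention
#' (`"le_is_metastatic"`) a pair whose total does not exceed the threshold
#' is called metastatic, and MPLC when it does exceed it. The alternative
#' convention `"lt_is_metastatic"` places the boundary value itself in the
#' MPLC class.
#'
#' @param pair A [PairDValue-class], or a bare numeric total in \[0, 400\].
#' @param threshold Non-negative integer reference value (default 90).
#' @param boundary Boundary convention, `"le_is_metastatic"` (default) or
#'   `"lt_is_metastatic"`.
#' @return A [Classification-class].
#' @examples
#' classifyPair(90)   # metastatic: does not exceed 90
#' classifyPair(100)  # MPLC
#' @export
classifyPair <- function(pair, threshold = 90L,
                         boundary = c("le_is_metastatic",
                                      "lt_is_metastatic")) {
  boundary <- match.arg(boundary)
  if (length(threshold) != 1L || !is.finite(threshold) || threshold < 0)
    stop("threshold must be a single non-negative integer")
  total <- if (is(pair, "PairDValue")) totalD(pair) else {
    if (!is.numeric(pair) || length(pair) != 1L || !is.finite(pair) ||
        pair < 0 || pair > 400)
      stop("pair must be a PairDValue or a single total in [0, 400]")
    as.integer(pair)
  }
  metastatic <- if (boundary == "le_is_metastatic") total <= threshold
                else total < threshold
  new("Classification", call = if (metastatic) "metastatic" else "MPLC",
      total = as.integer(total), threshold = as.integer(threshold))
}

#' Smallest total D-value classified as MPLC
#'
#' Given that per-marker D-values are decile multiples, the achievable
#' totals are 0, 10, ..., 400. Returns the smallest achievable total the
#' default rule labels MPLC at the given threshold, or `NA` (with a
#' warning) when no achievable total exceeds it.
#'
#' @param threshold Non-negative integer reference value (default 90).
#' @return Integer, or `NA_integer_` if the threshold is unreachable.
#' @examples
#' minMplcTotal()     # 100
#' minMplcTotal(0)    # 10
#' @export
minMplcTotal <- function(threshold = 90L) {
  if (length(threshold) != 1L || !is.finite(threshold) || threshold < 0)
    stop("threshold must be a single non-negative integer")
  achievable <- seq(0L, 400L, by = 10L)
  mplc <- achievable[vapply(achievable, function(tot)
    modelCall(classifyPair(tot, threshold)) == "MPLC", logical(1L))]
  if (!length(mplc)) {
    warning("no achievable total (0..400 in steps of 10) exceeds threshold ",
            threshold)
    return(NA_integer_)
  }
  min(mplc)
}
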