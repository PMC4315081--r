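# Model call vs clinical diagnosis: 2x2 tables, agreement statistics and
# threshold-sweep operating characteristics.
#
# Percent agreement and Cohen's kappa are this package's quantification of
# the reclassification table; the source study reports only the counts and
# per-group fractions.

.asCallLabel <- function(x) {
  lab <- if (is(x, "Classification")) modelCall(x) else as.character(x)
  switch(lab, MPLC = "MPLC", metastatic = "IPM", IPM = "IPM",
         stop("unknown model call label '", lab,
              "' (expected MPLC, metastatic or IPM)"))
}

#' Build a reclassification table from calls and clinical labels
#'
#' Cross-tabulates the model's calls against the clinical (Martini-Melamed)
#' diagnoses. Metastatic model calls are tabulated in the IPM row: in the
#' reclassification setting a metastatic second lung lesion is an
#' intrapulmonary metastasis.
#'
#' @param calls List of [Classification-class] objects, or a character
#'   vector of `"MPLC"` / `"metastatic"` / `"IPM"` labels.
#' @param clinical Character vector of clinical diagnoses, `"MPLC"` or
#'   `"IPM"`, same length as `calls`.
#' @return A [ReclassificationTable-class]; its counts sum to the input
#'   length.
#' @examples
#' buildReclassification(c("MPLC", "metastatic"), c("MPLC", "IPM"))
#' @export
buildReclassification <- function(calls, clinical) {
  if (length(calls) != length(clinical))
    stop("calls and clinical labels differ in length (", length(calls),
         " vs ", length(clinical), ")")
  callLab <- vapply(calls, .asCallLabel, character(1L))
  clinical <- as.character(clinical)
  badClin <- setdiff(unique(clinical), c("MPLC", "IPM"))
  if (length(badClin))
    stop("unknown clinical label(s): ", paste(badClin, collapse = ", "))
  cell <- function(m, c) sum(callLab == m & clinical == c)
  ReclassificationTable(mplc_mplc = cell("MPLC", "MPLC"),
                        mplc_ipm = cell("MPLC", "IPM"),
                        ipm_mplc = cell("IPM", "MPLC"),
                        ipm_ipm = cell("IPM", "IPM"))
}

#' Agreement statistics for a reclassification table
#'
#' Computes overall percent agreement (100 x diagonal / total), Cohen's
#' chance-corrected kappa, and per-clinical-group concordant fractions
#' (which fraction of each clinical group the model calls the same way).
#' Kappa uses the standard 2x2 closed form
#' (p_o - p_e) / (1 - p_e) with p_e from the table margins; it is `NaN` for
#' a degenerate table whose expected agreement is already 1.
#'
#' @param table A [ReclassificationTable-class] with at least one count.
#' @return An [AgreementReport-class].
#' @examples
#' agreement(reclassificationCounts())
#' @export
agreement <- function(table) {
  stopifnot(is(table, "ReclassificationTable"))
  cts <- counts(table)
  n <- sum(cts)
  if (n == 0L) stop("cannot compute agreement on an empty table")
  po <- sum(diag(cts)) / n
  pe <- sum(rowSums(cts) * colSums(cts)) / n^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps^0.5) NaN else
    (po - pe) / (1 - pe)
  colTot <- colSums(cts)
  perGroup <- ifelse(colTot > 0, diag(cts) / colTot, NaN)
  names(perGroup) <- colnames(cts)
  new("AgreementReport", table = table, percentAgreement = 100 * po,
      kappa = kappa, perGroup = perGroup)
}

#' Threshold sweep over the control groups
#'
#' Operating characteristics of the cut-off rule as the threshold varies,
#' computed on labeled control pairs: metastatic controls (known shared
#' clonality, e.g. lymph-node or distant metastases) and MPLC controls
#' (known independent clonality, e.g. different-histology MPLC).
#' "Metastatic" is treated as the positive class by reporting convention;
#' both rates are returned. Thresholds are restricted to multiples of 10
#' because all achievable totals are — intermediate values are redundant.
#'
#' @param metastaticControls,mplcControls Non-empty lists of
#'   [PairDValue-class] objects (or numeric vectors of totals).
#' @param thresholds Integer thresholds to sweep (default 0..400 by 10).
#' @param boundary Boundary convention, see [classifyPair()].
#' @return A `data.frame` with columns `threshold`,
#'   `sensitivity_metastatic` (fraction of metastatic controls called
#'   metastatic; non-decreasing in threshold) and `specificity_metastatic`
#'   (fraction of MPLC controls called MPLC; non-increasing).
#' @examples
#' thresholdSweep(controlPairDValues(), list(PairDValue("m1",
#'   c(p53 = 60, p16 = 40, p27 = 30, cerbB2 = 20))))
#' @export
thresholdSweep <- function(metastaticControls, mplcControls,
                           thresholds = seq(0L, 400L, by = 10L),
                           boundary = c("le_is_metastatic",
                                        "lt_is_metastatic")) {
  boundary <- match.arg(boundary)
  totals <- function(x) {
    if (is.numeric(x)) return(as.integer(x))
    vapply(x, function(p) totalD(p), integer(1L))
  }
  metTot <- totals(metastaticControls)
  mplcTot <- totals(mplcControls)
  if (!length(metTot)) stop("metastatic control list is empty")
  if (!length(mplcTot)) stop("MPLC control list is empty")
  isMet <- function(tot, thr)
    if (boundary == "le_is_metastatic") tot <= thr else tot < thr
  data.frame(
    threshold = as.integer(thresholds),
    sensitivity_metastatic = vapply(thresholds, function(thr)
      mean(isMet(metTot, thr)), numeric(1L)),
    specificity_metastatic = vapply(thresholds, function(thr)
      mean(!isMet(mplcTot, thr)), numeric(1L)))
}
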