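#' @import methods
NULL

#' The four-marker immunohistochemistry panel
#'
#' Canonical marker names used throughout the package, in the fixed order
#' p53, p16, p27, c-erbB2. All score vectors and fixture columns follow this
#' order. Staining is read in the nucleus for p53/p16/p27 and on the cell
#' membrane for c-erbB2; the localization is metadata only and no computation
#' depends on it.
#'
#' @return Character vector of the four marker names.
#' @examples
#' markerPanel()
#' @export
markerPanel <- function() c("p53", "p16", "p27", "cerbB2")

#' @rdname markerPanel
#' @return `markerLocalization()`: named character vector giving the expected
#'   staining compartment for each marker.
#' @export
markerLocalization <- function() {
  c(p53 = "nuclear", p16 = "nuclear", p27 = "nuclear", cerbB2 = "membrane")
}

.lesionRoles <- c("primary", "second_lesion", "lymph_node_met", "distant_met")

.isDecile <- function(x) {
  is.finite(x) & x >= 0 & x <= 100 & (x %% 10 == 0)
}

# ---------------------------------------------------------------------------
# MarkerScore
# ---------------------------------------------------------------------------

#' MarkerScore: a decile staining score for one marker
#'
#' A single immunohistochemistry reading: the marker, its decile-binned
#' percent-positivity score (0, 10, ..., 100), and the staining compartment
#' (nuclear for p53/p16/p27, membrane for c-erbB2). The localization is
#' carried as metadata and checked for consistency, but no computation uses
#' it.
#'
#' @slot marker Character, one of [markerPanel()].
#' @slot score Integer multiple of 10 in \[0, 100\].
#' @slot localization Character, `"nuclear"` or `"membrane"`.
#'
#' @aliases MarkerScore
#' @export
setClass("MarkerScore",
  representation(marker = "character", score = "integer",
                 localization = "character"))

setValidity("MarkerScore", function(object) {
  msg <- character()
  if (length(object@marker) != 1L || !object@marker %in% markerPanel())
    msg <- c(msg, sprintf("marker must be one of %s",
                          paste(markerPanel(), collapse = ", ")))
  if (length(object@score) != 1L || !.isDecile(object@score))
    msg <- c(msg, "score must be a multiple of 10 in [0, 100]")
  if (length(object@marker) == 1L && object@marker %in% markerPanel() &&
      !identical(object@localization,
                 unname(markerLocalization()[object@marker])))
    msg <- c(msg, sprintf("localization for %s must be '%s'", object@marker,
                          markerLocalization()[object@marker]))
  if (length(msg)) msg else TRUE
})

#' Construct a MarkerScore
#'
#' @param marker One of [markerPanel()].
#' @param score Decile score, a multiple of 10 in \[0, 100\].
#' @param localization Staining compartment; defaults to the compartment the
#'   panel prescribes for `marker`.
#' @return A [MarkerScore-class] object.
#' @examples
#' MarkerScore("p53", 40)
#' @export
MarkerScore <- function(marker, score,
                        localization = markerLocalization()[[marker]]) {
  marker <- as.character(marker)
  if (!marker %in% markerPanel())
    stop("unknown marker '", marker, "'; panel is ",
         paste(markerPanel(), collapse = ", "))
  new("MarkerScore", marker = marker, score = as.integer(score),
      localization = localization)
}

#' @describeIn MarkerScore-class the marker name.
#' @param object,x A `MarkerScore`.
#' @export
setGeneric("marker", function(x) standardGeneric("marker"))

#' @rdname MarkerScore-class
#' @export
setMethod("marker", "MarkerScore", function(x) x@marker)

#' @rdname MarkerScore-class
#' @export
setGeneric("score", function(x) standardGeneric("score"))

#' @rdname MarkerScore-class
#' @export
setMethod("score", "MarkerScore", function(x) x@score)

setMethod("show", "MarkerScore", function(object) {
  cat(sprintf("MarkerScore: %s = %d (%s)\n", object@marker, object@score,
              object@localization))
})

# ---------------------------------------------------------------------------
# SpecimenProfile
# ---------------------------------------------------------------------------

#' SpecimenProfile: the four-marker score vector of one lesion
#'
#' Holds the decile staining scores of all four panel markers for one lesion
#' of one patient, together with the lesion's role (primary tumor, second
#' separate lesion, lymph-node metastasis, or distant metastasis).
#'
#' @slot patientId Character scalar.
#' @slot lesionRole One of `"primary"`, `"second_lesion"`,
#'   `"lymph_node_met"`, `"distant_met"`.
#' @slot scores Named integer vector over exactly the four panel markers,
#'   each a multiple of 10 in \[0, 100\], stored in panel order.
#'
#' @aliases SpecimenProfile
#' @export
setClass("SpecimenProfile",
  representation(patientId = "character", lesionRole = "character",
                 scores = "integer"))

setValidity("SpecimenProfile", function(object) {
  msg <- character()
  if (length(object@patientId) != 1L || is.na(object@patientId) ||
      !nzchar(object@patientId))
    msg <- c(msg, "patientId must be a non-empty string")
  if (length(object@lesionRole) != 1L || !object@lesionRole %in% .lesionRoles)
    msg <- c(msg, sprintf("lesionRole must be one of %s",
                          paste(.lesionRoles, collapse = ", ")))
  if (!identical(names(object@scores), markerPanel()))
    msg <- c(msg, "scores must be named by exactly the four panel markers")
  else if (!all(.isDecile(object@scores)))
    msg <- c(msg, "all scores must be multiples of 10 in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' Construct a SpecimenProfile
#'
#' @param patientId Patient identifier.
#' @param lesionRole Lesion role, one of `"primary"`, `"second_lesion"`,
#'   `"lymph_node_met"`, `"distant_met"`.
#' @param scores Named vector or list of decile scores covering all four
#'   panel markers exactly once (any order; stored in panel order).
#' @return A [SpecimenProfile-class] object.
#' @examples
#' SpecimenProfile("P01", "primary", c(p53 = 40, p16 = 0, p27 = 20, cerbB2 = 10))
#' @export
SpecimenProfile <- function(patientId, lesionRole, scores) {
  scores <- unlist(scores)
  nm <- names(scores)
  if (is.null(nm)) stop("scores must be named by marker")
  dup <- nm[duplicated(nm)]
  if (length(dup))
    stop("duplicate marker in scores: ", paste(unique(dup), collapse = ", "))
  missing <- setdiff(markerPanel(), nm)
  if (length(missing))
    stop("missing marker in scores: ", paste(missing, collapse = ", "))
  extra <- setdiff(nm, markerPanel())
  if (length(extra))
    stop("unknown marker in scores: ", paste(extra, collapse = ", "))
  new("SpecimenProfile", patientId = as.character(patientId),
      lesionRole = as.character(lesionRole),
      scores = stats::setNames(as.integer(scores[markerPanel()]),
                               markerPanel()))
}

#' @describeIn SpecimenProfile-class the patient identifier.
#' @param x,object A `SpecimenProfile`.
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname SpecimenProfile-class
#' @export
setMethod("patientId", "SpecimenProfile", function(x) x@patientId)

#' @rdname SpecimenProfile-class
#' @export
setGeneric("lesionRole", function(x) standardGeneric("lesionRole"))

#' @rdname SpecimenProfile-class
#' @export
setMethod("lesionRole", "SpecimenProfile", function(x) x@lesionRole)

#' @rdname SpecimenProfile-class
#' @export
setGeneric("markerScores", function(x) standardGeneric("markerScores"))

#' @rdname SpecimenProfile-class
#' @export
setMethod("markerScores", "SpecimenProfile", function(x) x@scores)

setMethod("show", "SpecimenProfile", function(object) {
  cat(sprintf("SpecimenProfile %s [%s]\n", object@patientId,
              object@lesionRole))
  print(object@scores)
})

# ---------------------------------------------------------------------------
# PairDValue
# ---------------------------------------------------------------------------

#' PairDValue: per-marker and total D-values of a lesion pair
#'
#' The absolute decile-score differences (D-values) between two lesions of
#' one patient, per marker and summed. The `total` slot is always the sum of
#' the per-marker values; fixture-loaded control cases may in addition carry
#' the total printed in the source table (`printedTotal`), which is kept
#' verbatim and never used downstream (see [validateTotals()]).
#'
#' @slot patientId Character scalar.
#' @slot perMarker Named integer vector over the four panel markers; each a
#'   multiple of 10 in \[0, 100\].
#' @slot total Integer, sum of `perMarker`, in \[0, 400\].
#' @slot printedTotal Integer or `NA`; a separately recorded total for
#'   fixture data.
#'
#' @aliases PairDValue
#' @export
setClass("PairDValue",
  representation(patientId = "character", perMarker = "integer",
                 total = "integer", printedTotal = "integer"))

setValidity("PairDValue", function(object) {
  msg <- character()
  if (!identical(names(object@perMarker), markerPanel()))
    msg <- c(msg, "perMarker must be named by exactly the four panel markers")
  else if (!all(.isDecile(object@perMarker)))
    msg <- c(msg, "per-marker D-values must be multiples of 10 in [0, 100]")
  else if (!identical(object@total, sum(object@perMarker)))
    msg <- c(msg, "total must equal the sum of the per-marker D-values")
  if (length(object@printedTotal) != 1L)
    msg <- c(msg, "printedTotal must be a single integer or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a PairDValue
#'
#' The total is always recomputed from the per-marker values; a printed
#' total, when supplied (fixture data), is stored alongside verbatim.
#'
#' @param patientId Patient (or control case) identifier.
#' @param perMarker Named vector of per-marker D-values covering the four
#'   panel markers.
#' @param printedTotal Optional separately recorded total (kept verbatim,
#'   never used in computations).
#' @return A [PairDValue-class] object.
#' @examples
#' PairDValue("case1", c(p53 = 0, p16 = 10, p27 = 0, cerbB2 = 10))
#' @export
PairDValue <- function(patientId, perMarker, printedTotal = NA_integer_) {
  perMarker <- unlist(perMarker)
  missing <- setdiff(markerPanel(), names(perMarker))
  if (length(missing))
    stop("missing marker D-value: ", paste(missing, collapse = ", "))
  pm <- stats::setNames(as.integer(perMarker[markerPanel()]), markerPanel())
  new("PairDValue", patientId = as.character(patientId), perMarker = pm,
      total = sum(pm), printedTotal = as.integer(printedTotal))
}

#' @rdname PairDValue-class
#' @param x,object A `PairDValue`.
#' @export
setMethod("patientId", "PairDValue", function(x) x@patientId)

#' @describeIn PairDValue-class named per-marker D-values.
#' @export
setGeneric("perMarkerD", function(x) standardGeneric("perMarkerD"))

#' @rdname PairDValue-class
#' @export
setMethod("perMarkerD", "PairDValue", function(x) x@perMarker)

#' @describeIn PairDValue-class the recomputed total D-value.
#' @export
setGeneric("totalD", function(x) standardGeneric("totalD"))

#' @rdname PairDValue-class
#' @export
setMethod("totalD", "PairDValue", function(x) x@total)

#' @describeIn PairDValue-class the verbatim printed total (`NA` for
#'   model-computed pairs).
#' @export
setGeneric("printedTotal", function(x) standardGeneric("printedTotal"))

#' @rdname PairDValue-class
#' @export
setMethod("printedTotal", "PairDValue", function(x) x@printedTotal)

setMethod("show", "PairDValue", function(object) {
  cat(sprintf("PairDValue %s: total = %d\n", object@patientId, object@total))
  print(object@perMarker)
  if (!is.na(object@printedTotal))
    cat(sprintf("  (printed total: %d)\n", object@printedTotal))
})

# ---------------------------------------------------------------------------
# Classification
# ---------------------------------------------------------------------------

#' Classification: the model's call for one lesion pair
#'
#' The diagnostic call (`"MPLC"` or `"metastatic"`) produced by applying the
#' cut-off rule to a pair's total D-value, recording the total and the
#' threshold used.
#'
#' @slot call `"MPLC"` or `"metastatic"`.
#' @slot total Integer total D-value the call was made on.
#' @slot threshold Integer threshold used (default rule: total > threshold
#'   is MPLC).
#'
#' @aliases Classification
#' @export
setClass("Classification",
  representation(call = "character", total = "integer",
                 threshold = "integer"))

setValidity("Classification", function(object) {
  msg <- character()
  if (length(object@call) != 1L || !object@call %in% c("MPLC", "metastatic"))
    msg <- c(msg, "call must be 'MPLC' or 'metastatic'")
  if (length(object@threshold) != 1L || is.na(object@threshold) ||
      object@threshold < 0L)
    msg <- c(msg, "threshold must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' @describeIn Classification-class the diagnostic call.
#' @param x,object A `Classification`.
#' @export
setGeneric("modelCall", function(x) standardGeneric("modelCall"))

#' @rdname Classification-class
#' @export
setMethod("modelCall", "Classification", function(x) x@call)

#' @rdname Classification-class
#' @export
setMethod("totalD", "Classification", function(x) x@total)

#' @describeIn Classification-class the threshold the call used.
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

#' @rdname Classification-class
#' @export
setMethod("threshold", "Classification", function(x) x@threshold)

setMethod("show", "Classification", function(object) {
  cat(sprintf("Classification: %s (total %d, threshold %d)\n", object@call,
              object@total, object@threshold))
})

# ---------------------------------------------------------------------------
# ReclassificationTable
# ---------------------------------------------------------------------------

#' ReclassificationTable: model call versus clinical diagnosis
#'
#' A 2x2 contingency table of the model's call (rows: MPLC, IPM) against the
#' clinical Martini-Melamed diagnosis (columns: MPLC, IPM). Margins and the
#' grand total are always derived, never stored.
#'
#' @slot counts 2x2 non-negative integer matrix with dimnames
#'   `list(model = c("MPLC","IPM"), clinical = c("MPLC","IPM"))`.
#'
#' @aliases ReclassificationTable
#' @export
setClass("ReclassificationTable", representation(counts = "matrix"))

setValidity("ReclassificationTable", function(object) {
  cts <- object@counts
  msg <- character()
  if (!is.numeric(cts) || !identical(dim(cts), c(2L, 2L)))
    msg <- c(msg, "counts must be a 2x2 numeric matrix")
  else {
    if (!identical(dimnames(cts),
                   list(model = c("MPLC", "IPM"),
                        clinical = c("MPLC", "IPM"))))
      msg <- c(msg, "counts must have model x clinical MPLC/IPM dimnames")
    if (any(cts < 0) || any(cts != round(cts)))
      msg <- c(msg, "counts must be non-negative integers")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ReclassificationTable
#'
#' @param mplc_mplc,mplc_ipm,ipm_mplc,ipm_ipm Cell counts, named
#'   model-call_clinical-diagnosis.
#' @return A [ReclassificationTable-class] object.
#' @examples
#' ReclassificationTable(29, 6, 7, 14)
#' @export
ReclassificationTable <- function(mplc_mplc, mplc_ipm, ipm_mplc, ipm_ipm) {
  cts <- matrix(as.integer(c(mplc_mplc, ipm_mplc, mplc_ipm, ipm_ipm)),
                nrow = 2L,
                dimnames = list(model = c("MPLC", "IPM"),
                                clinical = c("MPLC", "IPM")))
  new("ReclassificationTable", counts = cts)
}

#' @describeIn ReclassificationTable-class the 2x2 count matrix.
#' @param x,object A `ReclassificationTable`.
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname ReclassificationTable-class
#' @export
setMethod("counts", "ReclassificationTable", function(x) x@counts)

#' @describeIn ReclassificationTable-class the grand total.
#' @export
setGeneric("grandTotal", function(x) standardGeneric("grandTotal"))

#' @rdname ReclassificationTable-class
#' @export
setMethod("grandTotal", "ReclassificationTable",
          function(x) sum(x@counts))

setMethod("show", "ReclassificationTable", function(object) {
  cat("ReclassificationTable (model call x clinical diagnosis)\n")
  m <- addmargins(object@counts)
  dimnames(m) <- list(model = c("MPLC", "IPM", "Total"),
                      clinical = c("MPLC", "IPM", "Total"))
  print(m)
})

# ---------------------------------------------------------------------------
# AgreementReport
# ---------------------------------------------------------------------------

#' AgreementReport: agreement statistics for a reclassification table
#'
#' Percent agreement, Cohen's kappa and per-clinical-group concordant
#' fractions computed from a [ReclassificationTable-class]. These statistics
#' quantify the table; percent agreement and kappa are derived outputs of
#' this package, not figures from the source study.
#'
#' @slot table The underlying [ReclassificationTable-class].
#' @slot percentAgreement Real in \[0, 100\]: 100 x diagonal / grand total.
#' @slot kappa Cohen's chance-corrected kappa in \[-1, 1\] (`NaN` for a
#'   degenerate table whose expected agreement is 1).
#' @slot perGroup Named numeric vector: for each clinical group, the
#'   fraction of its cases the model calls concordantly.
#'
#' @aliases AgreementReport
#' @export
setClass("AgreementReport",
  representation(table = "ReclassificationTable",
                 percentAgreement = "numeric", kappa = "numeric",
                 perGroup = "numeric"))

setValidity("AgreementReport", function(object) {
  msg <- character()
  pa <- object@percentAgreement
  if (length(pa) != 1L || is.na(pa) || pa < 0 || pa > 100)
    msg <- c(msg, "percentAgreement must be in [0, 100]")
  if (length(object@kappa) != 1L ||
      (!is.nan(object@kappa) &&
       (object@kappa < -1 - 1e-12 || object@kappa > 1 + 1e-12)))
    msg <- c(msg, "kappa must be in [-1, 1] (or NaN when undefined)")
  pg <- object@perGroup
  if (any(!is.nan(pg) & (pg < 0 | pg > 1)))
    msg <- c(msg, "per-group fractions must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn AgreementReport-class overall percent agreement.
#' @param x,object An `AgreementReport`.
#' @export
setGeneric("percentAgreement", function(x) standardGeneric("percentAgreement"))

#' @rdname AgreementReport-class
#' @export
setMethod("percentAgreement", "AgreementReport",
          function(x) x@percentAgreement)

#' @describeIn AgreementReport-class Cohen's kappa.
#' @export
setGeneric("cohenKappa", function(x) standardGeneric("cohenKappa"))

#' @rdname AgreementReport-class
#' @export
setMethod("cohenKappa", "AgreementReport", function(x) x@kappa)

#' @describeIn AgreementReport-class per-clinical-group concordant fractions.
#' @export
setGeneric("perGroupFractions", function(x) standardGeneric("perGroupFractions"))

#' @rdname AgreementReport-class
#' @export
setMethod("perGroupFractions", "AgreementReport", function(x) x@perGroup)

setMethod("show", "AgreementReport", function(object) {
  show(object@table)
  cat(sprintf("Percent agreement: %.1f%%\n", object@percentAgreement))
  cat(sprintf("Cohen's kappa:     %.3f\n", object@kappa))
  cat(sprintf("Concordant fraction, clinical MPLC: %.3f; clinical IPM: %.3f\n",
              object@perGroup[["MPLC"]], object@perGroup[["IPM"]]))
})

# ---------------------------------------------------------------------------
# MarkerDistribution
# ---------------------------------------------------------------------------

#' MarkerDistribution: zero-inflated Beta law for percent positivity
#'
#' The synthetic generator's law for one marker's percent of immunopositive
#' cells: with probability `zeroInflation` a specimen is fully negative
#' (0%), otherwise the percent is 100 x Beta(alpha, beta).
#'
#' @slot marker One of [markerPanel()].
#' @slot zeroInflation Probability in \[0, 1\] of a fully negative specimen.
#' @slot alpha,beta Positive Beta shape parameters of the positive part.
#'
#' @aliases MarkerDistribution
#' @export
setClass("MarkerDistribution",
  representation(marker = "character", zeroInflation = "numeric",
                 alpha = "numeric", beta = "numeric"))

setValidity("MarkerDistribution", function(object) {
  msg <- character()
  if (length(object@marker) != 1L || !object@marker %in% markerPanel())
    msg <- c(msg, "marker must be one of the panel markers")
  if (length(object@zeroInflation) != 1L || is.na(object@zeroInflation) ||
      object@zeroInflation < 0 || object@zeroInflation > 1)
    msg <- c(msg, "zeroInflation must be a probability in [0, 1]")
  if (length(object@alpha) != 1L || !is.finite(object@alpha) ||
      object@alpha <= 0)
    msg <- c(msg, "alpha must be > 0")
  if (length(object@beta) != 1L || !is.finite(object@beta) ||
      object@beta <= 0)
    msg <- c(msg, "beta must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a MarkerDistribution
#'
#' @param marker One of [markerPanel()].
#' @param zeroInflation Probability of a fully negative specimen.
#' @param alpha,beta Beta shape parameters of the positive part.
#' @return A [MarkerDistribution-class] object.
#' @examples
#' markerDistribution("p53", zeroInflation = 0.5)
#' @export
markerDistribution <- function(marker, zeroInflation, alpha = 0.8,
                               beta = 0.8) {
  new("MarkerDistribution", marker = as.character(marker),
      zeroInflation = as.numeric(zeroInflation), alpha = as.numeric(alpha),
      beta = as.numeric(beta))
}

#' @rdname MarkerDistribution-class
#' @param x,object A `MarkerDistribution`.
#' @export
setMethod("marker", "MarkerDistribution", function(x) x@marker)

setMethod("show", "MarkerDistribution", function(object) {
  cat(sprintf(
    "MarkerDistribution %s: P(negative) = %.2f, positive ~ 100*Beta(%.2f, %.2f)\n",
    object@marker, object@zeroInflation, object@alpha, object@beta))
})
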