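# Decile staining scores from raw percent-positivity readings.
#
# The scoring scale is anchored on integer percent ranges (no staining -> 0,
# 1-10% -> 10, ..., 91-100% -> 100). Five-field means are fractional, so the
# bins are treated as half-open intervals {0}, (0,10], (10,20], ...,
# i.e. score = 10 * ceiling(pct / 10) with 0 mapping to 0. This is the only
# reading consistent with both the 0 anchor and the 1-10% bin.

#' Average five microscope-field percent readings
#'
#' The percent of immunopositive tumor cells is recorded in five randomly
#' selected high-power fields per specimen; the specimen-level percent is
#' their arithmetic mean.
#'
#' @param values Numeric vector of exactly 5 percent values, each in
#'   \[0, 100\].
#' @return The mean percent, a single number in \[0, 100\].
#' @examples
#' averageFields(c(10, 20, 30, 40, 50))  # 30
#' @seealso [binPercentage()], [scoreSpecimen()]
#' @export
averageFields <- function(values) {
  values <- as.numeric(values)
  if (length(values) != 5L)
    stop("exactly 5 field percentages are required, got ", length(values))
  bad <- which(!is.finite(values) | values < 0 | values > 100)
  if (length(bad))
    stop("field ", bad[1L], " is outside [0, 100]: ", values[bad[1L]])
  mean(values)
}

#' Bin a percent positivity into a decile staining score
#'
#' Maps a percent of positive cells onto the 11-point decile scale
#' \{0, 10, ..., 100\}: 0 stays 0 (no staining), and any positive percent
#' falls into the half-open interval (10(k-1), 10k\] whose score is 10k.
#' Vectorized; idempotent on its own outputs.
#'
#' @param pct Numeric vector of percents in \[0, 100\].
#' @return Integer vector of decile scores.
#' @examples
#' binPercentage(c(0, 35.2, 10, 10.4, 100))  # 0 40 10 20 100
#' @export
binPercentage <- function(pct) {
  nm <- names(pct)
  pct <- as.numeric(pct)
  bad <- which(!is.finite(pct) | pct < 0 | pct > 100)
  if (length(bad))
    stop("percent value outside [0, 100] at position ", bad[1L], ": ",
         pct[bad[1L]])
  out <- as.integer(ifelse(pct == 0, 0, 10 * ceiling(pct / 10)))
  names(out) <- nm
  out
}

#' Score one specimen across the four-marker panel
#'
#' Averages the five field readings for each marker and bins the mean onto
#' the decile scale, producing the specimen's four-marker score profile.
#'
#' @param fieldData Named list with one entry per panel marker (exactly the
#'   four of [markerPanel()], no duplicates), each a vector of 5 field
#'   percents.
#' @param patientId Patient identifier.
#' @param lesionRole Lesion role, see [SpecimenProfile()].
#' @return A [SpecimenProfile-class].
#' @examples
#' scoreSpecimen(
#'   list(p53 = rep(0, 5), p16 = c(31, 35, 40, 33, 37),
#'        p27 = rep(0, 5), cerbB2 = rep(0, 5)),
#'   patientId = "P01", lesionRole = "primary")
#' @export
scoreSpecimen <- function(fieldData, patientId, lesionRole) {
  nm <- names(fieldData)
  if (is.null(nm)) stop("fieldData must be a named list, one entry per marker")
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    stop("duplicate marker in fieldData: ", paste(dup, collapse = ", "))
  missing <- setdiff(markerPanel(), nm)
  if (length(missing))
    stop("missing marker in fieldData: ", paste(missing, collapse = ", "))
  extra <- setdiff(nm, markerPanel())
  if (length(extra))
    stop("unknown marker in fieldData: ", paste(extra, collapse = ", "))
  scores <- vapply(markerPanel(),
                   function(m) binPercentage(averageFields(fieldData[[m]])),
                   integer(1L))
  SpecimenProfile(patientId, lesionRole, scores)
}
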