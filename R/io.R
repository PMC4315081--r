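# Specimen table I/O.
#
# One row per (patient, lesion, marker). Three interchangeable score
# representations, exactly one per row (mixing across rows is allowed):
#   field1..field5  raw per-field percents, averaged then binned
#   percent         a single specimen-level percent, binned
#   score           a pre-binned decile score, taken as-is
# Strict mode additionally rejects pre-binned scores that are not decile
# multiples; otherwise they fail SpecimenProfile validation anyway.

.reprCols <- list(fields = paste0("field", 1:5), percent = "percent",
                  score = "score")

#' Read a specimen marker table (CSV/TSV)
#'
#' Reads a delimited table with one row per (patient, lesion, marker) and
#' columns `patient_id`, `lesion_role`, `marker`, plus exactly one score
#' representation per row: `field1..field5` (five field percents), `percent`
#' (single percent), or `score` (pre-binned decile). Each row is reduced to
#' a decile score via [averageFields()] and [binPercentage()].
#'
#' @param file Path to a CSV or TSV file, or a `data.frame` already in that
#'   layout.
#' @param sep Field separator; by default `"\t"` for `.tsv`/`.tab` files and
#'   `","` otherwise. Ignored for data-frame input.
#' @param strict If `TRUE`, reject pre-binned `score` values that are not
#'   multiples of 10 instead of erroring later at profile construction.
#' @return A `data.frame` with columns `patient_id`, `lesion_role`,
#'   `marker`, `score` (integer deciles), one row per input row.
#' @seealso [specimenProfiles()] to assemble [SpecimenProfile-class]
#'   objects, [pairDValues()] for the downstream pairing.
#' @export
readSpecimenTable <- function(file, sep = NULL, strict = FALSE) {
  if (is.data.frame(file)) {
    tab <- file
  } else {
    if (is.null(sep))
      sep <- if (grepl("\\.(tsv|tab)$", file, ignore.case = TRUE)) "\t" else ","
    tab <- utils::read.table(file, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
  }
  need <- c("patient_id", "lesion_role", "marker")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))

  score <- integer(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    present <- vapply(.reprCols, function(cols) {
      all(cols %in% names(tab)) && all(!is.na(tab[i, cols]))
    }, logical(1L))
    if (sum(present) != 1L)
      stop("row ", i, ": exactly one score representation required ",
           "(field1..field5, percent, or score); found ",
           paste(names(.reprCols)[present], collapse = " and "))
    repr <- names(.reprCols)[present]
    score[i] <- switch(repr,
      fields  = binPercentage(averageFields(
                  as.numeric(tab[i, .reprCols$fields]))),
      percent = binPercentage(as.numeric(tab[i, "percent"])),
      score   = {
        s <- as.numeric(tab[i, "score"])
        if (strict && (!is.finite(s) || s < 0 || s > 100 || s %% 10 != 0))
          stop("row ", i, ": pre-binned score ", s,
               " is not a decile multiple in [0, 100]")
        as.integer(s)
      })
  }
  data.frame(patient_id = as.character(tab$patient_id),
             lesion_role = as.character(tab$lesion_role),
             marker = as.character(tab$marker), score = score,
             stringsAsFactors = FALSE)
}

#' Assemble specimen profiles from a scored table
#'
#' Groups the long-format score table by (patient, lesion) and builds one
#' [SpecimenProfile-class] per lesion; every lesion must cover the four-
#' marker panel exactly once.
#'
#' @param scored A `data.frame` as returned by [readSpecimenTable()].
#' @return A list of [SpecimenProfile-class] objects.
#' @export
specimenProfiles <- function(scored) {
  key <- paste(scored$patient_id, scored$lesion_role, sep = "\r")
  lapply(split(scored, factor(key, levels = unique(key))), function(grp) {
    dup <- unique(grp$marker[duplicated(grp$marker)])
    if (length(dup))
      stop("patient ", grp$patient_id[1L], ", lesion ", grp$lesion_role[1L],
           ": duplicate marker ", paste(dup, collapse = ", "))
    SpecimenProfile(grp$patient_id[1L], grp$lesion_role[1L],
                    stats::setNames(grp$score, grp$marker))
  }) |> unname()
}

#' Pair primary lesions with the other lesions of each patient
#'
#' The diagnostic model is defined pairwise. For every patient, the primary
#' lesion is paired with each non-primary lesion and a [PairDValue-class] is
#' computed per pair; no patient-level call is synthesized for patients with
#' three or more lesions.
#'
#' @param profiles A list of [SpecimenProfile-class] objects (e.g. from
#'   [specimenProfiles()]).
#' @return A list of [PairDValue-class] objects, one per
#'   (primary, other-lesion) pair.
#' @export
pairDValues <- function(profiles) {
  ids <- vapply(profiles, patientId, character(1L))
  out <- list()
  for (pid in unique(ids)) {
    lesions <- profiles[ids == pid]
    roles <- vapply(lesions, lesionRole, character(1L))
    prim <- lesions[roles == "primary"]
    if (length(prim) != 1L)
      stop("patient ", pid, ": expected exactly one primary lesion, found ",
           length(prim))
    for (other in lesions[roles != "primary"])
      out[[length(out) + 1L]] <- totalDValue(prim[[1L]], other)
  }
  out
}

#' Write a specimen table to CSV
#'
#' @param tab A `data.frame` in the specimen-table layout.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writeSpecimenTable <- function(tab, file) {
  utils::write.csv(tab, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
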