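# Published control data, compiled in verbatim.
#
# The 30 lymph-node-metastasis control cases (per-marker D-values between
# primary tumor and nodal metastasis, plus the total as printed) and the 2x2
# reclassification counts of model call vs clinical Martini-Melamed
# diagnosis. Printed totals are kept verbatim; every downstream statistic
# uses totals recomputed from the per-marker values (see validateTotals).

.lymphNodeControlTable <- data.frame(
  case   = 1:30,
  p16    = c(10, 10,  0, 20, 40, 10, 30,  0, 40, 10,
             10,  0, 20, 30, 40, 20, 10, 20, 20,  0,
             20,  0, 10, 10,  0, 20, 30, 10, 20,  0),
  cerbB2 = c(10, 10, 20, 10, 10,  0,  0,  0,  0,  0,
              0, 10, 10, 10,  0,  0,  0,  0, 10,  0,
             20,  0, 20,  0, 30,  0,  0, 10,  0,  0),
  p27    = c( 0, 20, 10, 10, 20,  0,  0, 40, 10,  0,
             10, 10,  0, 20, 30,  0,  0,  0, 20, 10,
              0, 30,  0, 10, 20,  0, 20, 30,  0,  0),
  p53    = c( 0, 20, 10,  0, 20, 30, 10, 40,  0,  0,
             40,  0, 20,  0, 10, 40,  0,  0, 20,  0,
              0, 10,  0,  0, 30, 20, 10, 30,  0, 20),
  printed_total = c(20, 60, 40, 40, 90, 40, 40, 80, 50, 10,
                    60, 20, 30, 60, 80, 60, 10, 20, 70, 10,
                    40, 40, 30, 20, 80, 40, 60, 80, 20, 20))

#' Lymph-node-metastasis control D-values
#'
#' The 30 control cases with known shared clonality (primary lung tumor vs
#' its lymph-node metastasis): per-marker D-values for p16, c-erbB2, p27 and
#' p53 and the total as printed in the source table. One case's printed
#' total disagrees with its own per-marker values; [validateTotals()]
#' surfaces this, and all downstream statistics use recomputed sums.
#'
#' @return A 30-row `data.frame` with columns `case`, `p16`, `cerbB2`,
#'   `p27`, `p53`, `printed_total`.
#' @examples
#' head(lymphNodeControls())
#' @export
lymphNodeControls <- function() .lymphNodeControlTable

#' Control cases as PairDValue objects
#'
#' Wraps each row of [lymphNodeControls()] in a [PairDValue-class] whose
#' total is recomputed from the per-marker values and whose `printedTotal`
#' slot carries the table's total verbatim.
#'
#' @return A list of 30 [PairDValue-class] objects, named `case1..case30`.
#' @export
controlPairDValues <- function() {
  tab <- lymphNodeControls()
  out <- lapply(seq_len(nrow(tab)), function(i)
    PairDValue(paste0("case", tab$case[i]),
               c(p53 = tab$p53[i], p16 = tab$p16[i], p27 = tab$p27[i],
                 cerbB2 = tab$cerbB2[i]),
               printedTotal = tab$printed_total[i]))
  stats::setNames(out, paste0("case", tab$case))
}

#' Check printed totals against recomputed per-marker sums
#'
#' Data-QC over fixture (or any) pairs that carry a printed total: flags
#' every case where the printed total differs from the sum of the per-marker
#' D-values. On the packaged control fixture exactly one discrepancy exists;
#' recomputed sums, never printed totals, feed all downstream statistics.
#'
#' @param cases A list of [PairDValue-class] objects (default: the packaged
#'   control fixture).
#' @return A `data.frame` with columns `case`, `recomputed`, `printed`, one
#'   row per discrepancy (zero rows when all totals agree; pairs with no
#'   printed total are skipped).
#' @examples
#' validateTotals()  # one row: the control table's internal inconsistency
#' @export
validateTotals <- function(cases = controlPairDValues()) {
  rows <- lapply(cases, function(p) {
    if (is.na(printedTotal(p)) || totalD(p) == printedTotal(p)) return(NULL)
    data.frame(case = patientId(p), recomputed = totalD(p),
               printed = printedTotal(p), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows))
    return(data.frame(case = character(), recomputed = integer(),
                      printed = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published reclassification counts
#'
#' The 2x2 table of model call against clinical Martini-Melamed diagnosis
#' for the 56 reclassified patients: 29 of 36 clinical MPLC kept the MPLC
#' call, 14 of 20 clinical IPM kept the IPM call.
#'
#' @return A [ReclassificationTable-class].
#' @examples
#' reclassificationCounts()
#' @export
reclassificationCounts <- function() {
  ReclassificationTable(mplc_mplc = 29, mplc_ipm = 6, ipm_mplc = 7,
                        ipm_ipm = 14)
}

#' Study-group sizes
#'
#' Patient counts of the study cohorts: the metastasis control groups
#' (known shared clonality), the different-histology MPLC positive controls
#' (known independent clonality), and the two reclassified cohorts.
#'
#' @return A named integer vector.
#' @examples
#' cohortSizes()
#' @export
cohortSizes <- function() {
  c(intrapulmonary_met = 20L, distant_met = 11L, lymph_node_met = 30L,
    mplc_same_histology = 36L, mplc_different_histology = 14L)
}

#' Export the control fixture in the specimen-table dialect
#'
#' The control table publishes only D-values, not the underlying per-lesion
#' scores, so this export embeds each case as a synthetic lesion pair that
#' reproduces the printed D-values exactly: the primary lesion carries the
#' D-value as its score and the nodal lesion scores 0, making
#' |score_T1 - score_T2| equal the published D-value marker by marker. The
#' pairs are synthetic carriers of the D-values, not reconstructions of the
#' unpublished raw staining percentages.
#'
#' @return A `data.frame` in the layout [readSpecimenTable()] accepts
#'   (pre-binned `score` representation), 8 rows per case.
#' @examples
#' spec <- controlsAsSpecimens()
#' pairs <- pairDValues(specimenProfiles(readSpecimenTable(spec)))
#' totalD(pairs[[1]])  # recovers case 1's total
#' @export
controlsAsSpecimens <- function() {
  tab <- lymphNodeControls()
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    id <- paste0("case", tab$case[i])
    d <- c(p53 = tab$p53[i], p16 = tab$p16[i], p27 = tab$p27[i],
           cerbB2 = tab$cerbB2[i])
    rbind(
      data.frame(patient_id = id, lesion_role = "primary",
                 marker = names(d), score = unname(d),
                 stringsAsFactors = FALSE),
      data.frame(patient_id = id, lesion_role = "lymph_node_met",
                 marker = names(d), score = 0L, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
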