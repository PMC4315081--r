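# Synthetic tumor-pair generator.
#
# Emulates the two mechanisms behind multifocal disease: a clonally related
# pair shares one percent-positivity profile up to drift noise (Gaussian on
# the percent scale, clipped to [0,100]); an independent pair draws the two
# profiles separately from per-marker zero-inflated Beta laws. Defaults
# translate reported marker prevalences in NSCLC into zero-inflation
# weights (p53 altered in ~50%, p16 ~50%, p27 retained in ~25%, c-erbB2
# overexpressed in ~37%) with a dispersed Beta(0.8, 0.8) positive part.
# These are synthetic test-harness defaults, not a fit to any cohort.

#' Default per-marker positivity distributions
#'
#' @param alpha,beta Beta shape parameters shared by all four positive
#'   parts.
#' @return Named list of [MarkerDistribution-class] objects, one per panel
#'   marker, with zero-inflation weights p53 0.50, p16 0.50, p27 0.75,
#'   c-erbB2 0.63.
#' @examples
#' defaultMarkerDistributions()
#' @export
defaultMarkerDistributions <- function(alpha = 0.8, beta = 0.8) {
  zi <- c(p53 = 0.50, p16 = 0.50, p27 = 0.75, cerbB2 = 0.63)
  lapply(stats::setNames(nm = markerPanel()), function(m)
    markerDistribution(m, zeroInflation = zi[[m]], alpha = alpha,
                       beta = beta))
}

#' Sample percent positivity from a marker law
#'
#' With probability `zeroInflation` the specimen is fully negative (0%),
#' otherwise the percent is 100 x Beta(alpha, beta). Uses the current R
#' random-number stream.
#'
#' @param dist A [MarkerDistribution-class].
#' @param n Number of draws.
#' @return Numeric vector of percents in \[0, 100\].
#' @examples
#' set.seed(1)
#' sampleSpecimenPercent(markerDistribution("p53", 0.5), n = 5)
#' @export
sampleSpecimenPercent <- function(dist, n = 1L) {
  stopifnot(is(dist, "MarkerDistribution"))
  validObject(dist)
  zero <- stats::runif(n) < dist@zeroInflation
  pct <- 100 * stats::rbeta(n, dist@alpha, dist@beta)
  ifelse(zero, 0, pct)
}

.drawProfilePercents <- function(markerDists) {
  vapply(markerPanel(), function(m)
    sampleSpecimenPercent(markerDists[[m]], 1L), numeric(1L))
}

#' Generate one synthetic lesion pair
#'
#' Draws the primary lesion's percent profile from the marker laws; the
#' second lesion is either the same profile plus clipped Gaussian drift
#' (`relation = "clonal"`, true label `"metastatic-like"`) or an
#' independent draw from the same laws (`relation = "independent"`, true
#' label `"MPLC-like"`). Both profiles are then decile-binned.
#'
#' @param relation `"clonal"` or `"independent"`.
#' @param driftSd Non-negative drift standard deviation on the percent
#'   scale (clonal pairs only; default 5).
#' @param markerDists Named list of [MarkerDistribution-class] objects
#'   covering the panel.
#' @param patientId Identifier for the generated pair.
#' @return A list with elements `t1`, `t2` ([SpecimenProfile-class]),
#'   `label` (the true relation label) and `percents` (the pre-binning
#'   percent matrix).
#' @examples
#' set.seed(7)
#' generatePair("clonal", driftSd = 0)$label
#' @export
generatePair <- function(relation = c("clonal", "independent"), driftSd = 5,
                         markerDists = defaultMarkerDistributions(),
                         patientId = "synthetic") {
  relation <- match.arg(relation)
  if (length(driftSd) != 1L || !is.finite(driftSd) || driftSd < 0)
    stop("driftSd must be a single non-negative number")
  missing <- setdiff(markerPanel(), names(markerDists))
  if (length(missing))
    stop("markerDists missing marker(s): ", paste(missing, collapse = ", "))
  p1 <- .drawProfilePercents(markerDists)
  p2 <- if (relation == "clonal") {
    pmin(pmax(p1 + stats::rnorm(length(p1), 0, driftSd), 0), 100)
  } else {
    .drawProfilePercents(markerDists)
  }
  list(
    t1 = SpecimenProfile(patientId, "primary", binPercentage(p1)),
    t2 = SpecimenProfile(patientId, "second_lesion", binPercentage(p2)),
    label = if (relation == "clonal") "metastatic-like" else "MPLC-like",
    percents = rbind(t1 = p1, t2 = p2))
}

#' Generate a labeled synthetic cohort
#'
#' Produces a reproducible labeled dataset of `nClonal` clonally related
#' and `nIndependent` independent pairs in the pipeline's specimen-table
#' layout (percent representation) plus a label sidecar. A single seed
#' drives one root generator, so the same seed reproduces the cohort
#' exactly; the ambient RNG state is restored on exit.
#'
#' @param nClonal,nIndependent Group sizes; their sum must be positive.
#' @param driftSd Clonal drift standard deviation (percent scale).
#' @param markerDists Named list of [MarkerDistribution-class] objects.
#' @param seed Integer seed for the root generator (`NULL`: use the ambient
#'   stream).
#' @return A list with `specimens` (`data.frame`: `patient_id`,
#'   `lesion_role`, `marker`, `percent`; 8 rows per pair) and `labels`
#'   (`data.frame`: `patient_id`, `label`).
#' @examples
#' cohort <- generateCohort(3, 2, seed = 1)
#' cohort$labels
#' @export
generateCohort <- function(nClonal, nIndependent, driftSd = 5,
                           markerDists = defaultMarkerDistributions(),
                           seed = NULL) {
  nClonal <- as.integer(nClonal); nIndependent <- as.integer(nIndependent)
  if (nClonal < 0L || nIndependent < 0L || nClonal + nIndependent <= 0L)
    stop("need non-negative group sizes with nClonal + nIndependent > 0")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  relations <- rep(c("clonal", "independent"), c(nClonal, nIndependent))
  ids <- sprintf("pair%03d", seq_along(relations))
  specimens <- vector("list", length(relations))
  labels <- character(length(relations))
  for (i in seq_along(relations)) {
    pair <- generatePair(relations[i], driftSd = driftSd,
                         markerDists = markerDists, patientId = ids[i])
    labels[i] <- pair$label
    specimens[[i]] <- data.frame(
      patient_id = ids[i],
      lesion_role = rep(c("primary", "second_lesion"), each = 4L),
      marker = rep(markerPanel(), 2L),
      percent = c(pair$percents["t1", ], pair$percents["t2", ]),
      stringsAsFactors = FALSE)
  }
  specimens <- do.call(rbind, specimens)
  rownames(specimens) <- NULL
  list(specimens = specimens,
       labels = data.frame(patient_id = ids, label = labels,
                           stringsAsFactors = FALSE))
}

#' Write a synthetic cohort to disk
#'
#' Writes the specimen table as CSV and the label sidecar as TSV. Percents
#' are serialized with full precision so the same seed yields a
#' byte-identical file.
#'
#' @param cohort A list as returned by [generateCohort()].
#' @param specimenFile Path for the specimen CSV.
#' @param labelFile Optional path for the labels TSV (`NULL` to skip).
#' @return `specimenFile`, invisibly.
#' @export
writeCohort <- function(cohort, specimenFile, labelFile = NULL) {
  spec <- cohort$specimens
  spec$percent <- sprintf("%.12g", spec$percent)
  utils::write.csv(spec, specimenFile, row.names = FALSE, quote = FALSE)
  if (!is.null(labelFile))
    utils::write.table(cohort$labels, labelFile, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(specimenFile)
}
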