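#' Medication adjustment of measured blood pressure
#'
#' For samples on anti-hypertensive medication, 15 mmHg is added to the
#' measured systolic and 10 mmHg to the measured diastolic pressure (the
#' standard GWAS adjustment for treated individuals); untreated samples are
#' unchanged. Pulse pressure of treated samples therefore increases by
#' exactly 5 mmHg.
#'
#' @param sbp,dbp measured pressures (mmHg), vectorized; sbp > dbp required.
#' @param onMed logical medication flag.
#' @param effect named numeric \code{c(sbp, dbp)} added for treated samples.
#' @return list with \code{sbp_adj} and \code{dbp_adj}.
#' @examples
#' adjustForMedication(135, 85, TRUE)   # 150 / 95
#' @export
adjustForMedication <- function(sbp, dbp, onMed,
                                effect = c(sbp = 15, dbp = 10)) {
  if (any(dbp <= 0)) stop("pressures must be positive")
  if (any(sbp <= dbp)) stop("sbp must exceed dbp for every sample")
  list(sbp_adj = sbp + effect[["sbp"]] * as.numeric(onMed),
       dbp_adj = dbp + effect[["dbp"]] * as.numeric(onMed))
}

#' Derived pressures: pulse pressure and mean arterial pressure
#'
#' PP = SBP - DBP; MAP = (SBP + 2 DBP) / 3 (equivalently DBP + PP/3).
#'
#' @param sbp,dbp pressures in mmHg; sbp > dbp required.
#' @return list with \code{pp} and \code{map}.
#' @examples
#' derivePressures(159.7, 101.3)
#' @export
derivePressures <- function(sbp, dbp) {
  if (any(sbp <= dbp)) stop("sbp must exceed dbp")
  pp <- sbp - dbp
  list(pp = pp, map = (sbp + 2 * dbp) / 3)
}

#' Hypertension classification
#'
#' True iff measured SBP >= 140 mmHg, measured DBP >= 90 mmHg, or the sample
#' is on anti-hypertensive medication. Classification always uses raw
#' (pre-adjustment) pressures: the +15/+10 medication adjustment applies
#' only to the continuous traits.
#'
#' @param sbp,dbp measured (unadjusted) pressures, mmHg.
#' @param onMed logical medication flag.
#' @export
classifyHypertension <- function(sbp, dbp, onMed) {
  sbp >= 140 | dbp >= 90 | as.logical(onMed)
}

#' Average repeated blood-pressure readings
#'
#' Three readings are taken; the mean of the final two is used.
#'
#' @param readings list of length-2 numeric vectors \code{c(sbp, dbp)}, or a
#'   3 x 2 matrix with one reading per row.
#' @return list with \code{sbp} and \code{dbp}.
#' @export
averageBpReadings <- function(readings) {
  if (is.list(readings)) readings <- do.call(rbind, readings)
  if (!is.matrix(readings) || nrow(readings) != 3L || ncol(readings) != 2L)
    stop("exactly 3 readings of (sbp, dbp) are required")
  m <- colMeans(readings[2:3, , drop = FALSE])
  list(sbp = m[[1]], dbp = m[[2]])
}

#' Prepare analysis-ready blood-pressure traits
#'
#' Appends to a raw phenotype table (sample_id, sex, age, sbp, dbp, on_med)
#' the medication-adjusted pressures, derived PP and MAP (computed from the
#' adjusted pressures), and the hypertension flag (computed from the raw
#' pressures). Raw columns are never overwritten.
#'
#' @param phen phenotype data.frame.
#' @return the table with sbp_adj, dbp_adj, pp, map, hypertensive appended.
#' @export
preparePhenotypes <- function(phen) {
  need <- c("sample_id", "sex", "age", "sbp", "dbp", "on_med")
  miss <- setdiff(need, colnames(phen))
  if (length(miss))
    stop("phenotype table lacks columns: ", paste(miss, collapse = ", "))
  adj <- adjustForMedication(phen$sbp, phen$dbp, phen$on_med)
  der <- derivePressures(adj$sbp_adj, adj$dbp_adj)
  phen$sbp_adj <- adj$sbp_adj
  phen$dbp_adj <- adj$dbp_adj
  phen$pp <- der$pp
  phen$map <- der$map
  phen$hypertensive <- classifyHypertension(phen$sbp, phen$dbp, phen$on_med)
  phen
}

# Pull the analysis trait vector out of a prepared phenotype table.
.traitVector <- function(phen, trait = c("SBP", "DBP", "MAP", "PP")) {
  trait <- match.arg(trait)
  col <- switch(trait, SBP = "sbp_adj", DBP = "dbp_adj",
                MAP = "map", PP = "pp")
  if (!col %in% colnames(phen))
    stop("phenotype table is not prepared; call preparePhenotypes() first")
  phen[[col]]
}
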