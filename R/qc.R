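## Exclusion rules and audit log.

#' Severe-movement flag
#'
#' An ablation has severe movement artifact if the absolute value of either
#' control recoil exceeds the measured initial recoil velocity. The
#' comparison is against the signed IRV (so a negative IRV with any nonzero
#' control is flagged); exact ties (`|control| == irv`) are kept, since the
#' rule requires strictly greater.
#'
#' @param irv measured IRV, \eqn{\mu m/s}.
#' @param orthIrv,parIrv control IRVs, \eqn{\mu m/s}.
#' @return logical.
#' @examples
#' severeMovementCheck(2.8, 0.1, -0.2)  # FALSE
#' severeMovementCheck(1.0, 1.5, 0.0)   # TRUE
#' @export
severeMovementCheck <- function(irv, orthIrv, parIrv) {
  if (any(is.na(c(irv, orthIrv, parIrv))))
    stopValidation("severe-movement check requires all three IRVs")
  abs(orthIrv) > irv | abs(parIrv) > irv
}

#' Apply the measurement exclusion rules
#'
#' Removes measurements for any of: ablation outside the admissible regions
#' (midline / lateral folds), unknown embryo sex or somite stage, bubbles in
#' the ablation path, severe movement artifact (see
#' [severeMovementCheck()]), or failed point selection
#' (insufficient landmarks). Every input measurement receives exactly one
#' QC decision; kept is TRUE iff the reason list is empty.
#'
#' @param measurements data.frame from [measureCohort()] (or matching
#'   columns recording_id, embryo_id, irv, orth_irv, par_irv, region, plus
#'   optional bubbles / outside_region / insufficient_landmarks flags).
#' @param metadata data.frame: embryo_id, sex, somites (embryo_id unique).
#'   Measurements that do not join are treated as unknown sex/stage.
#' @param severeMovementScope `"ablation"` (default: flag individual
#'   measurements) or `"embryo"` (drop every ablation of an embryo if any
#'   one is flagged).
#' @return list: `analysis` (kept measurements joined to metadata),
#'   `decisions` (recording_id, kept, reasons), `counts` (kept ablations and
#'   distinct kept embryos).
#' @export
applyExclusions <- function(measurements, metadata,
                            severeMovementScope = c("ablation", "embryo")) {
  severeMovementScope <- match.arg(severeMovementScope)
  if (anyDuplicated(measurements$recording_id))
    stopValidation("duplicate recording_id in measurements")
  if (anyDuplicated(metadata$embryo_id))
    stopValidation("duplicate embryo_id in metadata")
  mIdx <- match(measurements$embryo_id, metadata$embryo_id)
  sex <- metadata$sex[mIdx]
  somites <- metadata$somites[mIdx]

  n <- nrow(measurements)
  reasons <- vector("list", n)
  add <- function(i, r) reasons[[i]] <<- c(reasons[[i]], r)
  insuff <- measurements$insufficient_landmarks %||% rep(FALSE, n)
  bub <- measurements$bubbles %||% rep(FALSE, n)
  outR <- measurements$outside_region %||% rep(FALSE, n)

  severe <- rep(FALSE, n)
  measurable <- !is.na(measurements$irv)
  severe[measurable] <- severeMovementCheck(
    measurements$irv[measurable], measurements$orth_irv[measurable],
    measurements$par_irv[measurable])
  if (severeMovementScope == "embryo") {
    bad <- unique(measurements$embryo_id[severe])
    severe <- measurements$embryo_id %in% bad
  }
  for (i in seq_len(n)) {
    if (outR[i] || !(measurements$region[i] %in% c("midline", "lateral")))
      add(i, "outside_region")
    if (is.na(mIdx[i]) || is.na(sex[i]) || sex[i] == "unknown" ||
        is.na(somites[i]))
      add(i, "unknown_sex_or_stage")
    if (isTRUE(bub[i])) add(i, "bubbles")
    if (isTRUE(insuff[i])) add(i, "insufficient_landmarks")
    if (isTRUE(severe[i])) add(i, "severe_movement")
  }
  kept <- lengths(reasons) == 0L
  decisions <- data.frame(
    recording_id = measurements$recording_id, kept = kept,
    reasons = vapply(reasons, paste, character(1L), collapse = ";"),
    stringsAsFactors = FALSE)
  analysis <- measurements[kept, , drop = FALSE]
  analysis$sex <- sex[kept]
  analysis$somites <- somites[kept]
  rownames(analysis) <- NULL
  list(analysis = analysis, decisions = decisions,
       counts = c(ablations = sum(kept),
                  embryos = length(unique(analysis$embryo_id))))
}
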