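## Cohort-level measurement pipeline: landmark sets -> indexed annular
## metrics, measurement records -> indexed volumetric/hemodynamic variables,
## assembled as one long table ready for comparisonTable().

## Derive the indexed volumetric and hemodynamic variable panel from a
## per-subject/visit measurement record table (columns as written by
## writeMeasurements()). Returns a long data.frame.
.recordsToLong <- function(records) {
  sv <- strokeVolumeEF(records$LVEDV_mL, records$LVESV_mL)
  mr <- mitralRegurgitation(sv$TSV, records$RV_TSV_mL)
  bw <- records$BW_kg
  long <- list(
    LVEDVi = indexMeasurement(records$LVEDV_mL, "volume", bw),
    LVESVi = indexMeasurement(records$LVESV_mL, "volume", bw),
    LVEF_pct = 100 * sv$EF,
    LVSVi = indexMeasurement(sv$TSV, "volume", bw),
    RVoli = indexMeasurement(mr$RVol, "volume", bw),
    RF_pct = 100 * mr$RF,
    LAESVi = indexMeasurement(records$LAESV_mL, "volume", bw),
    LAEDVi = indexMeasurement(records$LAEDV_mL, "volume", bw),
    MBP = records$MBP_mmHg)
  if (all(c("VTI_cm", "AVCSA_cm2") %in% names(records))) {
    fsv <- forwardStrokeVolume(records$VTI_cm, records$AVCSA_cm2)
    long$Ea <- arterialElastance(records$MBP_mmHg, fsv, bw)
  }
  if (all(c("AoArea_max_mm2", "AoArea_min_mm2") %in% names(records)))
    long$ADI_x1000 <- 1e3 * aorticDistensibilityIndex(
      records$AoArea_max_mm2, records$AoArea_min_mm2,
      records$SAP_mmHg, records$DAP_mmHg)
  do.call(rbind, lapply(names(long), function(v)
    data.frame(subject_id = records$subject_id, visit = records$visit,
               phase = NA_character_, variable = v, value = long[[v]],
               stringsAsFactors = FALSE)))
}

#' Measure a synthetic cohort through the full pipeline
#'
#' Produces the long-format indexed variable table the paired statistics
#' consume. Annular metrics come either from the landmark sets via
#' [annulusMetrics()] (spline reconstruction, projection, indexing) when
#' available, or from the generator's closed-form saddle metrics when the
#' cohort was generated at measurement level; volumetric and hemodynamic
#' variables are always derived from the measurement records via
#' [strokeVolumeEF()], [mitralRegurgitation()], [forwardStrokeVolume()],
#' [arterialElastance()] and [aorticDistensibilityIndex()], with allometric
#' indexing per [indexMeasurement()]. The leaflet-to-annulus index uses the
#' late-systolic APD.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param M resample size for [resampleRing()] when landmarks are used.
#' @param useLandmarks reconstruct geometry from landmark sets (default:
#'   whenever the cohort has them).
#' @return long data.frame: subject_id, visit, phase (NA for non-phase
#'   variables), variable, value. Annular variables are `MAAi`
#'   (cm^2/m^2), `APDi`, `ICDi`, `TTDi` (mm/kg^(1/3)), `SI`, `LAI`;
#'   volumetric/hemodynamic variables are `LVEDVi`, `LVESVi`, `LVEF_pct`,
#'   `LVSVi`, `RVoli`, `RF_pct`, `LAESVi`, `LAEDVi`, `MBP`, `Ea`,
#'   `ADI_x1000`.
#' @export
measureCohort <- function(cohort, M = 512L,
                          useLandmarks = length(cohort@landmarks) > 0L) {
  stopifnot(is(cohort, "SyntheticCohort"))
  bwMap <- stats::setNames(cohort@subjects$BW_kg, cohort@subjects$subject_id)
  recs <- cohort@records

  if (useLandmarks) {
    if (!length(cohort@landmarks)) stop("cohort carries no landmark sets")
    rows <- lapply(cohort@landmarks, function(lm) {
      m <- annulusMetrics(lm, M = M)
      bw <- bwMap[[m$subject_id]]
      data.frame(subject_id = m$subject_id, visit = m$visit, phase = m$phase,
                 MAAi = indexMeasurement(m$MAA, "area", bw),
                 APDi = indexMeasurement(m$APD, "linear", bw),
                 ICDi = indexMeasurement(m$ICD, "linear", bw),
                 TTDi = indexMeasurement(m$TTD, "linear", bw),
                 SI = m$SI, APD_mm = m$APD, stringsAsFactors = FALSE)
    })
    ann <- do.call(rbind, rows)
  } else {
    ann <- cohort@annulus[, c("subject_id", "visit", "phase",
                              "MAAi", "APDi", "ICDi", "TTDi", "SI")]
    ann$APD_mm <- ann$APDi * bwMap[ann$subject_id]^(1 / 3)
  }

  annLong <- do.call(rbind, lapply(c("MAAi", "APDi", "ICDi", "TTDi", "SI"),
    function(v) data.frame(subject_id = ann$subject_id, visit = ann$visit,
                           phase = ann$phase, variable = v, value = ann[[v]],
                           stringsAsFactors = FALSE)))

  ## LAI: total leaflet length over the late-systolic APD (both in mm)
  laiLong <- NULL
  ls <- ann[ann$phase == "LS", , drop = FALSE]
  if (nrow(ls) &&
      all(c("aortic_leaflet_mm", "parietal_leaflet_mm") %in% names(recs))) {
    key <- paste(ls$subject_id, ls$visit)
    rkey <- paste(recs$subject_id, recs$visit)
    idx <- match(key, rkey)
    tll <- recs$aortic_leaflet_mm[idx] + recs$parietal_leaflet_mm[idx]
    laiLong <- data.frame(subject_id = ls$subject_id, visit = ls$visit,
                          phase = NA_character_, variable = "LAI",
                          value = tll / ls$APD_mm, stringsAsFactors = FALSE)
  }

  out <- rbind(annLong, laiLong, .recordsToLong(recs))
  rownames(out) <- NULL
  out
}

#' Run the full paired analysis on a cohort
#'
#' Convenience facade: [measureCohort()] then [comparisonTable()] and
#' [formatComparisonTable()].
#'
#' @param cohort a [SyntheticCohort-class].
#' @param variables,phases passed to [comparisonTable()].
#' @param M,useLandmarks passed to [measureCohort()].
#' @param alpha significance level.
#' @return list with `measurements` (long table), `table` (numeric
#'   comparison table) and `formatted` (publication-style rendering).
#' @export
analyzeCohort <- function(cohort, variables = NULL, phases = NULL, M = 512L,
                          useLandmarks = length(cohort@landmarks) > 0L,
                          alpha = 0.05) {
  long <- measureCohort(cohort, M = M, useLandmarks = useLandmarks)
  tbl <- comparisonTable(long, variables = variables, phases = phases,
                         alpha = alpha)
  list(measurements = long, table = tbl,
       formatted = formatComparisonTable(tbl))
}
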