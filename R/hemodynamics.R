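## Arterial load estimates: elastance and the aortic distensibility index.

#' Forward stroke volume from aortic Doppler
#'
#' FSV = aortic velocity-time integral x aortic valve cross-sectional area
#' (cm x cm^2 = cm^3 = mL).
#'
#' @param VTI aortic velocity-time integral (cm), > 0.
#' @param AV_CSA aortic valve cross-sectional area (cm^2), > 0.
#' @return FSV in mL.
#' @export
forwardStrokeVolume <- function(VTI, AV_CSA) {
  if (any(VTI <= 0) || any(AV_CSA <= 0))
    stop("VTI and AV_CSA must be positive")
  VTI * AV_CSA
}

#' Arterial elastance estimate
#'
#' Ea = mean oscillometric blood pressure divided by the weight-indexed LV
#' forward stroke volume: Ea = MBP / (FSV / BW), in mmHg/mL/kg. The MBP is
#' the recorded oscillometric mean, not derived from SAP/DAP.
#'
#' @param MBP mean oscillometric blood pressure (mmHg).
#' @param FSV forward stroke volume (mL), > 0.
#' @param BW body weight (kg), > 0.
#' @return Ea in mmHg/mL/kg.
#' @export
arterialElastance <- function(MBP, FSV, BW) {
  if (any(FSV <= 0)) stop("FSV must be positive")
  if (any(BW <= 0)) stop("BW must be positive")
  MBP / (FSV / BW)
}

#' Aortic distensibility index (ADI)
#'
#' Fractional cross-sectional area change of the ascending aorta per mmHg of
#' systemic pulse pressure: ADI = ((area_max - area_min) / area_min) /
#' (SAP - DAP), in mmHg^-1. The diastolic (minimal) area is the denominator
#' of the fractional change. Reports conventionally print ADI x 10^3.
#'
#' @param areaMax,areaMin maximal and minimal ascending-aortic
#'   cross-sectional areas (mm^2), areaMin > 0.
#' @param SAP,DAP systolic and diastolic arterial pressures (mmHg),
#'   SAP > DAP.
#' @return ADI in mmHg^-1 (multiply by 1e3 for the reported scale).
#' @examples
#' 1e3 * aorticDistensibilityIndex(120, 100, 120, 80)  # 5.0
#' @export
aorticDistensibilityIndex <- function(areaMax, areaMin, SAP, DAP) {
  if (any(areaMin <= 0)) stop("areaMin must be positive")
  if (any(SAP <= DAP)) stop("SAP must exceed DAP")
  ((areaMax - areaMin) / areaMin) / (SAP - DAP)
}
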