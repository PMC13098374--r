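## Chamber volumetrics: stroke volumes, ejection fraction, volumetric
## mitral-regurgitation quantification, and allometric indexing.

#' Total stroke volume and ejection fraction
#'
#' TSV = LVEDV - LVESV; EF = TSV / LVEDV. An EF of exactly 1 (LVESV = 0) is
#' mathematically allowed but physiologically implausible and is flagged
#' with a warning.
#'
#' @param LVEDV,LVESV left-ventricular end-diastolic and end-systolic
#'   volumes (mL), with LVEDV > LVESV >= 0.
#' @return list with `TSV` (mL) and `EF` (fraction of LVEDV).
#' @export
strokeVolumeEF <- function(LVEDV, LVESV) {
  if (any(LVESV < 0)) stop("LVESV must be non-negative")
  if (any(LVESV >= LVEDV)) stop("LVEDV must exceed LVESV")
  if (any(LVESV == 0)) warning("LVESV = 0 gives EF = 1; physiologically implausible")
  tsv <- LVEDV - LVESV
  list(TSV = tsv, EF = tsv / LVEDV)
}

#' Volumetric mitral regurgitation
#'
#' With no relevant right-sided regurgitation the right-ventricular TSV is a
#' surrogate for the LV forward stroke volume, so the regurgitant volume is
#' the biventricular stroke-volume difference: RVol = LV TSV - RV TSV, and
#' the regurgitant fraction RF = RVol / LV TSV. A negative RVol (RV TSV
#' exceeding LV TSV) is physiologically implausible; it is returned
#' unclipped with a warning so downstream statistics stay unbiased.
#'
#' @param LV_TSV left-ventricular total stroke volume (mL), > 0.
#' @param RV_TSV right-ventricular total stroke volume (mL).
#' @return list with `RVol` (mL) and `RF` (fraction of LV TSV).
#' @examples
#' mitralRegurgitation(25, 18)  # RVol 7 mL, RF 0.28
#' @export
mitralRegurgitation <- function(LV_TSV, RV_TSV) {
  if (any(LV_TSV <= 0)) stop("LV_TSV must be positive")
  rvol <- LV_TSV - RV_TSV
  if (any(rvol < 0))
    warning("negative regurgitant volume (RV TSV > LV TSV); returned unclipped")
  list(RVol = rvol, RF = rvol / LV_TSV)
}

#' Canine body surface area
#'
#' Standard canine allometric form BSA = 0.101 * BW^(2/3) (BW in kg, BSA in
#' m^2). The constant is recorded so that area indices can be rescaled if a
#' different convention is needed.
#'
#' @param BW body weight in kg, > 0.
#' @param k allometric constant (default 0.101).
#' @return BSA in m^2.
#' @export
canineBSA <- function(BW, k = 0.101) {
  if (any(BW <= 0)) stop("BW must be positive")
  k * BW^(2 / 3)
}

#' Allometric indexing of a measurement
#'
#' Removes body-size dependence: linear measures (mm) are divided by
#' BW^(1/3) (mm/kg^(1/3)), areas (mm^2) are converted to cm^2 and divided by
#' BSA (cm^2/m^2), volumes (mL) are divided by BW (mL/kg).
#'
#' @param value measurement in mm, mm^2 or mL according to `kind`.
#' @param kind `"linear"`, `"area"` or `"volume"`.
#' @param BW body weight in kg.
#' @param bsaConstant passed to [canineBSA()] for area indexing.
#' @return indexed value.
#' @examples
#' indexMeasurement(20, "linear", BW = 8)   # 10 mm/kg^(1/3)
#' indexMeasurement(40, "volume", BW = 10)  # 4 mL/kg
#' @export
indexMeasurement <- function(value, kind = c("linear", "area", "volume"),
                             BW, bsaConstant = 0.101) {
  kind <- match.arg(kind)
  if (any(BW <= 0)) stop("BW must be positive")
  switch(kind,
         linear = value / BW^(1 / 3),
         area = (value / 100) / canineBSA(BW, bsaConstant),
         volume = value / BW)
}
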