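## S4 classes for the annulus-geometry and cohort containers.

#' @importFrom methods new is validObject setClass setGeneric setMethod setValidity show
NULL

.PHASE_LEVELS <- c("MD", "LD", "ED", "MS", "LS", "ES")
.VISIT_LEVELS <- c("pre", "post")

#' Cardiac phase labels
#'
#' Ordered labels of the analysed cardiac phases: mid-diastole (MD, onset of
#' diastasis), late diastole (LD, just before atrial contraction), end
#' diastole (ED, after atrial contraction), mid-systole (MS), late systole
#' (LS, the phase used for the leaflet-to-annulus index) and end systole
#' (ES, minimal left-ventricular volume).
#'
#' @return character vector of the six phase labels in cycle order.
#' @export
phaseLevels <- function() .PHASE_LEVELS

#' AnnulusLandmarkSet: ordered 3D marker ring for one subject/visit/phase
#'
#' Sixteen ordered markers (millimetres, device frame) placed around the
#' mitral annulus, two of which are flagged as the left/lateral and
#' right/medial fibrous trigones. Markers are ordered counter-clockwise when
#' viewed from the left atrium (the `winding` tag records this convention).
#'
#' @slot subjectId character scalar.
#' @slot visit `"pre"` or `"post"`.
#' @slot phase one of [phaseLevels()].
#' @slot markers 16 x 3 numeric matrix (x, y, z in mm).
#' @slot trigoneIndices integer pair of 1-based marker indices
#'   (left/lateral, right/medial).
#' @slot winding orientation tag, currently always `"ccw_atrial"`.
#' @export
setClass("AnnulusLandmarkSet",
  representation(subjectId = "character", visit = "character",
                 phase = "character", markers = "matrix",
                 trigoneIndices = "integer", winding = "character"),
  prototype(winding = "ccw_atrial"))

setValidity("AnnulusLandmarkSet", function(object) {
  m <- object@markers
  msg <- character()
  if (!is.numeric(m) || !identical(dim(m), c(16L, 3L)))
    msg <- c(msg, "markers must be a 16 x 3 numeric matrix")
  if (any(!is.finite(m)))
    msg <- c(msg, "markers must be finite")
  ti <- object@trigoneIndices
  if (length(ti) != 2L || anyNA(ti) || ti[1L] == ti[2L] ||
      any(ti < 1L) || any(ti > 16L))
    msg <- c(msg, "trigoneIndices must be two distinct indices in 1..16")
  if (length(object@visit) != 1L || !object@visit %in% .VISIT_LEVELS)
    msg <- c(msg, "visit must be 'pre' or 'post'")
  if (length(object@phase) != 1L || !object@phase %in% .PHASE_LEVELS)
    msg <- c(msg, sprintf("phase must be one of %s",
                          paste(.PHASE_LEVELS, collapse = ", ")))
  if (!identical(object@winding, "ccw_atrial"))
    msg <- c(msg, "winding must be 'ccw_atrial'")
  if (is.numeric(m) && identical(dim(m), c(16L, 3L)) && all(is.finite(m))) {
    nxt <- rbind(m[-1L, , drop = FALSE], m[1L, , drop = FALSE])
    if (any(sqrt(rowSums((m - nxt)^2)) <= 1e-6))
      msg <- c(msg, "consecutive markers coincide (distance <= 1e-6 mm)")
  }
  if (length(msg)) msg else TRUE
})

#' Constructor for AnnulusLandmarkSet
#'
#' @param markers 16 x 3 numeric matrix of marker coordinates (mm).
#' @param trigoneIndices integer pair of 1-based marker indices flagging the
#'   fibrous trigones.
#' @param subjectId,visit,phase identifiers; see class slots.
#' @param winding marker ordering convention tag.
#' @return an [AnnulusLandmarkSet-class] object.
#' @examples
#' th <- 2 * pi * (0:15) / 16
#' lm <- AnnulusLandmarkSet(cbind(6 * cos(th), 6.5 * sin(th), cos(2 * th)),
#'                          trigoneIndices = c(3L, 15L))
#' trigoneDistance(lm)
#' @export
AnnulusLandmarkSet <- function(markers, trigoneIndices,
                               subjectId = "subject", visit = "pre",
                               phase = "ES", winding = "ccw_atrial") {
  new("AnnulusLandmarkSet", subjectId = as.character(subjectId),
      visit = as.character(visit), phase = as.character(phase),
      markers = as.matrix(markers),
      trigoneIndices = as.integer(trigoneIndices), winding = winding)
}

#' AnnulusRing: dense closed reconstruction of the annulus
#'
#' A closed periodic interpolating curve through the 16 markers, resampled
#' at approximately arc-length-uniform points, together with its
#' total-least-squares projection plane and the aortic/parietal partition of
#' the ring (the aortic portion is the arc between the trigones on the
#' anterior side).
#'
#' @slot curve M x 3 numeric matrix of resampled points (first point not
#'   repeated; the curve is closed implicitly).
#' @slot planeOrigin,planeNormal best-fit plane; the unit normal points
#'   toward the left atrium.
#' @slot portion character vector of length M, `"aortic"` or `"parietal"`.
#' @slot trigoneCurveIndex integer pair: curve indices nearest the trigone
#'   markers.
#' @slot selfIntersecting logical flag: the projected ring crosses itself
#'   (metrics are still computed, with a warning upstream).
#' @export
setClass("AnnulusRing",
  representation(curve = "matrix", planeOrigin = "numeric",
                 planeNormal = "numeric", portion = "character",
                 trigoneCurveIndex = "integer", selfIntersecting = "logical"))

setValidity("AnnulusRing", function(object) {
  msg <- character()
  if (!is.numeric(object@curve) || ncol(object@curve) != 3L ||
      nrow(object@curve) < 64L)
    msg <- c(msg, "curve must be an M x 3 numeric matrix with M >= 64")
  if (abs(sqrt(sum(object@planeNormal^2)) - 1) > 1e-8)
    msg <- c(msg, "planeNormal must be unit length")
  if (length(object@portion) != nrow(object@curve))
    msg <- c(msg, "portion must label every curve point")
  if (!all(object@portion %in% c("aortic", "parietal")))
    msg <- c(msg, "portion labels must be 'aortic' or 'parietal'")
  if (!all(c("aortic", "parietal") %in% object@portion))
    msg <- c(msg, "both aortic and parietal portions must be non-empty")
  if (length(msg)) msg else TRUE
})

#' LeafletMeasurement: mitral leaflet lengths at late systole
#'
#' Lengths (mm) of the aortic (anterior) and parietal (posterior) mitral
#' valve leaflets measured across the centre of the valve at a late-systolic
#' phase; their sum is the total leaflet length (TLL) used by the
#' leaflet-to-annulus index.
#'
#' @slot aorticLeafletLength,parietalLeafletLength mm, both > 0.
#' @slot phase must be `"LS"`.
#' @export
setClass("LeafletMeasurement",
  representation(aorticLeafletLength = "numeric",
                 parietalLeafletLength = "numeric", phase = "character"))

setValidity("LeafletMeasurement", function(object) {
  msg <- character()
  if (object@aorticLeafletLength <= 0 || object@parietalLeafletLength <= 0)
    msg <- c(msg, "leaflet lengths must be positive")
  if (!identical(object@phase, "LS"))
    msg <- c(msg, "leaflet lengths are defined at late systole (phase 'LS')")
  if (length(msg)) msg else TRUE
})

#' @rdname LeafletMeasurement-class
#' @param aorticLeafletLength,parietalLeafletLength leaflet lengths in mm.
#' @param phase phase label; must be `"LS"`.
#' @return a `LeafletMeasurement` object.
#' @export
LeafletMeasurement <- function(aorticLeafletLength, parietalLeafletLength,
                               phase = "LS") {
  new("LeafletMeasurement", aorticLeafletLength = aorticLeafletLength,
      parietalLeafletLength = parietalLeafletLength, phase = phase)
}

#' MADProfile: per-phase annulus metrics for one subject/visit
#'
#' Mitral annular dynamics profile: the annulus metric panel evaluated at
#' each available cardiac phase, ordered MD < LD < ED < MS < LS < ES.
#' Missing phases are recorded as absent, never interpolated.
#'
#' @slot subjectId,visit identifiers.
#' @slot series data.frame with one row per phase (column `phase` plus
#'   metric columns such as `MAA`, `APD`, `ICD`, `TTD`, `SI`).
#' @slot lai leaflet-to-annulus index at late systole (`NA` if unavailable).
#' @export
setClass("MADProfile",
  representation(subjectId = "character", visit = "character",
                 series = "data.frame", lai = "numeric"))

setValidity("MADProfile", function(object) {
  msg <- character()
  ph <- object@series$phase
  if (is.null(ph)) return("series must have a 'phase' column")
  if (anyDuplicated(ph)) msg <- c(msg, "duplicate phase entries")
  if (!all(ph %in% .PHASE_LEVELS)) msg <- c(msg, "unknown phase label")
  if (!all(c("ED", "ES") %in% ph))
    msg <- c(msg, "profile must contain at least ED and ES")
  if (length(msg)) msg else TRUE
})

#' SyntheticCohort: simulated paired cohort with known ground truth
#'
#' A cohort of subjects, each with paired pre/post visits: annulus geometry
#' per cardiac phase (optionally realised as landmark sets), chamber volumes,
#' pressures and flow quantities, plus the generating truth parameters for
#' recovery and calibration studies.
#'
#' @slot subjects data.frame: subject_id, BW_kg, BSA_m2.
#' @slot annulus data.frame: one row per subject x visit x phase with true
#'   and measured saddle parameters and analytic indexed metrics.
#' @slot records data.frame: one row per subject x visit with volumes (mL),
#'   pressures (mmHg), aortic areas (mm2) and flow quantities.
#' @slot landmarks named list of [AnnulusLandmarkSet-class] objects (empty
#'   when the cohort was generated at measurement level only).
#' @slot truth list of generating parameters, subject-level effects and
#'   programmed effect sizes.
#' @slot config the generator configuration used.
#' @slot seed integer RNG seed the cohort was generated with.
#' @export
setClass("SyntheticCohort",
  representation(subjects = "data.frame", annulus = "data.frame",
                 records = "data.frame", landmarks = "list",
                 truth = "list", config = "list", seed = "integer"))

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  if (!all(c("subject_id", "BW_kg", "BSA_m2") %in% names(object@subjects)))
    msg <- c(msg, "subjects must have subject_id, BW_kg, BSA_m2")
  if (any(object@subjects$BW_kg <= 0)) msg <- c(msg, "BW_kg must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AnnulusLandmarkSet", function(object) {
  cat(sprintf("AnnulusLandmarkSet: %s / %s / %s\n  16 markers (mm), trigones at markers %d and %d\n",
              object@subjectId, object@visit, object@phase,
              object@trigoneIndices[1L], object@trigoneIndices[2L]))
})

setMethod("show", "AnnulusRing", function(object) {
  cat(sprintf("AnnulusRing: %d resampled points (%d aortic / %d parietal)%s\n",
              nrow(object@curve), sum(object@portion == "aortic"),
              sum(object@portion == "parietal"),
              if (object@selfIntersecting) " [projected curve self-intersects]" else ""))
})

setMethod("show", "MADProfile", function(object) {
  cat(sprintf("MADProfile: %s / %s, phases: %s\n", object@subjectId,
              object@visit, paste(object@series$phase, collapse = " ")))
  if (!is.na(object@lai)) cat(sprintf("  LAI (late systole): %.3f\n", object@lai))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d subjects x {pre, post}, seed %d\n",
              nrow(object@subjects), object@seed))
  cat(sprintf("  %d landmark sets, %d annulus rows, %d measurement records\n",
              length(object@landmarks), nrow(object@annulus),
              nrow(object@records)))
})
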