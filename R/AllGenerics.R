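## Generics and accessors.

#' Accessors for landmark sets and rings
#'
#' @param x an [AnnulusLandmarkSet-class], [AnnulusRing-class],
#'   [MADProfile-class] or [SyntheticCohort-class] object.
#' @name accessors
NULL

#' @rdname accessors
#' @return `markers()`: 16 x 3 numeric matrix of marker coordinates (mm).
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' @rdname accessors
#' @export
setMethod("markers", "AnnulusLandmarkSet", function(x) x@markers)

#' @rdname accessors
#' @return `trigoneIndices()`: integer pair of 1-based trigone marker indices.
#' @export
setGeneric("trigoneIndices", function(x) standardGeneric("trigoneIndices"))

#' @rdname accessors
#' @export
setMethod("trigoneIndices", "AnnulusLandmarkSet", function(x) x@trigoneIndices)

#' @rdname accessors
#' @return `ringCurve()`: M x 3 matrix of resampled ring points.
#' @export
setGeneric("ringCurve", function(x) standardGeneric("ringCurve"))

#' @rdname accessors
#' @export
setMethod("ringCurve", "AnnulusRing", function(x) x@curve)

#' @rdname accessors
#' @return `planeNormal()`: unit normal of the best-fit plane.
#' @export
setGeneric("planeNormal", function(x) standardGeneric("planeNormal"))

#' @rdname accessors
#' @export
setMethod("planeNormal", "AnnulusRing", function(x) x@planeNormal)

#' @rdname accessors
#' @return `ringPortion()`: per-point `"aortic"`/`"parietal"` labels.
#' @export
setGeneric("ringPortion", function(x) standardGeneric("ringPortion"))

#' @rdname accessors
#' @export
setMethod("ringPortion", "AnnulusRing", function(x) x@portion)

#' @rdname accessors
#' @return `profileSeries()`: the per-phase metric data.frame of a profile.
#' @export
setGeneric("profileSeries", function(x) standardGeneric("profileSeries"))

#' @rdname accessors
#' @export
setMethod("profileSeries", "MADProfile", function(x) x@series)

#' @rdname accessors
#' @return `cohortSubjects()`: subject table (subject_id, BW_kg, BSA_m2).
#' @export
setGeneric("cohortSubjects", function(x) standardGeneric("cohortSubjects"))

#' @rdname accessors
#' @export
setMethod("cohortSubjects", "SyntheticCohort", function(x) x@subjects)

#' @rdname accessors
#' @return `cohortRecords()`: per subject x visit measurement records.
#' @export
setGeneric("cohortRecords", function(x) standardGeneric("cohortRecords"))

#' @rdname accessors
#' @export
setMethod("cohortRecords", "SyntheticCohort", function(x) x@records)

#' @rdname accessors
#' @return `cohortLandmarks()`: named list of landmark sets.
#' @export
setGeneric("cohortLandmarks", function(x) standardGeneric("cohortLandmarks"))

#' @rdname accessors
#' @export
setMethod("cohortLandmarks", "SyntheticCohort", function(x) x@landmarks)

#' @rdname accessors
#' @return `cohortTruth()`: generating truth parameters and programmed effects.
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @rdname accessors
#' @export
setMethod("cohortTruth", "SyntheticCohort", function(x) x@truth)
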