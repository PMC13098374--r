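## Readers and writers for landmark files (JSON/CSV), measurement tables,
## whole simulated cohorts, and the bundled reference summary fixture.

.MEASUREMENT_REQUIRED <- c("subject_id", "visit", "LVEDV_mL", "LVESV_mL",
                           "LAEDV_mL", "LAESV_mL", "RV_TSV_mL", "BW_kg")
.MEASUREMENT_OPTIONAL <- c("SAP_mmHg", "DAP_mmHg", "MBP_mmHg",
                           "AoArea_max_mm2", "AoArea_min_mm2", "VTI_cm",
                           "AVCSA_cm2", "aortic_leaflet_mm",
                           "parietal_leaflet_mm")

#' Write a landmark set to JSON or CSV
#'
#' JSON schema: `{"subject_id", "visit", "phase", "units": "mm",
#' "markers": [[x,y,z] x 16], "trigone_indices": [i, j]}` with 0-based
#' trigone indices. CSV dialect: one row per marker with columns
#' subject_id, visit, phase, idx (0-based), x, y, z, is_trigone.
#'
#' @param set an [AnnulusLandmarkSet-class].
#' @param path output path; format chosen by extension (`.json`/`.csv`)
#'   unless `format` is given.
#' @param format `"auto"`, `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
writeLandmarks <- function(set, path, format = c("auto", "json", "csv")) {
  stopifnot(is(set, "AnnulusLandmarkSet"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (format == "json") {
    obj <- list(subject_id = set@subjectId, visit = set@visit,
                phase = set@phase, units = "mm",
                markers = unname(lapply(seq_len(16L),
                                        function(i) set@markers[i, ])),
                trigone_indices = set@trigoneIndices - 1L)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(subject_id = set@subjectId, visit = set@visit,
                     phase = set@phase, idx = 0:15,
                     x = set@markers[, 1L], y = set@markers[, 2L],
                     z = set@markers[, 3L],
                     is_trigone = as.integer(seq_len(16L) %in% set@trigoneIndices))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a landmark set from JSON or CSV
#'
#' Counterpart of [writeLandmarks()]; round-trips are lossless to well below
#' 1e-9 mm. Schema violations raise errors naming the offending field.
#'
#' @param path input path (`.json` or `.csv`).
#' @return an [AnnulusLandmarkSet-class].
#' @export
readLandmarks <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("subject_id", "visit", "phase", "idx", "x", "y", "z", "is_trigone")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("landmark CSV missing column(s): ", paste(miss, collapse = ", "))
    df <- df[order(df$idx), , drop = FALSE]
    if (nrow(df) != 16L)
      stop(sprintf("expected 16 markers, found %d", nrow(df)))
    ti <- which(df$is_trigone == 1L)
    if (length(ti) != 2L)
      stop(sprintf("expected 2 trigone markers (is_trigone = 1), found %d",
                   length(ti)))
    AnnulusLandmarkSet(as.matrix(df[, c("x", "y", "z")]), trigoneIndices = ti,
                       subjectId = df$subject_id[1L], visit = df$visit[1L],
                       phase = df$phase[1L])
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (f in c("subject_id", "visit", "phase", "markers", "trigone_indices"))
      if (is.null(obj[[f]])) stop("landmark JSON missing field: ", f)
    if (!is.null(obj$units) && !identical(obj$units, "mm"))
      stop("landmark JSON field 'units' must be \"mm\"")
    m <- obj$markers
    if (is.list(m)) m <- do.call(rbind, m)
    m <- as.matrix(m)
    if (nrow(m) != 16L)
      stop(sprintf("expected 16 markers, found %d", nrow(m)))
    if (ncol(m) != 3L) stop("each marker must have 3 coordinates (x, y, z)")
    ti <- as.integer(obj$trigone_indices) + 1L
    if (length(ti) != 2L || any(ti < 1L) || any(ti > 16L))
      stop("trigone_indices must be two 0-based indices in 0..15")
    AnnulusLandmarkSet(m, trigoneIndices = ti, subjectId = obj$subject_id,
                       visit = obj$visit, phase = obj$phase)
  }
}

#' Write / read per-subject measurement tables
#'
#' CSV with one row per subject x visit. Required columns:
#' subject_id, visit, LVEDV_mL, LVESV_mL, LAEDV_mL, LAESV_mL, RV_TSV_mL,
#' BW_kg; hemodynamic and leaflet columns (SAP_mmHg, DAP_mmHg, MBP_mmHg,
#' AoArea_max_mm2, AoArea_min_mm2, VTI_cm, AVCSA_cm2, aortic_leaflet_mm,
#' parietal_leaflet_mm) are optional. Unknown columns are ignored with a
#' message. Volume invariants (LVEDV > LVESV >= 0, LAESV >= LAEDV >= 0,
#' BW > 0) are validated on read.
#'
#' @param records data.frame of measurement records.
#' @param path CSV path.
#' @return `writeMeasurements()`: the path, invisibly;
#'   `readMeasurements()`: the validated records data.frame.
#' @export
writeMeasurements <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMeasurements
#' @export
readMeasurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.MEASUREMENT_REQUIRED, names(df))
  if (length(miss))
    stop("measurement table missing required column(s): ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(df), c(.MEASUREMENT_REQUIRED, .MEASUREMENT_OPTIONAL))
  if (length(extra))
    message("ignoring unknown measurement column(s): ",
            paste(extra, collapse = ", "))
  if (any(df$BW_kg <= 0)) stop("BW_kg must be positive")
  if (any(df$LVESV_mL < 0) || any(df$LVESV_mL >= df$LVEDV_mL))
    stop("volume invariant violated: need LVEDV_mL > LVESV_mL >= 0")
  if (any(df$LAEDV_mL < 0) || any(df$LAESV_mL < df$LAEDV_mL))
    stop("volume invariant violated: need LAESV_mL >= LAEDV_mL >= 0")
  df[, intersect(c(.MEASUREMENT_REQUIRED, .MEASUREMENT_OPTIONAL), names(df))]
}

#' Write a simulated cohort to disk
#'
#' Writes `measurements.csv` plus one landmark JSON file per
#' subject/visit/phase under `landmarks/`, in the same formats the readers
#' consume (round-trip tested).
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  dir.create(file.path(dir, "landmarks"), recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, "measurements.csv")
  writeMeasurements(cohort@records, paths)
  for (nm in names(cohort@landmarks)) {
    p <- file.path(dir, "landmarks", paste0(nm, ".json"))
    writeLandmarks(cohort@landmarks[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

.REFERENCE_MD5 <- c(
  reference_table1_demographics.csv = "537b9ada84f3edd6fb18bbe4012fe512",
  reference_table2_annulus.csv = "7fd79e2e78d91d1835c6e69679bd195a",
  reference_table3_volumes.csv = "5e8d28a89a490ec86361a51f434e28cc")

#' Bundled reference cohort summaries
#'
#' Loads the read-only fixture of printed summary statistics (means, SDs,
#' medians, IQRs, mean differences, 95% CIs and p-values) from the published
#' 20-dog preclinical-MMVD pimobendan cohort that this package's workflow is
#' designed to reproduce: demographics, the per-phase annular geometry panel
#' (indexed units) and the volumetric/hemodynamic panel. Values are stored
#' verbatim as printed; file checksums are verified on load.
#'
#' @return list of data.frames: `demographics`, `annulus` (metric x phase),
#'   `volumes` (variable-level panel).
#' @examples
#' ref <- referenceSummaries()
#' subset(ref$annulus, metric == "APD" & phase == "ES")
#' @export
referenceSummaries <- function() {
  dirp <- system.file("extdata", package = "mitralCT")
  out <- list()
  for (f in names(.REFERENCE_MD5)) {
    path <- file.path(dirp, f)
    if (!file.exists(path)) stop("bundled fixture missing: ", f)
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, unname(.REFERENCE_MD5[f])))
      stop("fixture checksum mismatch for ", f)
    out[[f]] <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  list(demographics = out[[1L]], annulus = out[[2L]], volumes = out[[3L]])
}
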