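## Saddle-ring reconstruction and the annular metric panel.
##
## The annulus is modelled as a closed periodic cubic interpolating curve
## through the 16 markers (chord-length parametrisation), resampled at M
## approximately arc-length-uniform points. "Projected" quantities are
## measured in the total-least-squares plane of the resampled curve.

#' Reconstruct a dense closed annulus ring from 16 markers
#'
#' Interpolates the ordered markers with a closed periodic cubic spline under
#' chord-length parametrisation, resamples the curve at `M` approximately
#' arc-length-uniform points, fits the total-least-squares projection plane
#' (normal oriented toward the atrium using the marker winding), and splits
#' the ring into aortic and parietal portions at the trigones. The aortic
#' portion is the shorter arc between the trigones, which flank the
#' aortomitral continuity.
#'
#' @param landmarks an [AnnulusLandmarkSet-class].
#' @param M number of resampled points (>= 64; default 512).
#' @return an [AnnulusRing-class]. If the projected curve self-intersects the
#'   ring is flagged (and a warning emitted); metrics are still computable.
#' @examples
#' th <- 2 * pi * (0:15) / 16
#' lm <- AnnulusLandmarkSet(cbind(6 * cos(th), 6.5 * sin(th), cos(2 * th)),
#'                          trigoneIndices = c(3L, 15L))
#' ring <- resampleRing(lm)
#' annulusArea(ring)  # close to pi * 6 * 6.5
#' @export
resampleRing <- function(landmarks, M = 512L) {
  stopifnot(is(landmarks, "AnnulusLandmarkSet"))
  validObject(landmarks)
  M <- as.integer(M)
  if (M < 64L) stop("M must be at least 64")
  P <- landmarks@markers
  Pc <- rbind(P, P[1L, ])
  chord <- sqrt(rowSums((Pc[-1L, ] - Pc[-17L, ])^2))
  tknot <- c(0, cumsum(chord))
  Ttot <- tknot[17L]

  ## dense pass for arc length, then invert to uniform arc length
  nDense <- max(2048L, 4L * M)
  td <- seq(0, Ttot, length.out = nDense + 1L)
  dense <- vapply(1:3, function(j)
    stats::spline(tknot, Pc[, j], method = "periodic", xout = td)$y,
    numeric(nDense + 1L))
  seg <- sqrt(rowSums((dense[-1L, , drop = FALSE] -
                       dense[-(nDense + 1L), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  sTarget <- cum[nDense + 1L] * (0:(M - 1L)) / M
  tq <- stats::approx(cum, td, xout = sTarget, ties = "ordered")$y
  curve <- vapply(1:3, function(j)
    stats::spline(tknot, Pc[, j], method = "periodic", xout = tq)$y,
    numeric(M))

  plane <- .fitPlane(curve)
  normal <- .orientNormal(curve, plane$origin, plane$normal)

  ## portion split: curve points nearest each trigone marker
  ti <- landmarks@trigoneIndices
  nearest <- vapply(ti, function(k) {
    d2 <- rowSums(sweep(curve, 2L, P[k, ])^2)
    which.min(d2)
  }, integer(1L))
  if (nearest[1L] == nearest[2L])
    stop("degenerate ring: trigones collapse to the same curve point")
  i1 <- min(nearest); i2 <- max(nearest)
  arcA <- seq(i1, i2)                      # i1..i2
  arcB <- c(seq(i2, M), seq_len(i1))       # wrap-around arc
  portion <- rep("parietal", M)
  shorter <- if (length(arcA) <= length(arcB)) arcA else arcB
  portion[shorter] <- "aortic"

  xy <- .projectToPlane(curve, plane$origin, normal)
  selfInt <- .polygonSelfIntersects(xy)
  if (selfInt)
    warning("projected annulus curve self-intersects; metrics computed anyway")

  new("AnnulusRing", curve = curve, planeOrigin = plane$origin,
      planeNormal = normal, portion = portion,
      trigoneCurveIndex = as.integer(nearest), selfIntersecting = selfInt)
}

#' Mitral annular area (MAA)
#'
#' Area of the polygon formed by projecting the dense ring onto its best-fit
#' plane (shoelace formula, absolute value).
#'
#' @param ring an [AnnulusRing-class].
#' @return MAA in mm^2.
#' @export
annulusArea <- function(ring) {
  stopifnot(is(ring, "AnnulusRing"))
  xy <- .projectToPlane(ring@curve, ring@planeOrigin, ring@planeNormal)
  abs(.polygonArea(xy))
}

#' Aortoparietal distance (APD) and saddle horns
#'
#' The aortic and parietal horns are the points of maximal elevation above
#' the best-fit plane within the aortic and parietal portions respectively;
#' the APD is the in-plane distance between their projections, drawn across
#' the centre of the annulus. For nearly flat rings (maximal elevation below
#' `flatTol` mm) the horns are instead taken as the intersections of the
#' projected curve with the axis through the projected centroid and the
#' midpoint of the trigone chord.
#'
#' @param ring an [AnnulusRing-class].
#' @param flatTol saddle-height threshold (mm) below which the flat-ring
#'   fallback axis is used.
#' @return list with `APD` (mm), `horns` (2 x 3 matrix: aortic then parietal
#'   point), `axis` (unit in-plane direction of the APD in plane-basis
#'   coordinates) and `method` (`"elevation"` or `"flat_axis"`).
#' @export
aortoparietalDistance <- function(ring, flatTol = 0.05) {
  stopifnot(is(ring, "AnnulusRing"))
  basis <- .planeBasis(ring@planeNormal)
  xy <- .projectToPlane(ring@curve, ring@planeOrigin, ring@planeNormal, basis)
  elev <- sweep(ring@curve, 2L, ring@planeOrigin) %*% ring@planeNormal
  aorticIdx <- which(ring@portion == "aortic")
  parietalIdx <- which(ring@portion == "parietal")
  if (!length(aorticIdx) || !length(parietalIdx))
    stop("both ring portions must be non-empty")

  if (max(elev) >= flatTol) {
    ia <- aorticIdx[which.max(elev[aorticIdx])]
    ip <- parietalIdx[which.max(elev[parietalIdx])]
    hornsXY <- xy[c(ia, ip), , drop = FALSE]
    horns <- ring@curve[c(ia, ip), , drop = FALSE]
    method <- "elevation"
  } else {
    ## flat ring: axis through projected centroid and trigone-chord midpoint
    centroid <- colMeans(xy)
    trigXY <- xy[ring@trigoneCurveIndex, , drop = FALSE]
    mid <- colMeans(trigXY)
    d <- mid - centroid
    nd <- sqrt(sum(d^2))
    if (nd < 1e-9) stop("flat-ring fallback axis is degenerate")
    d <- d / nd
    ## signed perpendicular distance of each curve point to the axis
    rel <- sweep(xy, 2L, centroid)
    s <- rel[, 1L] * d[2L] - rel[, 2L] * d[1L]
    nPt <- nrow(xy)
    nxt <- c(seq_len(nPt)[-1L], 1L)
    crossing <- which(s * s[nxt] < 0 | s == 0)
    if (length(crossing) < 2L) stop("fallback axis does not cross the ring twice")
    crossPts <- t(vapply(crossing, function(i) {
      j <- nxt[i]
      w <- if (s[i] == 0) 0 else s[i] / (s[i] - s[j])
      xy[i, ] + w * (xy[j, ] - xy[i, ])
    }, numeric(2L)))
    proj <- as.vector(sweep(crossPts, 2L, centroid) %*% d)
    iA <- which.max(proj); iP <- which.min(proj)
    hornsXY <- crossPts[c(iA, iP), , drop = FALSE]
    ## lift in-plane fallback horns back to 3D on the plane
    horns <- sweep(hornsXY %*% basis, 2L, ring@planeOrigin, FUN = "+")
    method <- "flat_axis"
  }
  apd <- sqrt(sum((hornsXY[1L, ] - hornsXY[2L, ])^2))
  axis <- (hornsXY[1L, ] - hornsXY[2L, ]) / apd
  list(APD = apd, horns = horns, axis = axis, method = method)
}

#' Intercommissural distance (ICD)
#'
#' Maximal caliper width of the projected ring measured along the in-plane
#' direction orthogonal to the projected APD axis (max minus min of the
#' scalar projections).
#'
#' @param ring an [AnnulusRing-class].
#' @param apdAxis unit in-plane APD direction in plane-basis coordinates, as
#'   returned by [aortoparietalDistance()].
#' @return ICD in mm.
#' @export
intercommissuralDistance <- function(ring, apdAxis) {
  stopifnot(is(ring, "AnnulusRing"))
  n <- sqrt(sum(apdAxis^2))
  if (!is.finite(n) || n < 1e-12) stop("apdAxis must be a non-zero in-plane direction")
  apdAxis <- apdAxis / n
  w <- c(-apdAxis[2L], apdAxis[1L])
  xy <- .projectToPlane(ring@curve, ring@planeOrigin, ring@planeNormal)
  proj <- xy %*% w
  max(proj) - min(proj)
}

#' Trigone-to-trigone distance (TTD)
#'
#' Straight 3D Euclidean distance between the two flagged trigone markers.
#'
#' @param landmarks an [AnnulusLandmarkSet-class].
#' @return TTD in mm.
#' @export
trigoneDistance <- function(landmarks) {
  stopifnot(is(landmarks, "AnnulusLandmarkSet"))
  ti <- landmarks@trigoneIndices
  sqrt(sum((landmarks@markers[ti[1L], ] - landmarks@markers[ti[2L], ])^2))
}

#' Sphericity index (SI)
#'
#' SI = APD / ICD: values near 1 indicate a circular (spherical) annulus,
#' smaller values an annulus elongated along the intercommissural axis.
#'
#' @param APD aortoparietal distance (mm).
#' @param ICD intercommissural distance (mm), must be positive.
#' @return dimensionless SI.
#' @export
sphericityIndex <- function(APD, ICD) {
  if (any(ICD <= 0)) stop("ICD must be positive")
  APD / ICD
}

#' Leaflet-to-annulus index (LAI)
#'
#' LAI = TLL / APD at late systole, where TLL is the summed aortic and
#' parietal leaflet length. A coaptation-reserve measure: larger values mean
#' more leaflet tissue per unit annular dimension.
#'
#' @param leaflets a [LeafletMeasurement-class] (phase must be `"LS"`).
#' @param APD late-systolic aortoparietal distance (mm), must be positive.
#' @return dimensionless LAI.
#' @export
leafletAnnulusIndex <- function(leaflets, APD) {
  stopifnot(is(leaflets, "LeafletMeasurement"))
  validObject(leaflets)
  if (APD <= 0) stop("APD must be positive")
  (leaflets@aorticLeafletLength + leaflets@parietalLeafletLength) / APD
}

#' Full annular metric panel for one landmark set
#'
#' Facade chaining [resampleRing()], [annulusArea()],
#' [aortoparietalDistance()], [intercommissuralDistance()],
#' [trigoneDistance()] and [sphericityIndex()] (plus
#' [leafletAnnulusIndex()] when leaflet lengths are supplied, which requires
#' the landmark set to be at late systole). Deterministic for fixed input
#' and `M`.
#'
#' @param landmarks an [AnnulusLandmarkSet-class].
#' @param leaflets optional [LeafletMeasurement-class] for the LAI.
#' @param M resample size passed to [resampleRing()].
#' @return one-row data.frame: subject_id, visit, phase, MAA (mm^2), APD,
#'   ICD, TTD (mm), SI, TLL, LAI (NA without leaflets), self_intersecting.
#' @examples
#' th <- 2 * pi * (0:15) / 16
#' lm <- AnnulusLandmarkSet(cbind(6 * cos(th), 6.5 * sin(th), cos(2 * th)),
#'                          trigoneIndices = c(3L, 15L))
#' annulusMetrics(lm)
#' @export
annulusMetrics <- function(landmarks, leaflets = NULL, M = 512L) {
  ring <- resampleRing(landmarks, M = M)
  maa <- annulusArea(ring)
  apd <- aortoparietalDistance(ring)
  icd <- intercommissuralDistance(ring, apd$axis)
  ttd <- trigoneDistance(landmarks)
  tll <- NA_real_; lai <- NA_real_
  if (!is.null(leaflets)) {
    if (!identical(landmarks@phase, "LS"))
      stop("LAI requires a late-systolic (LS) landmark set")
    tll <- leaflets@aorticLeafletLength + leaflets@parietalLeafletLength
    lai <- leafletAnnulusIndex(leaflets, apd$APD)
  }
  data.frame(subject_id = landmarks@subjectId, visit = landmarks@visit,
             phase = landmarks@phase, MAA = maa, APD = apd$APD, ICD = icd,
             TTD = ttd, SI = sphericityIndex(apd$APD, icd),
             TLL = tll, LAI = lai,
             self_intersecting = ring@selfIntersecting,
             stringsAsFactors = FALSE)
}
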