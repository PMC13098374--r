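test_that("ring reconstruction interpolates a planar circle to within 0.1 mm", {
  lm <- AnnulusLandmarkSet(saddlePoints(10, 10, 0, 16),
                           trigoneIndices = c(15L, 3L))
  ring <- resampleRing(lm)
  radii <- sqrt(rowSums(ringCurve(ring)[, 1:2]^2))
  expect_lt(max(abs(radii - 10)), 0.1)
  expect_equal(annulusArea(ring), pi * 100, tolerance = 0.01)
  apd <- aortoparietalDistance(ring)
  icd <- intercommissuralDistance(ring, apd$axis)
  expect_equal(apd$APD, 20, tolerance = 0.01)
  expect_equal(icd, 20, tolerance = 0.01)
})

test_that("best-fit plane normal of a symmetric saddle is the z axis", {
  lm <- AnnulusLandmarkSet(saddlePoints(6, 6.5, 1, 16),
                           trigoneIndices = c(15L, 3L))
  ring <- resampleRing(lm)
  expect_lt(min(sum((planeNormal(ring) - c(0, 0, 1))^2),
                sum((planeNormal(ring) + c(0, 0, 1))^2)), 1e-12)
  ## winding is CCW from +z, so the oriented normal is +z
  expect_equal(planeNormal(ring), c(0, 0, 1), tolerance = 1e-6)
})

test_that("metric panel matches saddle closed forms within 1%", {
  cases <- list(c(6, 6.5, 1), c(12.5, 10, 3), c(5, 7, 0.5))
  for (p in cases) {
    a <- p[1]; b <- p[2]; h <- p[3]
    m <- annulusMetrics(annulusFromParams(a, b, h, trigoneAngles = c(-1, 1)))
    expect_equal(m$MAA, pi * a * b, tolerance = 0.01)
    expect_equal(m$APD, 2 * a, tolerance = 0.01)
    expect_equal(m$ICD, 2 * b, tolerance = 0.01)
    expect_equal(m$SI, a / b, tolerance = 0.01)
    ## projected area is independent of saddle height
    mFlat <- annulusMetrics(annulusFromParams(a, b, 0, trigoneAngles = c(-1, 1)))
    expect_equal(m$MAA, mFlat$MAA, tolerance = 0.01)
  }
})

test_that("projected area agrees with a dense analytic polygon oracle", {
  mEll <- annulusMetrics(annulusFromParams(12.5, 10, 0, trigoneAngles = c(-1, 1)))
  expect_equal(mEll$MAA, 392.70, tolerance = 0.01)
  expect_equal(mEll$MAA, densePolygonArea(12.5, 10, 0), tolerance = 0.01)
  mSad <- annulusMetrics(annulusFromParams(12.5, 10, 3, trigoneAngles = c(-1, 1)))
  expect_equal(mSad$MAA, densePolygonArea(12.5, 10, 3), tolerance = 0.01)
})

test_that("metrics are rigid-motion invariant to 1e-9 relative", {
  base <- annulusFromParams(6, 6.5, 1, trigoneAngles = c(-1, 1))
  m0 <- annulusMetrics(base)
  angles <- list(c(0.3, -1.1, 2.0), c(-2.4, 0.7, 0.1), c(1.2, 1.2, -0.5))
  for (i in seq_along(angles)) {
    tf <- rigidFromAngles(angles[[i]][1], angles[[i]][2], angles[[i]][3],
                          t = c(10 * i, -5 * i, 3 * i))
    lm <- AnnulusLandmarkSet(applyRigidTransform(markers(base), tf),
                             trigoneIndices(base))
    m1 <- annulusMetrics(lm)
    for (v in c("MAA", "APD", "ICD", "TTD", "SI"))
      expect_lt(abs(m1[[v]] - m0[[v]]) / m0[[v]], 1e-9)
  }
})

test_that("metrics scale correctly under coordinate scaling", {
  base <- annulusFromParams(6, 6.5, 1, trigoneAngles = c(-1, 1))
  m0 <- annulusMetrics(base)
  s <- 2.37
  lm <- AnnulusLandmarkSet(s * markers(base), trigoneIndices(base))
  m1 <- annulusMetrics(lm)
  expect_equal(m1$APD, s * m0$APD, tolerance = 1e-9)
  expect_equal(m1$ICD, s * m0$ICD, tolerance = 1e-9)
  expect_equal(m1$TTD, s * m0$TTD, tolerance = 1e-9)
  expect_equal(m1$MAA, s^2 * m0$MAA, tolerance = 1e-9)
  expect_equal(m1$SI, m0$SI, tolerance = 1e-9)
})

test_that("flat-ring fallback axis recovers the aortoparietal distance", {
  lm <- annulusFromParams(6, 6.5, 0, trigoneAngles = c(-1, 1))
  ring <- resampleRing(lm)
  apd <- aortoparietalDistance(ring)
  expect_identical(apd$method, "flat_axis")
  expect_equal(apd$APD, 12, tolerance = 0.01)
  ## saddle route uses horn elevations instead
  ring2 <- resampleRing(annulusFromParams(6, 6.5, 1, trigoneAngles = c(-1, 1)))
  expect_identical(aortoparietalDistance(ring2)$method, "elevation")
})

test_that("APD and MAA increase strictly with the aortoparietal semi-axis", {
  ms <- lapply(c(5, 6, 7), function(a)
    annulusMetrics(annulusFromParams(a, 6.5, 1, trigoneAngles = c(-1, 1))))
  apds <- vapply(ms, function(m) m$APD, numeric(1))
  maas <- vapply(ms, function(m) m$MAA, numeric(1))
  expect_true(all(diff(apds) > 0))
  expect_true(all(diff(maas) > 0))
})

test_that("trigone distance is the 3D chord between the flagged markers", {
  m <- saddlePoints(10, 10, 0, 16)
  m[1L, ] <- c(0, 0, 0); m[9L, ] <- c(6, 0, 0)
  ## direct placement of the two trigones
  lm <- AnnulusLandmarkSet(m, trigoneIndices = c(1L, 9L))
  expect_equal(trigoneDistance(lm), 6)
  ## synthetic saddle: chord from the parametrisation at the marker angles
  lm2 <- annulusFromParams(6, 6.5, 1, trigoneAngles = c(-1, 1))
  th <- 2 * pi * (trigoneIndices(lm2) - 1L) / 16
  expected <- sqrt((6 * (cos(th[1]) - cos(th[2])))^2 +
                   (6.5 * (sin(th[1]) - sin(th[2])))^2 +
                   (1 * (cos(2 * th[1]) - cos(2 * th[2])))^2)
  expect_equal(trigoneDistance(lm2), expected, tolerance = 1e-12)
})

test_that("sphericity and leaflet-annulus indices follow their definitions", {
  expect_equal(sphericityIndex(10, 10), 1)
  expect_equal(round(sphericityIndex(10.96, 11.32), 2), 0.97)
  expect_error(sphericityIndex(10, 0), "ICD")
  lf <- LeafletMeasurement(8, 7)
  expect_equal(leafletAnnulusIndex(lf, 12), 1.25)
  expect_equal(leafletAnnulusIndex(LeafletMeasurement(6, 6), 12), 1)
  expect_error(leafletAnnulusIndex(lf, 0), "APD")
  expect_error(LeafletMeasurement(8, 7, phase = "ES"), "late systole")
  ## LAI through the facade requires a late-systolic landmark set
  lmES <- annulusFromParams(6, 6.5, 1, phase = "ES")
  expect_error(annulusMetrics(lmES, leaflets = lf), "LS")
  lmLS <- annulusFromParams(6, 6.5, 1, phase = "LS")
  m <- annulusMetrics(lmLS, leaflets = lf)
  expect_equal(m$TLL, 15)
  expect_equal(m$LAI, 15 / m$APD, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected and crossings flagged", {
  m <- saddlePoints(10, 10, 0, 16)
  m[2L, ] <- m[1L, ]
  expect_error(AnnulusLandmarkSet(m, c(1L, 9L)), "coincide")
  expect_error(resampleRing(annulusFromParams(6, 6.5, 1), M = 32), "M must be")
  ## swapped arc ordering makes the projected curve cross itself
  cross <- saddlePoints(10, 10, 0, 16)[c(1:8, 10, 9, 11:16), ]
  lmX <- AnnulusLandmarkSet(cross, c(15L, 3L))
  expect_warning(ringX <- resampleRing(lmX), "self-intersects")
  expect_true(ringX@selfIntersecting)
  expect_gt(annulusArea(ringX), 0)
})
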