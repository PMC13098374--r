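## Low-level 3D geometry helpers shared by the annulus modules.
## All coordinates are millimetres in an arbitrary device frame.

#' Total-least-squares plane fit
#'
#' Fits the plane minimising orthogonal distances to a point cloud (the
#' smallest principal axis of the centred points).
#'
#' @param pts numeric matrix, n x 3.
#' @return list with `origin` (centroid) and unit `normal`.
#' @keywords internal
.fitPlane <- function(pts) {
  origin <- colMeans(pts)
  ctr <- sweep(pts, 2L, origin)
  e <- eigen(crossprod(ctr), symmetric = TRUE)
  normal <- e$vectors[, 3L]
  list(origin = origin, normal = normal / sqrt(sum(normal^2)))
}

## Orient `normal` so the closed curve winds counter-clockwise about it
## (right-hand rule); with markers ordered CCW from the atrial view this
## points the normal toward the left atrium.
.orientNormal <- function(curve, origin, normal) {
  r <- sweep(curve, 2L, origin)
  r2 <- rbind(r[-1L, , drop = FALSE], r[1L, , drop = FALSE])
  areaVec <- 0.5 * colSums(cbind(
    r[, 2L] * r2[, 3L] - r[, 3L] * r2[, 2L],
    r[, 3L] * r2[, 1L] - r[, 1L] * r2[, 3L],
    r[, 1L] * r2[, 2L] - r[, 2L] * r2[, 1L]))
  if (sum(areaVec * normal) < 0) -normal else normal
}

## Orthonormal in-plane basis (u, v) with u x v = normal.
.planeBasis <- function(normal) {
  seed <- if (abs(normal[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- seed - sum(seed * normal) * normal
  u <- u / sqrt(sum(u^2))
  v <- c(normal[2L] * u[3L] - normal[3L] * u[2L],
         normal[3L] * u[1L] - normal[1L] * u[3L],
         normal[1L] * u[2L] - normal[2L] * u[1L])
  ## v = n x u so that (u, v, n) is right-handed and u x v = n
  rbind(u, v)
}

## Project 3D points into plane coordinates (n x 2).
.projectToPlane <- function(pts, origin, normal, basis = .planeBasis(normal)) {
  ctr <- sweep(pts, 2L, origin)
  cbind(ctr %*% basis[1L, ], ctr %*% basis[2L, ])
}

## Signed shoelace area of a closed 2D polygon (vertices not repeated).
.polygonArea <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  0.5 * sum(x * yn - xn * y)
}

## Proper segment-crossing test (shared endpoints of adjacent polygon edges
## are excluded by the caller). Vectorised over segment pairs.
.segmentsCross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) {
    (b[, 1L] - a[, 1L]) * (c[, 2L] - a[, 2L]) -
      (b[, 2L] - a[, 2L]) * (c[, 1L] - a[, 1L])
  }
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

## TRUE if the closed polygon self-intersects (tested on up to `maxVertices`
## evenly subsampled vertices; degenerate landmarking detector, not an exact
## computational-geometry routine).
.polygonSelfIntersects <- function(xy, maxVertices = 128L) {
  n <- nrow(xy)
  if (n > maxVertices) {
    xy <- xy[round(seq(1L, n, length.out = maxVertices + 1L))[-(maxVertices + 1L)], , drop = FALSE]
    n <- nrow(xy)
  }
  nxt <- c(seq_len(n)[-1L], 1L)
  idx <- utils::combn(n, 2L)
  i <- idx[1L, ]; j <- idx[2L, ]
  ## skip adjacent edges (share a vertex)
  keep <- (j - i > 1L) & !(i == 1L & j == n)
  i <- i[keep]; j <- j[keep]
  if (!length(i)) return(FALSE)
  any(.segmentsCross(xy[i, , drop = FALSE], xy[nxt[i], , drop = FALSE],
                     xy[j, , drop = FALSE], xy[nxt[j], , drop = FALSE]))
}

#' Random rigid transform
#'
#' Draws a uniformly random rotation (QR of a Gaussian matrix, determinant
#' fixed to +1) and a Gaussian translation from the current RNG stream.
#'
#' @param translationSD standard deviation (mm) of each translation component.
#' @return list with 3x3 rotation `R` and length-3 translation `t`.
#' @export
randomRigidTransform <- function(translationSD = 20) {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  R <- qr.Q(qr_)
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  list(R = R, t = stats::rnorm(3L, sd = translationSD))
}

#' Apply a rigid transform to points
#'
#' @param pts n x 3 matrix.
#' @param transform list with rotation `R` and translation `t`.
#' @return transformed n x 3 matrix.
#' @export
applyRigidTransform <- function(pts, transform) {
  sweep(pts %*% t(transform$R), 2L, -transform$t)
}
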