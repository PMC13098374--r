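## Independent oracles used across the suite. These deliberately avoid the
## package's reconstruction path: analytic parametrisations evaluated
## densely, brute-force enumeration, and closed-form statistics.

## markers/points on the saddle curve (a cos t, b sin t, h cos 2t)
saddlePoints <- function(a, b, h, n) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(a * cos(th), b * sin(th), h * cos(2 * th))
}

## brute-force projected area: shoelace on n points of the analytic curve
## projected onto z = 0 (the symmetry plane of the family)
densePolygonArea <- function(a, b, h, n = 1e5) {
  p <- saddlePoints(a, b, h, n)
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(0.5 * sum(x * yn - xn * y))
}

## exact two-sided signed-rank p by full 2^m sign enumeration
## (zeros dropped, midranks), independent of the package's DP routine
enumSignedRankP <- function(diffs) {
  d <- diffs[diffs != 0]
  m <- length(d)
  r <- rank(abs(d))
  Wobs <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  W <- as.vector(signs %*% r)
  mean(abs(W - mu) >= abs(Wobs - mu) - 1e-9)
}

## deterministic rigid transform from explicit angles (no RNG dependence)
rigidFromAngles <- function(ax, ay, az, t = c(0, 0, 0)) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  list(R = Rz %*% Ry %*% Rx, t = t)
}

## long-format helper: paired measurement table for a variable
pairedLong <- function(pre, post, variable = "v", phase = NA_character_) {
  n <- length(pre)
  ids <- sprintf("S%02d", seq_len(n))
  data.frame(subject_id = rep(ids, 2L),
             visit = rep(c("pre", "post"), each = n),
             phase = phase, variable = variable,
             value = c(pre, post), stringsAsFactors = FALSE)
}
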