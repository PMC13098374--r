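## Mitral-annular-dynamics profiles: per-phase metric series and the
## classification of systolic annular behaviour.

#' Assemble a mitral-annular-dynamics profile
#'
#' Orders per-phase metric rows (as produced by [annulusMetrics()]) into a
#' profile for one subject/visit. At least ED and ES must be present;
#' missing phases are simply absent, never interpolated.
#'
#' @param metricsByPhase data.frame with a `phase` column and metric columns
#'   (all rows must share one subject/visit).
#' @return a [MADProfile-class].
#' @export
buildMADProfile <- function(metricsByPhase) {
  stopifnot(is.data.frame(metricsByPhase), "phase" %in% names(metricsByPhase))
  if (anyDuplicated(metricsByPhase$phase))
    stop("duplicate phase entries in profile input")
  sid <- if ("subject_id" %in% names(metricsByPhase))
    as.character(metricsByPhase$subject_id[1L]) else "subject"
  vis <- if ("visit" %in% names(metricsByPhase))
    as.character(metricsByPhase$visit[1L]) else "pre"
  ord <- order(match(metricsByPhase$phase, .PHASE_LEVELS))
  series <- metricsByPhase[ord, , drop = FALSE]
  rownames(series) <- NULL
  lai <- NA_real_
  if ("LAI" %in% names(series) && "LS" %in% series$phase) {
    v <- series$LAI[series$phase == "LS"]
    if (!is.na(v)) lai <- v
  }
  new("MADProfile", subjectId = sid, visit = vis, series = series, lai = lai)
}

#' Classify systolic annular behaviour
#'
#' Compares a metric at end systole against end diastole: relative change
#' (ES - ED)/ED above `tolerance` is systolic `"expansion"` (the abnormal
#' pattern of degenerative mitral valve disease), below `-tolerance` is
#' `"contraction"` (the normal pattern), otherwise `"none"`. The
#' classification is invariant to allometric indexing since the denominators
#' cancel in the ratio.
#'
#' @param profile a [MADProfile-class] containing ED and ES.
#' @param metric one of `"MAA"`, `"APD"`, `"ICD"`, `"TTD"`.
#' @param tolerance dead-band on the relative change (default 0.01, i.e. 1%),
#'   guarding per-subject calls against noise-driven sign flips.
#' @return list with `classification`, `delta` (ES - ED) and `relativeChange`.
#' @export
systolicBehavior <- function(profile, metric = c("MAA", "APD", "ICD", "TTD"),
                             tolerance = 0.01) {
  stopifnot(is(profile, "MADProfile"))
  metric <- match.arg(metric)
  s <- profile@series
  if (!all(c("ED", "ES") %in% s$phase)) stop("profile must contain ED and ES")
  ed <- s[[metric]][s$phase == "ED"]
  es <- s[[metric]][s$phase == "ES"]
  rel <- (es - ed) / ed
  cls <- if (rel > tolerance) "expansion"
         else if (rel < -tolerance) "contraction"
         else "none"
  list(classification = cls, delta = es - ed, relativeChange = rel)
}

#' Phase at which a metric is minimal
#'
#' Ties are broken toward the earlier phase in cycle order.
#'
#' @param profile a [MADProfile-class].
#' @param metric metric column name in the profile series.
#' @return the phase label (character scalar).
#' @export
phaseOfMinimum <- function(profile, metric = "MAA") {
  stopifnot(is(profile, "MADProfile"))
  s <- profile@series
  if (!metric %in% names(s)) stop(sprintf("metric '%s' not in profile", metric))
  ## series rows are already in cycle order; which.min takes the first tie
  s$phase[which.min(s[[metric]])]
}

#' Plot a mitral-annular-dynamics profile
#'
#' Simple base-graphics phase series of one metric for one or more profiles.
#'
#' @param profiles list of [MADProfile-class] objects (e.g. pre and post).
#' @param metric metric column to plot.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the plotted matrix (phase x profile).
#' @export
plotMADProfile <- function(profiles, metric = "MAA", ...) {
  if (is(profiles, "MADProfile")) profiles <- list(profiles)
  phases <- .PHASE_LEVELS
  mat <- vapply(profiles, function(p) {
    s <- p@series
    v <- rep(NA_real_, length(phases))
    v[match(s$phase, phases)] <- s[[metric]]
    v
  }, numeric(length(phases)))
  graphics::matplot(seq_along(phases), mat, type = "b", pch = 19,
                    xaxt = "n", xlab = "cardiac phase", ylab = metric, ...)
  graphics::axis(1, at = seq_along(phases), labels = phases)
  invisible(mat)
}
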