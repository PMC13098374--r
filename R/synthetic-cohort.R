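## Synthetic paired-cohort generator with known ground truth.
##
## The annulus is simulated from the saddle family
##   x = a cos(theta), y = b sin(theta), z = h cos(2 theta),
## the simplest closed curve with two elevated horns (theta = 0, pi) and two
## commissural lows, whose metric panel has closed forms (MAA -> pi*a*b,
## APD -> 2a, ICD -> 2b, SI -> a/b). Semi-axes are parametrised in indexed
## units (mm/kg^(1/3)) so that indexed summary statistics are body-weight
## independent by construction; per-subject millimetre coordinates are
## recovered by multiplying with BW^(1/3).

.BSA_SCALE <- 100 * 0.101  # mm^2 -> cm^2/m^2 conversion built into MAAi

#' Default synthetic-cohort configuration
#'
#' Defaults emulate a preclinical-MMVD cohort of 20 dogs with paired
#' pre/post visits: body weight uniform on 4.3-19.6 kg; per-phase indexed
#' saddle semi-axes whose closed-form metrics match the pre-treatment
#' indexed annular panel (end-systolic APDi ~ 11 mm/kg^(1/3) with systolic
#' expansion relative to ED); volumes built from LVEDVi 4.21 mL/kg, total
#' EF 0.64 and regurgitant fraction 0.371; oscillometric pressures around
#' MBP 89.5 mmHg; and post-treatment effects that contract the systolic
#' annulus (ES semi-axis multipliers 0.906/0.934, i.e. programmed indexed
#' ES APD and ICD reductions of 1.03 and 0.75) and reduce volumes and RF
#' while leaving diastolic annulus geometry, the trigone chord and
#' pressures unchanged.
#'
#' @param n_subjects number of subjects (default 20).
#' @return nested configuration list (phases, volumes, pressures, effects,
#'   noise, trigone angles).
#' @export
defaultCohortConfig <- function(n_subjects = 20L) {
  list(
    n_subjects = as.integer(n_subjects),
    bw_range = c(4.3, 19.6),
    n_markers = 16L,
    trigone_angles = c(-pi / 4, pi / 4),
    phases = data.frame(
      phase = c("MD", "LD", "ED", "MS", "LS", "ES"),
      a_i = c(10.68, 10.85, 9.75, 10.52, 10.74, 10.96) / 2,
      b_i = c(12.10, 12.17, 11.18, 11.57, 11.45, 11.32) / 2,
      h_i = 1.2,
      stringsAsFactors = FALSE),
    leaflets = list(aortic_i = 7.8, parietal_i = 5.2),
    volumes = list(LVEDVi = 4.21, EF = 0.6401, RF = 0.371,
                   LAESVi = 1.94, LAEDVi = 0.96),
    pressures = list(MBP = 89.5, SAP = 120, DAP = 75),
    aorta = list(frac_change = 0.242, area_coef = 30),
    av_csa_coef = 0.30,
    effects = list(
      a_mult = c(MD = 1, LD = 1, ED = 1, MS = 1, LS = 0.950, ES = 0.906),
      b_mult = c(MD = 1, LD = 1, ED = 1, MS = 0.976, LS = 0.955, ES = 0.934),
      d_LVEDVi = -0.52, d_LVESVi = -0.28, d_RF = -0.0975,
      d_LAESVi = -0.43, d_LAEDVi = -0.18,
      d_TLLi = 0, d_MBP = 0, d_frac = 0),
    noise = list(
      marker_sd_mm = 0.3,
      axis_subject_sd = 0.55, axis_visit_sd = 0.35, h_visit_sd = 0.1,
      tll_subject_sd = 0.9, tll_visit_sd = 0.35,
      edv_subject_sd = 0.55, edv_visit_sd = 0.40,
      esv_visit_sd = 0.12, ef_subject_sd = 0.03,
      rf_subject_sd = 0.08, rf_visit_sd = 0.05,
      lafill_subject_sd = 0.25, lafill_visit_sd = 0.15,
      laedv_subject_sd = 0.25, laedv_visit_sd = 0.10,
      mbp_subject_sd = 15, mbp_visit_sd = 10, pp_visit_sd = 5,
      frac_subject_sd = 0.04, frac_visit_sd = 0.03, area_visit_sd = 5),
    rigid_transforms = TRUE)
}

#' Configuration scaled for null or noiseless experiments
#'
#' Helpers deriving special-case configurations from a base configuration:
#' `nullEffectConfig()` removes every programmed treatment effect;
#' `noiselessConfig()` zeroes every noise source (marker jitter, visit and
#' subject variation).
#'
#' @param config base configuration (default [defaultCohortConfig()]).
#' @return modified configuration list.
#' @export
nullEffectConfig <- function(config = defaultCohortConfig()) {
  config$effects$a_mult[] <- 1
  config$effects$b_mult[] <- 1
  for (nm in c("d_LVEDVi", "d_LVESVi", "d_RF", "d_LAESVi", "d_LAEDVi",
               "d_TLLi", "d_MBP", "d_frac"))
    config$effects[[nm]] <- 0
  config
}

#' @rdname nullEffectConfig
#' @export
noiselessConfig <- function(config = defaultCohortConfig()) {
  config$noise[] <- lapply(config$noise, function(x) 0)
  config
}

#' Synthetic annulus landmark set from saddle parameters
#'
#' Places `nMarkers` markers at equal parameter angles on the saddle curve
#' (a cos(theta), b sin(theta), h cos(2 theta)), flags the two markers
#' nearest the trigone angles as trigones, adds isotropic Gaussian jitter,
#' and optionally applies a rigid transform. All randomness comes from the
#' current RNG stream, so a fixed seed gives bit-identical output.
#'
#' @param a,b,h saddle semi-axes and height (mm), all > 0 (h >= 0).
#' @param trigoneAngles two parameter angles (radians) flanking the aortic
#'   horn at theta = 0.
#' @param nMarkers number of markers (default 16).
#' @param jitter isotropic Gaussian marker jitter SD (mm), >= 0.
#' @param transform `NULL` (identity), `"random"` (seeded random rigid
#'   transform) or a list with `R` and `t`.
#' @param pin optional list (`a`, `b`, `h`) of alternative saddle parameters
#'   used for the trigone markers only, modelling the fibrous (fixed)
#'   trigones when the muscular annulus is rescaled.
#' @param subjectId,visit,phase identifiers for the landmark set.
#' @return an [AnnulusLandmarkSet-class].
#' @examples
#' lm <- annulusFromParams(6, 6.5, 1)
#' annulusMetrics(lm)[, c("MAA", "APD", "ICD", "SI")]  # ~ pi*6*6.5, 12, 13
#' @export
annulusFromParams <- function(a, b, h, trigoneAngles = c(-pi / 4, pi / 4),
                              nMarkers = 16L, jitter = 0, transform = NULL,
                              pin = NULL, subjectId = "synthetic",
                              visit = "pre", phase = "ES") {
  if (a <= 0 || b <= 0 || h < 0) stop("saddle parameters must be positive (h >= 0)")
  if (jitter < 0) stop("jitter must be non-negative")
  theta <- 2 * pi * (seq_len(nMarkers) - 1L) / nMarkers
  angDist <- function(x, y) {
    d <- abs(x - y) %% (2 * pi)
    pmin(d, 2 * pi - d)
  }
  ti <- vapply(trigoneAngles, function(ang)
    which.min(angDist(theta, ang)), integer(1L))
  if (ti[1L] == ti[2L]) stop("trigone angles map to the same marker")
  m <- cbind(a * cos(theta), b * sin(theta), h * cos(2 * theta))
  if (!is.null(pin))
    m[ti, ] <- cbind(pin$a * cos(theta[ti]), pin$b * sin(theta[ti]),
                     pin$h * cos(2 * theta[ti]))
  if (jitter > 0)
    m <- m + matrix(stats::rnorm(3L * nMarkers, sd = jitter), nMarkers, 3L)
  if (!is.null(transform)) {
    if (identical(transform, "random")) transform <- randomRigidTransform()
    m <- applyRigidTransform(m, transform)
  }
  AnnulusLandmarkSet(m, trigoneIndices = ti, subjectId = subjectId,
                     visit = visit, phase = phase)
}

#' Post-treatment annulus truth parameters
#'
#' Applies the programmed treatment effect to the per-phase saddle
#' parameter table: semi-axes are multiplied by the phase-specific effect
#' multipliers (1 at diastolic phases by default), leaving saddle height
#' unchanged. The trigone chord is held fixed separately (the generator pins
#' trigone markers at their unmultiplied positions).
#'
#' @param phases per-phase parameter data.frame (columns phase, a_i, b_i,
#'   h_i), as in [defaultCohortConfig()].
#' @param effects effects list with named `a_mult` and `b_mult` vectors.
#' @return the post-treatment phase table.
#' @export
applyTreatmentEffect <- function(phases, effects) {
  if (any(effects$a_mult <= 0) || any(effects$b_mult <= 0))
    stop("effect multipliers must be positive")
  phases$a_i <- phases$a_i * unname(effects$a_mult[phases$phase])
  phases$b_i <- phases$b_i * unname(effects$b_mult[phases$phase])
  phases
}

## run expr with a fixed seed, restoring the caller's RNG state afterwards
.withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

.checkCohortConfig <- function(config) {
  v <- config$volumes
  if (config$n_subjects < 3L) stop("n_subjects must be at least 3")
  if (v$EF <= 0 || v$EF >= 1) stop("infeasible config: EF must be in (0, 1)")
  if (v$RF <= 0 || v$RF >= 1) stop("infeasible config: RF must be in (0, 1)")
  rfPost <- v$RF + config$effects$d_RF
  if (rfPost <= 0 || rfPost >= 1)
    stop("infeasible config: post-treatment RF must be in (0, 1)")
  if (any(unlist(config$phases[, c("a_i", "b_i")]) <= 0) ||
      any(config$phases$h_i < 0))
    stop("infeasible config: saddle parameters must be positive")
  if (any(config$effects$a_mult <= 0) || any(config$effects$b_mult <= 0))
    stop("effect multipliers must be positive")
  if (any(unlist(config$noise) < 0)) stop("noise SDs must be non-negative")
  invisible(TRUE)
}

#' Generate a synthetic paired cohort
#'
#' Simulates `n` subjects with paired pre/post visits. Subject-level random
#' effects (annulus size, EF, RF, volumes, pressures) are shared between
#' visits, giving the paired structure; post-treatment effects are applied
#' to the truth; measurement noise is added last. Volumes are built so that
#' LV TSV = RV TSV + RVol holds exactly before noise (RV TSV is derived as
#' TSV x (1 - RF)), and the echo forward stroke volume (VTI x AV CSA)
#' equals the RV TSV. With `landmarks = TRUE` every subject/visit/phase is
#' also realised as a 16-marker landmark set (jittered, randomly rigidly
#' transformed); trigone markers of post visits are pinned at their
#' unmultiplied positions, so the trigone chord carries no treatment effect.
#'
#' @param config configuration list, see [defaultCohortConfig()].
#' @param seed integer RNG seed; identical config + seed gives a
#'   bit-identical cohort.
#' @param landmarks generate landmark sets (TRUE) or measurement-level
#'   records only (FALSE; faster, used for large simulation studies).
#' @return a [SyntheticCohort-class].
#' @examples
#' coh <- generateCohort(defaultCohortConfig(5), seed = 1, landmarks = FALSE)
#' head(cohortRecords(coh))
#' @export
generateCohort <- function(config = defaultCohortConfig(), seed = 1L,
                           landmarks = TRUE) {
  .checkCohortConfig(config)
  .withSeed(seed, {
    n <- config$n_subjects
    ns <- config$noise
    ph <- config$phases
    nPhase <- nrow(ph)
    subjects <- data.frame(
      subject_id = sprintf("S%02d", seq_len(n)),
      BW_kg = stats::runif(n, config$bw_range[1L], config$bw_range[2L]),
      stringsAsFactors = FALSE)
    subjects$BSA_m2 <- canineBSA(subjects$BW_kg)

    ## subject-level random effects (shared pre/post)
    sAxis <- stats::rnorm(n, 0, ns$axis_subject_sd)
    sTLL <- stats::rnorm(n, 0, ns$tll_subject_sd)
    efSub <- stats::rnorm(n, config$volumes$EF, ns$ef_subject_sd)
    rfSub <- stats::rnorm(n, config$volumes$RF, ns$rf_subject_sd)
    sEDV <- stats::rnorm(n, 0, ns$edv_subject_sd)
    sLAFill <- stats::rnorm(n, 0, ns$lafill_subject_sd)
    sLAEDV <- stats::rnorm(n, 0, ns$laedv_subject_sd)
    sMBP <- stats::rnorm(n, 0, ns$mbp_subject_sd)
    sFrac <- stats::rnorm(n, 0, ns$frac_subject_sd)

    ## ---- annulus truth + measurement (long over subject x visit x phase)
    grid <- expand.grid(phaseIdx = seq_len(nPhase), visit = .VISIT_LEVELS,
                        subjIdx = seq_len(n), stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    aMult <- ifelse(grid$visit == "post",
                    unname(config$effects$a_mult[ph$phase[grid$phaseIdx]]), 1)
    bMult <- ifelse(grid$visit == "post",
                    unname(config$effects$b_mult[ph$phase[grid$phaseIdx]]), 1)
    eA <- stats::rnorm(nrow(grid), 0, ns$axis_visit_sd)
    eB <- stats::rnorm(nrow(grid), 0, ns$axis_visit_sd)
    eH <- stats::rnorm(nrow(grid), 0, ns$h_visit_sd)
    aPin <- ph$a_i[grid$phaseIdx] + sAxis[grid$subjIdx] + eA
    bPin <- ph$b_i[grid$phaseIdx] + sAxis[grid$subjIdx] + eB
    aMeas <- (ph$a_i[grid$phaseIdx] + sAxis[grid$subjIdx]) * aMult + eA
    bMeas <- (ph$b_i[grid$phaseIdx] + sAxis[grid$subjIdx]) * bMult + eB
    hMeas <- pmax(ph$h_i[grid$phaseIdx] + eH, 0)
    if (any(aMeas <= 0) || any(bMeas <= 0))
      stop("infeasible config: noise produced non-positive semi-axes")

    ## trigone chord from pinned (unmultiplied) parameters at the marker
    ## grid angles nearest the trigone angles
    theta <- 2 * pi * (seq_len(config$n_markers) - 1L) / config$n_markers
    angDist <- function(x, y) { d <- abs(x - y) %% (2 * pi); pmin(d, 2 * pi - d) }
    tIdx <- vapply(config$trigone_angles, function(ang)
      which.min(angDist(theta, ang)), integer(1L))
    t1 <- theta[tIdx[1L]]; t2 <- theta[tIdx[2L]]
    ttdI <- sqrt((aPin * (cos(t1) - cos(t2)))^2 +
                 (bPin * (sin(t1) - sin(t2)))^2 +
                 (hMeas * (cos(2 * t1) - cos(2 * t2)))^2)

    annulus <- data.frame(
      subject_id = subjects$subject_id[grid$subjIdx],
      visit = grid$visit, phase = ph$phase[grid$phaseIdx],
      a_i = aMeas, b_i = bMeas, h_i = hMeas, a_pin_i = aPin, b_pin_i = bPin,
      APDi = 2 * aMeas, ICDi = 2 * bMeas,
      MAAi = pi * aMeas * bMeas / .BSA_SCALE,
      TTDi = ttdI, SI = aMeas / bMeas, stringsAsFactors = FALSE)

    ## ---- per subject x visit measurement records
    rec <- expand.grid(visit = .VISIT_LEVELS, subjIdx = seq_len(n),
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    post <- rec$visit == "post"
    ef <- config$effects
    bw <- subjects$BW_kg[rec$subjIdx]
    edvI <- config$volumes$LVEDVi + sEDV[rec$subjIdx] +
      ifelse(post, ef$d_LVEDVi, 0) + stats::rnorm(nrow(rec), 0, ns$edv_visit_sd)
    esvI <- (config$volumes$LVEDVi + sEDV[rec$subjIdx]) *
      (1 - efSub[rec$subjIdx]) + ifelse(post, ef$d_LVESVi, 0) +
      stats::rnorm(nrow(rec), 0, ns$esv_visit_sd)
    if (any(esvI <= 0) || any(esvI >= edvI))
      stop("infeasible config: generated LVESV outside (0, LVEDV)")
    rf <- rfSub[rec$subjIdx] + ifelse(post, ef$d_RF, 0) +
      stats::rnorm(nrow(rec), 0, ns$rf_visit_sd)
    rf <- pmin(pmax(rf, 0.01), 0.99)  # keep RF physiologic in long simulations
    tsvI <- edvI - esvI
    rvTsvI <- tsvI * (1 - rf)  # conservation: LV TSV - RV TSV = RF * TSV
    ## LA volumes: minimal (end-diastolic) volume plus a strictly positive
    ## atrial filling volume, so LAESV >= LAEDV holds by construction
    ## small positive volumes are floored at 0.02 mL/kg so Gaussian noise
    ## cannot produce non-physiologic values in long simulation runs
    laedvI <- pmax(config$volumes$LAEDVi + sLAEDV[rec$subjIdx] +
                     ifelse(post, ef$d_LAEDVi, 0) +
                     stats::rnorm(nrow(rec), 0, ns$laedv_visit_sd), 0.02)
    fill0 <- config$volumes$LAESVi - config$volumes$LAEDVi
    laFill <- pmax(fill0 + sLAFill[rec$subjIdx] +
                     ifelse(post, ef$d_LAESVi - ef$d_LAEDVi, 0) +
                     stats::rnorm(nrow(rec), 0, ns$lafill_visit_sd), 0.02)
    laesvI <- laedvI + laFill
    mbp <- config$pressures$MBP + sMBP[rec$subjIdx] +
      ifelse(post, ef$d_MBP, 0) + stats::rnorm(nrow(rec), 0, ns$mbp_visit_sd)
    pp0 <- config$pressures$SAP - config$pressures$DAP
    pp <- pp0 + stats::rnorm(nrow(rec), 0, ns$pp_visit_sd)
    fracS <- (config$pressures$SAP - config$pressures$MBP) / pp0
    sap <- mbp + fracS * pp
    dap <- sap - pp
    frac <- config$aorta$frac_change + sFrac[rec$subjIdx] +
      ifelse(post, ef$d_frac, 0) + stats::rnorm(nrow(rec), 0, ns$frac_visit_sd)
    frac <- pmax(frac, 0.01)
    areaMin <- config$aorta$area_coef * bw^(2 / 3) +
      stats::rnorm(nrow(rec), 0, ns$area_visit_sd)
    areaMax <- areaMin * (1 + frac)
    avCsa <- config$av_csa_coef * bw^(2 / 3)
    fsv_mL <- rvTsvI * bw  # echo FSV equals the RV TSV surrogate
    tllI <- config$leaflets$aortic_i + config$leaflets$parietal_i +
      sTLL[rec$subjIdx] + ifelse(post, ef$d_TLLi, 0) +
      stats::rnorm(nrow(rec), 0, ns$tll_visit_sd)
    aorticFrac <- config$leaflets$aortic_i /
      (config$leaflets$aortic_i + config$leaflets$parietal_i)

    records <- data.frame(
      subject_id = subjects$subject_id[rec$subjIdx], visit = rec$visit,
      BW_kg = bw,
      LVEDV_mL = edvI * bw, LVESV_mL = esvI * bw,
      LAEDV_mL = laedvI * bw, LAESV_mL = laesvI * bw,
      RV_TSV_mL = rvTsvI * bw,
      SAP_mmHg = sap, DAP_mmHg = dap, MBP_mmHg = mbp,
      AoArea_max_mm2 = areaMax, AoArea_min_mm2 = areaMin,
      VTI_cm = fsv_mL / avCsa, AVCSA_cm2 = avCsa,
      aortic_leaflet_mm = aorticFrac * tllI * bw^(1 / 3),
      parietal_leaflet_mm = (1 - aorticFrac) * tllI * bw^(1 / 3),
      stringsAsFactors = FALSE)

    ## ---- landmark realisation
    lmList <- list()
    if (landmarks) {
      bwCbrt <- subjects$BW_kg^(1 / 3)
      for (r in seq_len(nrow(annulus))) {
        i <- grid$subjIdx[r]
        tf <- if (isTRUE(config$rigid_transforms)) randomRigidTransform() else NULL
        pin <- if (grid$visit[r] == "post")
          list(a = annulus$a_pin_i[r] * bwCbrt[i],
               b = annulus$b_pin_i[r] * bwCbrt[i],
               h = annulus$h_i[r] * bwCbrt[i]) else NULL
        set <- annulusFromParams(
          a = annulus$a_i[r] * bwCbrt[i], b = annulus$b_i[r] * bwCbrt[i],
          h = annulus$h_i[r] * bwCbrt[i],
          trigoneAngles = config$trigone_angles,
          nMarkers = config$n_markers, jitter = ns$marker_sd_mm,
          transform = tf, pin = pin,
          subjectId = annulus$subject_id[r], visit = annulus$visit[r],
          phase = annulus$phase[r])
        lmList[[paste(annulus$subject_id[r], annulus$visit[r],
                      annulus$phase[r], sep = "_")]] <- set
      }
    }

    truth <- list(
      subject_axis_effect = sAxis, subject_EF = efSub, subject_RF = rfSub,
      es_apd_effect = 2 * (1 - unname(config$effects$a_mult["ES"])) *
        ph$a_i[ph$phase == "ES"],
      es_icd_effect = 2 * (1 - unname(config$effects$b_mult["ES"])) *
        ph$b_i[ph$phase == "ES"],
      edv_effect = -config$effects$d_LVEDVi,
      rf_effect = -config$effects$d_RF,
      phases_post = applyTreatmentEffect(ph, config$effects))

    new("SyntheticCohort", subjects = subjects, annulus = annulus,
        records = records, landmarks = lmList, truth = truth,
        config = config, seed = as.integer(seed))
  })
}
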