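test_that("noise-free markers lie exactly on the saddle curve", {
  lm <- annulusFromParams(6, 6.5, 1, trigoneAngles = c(-1, 1))
  expect_equal(markers(lm), saddlePoints(6, 6.5, 1, 16), tolerance = 1e-15)
  expect_error(annulusFromParams(6, 6.5, 1, jitter = -0.1), "non-negative")
  expect_error(annulusFromParams(-6, 6.5, 1), "positive")
})

test_that("identical config and seed give bit-identical cohorts", {
  cfg <- defaultCohortConfig(5)
  a <- generateCohort(cfg, seed = 99, landmarks = TRUE)
  b <- generateCohort(cfg, seed = 99, landmarks = TRUE)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- generateCohort(cfg, seed = 100, landmarks = FALSE)
  expect_false(identical(cohortRecords(a)$LVEDV_mL, cohortRecords(c2)$LVEDV_mL))
})

test_that("generator restores the caller's RNG state", {
  set.seed(1234)
  x1 <- rnorm(1)
  set.seed(1234)
  invisible(generateCohort(defaultCohortConfig(3), seed = 5, landmarks = FALSE))
  expect_identical(rnorm(1), x1)
})

test_that("volumes conserve LV TSV = RV TSV + RVol and recover RF", {
  coh <- generateCohort(defaultCohortConfig(8), seed = 3, landmarks = FALSE)
  r <- cohortRecords(coh)
  sv <- strokeVolumeEF(r$LVEDV_mL, r$LVESV_mL)
  mr <- mitralRegurgitation(sv$TSV, r$RV_TSV_mL)
  expect_equal(sv$TSV - r$RV_TSV_mL, mr$RVol, tolerance = 1e-12)
  ## noiseless cohort: measured RF equals the programmed RF for every record
  cfg0 <- noiselessConfig(nullEffectConfig(defaultCohortConfig(6)))
  coh0 <- generateCohort(cfg0, seed = 4, landmarks = FALSE)
  long <- measureCohort(coh0)
  rf <- long$value[long$variable == "RF_pct"]
  expect_equal(rf, rep(100 * cfg0$volumes$RF, length(rf)), tolerance = 1e-9)
})

test_that("zero noise and zero effect give null paired differences", {
  cfg0 <- noiselessConfig(nullEffectConfig(defaultCohortConfig(5)))
  coh0 <- generateCohort(cfg0, seed = 8, landmarks = TRUE)
  long <- measureCohort(coh0)  # full landmark-reconstruction route
  wide <- merge(long[long$visit == "pre", ], long[long$visit == "post", ],
                by = c("subject_id", "variable", "phase"))
  d <- wide$value.x - wide$value.y
  geom <- wide$variable %in% c("MAAi", "APDi", "ICDi", "TTDi", "SI", "LAI")
  ## record-derived variables are bitwise identical across visits
  expect_equal(max(abs(d[!geom])), 0)
  ## geometric metrics pass through independent random rigid transforms,
  ## so differences vanish only to rigid-invariance tolerance
  expect_lt(max(abs(d[geom]) / abs(wide$value.x[geom])), 1e-9)
})

test_that("treatment effect contracts the systolic annulus, sparing trigones", {
  cfg <- noiselessConfig(defaultCohortConfig(3))
  coh <- generateCohort(cfg, seed = 6, landmarks = TRUE)
  long <- measureCohort(coh)
  for (v in c("pre", "post")) {
    s <- long[long$subject_id == "S01" & long$visit == v &
              long$variable == "MAAi", ]
    prof <- buildMADProfile(data.frame(phase = s$phase, MAA = s$value))
    expected <- if (v == "pre") "expansion" else "contraction"
    expect_identical(systolicBehavior(prof, "MAA")$classification, expected,
                     info = v)
  }
  ## trigone chord carries no treatment effect (pinned markers)
  ttd <- long[long$variable == "TTDi", ]
  wide <- merge(ttd[ttd$visit == "pre", ], ttd[ttd$visit == "post", ],
                by = c("subject_id", "phase"))
  expect_lt(max(abs(wide$value.x - wide$value.y) / wide$value.x), 1e-9)
  ## identity multipliers leave the truth untouched
  expect_identical(applyTreatmentEffect(cfg$phases, nullEffectConfig(cfg)$effects),
                   cfg$phases)
  post <- applyTreatmentEffect(cfg$phases, cfg$effects)
  expect_lt(post$a_i[post$phase == "ES"], cfg$phases$a_i[cfg$phases$phase == "ES"])
})

test_that("pre-treatment defaults sit near the published indexed means", {
  coh <- generateCohort(seed = 2024, landmarks = FALSE)
  long <- measureCohort(coh)
  pre <- function(v, ph = NULL) {
    s <- long[long$visit == "pre" & long$variable == v, ]
    if (!is.null(ph)) s <- s[!is.na(s$phase) & s$phase == ph, ]
    mean(s$value)
  }
  ref <- referenceSummaries()
  apdES <- ref$annulus[ref$annulus$metric == "APD" & ref$annulus$phase == "ES", ]
  expect_lt(abs(pre("APDi", "ES") - apdES$pre_mean), apdES$pre_sd)
  rf <- ref$volumes[ref$volumes$variable == "RF_pct", ]
  expect_lt(abs(pre("RF_pct") - rf$pre_center), rf$pre_sd)
  edv <- ref$volumes[ref$volumes$variable == "LVEDVi", ]
  expect_lt(abs(pre("LVEDVi") - edv$pre_center), edv$pre_sd)
})

test_that("estimated ES APD effect recovers the programmed value", {
  cfg <- defaultCohortConfig()
  truthEffect <- generateCohort(cfg, seed = 1, landmarks = FALSE)@truth$es_apd_effect
  nSim <- 200
  est <- vapply(seq_len(nSim), function(i) {
    coh <- generateCohort(cfg, seed = 5000 + i, landmarks = FALSE)
    ann <- coh@annulus
    es <- ann[ann$phase == "ES", ]
    wide <- merge(es[es$visit == "pre", c("subject_id", "APDi")],
                  es[es$visit == "post", c("subject_id", "APDi")],
                  by = "subject_id")
    mean(wide$APDi.x - wide$APDi.y)
  }, numeric(1))
  se <- sd(est) / sqrt(nSim)
  expect_lt(abs(mean(est) - truthEffect), 2 * se + 1e-12)
})

test_that("infeasible configurations are rejected", {
  cfg <- defaultCohortConfig()
  cfg$volumes$RF <- 1.2
  expect_error(generateCohort(cfg), "RF")
  cfg <- defaultCohortConfig()
  cfg$volumes$EF <- 1.0
  expect_error(generateCohort(cfg), "EF")
  cfg <- defaultCohortConfig(2)
  expect_error(generateCohort(cfg), "at least 3")
  cfg <- defaultCohortConfig()
  cfg$effects$a_mult["ES"] <- -1
  expect_error(generateCohort(cfg), "multipliers")
})
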