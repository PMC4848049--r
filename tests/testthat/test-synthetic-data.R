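# Synthetic trace and survey generator.

test_that("identical seed and config give bit-identical output", {
  cfg <- simulationConfig(seed = 17)
  site <- drawSitePhysiology(3, 1, cfg)[1, ]
  tr1 <- generateTrace(site, cfConstant(12), cfg, 6)
  tr2 <- generateTrace(site, cfConstant(12), cfg, 6)
  expect_identical(mapSignal(tr1), mapSignal(tr2))
  expect_identical(ecgSignal(tr1), ecgSignal(tr2))
  expect_identical(sensorSignal(tr1), sensorSignal(tr2))
  expect_identical(drawSitePhysiology(10, 0.5, cfg),
                   drawSitePhysiology(10, 0.5, cfg))

  pat <- lesionPattern(2, 2, patternSites = c("A1", "A2"), gapSites = "A2")
  sv1 <- generateSurvey(pat, cfg)
  sv2 <- generateSurvey(pat, cfg)
  expect_identical(mapSignal(sv1$sites[[3]]$post),
                   mapSignal(sv2$sites[[3]]$post))
})

test_that("drawn thresholds recover the configured moments", {
  cfg <- simulationConfig(seed = 23)
  sites <- drawSitePhysiology(400, 1, cfg)
  thr <- sites$cfThreshold
  expect_true(all(thr >= cfg@thresholdFloor))
  seMean <- cfg@thresholdSd / sqrt(400)
  expect_lt(abs(mean(thr) - 7.6), 2 * seMean)
  seSd <- cfg@thresholdSd / sqrt(2 * 399)  # large-sample SE of the SD
  expect_lt(abs(sd(thr) - 4.4), 3 * seSd)
})

test_that("degenerate physiology settings behave as documented", {
  cfg <- simulationConfig(seed = 5)
  allDead <- drawSitePhysiology(5, 0, cfg)
  expect_true(all(!allDead$viable))
  expect_true(all(is.na(allDead$cfThreshold)))

  cfg0 <- simulationConfig(seed = 5, thresholdSd = 0)
  sites <- drawSitePhysiology(1000, 1, cfg0)
  expect_true(all(sites$cfThreshold == 7.6))

  mixed <- drawSitePhysiology(10, 0.62, cfg)
  expect_identical(sum(mixed$viable), 6L)  # round(10 * 0.62)

  expect_error(drawSitePhysiology(0, 1, cfg), class = "mapgap_argument_error")
  expect_error(drawSitePhysiology(5, 1.4, cfg), class = "mapgap_argument_error")
})

test_that("MAP elicitation follows the per-site force threshold", {
  cfg <- simulationConfig(seed = 31, breathHold = TRUE)
  cv <- idealCurve(cfg)
  site <- drawSitePhysiology(1, 1, cfg)[1, ]

  # supra-threshold constant force: every beat carries a detectable MAP
  tr <- generateTrace(site, cfConstant(site$cfThreshold + 5), cfg, 8)
  det <- detectMAP(tr, calibration = cv)
  expect_true(all(beatAssessments(det)$mapPresent))
  expect_identical(runStart(det), 1L)

  # ablated tissue never produces a MAP, whatever the force
  dead <- site; dead$viable <- FALSE
  trDead <- generateTrace(dead, cfConstant(50), cfg, 8)
  detDead <- detectMAP(trDead, calibration = cv)
  expect_false(any(beatAssessments(detDead)$mapPresent))
  expect_true(is.na(runStart(detDead)))
})

test_that("the first MAP-bearing beat matches the ramp-crossing oracle", {
  cfg <- simulationConfig(seed = 41, breathHold = TRUE)
  site <- drawSitePhysiology(1, 1, cfg)[1, ]
  site$cfThreshold <- 8
  rr <- 60 / cfg@heartRate
  rampDur <- 20 * rr
  tr <- generateTrace(site, cfRamp(0, 16, rampDur), cfg, rampDur + 1)
  md <- traceMetadata(tr)
  # brute-force oracle: evaluate the ramp at each beat's MAP onset time
  onsetTimes <- md$qrsTimes + cfg@mapOnsetDelay
  rampAt <- 16 * pmin(onsetTimes, rampDur) / rampDur
  oracleFirst <- which(rampAt >= 8)[1]
  expect_identical(which(md$elicited)[1], oracleFirst)
  det <- detectMAP(tr, calibration = idealCurve(cfg))
  expect_identical(which(beatAssessments(det)$mapPresent)[1], oracleFirst)
})

test_that("elicitation is monotone in constant contact force", {
  cfg <- simulationConfig(seed = 53)
  site <- drawSitePhysiology(1, 1, cfg)[1, ]
  cv <- idealCurve(cfg)
  elicits <- vapply(c(2, 5, 8, 12, 20, 35), function(g) {
    det <- detectMAP(generateTrace(site, cfConstant(g), cfg, 6),
                     calibration = cv)
    any(beatAssessments(det)$mapPresent)
  }, logical(1))
  # once TRUE, never FALSE again at larger force
  expect_true(all(diff(as.integer(elicits)) >= 0))
})

test_that("non-viable sites stay silent over 100+ beats at 50 g", {
  cfg <- simulationConfig(seed = 61)
  dead <- list(siteId = "X", viable = FALSE, cfThreshold = NA_real_,
               mapAmplitude = NA_real_, mapDuration = NA_real_)
  tr <- generateTrace(dead, cfConstant(50), cfg, 80)  # 106 beats at 80 bpm
  det <- detectMAP(tr, calibration = idealCurve(cfg))
  expect_gte(nrow(beatAssessments(det)), 100)
  expect_identical(sum(beatAssessments(det)$mapPresent), 0L)
})

test_that("generator inputs are validated", {
  cfg <- simulationConfig(seed = 2)
  site <- drawSitePhysiology(1, 1, cfg)[1, ]
  expect_error(generateTrace(site, function(t) -t, cfg, 6),
               class = "mapgap_argument_error")
  expect_error(generateTrace(site, cfConstant(5), cfg, 2),
               class = "mapgap_argument_error")  # fewer than 5 beats
  expect_error(generateSurvey(data.frame(), cfg),
               class = "mapgap_argument_error")
  expect_error(lesionPattern(2, 2, patternSites = "Z9"),
               class = "mapgap_argument_error")
  expect_error(lesionPattern(2, 2, patternSites = "A1", gapSites = "B2"),
               class = "mapgap_argument_error")
  expect_error(simulationConfig(sampleRate = 100), "sampleRate")
})

test_that("breath hold suppresses respiration wander", {
  site <- list(siteId = "X", viable = FALSE, cfThreshold = NA_real_,
               mapAmplitude = NA_real_, mapDuration = NA_real_)
  cfgHold <- simulationConfig(seed = 9, breathHold = TRUE, noiseSd = 0)
  cfgFree <- simulationConfig(seed = 9, breathHold = FALSE, noiseSd = 0)
  trHold <- generateTrace(site, cfConstant(0), cfgHold, 6)
  trFree <- generateTrace(site, cfConstant(0), cfgFree, 6)
  # quiet segment away from any beat: wander visible only without the hold
  t <- traceTime(trHold)
  quiet <- t > 0.95 & t < 1.2
  expect_lt(max(abs(mapSignal(trHold)[quiet])), 0.05)
  expect_gt(max(abs(mapSignal(trFree)[quiet])), 0.1)
  expect_true(trHold@qualityFlags$breathHold)
})
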