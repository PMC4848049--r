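# Filtering, QRS references, beat segmentation, per-beat MAP decision and
# the four-consecutive-waveform rule.

test_that("band-pass preserves the passband and rejects DC", {
  fs <- 1000
  n <- 40 * fs  # long enough for the 0.1 Hz high-pass transient to settle
  t <- (seq_len(n) - 1) / fs
  tone <- sin(2 * pi * 60 * t)
  tr <- newTrace(fs, map = tone, ecg = tone, sensor = numeric(n))
  filt <- bandpassFilter(tr)
  interior <- t > 15 & t < 25
  expect_lt(abs(max(abs(mapSignal(filt)[interior])) - 1), 0.05)

  trDC <- newTrace(fs, map = rep(10, n), ecg = rep(10, n),
                   sensor = numeric(n))
  filtDC <- bandpassFilter(trDC)
  expect_lt(max(abs(mapSignal(filtDC)[interior])), 0.5)

  expect_error(bandpassFilter(tr, detectorConfig(bandHigh = 600)),
               class = "mapgap_argument_error")
})

test_that("out-of-band tones are attenuated as the analytic response predicts", {
  fs <- 2000
  n <- 20 * fs
  t <- (seq_len(n) - 1) / fs
  tone <- sin(2 * pi * 500 * t)
  tr <- newTrace(fs, map = tone, ecg = numeric(n), sensor = numeric(n))
  filt <- bandpassFilter(tr)
  measured <- max(abs(mapSignal(filt)[t > 5 & t < 15]))

  # analytic oracle: evaluate the Butterworth transfer polynomials at the
  # tone frequency; filtfilt applies the magnitude squared, and the
  # high-pass is ~unity at 500 Hz
  lp <- signal::butter(3, 120 / (fs / 2), type = "low")
  z <- exp(-1i * 2 * pi * 500 / fs)
  H <- sum(lp$b * z^(0:(length(lp$b) - 1))) /
    sum(lp$a * z^(0:(length(lp$a) - 1)))
  expected <- Mod(H)^2
  expect_lt(measured, 10^(-20 / 20))  # at least 20 dB down
  # at ~-85 dB residual filtfilt edge effects leave numerical dust, so the
  # agreement with the analytic response is checked within a factor of two
  expect_lt(measured, 2 * expected)
  expect_gt(measured, expected / 2)
})

test_that("QRS detection finds every R peak within 10 ms", {
  cfg <- simulationConfig(seed = 3, breathHold = TRUE)
  site <- list(siteId = "X", viable = FALSE, cfThreshold = NA_real_,
               mapAmplitude = NA_real_, mapDuration = NA_real_)
  tr <- generateTrace(site, cfConstant(5), cfg, 8)  # 10 beats at 80 bpm
  filt <- bandpassFilter(tr)
  peaks <- detectQRS(filt)
  truth <- traceMetadata(tr)$qrsTimes
  expect_length(peaks, 10)
  expect_true(all(abs(peaks - truth) < 0.010))
  expect_true(all(diff(peaks) > 0))
})

test_that("flatline or single-beat ECG raises a no-beats error", {
  n <- 5000
  flat <- newTrace(1000, numeric(n), numeric(n), numeric(n))
  expect_error(detectQRS(flat), class = "mapgap_no_beats_error")
  one <- ecgTraceAt(1.0, durationS = 5, noiseSd = 0)
  expect_error(detectQRS(one), class = "mapgap_no_beats_error")
})

test_that("drifting heart rate is tracked beat for beat", {
  # RR shrinking from 1.0 s (60 bpm) to 0.6 s (100 bpm)
  rrs <- seq(1.0, 0.6, length.out = 24)
  truth <- 0.5 + cumsum(c(0, rrs[-1]))
  tr <- ecgTraceAt(truth, durationS = max(truth) + 0.5, seed = 8)
  peaks <- detectQRS(tr)
  expect_length(peaks, length(truth))
  # brute-force one-to-one nearest-time matching
  d <- abs(outer(peaks, truth, "-"))
  nearest <- apply(d, 1, which.min)
  expect_identical(sort(nearest), seq_along(truth))
  expect_true(all(d[cbind(seq_along(peaks), nearest)] < 0.010))
})

test_that("beat windows partition the trace interior", {
  n <- 4000
  tr <- newTrace(1000, numeric(n), numeric(n), numeric(n))
  qrs <- c(0.75, 1.5, 2.25)
  w <- segmentBeats(tr, qrs, preQrsOffset = 0.15)
  expect_equal(nrow(w), 3)
  expect_equal(w$end - w$start, rep(0.75, 3), tolerance = 1e-9)

  # every sample between the first and last boundary lies in exactly one core
  t <- traceTime(tr)
  inWin <- vapply(seq_len(nrow(w)), function(i)
    sum(t >= w$start[i] & t < w$end[i]), numeric(1))
  covered <- rowSums(vapply(seq_len(nrow(w)), function(i)
    t >= w$start[i] & t < w$end[i], logical(length(t))))
  interior <- t >= min(w$start) & t < max(w$end)
  expect_true(all(covered[interior] == 1))
  expect_true(all(covered[!interior] == 0))

  # irregular rhythm: boundaries follow the next-QRS-minus-offset rule
  qrsIrr <- c(0.5, 1.1, 2.4, 3.0)
  wIrr <- segmentBeats(tr, qrsIrr, preQrsOffset = 0.1)
  expect_equal(wIrr$start, qrsIrr - 0.1)
  expect_equal(wIrr$end[-4], qrsIrr[-1] - 0.1)
  expect_equal(wIrr$end[4], qrsIrr[4] + median(diff(qrsIrr)) - 0.1)

  expect_error(segmentBeats(tr, 1.0), class = "mapgap_no_beats_error")
})

test_that("the amplitude criterion is strict and the duration criterion inclusive", {
  win <- rectPulseWindow()
  # 97-sample pulse at 1 kHz measures MAPDUR of exactly 100 ms
  b <- assessBeat(rectPulseTrace(4, 97), win, earliestActivation = win$qrsTime)
  expect_true(b$mapPresent)
  expect_equal(b$mapdur, 100)
  expect_equal(b$amplitude, 4)

  # one sample shorter: 99 ms < 100 ms, no MAP
  b99 <- assessBeat(rectPulseTrace(4, 96), win, earliestActivation = win$qrsTime)
  expect_false(b99$mapPresent)

  # amplitude exactly at the 2 mV criterion: strict, so no MAP
  b2 <- assessBeat(rectPulseTrace(2, 97), win, earliestActivation = win$qrsTime)
  expect_false(b2$mapPresent)
  # infinitesimally above passes
  b2eps <- assessBeat(rectPulseTrace(2 + 1e-9, 97), win,
                      earliestActivation = win$qrsTime)
  expect_true(b2eps$mapPresent)

  # MAP-negative beats carry null metrics
  expect_true(is.na(b99$amplitude) && is.na(b99$at) && is.na(b99$eor) &&
                is.na(b99$mapdur))

  shortWin <- win; shortWin$end <- shortWin$start + 0.05
  expect_error(assessBeat(rectPulseTrace(4, 97), shortWin, win$qrsTime),
               class = "mapgap_window_error")
})

test_that("MAPDUR equals EOR minus AT for every assessed beat", {
  cfg <- simulationConfig(seed = 77)
  site <- drawSitePhysiology(1, 1, cfg)[1, ]
  tr <- generateTrace(site, cfConstant(site$cfThreshold + 6), cfg, 10)
  det <- detectMAP(tr, calibration = idealCurve(cfg))
  b <- beatAssessments(det)
  pres <- b[b$mapPresent, ]
  expect_gt(nrow(pres), 0)
  expect_equal(pres$mapdur, pres$eor - pres$at, tolerance = 1e-12)
})

test_that("detected metrics track generator ground truth", {
  cfg <- simulationConfig(seed = 19, breathHold = TRUE, noiseSd = 0.02)
  site <- drawSitePhysiology(1, 1, cfg)[1, ]
  site$mapAmplitude <- 4; site$mapDuration <- 200
  tr <- generateTrace(site, cfConstant(site$cfThreshold + 5), cfg, 9)
  det <- detectMAP(tr, calibration = idealCurve(cfg))
  b <- beatAssessments(det)
  expect_true(all(b$mapPresent))
  expect_true(all(abs(b$mapdur - 200) <= 10))
  expect_true(all(abs(b$amplitude - 4) <= 0.5))
  expect_true(all(b$at > 0))
})

test_that("scaling a detected waveform up never flips the decision off", {
  win <- rectPulseWindow()
  for (fac in c(1, 1.5, 3, 10)) {
    b <- assessBeat(rectPulseTrace(2.5 * fac, 120), win,
                    earliestActivation = win$qrsTime)
    expect_true(b$mapPresent)
  }
})

test_that("the run finder matches the exhaustive scan on randomized sequences", {
  cfg <- detectorConfig()
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(4:15, 1)
    beats <- data.frame(
      beatIndex = 1:n, qrsTime = 0.75 * (1:n), earliestActivation = NA_real_,
      mapPresent = runif(n) < 0.7,
      amplitude = runif(n, 3, 6) * sample(c(1, 1, 2), n, replace = TRUE),
      at = NA_real_, eor = NA_real_,
      mapdur = runif(n, 150, 250) * sample(c(1, 1, 2), n, replace = TRUE),
      cfAtBeat = round(runif(n, 2, 20), 2))
    beats$amplitude[!beats$mapPresent] <- NA_real_
    beats$mapdur[!beats$mapPresent] <- NA_real_
    res <- findConsistentRun(beats, cfg)
    oracle <- oracleRunScan(beats, cfg@consistencyRun, cfg@similarityTolerance)
    expect_identical(runStart(res), oracle)
    if (!is.na(oracle)) {
      expect_equal(cfAtDetection(res),
                   beats$cfAtBeat[oracle + cfg@consistencyRun - 1L])
    } else {
      expect_true(is.na(cfAtDetection(res)))
    }
  }
})

test_that("uniform and broken beat patterns resolve as expected", {
  mk <- function(present) data.frame(
    beatIndex = seq_along(present), qrsTime = 0.75 * seq_along(present),
    earliestActivation = NA_real_, mapPresent = present,
    amplitude = ifelse(present, 4, NA_real_),
    at = NA_real_, eor = NA_real_,
    mapdur = ifelse(present, 200, NA_real_),
    cfAtBeat = seq_along(present))
  resAll <- findConsistentRun(mk(rep(TRUE, 10)))
  expect_identical(runStart(resAll), 1L)
  expect_equal(cfAtDetection(resAll), 4)  # CF at the 4th beat of the run
  resBroken <- findConsistentRun(mk(rep(c(TRUE, TRUE, FALSE), 4)))
  expect_true(is.na(runStart(resBroken)))
  expect_true(is.na(cfAtDetection(resBroken)))
})

test_that("per-beat detection agrees with generator truth at default noise", {
  agree <- 0L; total <- 0L
  for (i in 1:10) {
    cfg <- simulationConfig(seed = 200 + i)
    site <- drawSitePhysiology(1, 1, cfg)[1, ]
    # half the traces probe just above threshold, half just below
    g <- if (i %% 2 == 0) site$cfThreshold + 3 else
      max(site$cfThreshold - 3, 0.1)
    tr <- generateTrace(site, cfConstant(g), cfg, 76)  # 100 beats
    det <- detectMAP(tr, calibration = idealCurve(cfg))
    truth <- traceMetadata(tr)$elicited
    got <- beatAssessments(det)$mapPresent
    nb <- min(length(truth), length(got))
    agree <- agree + sum(truth[1:nb] == got[1:nb])
    total <- total + nb
  }
  expect_gte(total, 1000)
  expect_gte(agree / total, 0.95)
})
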