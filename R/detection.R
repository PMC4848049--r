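#' @include AllClasses.R
NULL

# ---------------------------------------------------------------------------
# Filtering
# ---------------------------------------------------------------------------

#' Zero-phase band-pass filter the electrogram channels
#'
#' Applies the acquisition band (default 0.1-120 Hz) to the MAP and ECG
#' channels; the sensor and force channels are left untouched. The band is
#' realized as a cascade of second-order Butterworth high-pass and low-pass
#' sections, each run forward-backward (`signal::filtfilt`) so fiducial
#' timing is preserved; the cascade is numerically robust at the extreme
#' 0.1 Hz / Nyquist ratio where a single band-pass design is fragile.
#'
#' @param trace a [Trace-class].
#' @param config a [DetectorConfig-class] supplying `bandLow`/`bandHigh`.
#' @return A filtered [Trace-class].
#' @export
bandpassFilter <- function(trace, config = detectorConfig()) {
  nyq <- sampleRate(trace) / 2
  if (config@bandHigh >= nyq)
    abortArgument("bandHigh must be below the Nyquist frequency")
  # third-order low-pass: forward-backward filtering squares the magnitude
  # response, and a squared second-order section would already sag ~6% at
  # 60 Hz; order 3 keeps the passband flat to ~1.5% at the band centre
  hp <- signal::butter(2, config@bandLow / nyq, type = "high")
  lp <- signal::butter(3, config@bandHigh / nyq, type = "low")
  bp <- function(x) signal::filtfilt(lp, signal::filtfilt(hp, x))
  out <- trace
  out@map <- bp(trace@map)
  out@ecg <- bp(trace@ecg)
  out@metadata$filtered <- c(config@bandLow, config@bandHigh)
  out
}

# ---------------------------------------------------------------------------
# QRS detection and beat segmentation
# ---------------------------------------------------------------------------

#' Detect R peaks on the reference ECG channel
#'
#' Simple amplitude-and-refractory R-peak detector: local maxima above half
#' the global maximum, thinned so no two accepted peaks lie within the
#' refractory period (the larger peak wins). The R peaks serve as the
#' per-beat references for segmentation and for the earliest-activation
#' fiducial.
#'
#' @param trace a (filtered) [Trace-class].
#' @param refractory minimum R-R interval honoured, seconds.
#' @param minRAmplitude smallest plausible R amplitude, mV; a flatline or
#'   sub-threshold ECG raises a no-beats error.
#' @return Numeric vector of R-peak times, seconds (>= 2 of them).
#' @export
detectQRS <- function(trace, refractory = 0.3, minRAmplitude = 0.2) {
  ecg <- ecgSignal(trace)
  t <- traceTime(trace)
  mx <- max(ecg)
  if (!is.finite(mx) || mx < minRAmplitude)
    abortNoBeats("no QRS complexes detectable on the ECG channel")
  thr <- 0.5 * mx
  d <- diff(ecg)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  cand <- cand[ecg[cand] > thr]
  if (length(cand) == 0L)
    abortNoBeats("no QRS complexes detectable on the ECG channel")
  # refractory thinning: keep the larger of any two peaks closer than the
  # refractory period
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) && (t[i] - t[keep[length(keep)]]) < refractory) {
      if (ecg[i] > ecg[keep[length(keep)]]) keep[length(keep)] <- i
    } else {
      keep <- c(keep, i)
    }
  }
  if (length(keep) < 2L)
    abortNoBeats("fewer than 2 beats: cannot establish a rhythm")
  t[keep]
}

#' Segment a trace into per-beat windows
#'
#' One window per QRS reference, spanning from a fixed pre-QRS offset to the
#' next QRS (minus the same offset); the last window extends by the median
#' R-R interval. Window cores partition the trace interior: every sample
#' between the first and last window boundary belongs to exactly one core.
#'
#' @param trace a [Trace-class].
#' @param qrsTimes R-peak times from [detectQRS()], seconds (>= 2).
#' @param preQrsOffset seconds of pre-QRS margin, default 0.15.
#' @return data.frame with `beatIndex`, `qrsTime`, `start`, `end` (seconds;
#'   `end` exclusive).
#' @export
segmentBeats <- function(trace, qrsTimes, preQrsOffset = 0.15) {
  if (length(qrsTimes) < 2L)
    abortNoBeats("need at least 2 QRS references to segment beats")
  if (is.unsorted(qrsTimes, strictly = TRUE))
    abortArgument("qrsTimes must be strictly increasing")
  nb <- length(qrsTimes)
  medRR <- median(diff(qrsTimes))
  starts <- qrsTimes - preQrsOffset
  ends <- c(qrsTimes[-1] - preQrsOffset, qrsTimes[nb] + medRR - preQrsOffset)
  tmax <- (nSamples(trace) - 1) / sampleRate(trace)
  data.frame(beatIndex = seq_len(nb), qrsTime = qrsTimes,
             start = pmax(starts, 0), end = pmin(ends, tmax))
}

# Earliest recorded ventricular activation for each beat: QRS onset on the
# reference ECG, taken as the last sub-10%-of-R-amplitude sample before the
# R peak.
qrsOnsets <- function(trace, qrsTimes) {
  ecg <- ecgSignal(trace)
  t <- traceTime(trace)
  fs <- sampleRate(trace)
  vapply(qrsTimes, function(tk) {
    ipk <- as.integer(round(tk * fs)) + 1L
    ipk <- min(max(ipk, 1L), length(ecg))
    lvl <- 0.1 * ecg[ipk]
    i0 <- max(1L, ipk - as.integer(round(0.08 * fs)))
    seg <- ecg[i0:ipk]
    below <- which(seg < lvl)
    if (length(below) == 0L) return(t[i0])
    t[i0 + max(below) - 1L]
  }, numeric(1))
}

# ---------------------------------------------------------------------------
# Per-beat MAP assessment
# ---------------------------------------------------------------------------

#' Assess one beat window for the presence of a MAP
#'
#' Decides whether the window carries a recognizable MAP and, if so,
#' measures the repolarization metrics. The decision applies the
#' acquisition criteria exactly: amplitude strictly greater than
#' `minAmplitude` (peak relative to the pre-upstroke median baseline, or
#' peak-to-peak when configured) and MAP duration of at least `minDuration`
#' (inclusive). Local activation is the time of maximum upstroke velocity;
#' local end of repolarization (EOR) is the first post-peak time at which
#' the signal has recovered `repolarizationFraction` of its amplitude
#' toward baseline. Metrics are reported relative to the
#' earliest-activation fiducial: AT = local activation - earliest
#' activation; EOR = local EOR - earliest activation; MAPDUR = EOR - AT.
#' For a MAP-negative beat the metric fields are `NA`.
#'
#' @param trace a filtered [Trace-class].
#' @param window one row of [segmentBeats()] output (list or data.frame row
#'   with `beatIndex`, `qrsTime`, `start`, `end`).
#' @param earliestActivation the earliest recorded ventricular activation
#'   for this beat, seconds (QRS onset on the reference ECG).
#' @param config a [DetectorConfig-class].
#' @return One-row data.frame: `beatIndex`, `qrsTime`, `earliestActivation`,
#'   `mapPresent`, `amplitude` (mV), `at`, `eor`, `mapdur` (ms),
#'   `cfAtBeat` (g, `NA` without a force channel).
#' @export
assessBeat <- function(trace, window, earliestActivation,
                       config = detectorConfig()) {
  window <- as.list(window)
  m <- assessBeatCore(trace, window, earliestActivation, config)
  data.frame(beatIndex = window$beatIndex, qrsTime = window$qrsTime,
             earliestActivation = earliestActivation,
             mapPresent = m$present, amplitude = m$amplitude,
             at = m$at, eor = m$eor, mapdur = m$mapdur,
             cfAtBeat = m$cfAtBeat)
}

# centred 5-point moving average via cumsum (cheap stats::filter stand-in)
movAvg5 <- function(x) {
  n <- length(x)
  if (n < 5L) return(x)
  cs <- cumsum(c(0, x))
  out <- numeric(n)
  out[3:(n - 2)] <- (cs[6:(n + 1)] - cs[1:(n - 4)]) / 5
  out
}

assessBeatCore <- function(trace, window, earliestActivation, config) {
  fs <- sampleRate(trace)
  n <- nSamples(trace)
  i0 <- max(1L, as.integer(ceiling(window$start * fs + 1 - 1e-9)))
  i1 <- min(n, as.integer(ceiling(window$end * fs + 1 - 1e-9)) - 1L)
  if (i1 - i0 < 1L || (window$end - window$start) * 1000 < config@minDuration)
    abortWindow("beat window shorter than the minimum MAP duration")
  idx <- i0:i1
  sig <- mapSignal(trace)[idx]
  tw <- (idx - 1) / fs

  # local activation: maximum smoothed upstroke velocity at/after the QRS
  d <- diff(sig) * fs / 1000  # mV per ms
  ds <- movAvg5(d)
  sFrom <- max(1L, as.integer(ceiling((window$qrsTime - 0.05) * fs + 1 - 1e-9)) - i0 + 1L)
  searchable <- sFrom:length(ds)
  iu <- searchable[which.max(ds[searchable])]
  tAct <- tw[iu]

  # baseline: median of the pre-upstroke segment (robust to residual wander)
  nPre <- iu - as.integer(round(0.01 * fs))
  baseline <- if (nPre >= 3L) median(sig[seq_len(nPre)]) else
    median(sig[seq_len(min(5L, length(sig)))])

  ipk <- iu - 1L + which.max(sig[iu:length(sig)])
  amplitude <- if (config@amplitudeMode == "peak_to_peak")
    sig[ipk] - min(sig) else sig[ipk] - baseline

  # EOR: first post-peak recovery past the configured fraction
  recoverLevel <- baseline + (1 - config@repolarizationFraction) * amplitude
  post <- sig[(ipk + 1L):length(sig)]
  hit <- which(post <= recoverLevel)
  tEor <- if (ipk < length(sig) && length(hit)) tw[ipk + hit[1L]] else NA_real_

  at <- (tAct - earliestActivation) * 1000
  eor <- if (is.na(tEor)) NA_real_ else (tEor - earliestActivation) * 1000
  mapdur <- if (is.na(eor)) NA_real_ else eor - at

  # amplitude criterion strict; duration inclusive, with a 1e-9 ms guard so
  # floating-point cancellation cannot flip a beat sitting exactly on the
  # boundary (sample times are multiples of 1/fs)
  present <- isTRUE(amplitude > config@minAmplitude) &&
    !is.na(mapdur) && mapdur >= config@minDuration - 1e-9

  cf <- forceSignal(trace)
  cfAtBeat <- if (is.null(cf)) NA_real_ else median(cf[idx])

  list(present = present,
       amplitude = if (present) amplitude else NA_real_,
       at = if (present) at else NA_real_,
       eor = if (present) eor else NA_real_,
       mapdur = if (present) mapdur else NA_real_,
       cfAtBeat = cfAtBeat)
}

#' Assess every beat of a trace
#'
#' Convenience wrapper: computes per-beat earliest-activation fiducials
#' (QRS onsets) and runs [assessBeat()] over all windows.
#'
#' @param trace a filtered [Trace-class].
#' @param windows output of [segmentBeats()].
#' @param config a [DetectorConfig-class].
#' @return data.frame of per-beat assessments (one row per window).
#' @export
assessBeats <- function(trace, windows, config = detectorConfig()) {
  onsets <- qrsOnsets(trace, windows$qrsTime)
  nb <- nrow(windows)
  cores <- lapply(seq_len(nb), function(i)
    assessBeatCore(trace, list(beatIndex = windows$beatIndex[i],
                               qrsTime = windows$qrsTime[i],
                               start = windows$start[i],
                               end = windows$end[i]),
                   onsets[i], config))
  pull <- function(f) vapply(cores, function(x) as.numeric(x[[f]]), numeric(1))
  data.frame(beatIndex = windows$beatIndex, qrsTime = windows$qrsTime,
             earliestActivation = onsets,
             mapPresent = vapply(cores, function(x) x$present, logical(1)),
             amplitude = pull("amplitude"), at = pull("at"),
             eor = pull("eor"), mapdur = pull("mapdur"),
             cfAtBeat = pull("cfAtBeat"))
}

# ---------------------------------------------------------------------------
# The four-consecutive-waveform rule
# ---------------------------------------------------------------------------

# Pairwise relative similarity: every pair within `tol` relative difference.
allPairwiseSimilar <- function(x, tol) {
  if (any(!is.finite(x))) return(FALSE)
  mx <- max(x); mn <- min(x)
  (mx - mn) / mx <= tol  # worst pair is (max, min); relative to the larger
}

#' Find the first run of consecutive similar MAP waveforms
#'
#' Scans the beat sequence for the first run of `consistencyRun`
#' consecutive MAP-positive beats whose waveforms are mutually similar
#' (every pair within `similarityTolerance` relative difference in both
#' amplitude and MAPDUR). The contact force is read at the *last* beat of
#' that run — the force at the time of the last of the consecutive MAP
#' signals. When no qualifying run exists the result is a null detection
#' (`NA` run start and force), not an error.
#'
#' @param beats data.frame of per-beat assessments ([assessBeats()]), in
#'   temporal order.
#' @param config a [DetectorConfig-class].
#' @param maxCf maximum contact force applied over the recording, grams;
#'   defaults to the largest per-beat force seen.
#' @return A [DetectionResult-class].
#' @export
findConsistentRun <- function(beats, config = detectorConfig(),
                              maxCf = NULL) {
  L <- config@consistencyRun
  n <- nrow(beats)
  runStart <- NA_integer_
  if (n >= L) {
    for (s in seq_len(n - L + 1L)) {
      span <- s:(s + L - 1L)
      if (!all(beats$mapPresent[span])) next
      if (allPairwiseSimilar(beats$amplitude[span], config@similarityTolerance) &&
          allPairwiseSimilar(beats$mapdur[span], config@similarityTolerance)) {
        runStart <- as.integer(s)
        break
      }
    }
  }
  cfDet <- if (is.na(runStart)) NA_real_ else
    beats$cfAtBeat[runStart + L - 1L]
  if (is.null(maxCf)) {
    maxCf <- suppressWarnings(max(beats$cfAtBeat, na.rm = TRUE))
    if (!is.finite(maxCf)) maxCf <- NA_real_
  }
  new("DetectionResult", beats = beats, runStart = runStart,
      cfAtDetection = cfDet,
      maxCfApplied = if (is.finite(maxCf)) maxCf else NA_real_,
      metadata = list(consistencyRun = L,
                      similarityTolerance = config@similarityTolerance))
}

# ---------------------------------------------------------------------------
# Full detection pipeline for one trace
# ---------------------------------------------------------------------------

#' Run the full MAP detection pipeline on one trace
#'
#' Filter, detect QRS references, segment beats, assess each beat and apply
#' the four-consecutive-waveform rule. If a calibration curve is supplied
#' and the trace has no force channel yet, the sensor channel is calibrated
#' first so per-beat contact forces are available.
#'
#' @param trace a raw [Trace-class].
#' @param config a [DetectorConfig-class].
#' @param calibration optional [CalibrationCurve-class].
#' @return A [DetectionResult-class].
#' @examples
#' cfg <- simulationConfig(seed = 5)
#' site <- drawSitePhysiology(1, 1, cfg)[1, ]
#' tr <- generateTrace(site, cfConstant(site$cfThreshold + 5), cfg, 6)
#' cv <- calibrationCurve(cfg@fiberId, cfg@fiberSlope, cfg@fiberIntercept)
#' detectMAP(tr, calibration = cv)
#' @export
detectMAP <- function(trace, config = detectorConfig(), calibration = NULL) {
  if (is.null(forceSignal(trace)) && !is.null(calibration))
    trace <- applyCalibration(trace, calibration)
  filt <- bandpassFilter(trace, config)
  qrs <- detectQRS(filt)
  windows <- segmentBeats(filt, qrs, config@preQrsOffset)
  beats <- assessBeats(filt, windows, config)
  cf <- forceSignal(filt)
  findConsistentRun(beats, config,
                    maxCf = if (is.null(cf)) NULL else max(cf))
}
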