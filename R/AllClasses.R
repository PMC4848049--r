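#' @include utils.R
NULL

# ---------------------------------------------------------------------------
# SimulationConfig
# ---------------------------------------------------------------------------

#' Simulation configuration for synthetic MAP/ECG/sensor traces
#'
#' Holds every tunable of the synthetic-signal generator. The elicitation
#' model is a hard per-site force threshold: a beat carries a MAP if and only
#' if the tissue is viable and the instantaneous contact force at the MAP
#' onset of that beat reaches the site threshold. Thresholds across viable
#' sites follow a truncated normal whose realized mean and SD equal
#' `thresholdMean`/`thresholdSd` (moment-matched truncation at
#' `thresholdFloor`), defaulting to the 7.6 +/- 4.4 g observed on viable
#' epicardial ventricular septum.
#'
#' @slot sampleRate samples per second (>= 500; default 1000 resolves the
#'   2 ms MAP upstroke).
#' @slot heartRate beats per minute (default 80).
#' @slot thresholdMean,thresholdSd grams; realized mean/SD of the viable-site
#'   contact-force thresholds (defaults 7.6 and 4.4).
#' @slot thresholdFloor grams; lower truncation of the threshold
#'   distribution (default 0.5, avoids non-physical forces).
#' @slot noiseSd additive Gaussian noise SD on the MAP and ECG channels, mV.
#' @slot respirationAmplitude mV of sinusoidal baseline wander added to the
#'   MAP channel (suppressed when `breathHold`).
#' @slot respirationPeriod seconds per breath (default 4 s, 15 breaths/min).
#' @slot respirationForceAmplitude grams of respiratory modulation added to
#'   the applied contact force.
#' @slot breathHold logical; when TRUE respiration is suppressed, modelling a
#'   momentary 10-20 s breath hold during measurement.
#' @slot mapAmplitudeRange,mapDurationRange uniform ranges (mV, ms) for
#'   per-site MAP plateau amplitude and duration. The underlying study
#'   reports only the 2 mV / 100 ms detection floor, so the defaults
#'   (3-6 mV, 150-250 ms) are plausible-but-arbitrary plumbing values.
#' @slot farFieldAmplitude mV of the blunt far-field deflection carried by
#'   beats without an elicited MAP (kept below the detector's 2 mV floor).
#' @slot ecgAmplitude R-wave amplitude on the reference ECG channel, mV.
#' @slot mapOnsetDelay seconds from the R peak to local MAP onset.
#' @slot firstBeatTime seconds; time of the first R peak in a trace.
#' @slot fiberId,fiberSlope,fiberIntercept canonical simulated fiber Bragg
#'   grating: the sensor channel encodes force through the inverse of
#'   force = slope * shift + intercept (grams, g/nm).
#' @slot sensorNoiseSd nm of Gaussian noise on the wavelength-shift channel.
#' @slot seed integer seed; identical seed + config give bit-identical output.
#'
#' @seealso [simulationConfig()] for the user constructor.
#' @export
setClass("SimulationConfig", representation(
  sampleRate = "numeric", heartRate = "numeric",
  thresholdMean = "numeric", thresholdSd = "numeric", thresholdFloor = "numeric",
  noiseSd = "numeric",
  respirationAmplitude = "numeric", respirationPeriod = "numeric",
  respirationForceAmplitude = "numeric", breathHold = "logical",
  mapAmplitudeRange = "numeric", mapDurationRange = "numeric",
  farFieldAmplitude = "numeric", ecgAmplitude = "numeric",
  mapOnsetDelay = "numeric", firstBeatTime = "numeric",
  fiberId = "character", fiberSlope = "numeric", fiberIntercept = "numeric",
  sensorNoiseSd = "numeric", seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (!isScalarNumber(object@sampleRate) || object@sampleRate < 500)
    msgs <- c(msgs, "sampleRate must be a single number >= 500")
  if (!isScalarNumber(object@heartRate) || object@heartRate <= 0)
    msgs <- c(msgs, "heartRate must be positive")
  if (!isScalarNumber(object@thresholdSd) || object@thresholdSd < 0)
    msgs <- c(msgs, "thresholdSd must be >= 0")
  if (!isScalarNumber(object@thresholdMean) || object@thresholdMean <= 0)
    msgs <- c(msgs, "thresholdMean must be positive")
  amps <- c(object@noiseSd, object@respirationAmplitude,
            object@respirationForceAmplitude, object@farFieldAmplitude,
            object@ecgAmplitude, object@sensorNoiseSd)
  if (any(!is.finite(amps)) || any(amps < 0))
    msgs <- c(msgs, "all amplitude/noise parameters must be finite and >= 0")
  if (!isScalarNumber(object@respirationPeriod) || object@respirationPeriod <= 0)
    msgs <- c(msgs, "respirationPeriod must be positive")
  if (length(object@mapAmplitudeRange) != 2L || any(object@mapAmplitudeRange <= 0))
    msgs <- c(msgs, "mapAmplitudeRange must be two positive numbers")
  if (length(object@mapDurationRange) != 2L || any(object@mapDurationRange <= 0))
    msgs <- c(msgs, "mapDurationRange must be two positive numbers")
  if (!isScalarNumber(object@fiberSlope) || object@fiberSlope == 0)
    msgs <- c(msgs, "fiberSlope must be finite and nonzero")
  if (length(msgs)) msgs else TRUE
})

#' Create a simulation configuration
#'
#' All arguments have study-condition defaults; see
#' [SimulationConfig-class] for their meaning and units.
#'
#' @param sampleRate samples/s.
#' @param heartRate beats/min.
#' @param thresholdMean,thresholdSd,thresholdFloor grams.
#' @param noiseSd mV.
#' @param respirationAmplitude mV; `respirationPeriod` s;
#'   `respirationForceAmplitude` g.
#' @param breathHold logical.
#' @param mapAmplitudeRange mV (length 2); `mapDurationRange` ms (length 2).
#' @param farFieldAmplitude,ecgAmplitude mV.
#' @param mapOnsetDelay,firstBeatTime s.
#' @param fiberId,fiberSlope,fiberIntercept simulated fiber identity and
#'   calibration truth (g/nm, g).
#' @param sensorNoiseSd nm.
#' @param seed integer.
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(seed = 7)
#' cfg
#' @export
simulationConfig <- function(sampleRate = 1000, heartRate = 80,
                             thresholdMean = 7.6, thresholdSd = 4.4,
                             thresholdFloor = 0.5, noiseSd = 0.05,
                             respirationAmplitude = 0.2, respirationPeriod = 4,
                             respirationForceAmplitude = 0.3,
                             breathHold = FALSE,
                             mapAmplitudeRange = c(3, 6),
                             mapDurationRange = c(150, 250),
                             farFieldAmplitude = 0.3, ecgAmplitude = 1,
                             mapOnsetDelay = 0.02, firstBeatTime = 0.5,
                             fiberId = "fbg-sim-01", fiberSlope = 5,
                             fiberIntercept = 0, sensorNoiseSd = 0.01,
                             seed = 1L) {
  new("SimulationConfig",
      sampleRate = sampleRate, heartRate = heartRate,
      thresholdMean = thresholdMean, thresholdSd = thresholdSd,
      thresholdFloor = thresholdFloor, noiseSd = noiseSd,
      respirationAmplitude = respirationAmplitude,
      respirationPeriod = respirationPeriod,
      respirationForceAmplitude = respirationForceAmplitude,
      breathHold = breathHold,
      mapAmplitudeRange = mapAmplitudeRange,
      mapDurationRange = mapDurationRange,
      farFieldAmplitude = farFieldAmplitude, ecgAmplitude = ecgAmplitude,
      mapOnsetDelay = mapOnsetDelay, firstBeatTime = firstBeatTime,
      fiberId = fiberId, fiberSlope = fiberSlope,
      fiberIntercept = fiberIntercept, sensorNoiseSd = sensorNoiseSd,
      seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# DetectorConfig
# ---------------------------------------------------------------------------

#' MAP detector configuration
#'
#' Parameters of the filtering and per-beat MAP decision. The amplitude
#' criterion is strict (`> minAmplitude`) and the duration criterion
#' inclusive (`>= minDuration`), matching the acquisition convention of a
#' morphology of one hundred milliseconds or greater with amplitude more
#' than 2 mV.
#'
#' @slot bandLow,bandHigh band-pass corner frequencies in Hz
#'   (defaults 0.1 and 120).
#' @slot minAmplitude mV; MAP present requires amplitude strictly above this
#'   (default 2).
#' @slot minDuration ms; MAP present requires MAPDUR of at least this
#'   (default 100, inclusive).
#' @slot consistencyRun number of consecutive similar MAP-positive beats
#'   required before the contact force is read off (default 4).
#' @slot similarityTolerance maximum pairwise relative difference in
#'   amplitude and MAPDUR within a qualifying run (default 0.15).
#' @slot repolarizationFraction recovery fraction defining local end of
#'   repolarization (default 0.9: the APD90-style time at which the signal
#'   has recovered 90% of its amplitude toward baseline).
#' @slot preQrsOffset seconds of pre-QRS margin included in each beat window
#'   (default 0.15).
#' @slot amplitudeMode `"baseline"` (peak minus pre-upstroke median baseline,
#'   the default) or `"peak_to_peak"`.
#' @seealso [detectorConfig()]
#' @export
setClass("DetectorConfig", representation(
  bandLow = "numeric", bandHigh = "numeric",
  minAmplitude = "numeric", minDuration = "numeric",
  consistencyRun = "integer", similarityTolerance = "numeric",
  repolarizationFraction = "numeric", preQrsOffset = "numeric",
  amplitudeMode = "character"
))

setValidity("DetectorConfig", function(object) {
  msgs <- character()
  if (!(isScalarNumber(object@bandLow) && isScalarNumber(object@bandHigh) &&
        object@bandLow > 0 && object@bandLow < object@bandHigh))
    msgs <- c(msgs, "need 0 < bandLow < bandHigh")
  if (!isScalarNumber(object@minAmplitude) || object@minAmplitude <= 0)
    msgs <- c(msgs, "minAmplitude must be positive")
  if (!isScalarNumber(object@minDuration) || object@minDuration <= 0)
    msgs <- c(msgs, "minDuration must be positive")
  if (object@consistencyRun < 1L)
    msgs <- c(msgs, "consistencyRun must be >= 1")
  if (!isScalarNumber(object@repolarizationFraction) ||
      object@repolarizationFraction <= 0 || object@repolarizationFraction >= 1)
    msgs <- c(msgs, "repolarizationFraction must lie in (0, 1)")
  if (!object@amplitudeMode %in% c("baseline", "peak_to_peak"))
    msgs <- c(msgs, "amplitudeMode must be 'baseline' or 'peak_to_peak'")
  if (length(msgs)) msgs else TRUE
})

#' Create a detector configuration
#'
#' @param bandLow,bandHigh Hz.
#' @param minAmplitude mV (strict threshold).
#' @param minDuration ms (inclusive threshold).
#' @param consistencyRun beats.
#' @param similarityTolerance proportion.
#' @param repolarizationFraction proportion in (0, 1).
#' @param preQrsOffset s.
#' @param amplitudeMode "baseline" or "peak_to_peak".
#' @return A validated [DetectorConfig-class] object.
#' @examples
#' detectorConfig()
#' @export
detectorConfig <- function(bandLow = 0.1, bandHigh = 120, minAmplitude = 2,
                           minDuration = 100, consistencyRun = 4L,
                           similarityTolerance = 0.15,
                           repolarizationFraction = 0.9,
                           preQrsOffset = 0.15, amplitudeMode = "baseline") {
  new("DetectorConfig", bandLow = bandLow, bandHigh = bandHigh,
      minAmplitude = minAmplitude, minDuration = minDuration,
      consistencyRun = as.integer(consistencyRun),
      similarityTolerance = similarityTolerance,
      repolarizationFraction = repolarizationFraction,
      preQrsOffset = preQrsOffset, amplitudeMode = amplitudeMode)
}

# ---------------------------------------------------------------------------
# Trace
# ---------------------------------------------------------------------------

#' A uniformly sampled multichannel intracardiac recording
#'
#' Three co-registered channels sampled at a common rate: the bipolar MAP
#' electrogram (mV), the reference ECG (mV) and the raw fiber Bragg grating
#' wavelength shift (nm). After [applyCalibration()] the object additionally
#' carries a calibrated contact-force channel (grams). Time is implicit:
#' sample i occurs at (i - 1) / sampleRate seconds.
#'
#' @slot sampleRate samples per second (>= 500).
#' @slot map,ecg,sensor equal-length numeric channels (mV, mV, nm).
#' @slot force grams; length 0 until a calibration has been applied.
#' @slot qualityFlags list of data-quality flags (e.g. `breathHold`).
#' @slot metadata list; the generator stores ground truth here (site
#'   physiology, QRS times, per-beat elicitation) for testing.
#' @seealso [newTrace()], [mapSignal()], [bandpassFilter()]
#' @export
setClass("Trace", representation(
  sampleRate = "numeric", map = "numeric", ecg = "numeric",
  sensor = "numeric", force = "numeric",
  qualityFlags = "list", metadata = "list"
))

setValidity("Trace", function(object) {
  msgs <- character()
  n <- length(object@map)
  if (length(object@ecg) != n || length(object@sensor) != n)
    msgs <- c(msgs, "map, ecg and sensor channels must have equal length")
  if (length(object@force) != 0L && length(object@force) != n)
    msgs <- c(msgs, "force channel must be empty or match the channel length")
  if (!isScalarNumber(object@sampleRate) || object@sampleRate < 500)
    msgs <- c(msgs, "sampleRate must be a single number >= 500")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Trace
#'
#' @param sampleRate samples/s.
#' @param map,ecg,sensor equal-length numeric vectors (mV, mV, nm).
#' @param force optional calibrated force channel (grams).
#' @param qualityFlags,metadata lists.
#' @return A [Trace-class] object.
#' @export
newTrace <- function(sampleRate, map, ecg, sensor, force = numeric(0),
                     qualityFlags = list(), metadata = list()) {
  new("Trace", sampleRate = sampleRate, map = as.numeric(map),
      ecg = as.numeric(ecg), sensor = as.numeric(sensor),
      force = as.numeric(force), qualityFlags = qualityFlags,
      metadata = metadata)
}

# ---------------------------------------------------------------------------
# CalibrationCurve
# ---------------------------------------------------------------------------

#' A fitted per-fiber wavelength-to-force calibration
#'
#' Linear mapping `force = slope * shift + intercept` fitted by ordinary
#' least squares on bench data for one fiber Bragg grating. Calibration is
#' per-fiber and mandatory: applying a curve to a trace recorded with a
#' different fiber is an error.
#'
#' @slot fiberId fiber identity label.
#' @slot slope grams per nm (finite, nonzero).
#' @slot intercept grams.
#' @slot rmse root-mean-square residual of the fit, grams.
#' @slot nPoints number of bench points used (>= 2).
#' @slot shiftAccuracy nm; quoted sensor accuracy (default +/- 1 nm).
#' @seealso [fitCalibration()], [applyCalibration()]
#' @export
setClass("CalibrationCurve", representation(
  fiberId = "character", slope = "numeric", intercept = "numeric",
  rmse = "numeric", nPoints = "integer", shiftAccuracy = "numeric"
))

setValidity("CalibrationCurve", function(object) {
  msgs <- character()
  if (object@nPoints < 2L) msgs <- c(msgs, "nPoints must be >= 2")
  if (!isScalarNumber(object@slope) || object@slope == 0)
    msgs <- c(msgs, "slope must be finite and nonzero")
  if (!isScalarNumber(object@rmse) || object@rmse < 0)
    msgs <- c(msgs, "rmse must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CalibrationCurve directly
#'
#' Normally produced by [fitCalibration()]; the direct constructor exists for
#' round-tripping stored calibrations.
#'
#' @param fiberId label; `slope` g/nm; `intercept`, `rmse` g; `nPoints`
#'   count; `shiftAccuracy` nm.
#' @return A [CalibrationCurve-class] object.
#' @export
calibrationCurve <- function(fiberId, slope, intercept, rmse = 0,
                             nPoints = 2L, shiftAccuracy = 1) {
  new("CalibrationCurve", fiberId = fiberId, slope = slope,
      intercept = intercept, rmse = rmse, nPoints = as.integer(nPoints),
      shiftAccuracy = shiftAccuracy)
}

# ---------------------------------------------------------------------------
# DetectionResult
# ---------------------------------------------------------------------------

#' Result of MAP detection on one catheter application
#'
#' Per-beat assessments plus the outcome of the four-consecutive-waveform
#' rule: the index at which the first run of `consistencyRun` mutually
#' similar MAP-positive beats starts, and the contact force read at the
#' *last* beat of that run (`cfAtDetection`). When no qualifying run exists
#' both are `NA` — absence is a result, not an error.
#'
#' @slot beats data.frame with one row per beat: `beatIndex`, `qrsTime`,
#'   `earliestActivation`, `mapPresent`, `amplitude`, `at`, `eor`, `mapdur`,
#'   `cfAtBeat` (times s, metrics ms, amplitude mV, force g; metric fields
#'   are `NA` for MAP-negative beats).
#' @slot runStart integer beat index (1-based) or `NA`.
#' @slot cfAtDetection grams or `NA`; defined exactly when `runStart` is.
#' @slot maxCfApplied grams; maximum force applied over the recording.
#' @slot metadata list.
#' @seealso [detectMAP()], [findConsistentRun()]
#' @export
setClass("DetectionResult", representation(
  beats = "data.frame", runStart = "integer", cfAtDetection = "numeric",
  maxCfApplied = "numeric", metadata = "list"
))

setValidity("DetectionResult", function(object) {
  msgs <- character()
  if (is.na(object@runStart) && !is.na(object@cfAtDetection))
    msgs <- c(msgs, "cfAtDetection requires a qualifying run (runStart)")
  if (!is.na(object@cfAtDetection) && is.finite(object@maxCfApplied) &&
      object@maxCfApplied < object@cfAtDetection - 1e-9)
    msgs <- c(msgs, "maxCfApplied must be >= cfAtDetection")
  need <- c("beatIndex", "qrsTime", "mapPresent", "amplitude", "at", "eor",
            "mapdur", "cfAtBeat")
  if (!all(need %in% names(object@beats)))
    msgs <- c(msgs, paste("beats must contain columns:",
                          paste(need, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# ReferenceThreshold
# ---------------------------------------------------------------------------

#' Cohort reference for the contact force needed to elicit a MAP
#'
#' Mean and SD of the contact force at first sustained MAP detection over a
#' pre-ablation survey of viable tissue; used as the fallback comparator
#' when a site-matched pre-ablation force is unavailable.
#'
#' @slot meanCf,sdCf grams; `n` sites; `source` provenance label.
#' @seealso [buildReference()], [septalReference()]
#' @export
setClass("ReferenceThreshold", representation(
  meanCf = "numeric", sdCf = "numeric", n = "integer", source = "character"
))

setValidity("ReferenceThreshold", function(object) {
  msgs <- character()
  if (object@n < 1L) msgs <- c(msgs, "n must be >= 1")
  if (!isScalarNumber(object@meanCf) || object@meanCf <= 0)
    msgs <- c(msgs, "meanCf must be positive")
  if (!isScalarNumber(object@sdCf) || object@sdCf < 0)
    msgs <- c(msgs, "sdCf must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ReferenceThreshold
#'
#' @param meanCf,sdCf grams; `n` count; `source` label.
#' @return A [ReferenceThreshold-class] object.
#' @export
referenceThreshold <- function(meanCf, sdCf, n, source = "unspecified") {
  new("ReferenceThreshold", meanCf = meanCf, sdCf = sdCf,
      n = as.integer(n), source = source)
}

#' The published viable-tissue contact-force reference
#'
#' The epicardial ventricular septum pre-ablation survey statistic
#' (>200 points, 7.6 +/- 4.4 g) used as the cohort comparator when
#' classifying sites for which no site-matched pre-ablation force exists.
#'
#' @return A [ReferenceThreshold-class] with mean 7.6 g and SD 4.4 g.
#' @examples
#' septalReference()
#' @export
septalReference <- function() {
  referenceThreshold(7.6, 4.4, 200L, "epicardial ventricular septum survey")
}
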