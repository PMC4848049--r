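#' @include AllClasses.R
NULL

#' Trace accessors
#'
#' Accessors for the channels and geometry of a [Trace-class]:
#' `sampleRate()` (samples/s), `nSamples()`, `traceTime()` (the implicit
#' uniform time axis in seconds), `mapSignal()` / `ecgSignal()` (mV),
#' `sensorSignal()` (nm) and `forceSignal()` (grams; `NULL` until a
#' calibration has been applied). `forceSignal<-` installs a calibrated
#' force channel.
#'
#' @param x,object a [Trace-class].
#' @param value numeric force channel, grams.
#' @return Numeric vectors, except `forceSignal()` which returns `NULL` for
#'   an uncalibrated trace.
#' @name trace-accessors
#' @aliases sampleRate nSamples traceTime mapSignal ecgSignal sensorSignal
#'   forceSignal forceSignal<-
#' @examples
#' cfg <- simulationConfig(seed = 1)
#' site <- drawSitePhysiology(1, 1, cfg)
#' tr <- generateTrace(site[1, ], cfConstant(15), cfg, durationS = 5)
#' length(mapSignal(tr)) == nSamples(tr)
NULL

#' @rdname trace-accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname trace-accessors
#' @export
setMethod("sampleRate", "Trace", function(x) x@sampleRate)

#' @rdname trace-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname trace-accessors
#' @export
setMethod("nSamples", "Trace", function(x) length(x@map))

#' @rdname trace-accessors
#' @export
setGeneric("traceTime", function(x) standardGeneric("traceTime"))
#' @rdname trace-accessors
#' @export
setMethod("traceTime", "Trace",
          function(x) (seq_len(length(x@map)) - 1) / x@sampleRate)

#' @rdname trace-accessors
#' @export
setGeneric("mapSignal", function(x) standardGeneric("mapSignal"))
#' @rdname trace-accessors
#' @export
setMethod("mapSignal", "Trace", function(x) x@map)

#' @rdname trace-accessors
#' @export
setGeneric("ecgSignal", function(x) standardGeneric("ecgSignal"))
#' @rdname trace-accessors
#' @export
setMethod("ecgSignal", "Trace", function(x) x@ecg)

#' @rdname trace-accessors
#' @export
setGeneric("sensorSignal", function(x) standardGeneric("sensorSignal"))
#' @rdname trace-accessors
#' @export
setMethod("sensorSignal", "Trace", function(x) x@sensor)

#' @rdname trace-accessors
#' @export
setGeneric("forceSignal", function(x) standardGeneric("forceSignal"))
#' @rdname trace-accessors
#' @export
setMethod("forceSignal", "Trace",
          function(x) if (length(x@force)) x@force else NULL)

#' @rdname trace-accessors
#' @export
setGeneric("forceSignal<-", function(x, value) standardGeneric("forceSignal<-"))
#' @rdname trace-accessors
#' @export
setMethod("forceSignal<-", "Trace", function(x, value) {
  x@force <- as.numeric(value)
  validObject(x)
  x
})

#' @rdname trace-accessors
#' @export
setGeneric("traceMetadata", function(x) standardGeneric("traceMetadata"))
#' @rdname trace-accessors
#' @export
setMethod("traceMetadata", "Trace", function(x) x@metadata)

setMethod("show", "Trace", function(object) {
  n <- length(object@map)
  cat(sprintf("Trace: %d samples @ %g Hz (%.2f s)\n",
              n, object@sampleRate, n / object@sampleRate))
  cat(sprintf("  channels: map [mV], ecg [mV], sensor [nm]%s\n",
              if (length(object@force)) ", force [g]" else ""))
  if (isTRUE(object@qualityFlags$breathHold))
    cat("  breath-hold recording (respiration suppressed)\n")
  invisible(object)
})

#' CalibrationCurve accessors
#'
#' `fiberId()` returns the fiber label; `calSlope()` (g/nm), `calIntercept()`
#' (g) and `calRmse()` (g) return the fit parameters.
#'
#' @param x a [CalibrationCurve-class].
#' @name calibration-accessors
#' @aliases fiberId calSlope calIntercept calRmse
NULL

#' @rdname calibration-accessors
#' @export
setGeneric("fiberId", function(x) standardGeneric("fiberId"))
#' @rdname calibration-accessors
#' @export
setMethod("fiberId", "CalibrationCurve", function(x) x@fiberId)

#' @rdname calibration-accessors
#' @export
setGeneric("calSlope", function(x) standardGeneric("calSlope"))
#' @rdname calibration-accessors
#' @export
setMethod("calSlope", "CalibrationCurve", function(x) x@slope)

#' @rdname calibration-accessors
#' @export
setGeneric("calIntercept", function(x) standardGeneric("calIntercept"))
#' @rdname calibration-accessors
#' @export
setMethod("calIntercept", "CalibrationCurve", function(x) x@intercept)

#' @rdname calibration-accessors
#' @export
setGeneric("calRmse", function(x) standardGeneric("calRmse"))
#' @rdname calibration-accessors
#' @export
setMethod("calRmse", "CalibrationCurve", function(x) x@rmse)

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve [%s]: force = %.4g g/nm * shift %+.4g g\n",
              object@fiberId, object@slope, object@intercept))
  cat(sprintf("  rmse %.4g g over %d bench points (sensor accuracy +/- %g nm)\n",
              object@rmse, object@nPoints, object@shiftAccuracy))
  invisible(object)
})

#' DetectionResult accessors
#'
#' `beatAssessments()` returns the per-beat data.frame; `runStart()` the
#' 1-based index of the first qualifying four-beat run (or `NA`);
#' `cfAtDetection()` the contact force at the last beat of that run (grams,
#' or `NA`); `maxCfApplied()` the maximum force applied.
#'
#' @param x a [DetectionResult-class].
#' @name detection-accessors
#' @aliases beatAssessments runStart cfAtDetection maxCfApplied
NULL

#' @rdname detection-accessors
#' @export
setGeneric("beatAssessments", function(x) standardGeneric("beatAssessments"))
#' @rdname detection-accessors
#' @export
setMethod("beatAssessments", "DetectionResult", function(x) x@beats)

#' @rdname detection-accessors
#' @export
setGeneric("runStart", function(x) standardGeneric("runStart"))
#' @rdname detection-accessors
#' @export
setMethod("runStart", "DetectionResult", function(x) x@runStart)

#' @rdname detection-accessors
#' @export
setGeneric("cfAtDetection", function(x) standardGeneric("cfAtDetection"))
#' @rdname detection-accessors
#' @export
setMethod("cfAtDetection", "DetectionResult", function(x) x@cfAtDetection)

#' @rdname detection-accessors
#' @export
setGeneric("maxCfApplied", function(x) standardGeneric("maxCfApplied"))
#' @rdname detection-accessors
#' @export
setMethod("maxCfApplied", "DetectionResult", function(x) x@maxCfApplied)

setMethod("show", "DetectionResult", function(object) {
  nb <- nrow(object@beats)
  np <- sum(object@beats$mapPresent, na.rm = TRUE)
  cat(sprintf("DetectionResult: %d beats, %d MAP-positive\n", nb, np))
  if (is.na(object@runStart)) {
    cat("  no qualifying run of consecutive similar MAPs\n")
  } else {
    cat(sprintf("  first qualifying run starts at beat %d; CF at detection %.2f g\n",
                object@runStart, object@cfAtDetection))
  }
  cat(sprintf("  max CF applied %.2f g\n", object@maxCfApplied))
  invisible(object)
})

setMethod("show", "ReferenceThreshold", function(object) {
  cat(sprintf("ReferenceThreshold: %.2f +/- %.2f g over %d sites (%s)\n",
              object@meanCf, object@sdCf, object@n, object@source))
  invisible(object)
})

#' @rdname detection-accessors
#' @export
setGeneric("referenceMean", function(x) standardGeneric("referenceMean"))
#' @rdname detection-accessors
#' @export
setMethod("referenceMean", "ReferenceThreshold", function(x) x@meanCf)

#' @rdname detection-accessors
#' @export
setGeneric("referenceSd", function(x) standardGeneric("referenceSd"))
#' @rdname detection-accessors
#' @export
setMethod("referenceSd", "ReferenceThreshold", function(x) x@sdCf)

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %g Hz, %g bpm, thresholds %g +/- %g g (floor %g g), seed %d\n",
              object@sampleRate, object@heartRate, object@thresholdMean,
              object@thresholdSd, object@thresholdFloor, object@seed))
  invisible(object)
})

setMethod("show", "DetectorConfig", function(object) {
  cat(sprintf("DetectorConfig: band %g-%g Hz, amplitude > %g mV, duration >= %g ms, run of %d (tol %g)\n",
              object@bandLow, object@bandHigh, object@minAmplitude,
              object@minDuration, object@consistencyRun,
              object@similarityTolerance))
  invisible(object)
})
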