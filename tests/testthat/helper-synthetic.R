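# Shared fixtures, all built in code.

# exact calibration curve matching a simulation config's fiber truth
idealCurve <- function(cfg) {
  calibrationCurve(cfg@fiberId, cfg@fiberSlope, cfg@fiberIntercept,
                   rmse = 0, nPoints = 2L)
}

# Trace whose MAP channel is a single noiseless rectangular pulse of
# `widthSamples` samples at `amplitude` mV. With the pulse starting at
# sample iStart, the detector measures amplitude exactly and
# MAPDUR = widthSamples + 4 ms at 1 kHz (upstroke smoothing spreads the
# activation 3 samples before the jump; EOR lands 1 sample after the fall).
rectPulseTrace <- function(amplitude, widthSamples, fs = 1000,
                           durationS = 1.2, iStart = 400L) {
  n <- as.integer(durationS * fs)
  map <- numeric(n)
  map[iStart:(iStart + widthSamples - 1L)] <- amplitude
  newTrace(fs, map, ecg = numeric(n), sensor = numeric(n))
}

rectPulseWindow <- function(fs = 1000, iStart = 400L) {
  list(beatIndex = 1L, qrsTime = (iStart - 1) / fs - 0.02,
       start = (iStart - 1) / fs - 0.15, end = (iStart - 1) / fs + 0.6)
}

# ECG-only trace with Gaussian R waves at the given peak times.
ecgTraceAt <- function(peakTimes, fs = 1000, durationS = NULL,
                       amplitude = 1, noiseSd = 0.02, seed = 1) {
  durationS <- durationS %||% (max(peakTimes) + 0.5)
  n <- as.integer(durationS * fs)
  t <- (seq_len(n) - 1) / fs
  ecg <- numeric(n)
  for (tk in peakTimes)
    ecg <- ecg + amplitude * exp(-(t - tk)^2 / (2 * 0.008^2))
  set.seed(seed)
  ecg <- ecg + rnorm(n, 0, noiseSd)
  newTrace(fs, map = numeric(n), ecg = ecg, sensor = numeric(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent exhaustive-scan oracle for the four-consecutive-waveform
# rule: first window of length L with all beats MAP-positive and every
# pair within tol relative difference (relative to the larger value).
oracleRunScan <- function(beats, L = 4L, tol = 0.15) {
  n <- nrow(beats)
  if (n < L) return(NA_integer_)
  for (s in 1:(n - L + 1L)) {
    ok <- TRUE
    for (i in s:(s + L - 1L)) {
      if (!isTRUE(beats$mapPresent[i])) { ok <- FALSE; break }
      for (j in s:(s + L - 1L)) {
        if (i >= j) next
        for (col in c("amplitude", "mapdur")) {
          xi <- beats[[col]][i]; xj <- beats[[col]][j]
          if (!is.finite(xi) || !is.finite(xj) ||
              abs(xi - xj) / max(xi, xj) > tol) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (!ok) break
    }
    if (ok) return(as.integer(s))
  }
  NA_integer_
}
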