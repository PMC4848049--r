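#' @include AllClasses.R
NULL

#' Fit a per-fiber wavelength-to-force calibration
#'
#' Ordinary least-squares fit of `force = slope * shift + intercept` to
#' bench data for one fiber Bragg grating. The intercept is left free (the
#' bench protocol does not force the line through the origin) and recorded.
#' On collinear input the fit is exact (rmse 0 to numerical tolerance).
#'
#' @param points data.frame with columns `force_g` (applied force, grams,
#'   >= 0) and `shift_nm` (measured wavelength shift, nm); at least two
#'   points with at least two distinct shifts.
#' @param fiberId label identifying the fiber the bench run belongs to.
#' @param shiftAccuracy quoted sensor accuracy, nm (default 1).
#' @return A [CalibrationCurve-class].
#' @examples
#' bench <- data.frame(force_g = c(0, 10, 20), shift_nm = c(0, 2, 4))
#' fitCalibration(bench, "fiber-A")  # slope 5 g/nm, intercept 0, rmse 0
#' @export
fitCalibration <- function(points, fiberId = "fiber-1", shiftAccuracy = 1) {
  if (!is.data.frame(points) || !all(c("force_g", "shift_nm") %in% names(points)))
    abortArgument("points must be a data.frame with columns force_g and shift_nm")
  f <- points$force_g
  s <- points$shift_nm
  if (any(!is.finite(f)) || any(!is.finite(s)))
    abortArgument("calibration points must be finite")
  if (any(f < 0))
    abortArgument("applied bench forces must be non-negative")
  if (length(s) < 2L || length(unique(s)) < 2L)
    abortDegenerate("need at least 2 points with 2 distinct shift values")
  fit <- lm(f ~ s)
  co <- coef(fit)
  calibrationCurve(fiberId = fiberId,
                   slope = unname(co[2L]), intercept = unname(co[1L]),
                   rmse = sqrt(mean(residuals(fit)^2)),
                   nPoints = length(s), shiftAccuracy = shiftAccuracy)
}

#' Convert wavelength shift to contact force
#'
#' Applies a fitted [CalibrationCurve-class] pointwise
#' (`force = slope * shift + intercept`) and clips negative results to 0 —
#' contact force is non-negative by definition; clipping is reported via a
#' message. For a [Trace-class] the sensor channel is converted and
#' installed as the force channel after verifying the fiber identity
#' recorded in the trace metadata; a mismatched fiber is an error, not a
#' warning, because calibration is per-fiber and mandatory.
#'
#' @param x a numeric vector of wavelength shifts (nm) or a [Trace-class].
#' @param curve a [CalibrationCurve-class].
#' @param fiberId for the numeric method: the fiber the series was recorded
#'   with; must match `fiberId(curve)`. Defaults to the curve's fiber.
#' @return For numeric input, a numeric force series (grams, same length);
#'   for a Trace, a new Trace carrying a calibrated force channel.
#' @examples
#' cv <- calibrationCurve("fiber-A", slope = 5, intercept = 0)
#' applyCalibration(c(1, 2, 3), cv)  # 5 10 15
#' @export
setGeneric("applyCalibration",
           function(x, curve, ...) standardGeneric("applyCalibration"))

#' @rdname applyCalibration
#' @export
setMethod("applyCalibration", "numeric", function(x, curve,
                                                  fiberId = curve@fiberId) {
  if (!is(curve, "CalibrationCurve"))
    abortArgument("curve must be a CalibrationCurve")
  if (!identical(fiberId, curve@fiberId))
    abortMismatch(sprintf(
      "calibration curve is for fiber '%s' but the series was recorded with fiber '%s'",
      curve@fiberId, fiberId))
  out <- curve@slope * x + curve@intercept
  nClip <- sum(out < 0, na.rm = TRUE)
  if (nClip > 0) {
    message(sprintf("applyCalibration: clipped %d negative force value(s) to 0",
                    nClip))
    out <- pmax(out, 0)
  }
  out
})

#' @rdname applyCalibration
#' @export
setMethod("applyCalibration", "Trace", function(x, curve) {
  recFiber <- x@metadata$fiberId %||% curve@fiberId
  forceSignal(x) <- suppressMessages(
    applyCalibration(sensorSignal(x), curve, fiberId = recFiber))
  x
})

#' Simulate a calibration bench run
#'
#' Incrementally loads a simulated fiber with known slope/intercept and
#' records noisy wavelength shifts — the in-silico analogue of the bench
#' calibration performed before each experiment.
#'
#' @param forces applied forces, grams.
#' @param slope,intercept true fiber response (g/nm, g).
#' @param noiseSd Gaussian noise SD on the recorded shift, nm.
#' @param seed integer seed.
#' @return data.frame with columns `force_g`, `shift_nm`.
#' @examples
#' bench <- simulateBench(seq(0, 30, by = 2), slope = 5, seed = 1)
#' fitCalibration(bench, "fbg-sim-01")
#' @export
simulateBench <- function(forces = seq(0, 30, by = 2), slope = 5,
                          intercept = 0, noiseSd = 0.005, seed = 1L) {
  withSeed(seed, {
    shift <- (forces - intercept) / slope + rnorm(length(forces), 0, noiseSd)
    data.frame(force_g = forces, shift_nm = shift)
  })
}

#' Read and write calibration stores
#'
#' A calibration store is a JSON file keyed by fiber id, each entry holding
#' slope, intercept, rmse, number of bench points and sensor accuracy.
#'
#' @param curves a list of [CalibrationCurve-class] objects (or one curve).
#' @param path file path.
#' @return `readCalibration()` returns a named list of
#'   [CalibrationCurve-class] objects; `writeCalibration()` returns `path`
#'   invisibly.
#' @name calibration-io
NULL

#' @rdname calibration-io
#' @export
writeCalibration <- function(curves, path) {
  if (is(curves, "CalibrationCurve")) curves <- list(curves)
  entries <- lapply(curves, function(cv) list(
    slope = cv@slope, intercept = cv@intercept, rmse = cv@rmse,
    n_points = cv@nPoints, shift_accuracy = cv@shiftAccuracy))
  names(entries) <- vapply(curves, fiberId, character(1))
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname calibration-io
#' @export
readCalibration <- function(path) {
  raw <- jsonlite::read_json(path)
  out <- lapply(names(raw), function(id) {
    e <- raw[[id]]
    calibrationCurve(id, e$slope, e$intercept, e$rmse, e$n_points,
                     e$shift_accuracy)
  })
  names(out) <- names(raw)
  out
}
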