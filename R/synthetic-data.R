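#' @include AllClasses.R
NULL

# ---------------------------------------------------------------------------
# Threshold distribution
# ---------------------------------------------------------------------------

# Underlying (mu, sigma) of a normal truncated below at `floor` whose
# *truncated* mean/SD equal the targets. Solved numerically so the realized
# distribution of viable-site thresholds reproduces the configured 7.6/4.4 g
# exactly, despite the physical floor.
truncNormalParams <- function(targetMean, targetSd, floor) {
  if (targetSd == 0) return(list(mu = targetMean, sigma = 0))
  moments <- function(mu, sigma) {
    a <- (floor - mu) / sigma
    lam <- dnorm(a) / pnorm(a, lower.tail = FALSE)
    m <- mu + sigma * lam
    v <- sigma^2 * (1 + a * lam - lam^2)
    c(mean = m, sd = sqrt(max(v, 0)))
  }
  obj <- function(p) {
    mo <- moments(p[1], exp(p[2]))
    (mo["mean"] - targetMean)^2 + (mo["sd"] - targetSd)^2
  }
  fit <- optim(c(targetMean, log(targetSd)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Rejection sampler for the truncated normal; deterministic under the
# caller's RNG state.
rThreshold <- function(n, config) {
  if (config@thresholdSd == 0) return(rep(config@thresholdMean, n))
  par <- truncNormalParams(config@thresholdMean, config@thresholdSd,
                           config@thresholdFloor)
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(n, par$mu, par$sigma)
    out <- c(out, draw[draw >= config@thresholdFloor])
  }
  out[seq_len(n)]
}

# ---------------------------------------------------------------------------
# Site physiology
# ---------------------------------------------------------------------------

#' Draw per-site physiology for a synthetic survey
#'
#' Assigns each site a viability flag and, for viable sites, a
#' contact-force elicitation threshold (grams), a MAP plateau amplitude (mV)
#' and a MAP duration (ms). Thresholds follow the configured truncated
#' normal; amplitude and duration are uniform over the configured ranges.
#' The first `round(nSites * fractionViable)` sites are made viable and the
#' order is then shuffled under the config seed, so the viable count is
#' exact. Non-viable (ablated) sites never produce a MAP at any force.
#'
#' @param nSites number of sites (>= 1).
#' @param fractionViable proportion of viable sites in \[0, 1\].
#' @param config a [SimulationConfig-class].
#' @return A data.frame with one row per site: `siteId`, `viable`,
#'   `cfThreshold` (g, `NA` for non-viable sites), `mapAmplitude` (mV),
#'   `mapDuration` (ms), `inLesionPattern` (initialised `FALSE`; set by
#'   survey generators).
#' @examples
#' sites <- drawSitePhysiology(5, 0.6, simulationConfig(seed = 2))
#' sum(sites$viable)  # exactly round(5 * 0.6) = 3
#' @export
drawSitePhysiology <- function(nSites, fractionViable, config = simulationConfig()) {
  if (!isScalarNumber(nSites) || nSites < 1)
    abortArgument("nSites must be a positive count")
  if (!isScalarNumber(fractionViable) || fractionViable < 0 || fractionViable > 1)
    abortArgument("fractionViable must lie in [0, 1]")
  nSites <- as.integer(nSites)
  withSeed(config@seed, {
    nViable <- as.integer(round(nSites * fractionViable))
    viable <- c(rep(TRUE, nViable), rep(FALSE, nSites - nViable))
    viable <- viable[sample.int(nSites)]
    thr <- amp <- dur <- rep(NA_real_, nSites)
    if (nViable > 0L) {
      idx <- which(viable)
      thr[idx] <- rThreshold(nViable, config)
      amp[idx] <- runif(nViable, config@mapAmplitudeRange[1],
                        config@mapAmplitudeRange[2])
      dur[idx] <- runif(nViable, config@mapDurationRange[1],
                        config@mapDurationRange[2])
    }
    data.frame(siteId = sprintf("S%03d", seq_len(nSites)),
               viable = viable, cfThreshold = thr,
               mapAmplitude = amp, mapDuration = dur,
               inLesionPattern = FALSE, stringsAsFactors = FALSE)
  })
}

# ---------------------------------------------------------------------------
# Contact-force profiles
# ---------------------------------------------------------------------------

#' Contact-force profile helpers
#'
#' Profiles are functions of time (seconds) returning applied contact force
#' in grams; [generateTrace()] evaluates them on the full trace.
#' `cfConstant(g)` holds a fixed force; `cfRamp(from, to, duration)` rises
#' linearly and holds the end value; `cfRampHold(rate, holdAt)` rises at
#' `rate` g/s and holds once `holdAt` grams is reached — the operator model
#' of increasing force until MAPs appear, then holding steady.
#'
#' @param g,from,to,holdAt grams; `duration` s; `rate` g/s.
#' @return A function `f(t)` mapping seconds to grams.
#' @examples
#' f <- cfRamp(0, 16, 15)
#' f(c(0, 7.5, 15, 20))
#' @name cf-profiles
NULL

#' @rdname cf-profiles
#' @export
cfConstant <- function(g) {
  force(g)
  function(t) rep_len(g, length(t))
}

#' @rdname cf-profiles
#' @export
cfRamp <- function(from, to, duration) {
  force(from); force(to); force(duration)
  function(t) from + (to - from) * pmin(pmax(t, 0), duration) / duration
}

#' @rdname cf-profiles
#' @export
cfRampHold <- function(rate, holdAt, from = 0) {
  force(rate); force(holdAt); force(from)
  function(t) pmin(from + rate * pmax(t, 0), holdAt)
}

# ---------------------------------------------------------------------------
# Waveform templates (internal)
# ---------------------------------------------------------------------------

# MAP template relative to local onset: 2-ms linear upstroke to the plateau,
# flat plateau, exponential repolarization tail. The plateau/tau split is
# chosen so the APD90-style duration (onset to 90% recovery) equals
# `durationMs` up to the upstroke width.
mapTemplate <- function(trel, amplitude, durationMs) {
  rise <- 0.002
  d <- durationMs / 1000
  plateau <- 0.6 * d
  tau <- 0.4 * d / log(10)
  y <- numeric(length(trel))
  up <- trel >= 0 & trel < rise
  fl <- trel >= rise & trel < rise + plateau
  dn <- trel >= rise + plateau
  y[up] <- amplitude * trel[up] / rise
  y[fl] <- amplitude
  y[dn] <- amplitude * exp(-(trel[dn] - rise - plateau) / tau)
  y
}

# Gaussian bump helper for ECG waves and far-field residue.
gaussWave <- function(trel, amplitude, sd) {
  amplitude * exp(-trel^2 / (2 * sd^2))
}

# ---------------------------------------------------------------------------
# Trace generation
# ---------------------------------------------------------------------------

#' Generate one synthetic co-registered MAP/ECG/sensor trace
#'
#' The ECG channel carries QRS-like complexes (R wave with S dip and T wave)
#' at the configured heart rate. For each beat the applied contact force is
#' read at the MAP onset time; if the site is viable and the force reaches
#' the site threshold, the MAP channel carries a MAP-shaped deflection
#' (2-ms upstroke, plateau, exponential repolarization) with the site's
#' amplitude and duration, time-locked shortly after the QRS. Beats below
#' threshold — and every beat of a non-viable site — carry only a small
#' far-field residue below the detector's amplitude criterion. The sensor
#' channel encodes the applied force through the inverse of the canonical
#' fiber calibration plus wavelength noise. Respiration adds sinusoidal
#' baseline wander to the MAP and force channels unless `breathHold` is set.
#'
#' Ground truth (site physiology, QRS times, per-beat elicitation, applied
#' force at each beat) is stored in the trace metadata for testing.
#'
#' @param site one row of a [drawSitePhysiology()] data.frame (or an
#'   equivalent list with fields `viable`, `cfThreshold`, `mapAmplitude`,
#'   `mapDuration`).
#' @param cfProfile a function of time (s) returning applied force (g); see
#'   [cfConstant()], [cfRamp()], [cfRampHold()]. Must be non-negative over
#'   the trace.
#' @param config a [SimulationConfig-class]; `config@seed` makes the trace
#'   bit-reproducible.
#' @param durationS trace duration in seconds; must cover at least 5 beats.
#' @return A [Trace-class].
#' @examples
#' cfg <- simulationConfig(seed = 3)
#' site <- drawSitePhysiology(1, 1, cfg)[1, ]
#' tr <- generateTrace(site, cfConstant(site$cfThreshold + 5), cfg, 6)
#' tr
#' @export
generateTrace <- function(site, cfProfile, config = simulationConfig(),
                          durationS = 10) {
  site <- as.list(site)
  if (!is.function(cfProfile))
    abortArgument("cfProfile must be a function of time returning grams")
  fs <- config@sampleRate
  rr <- 60 / config@heartRate
  qrsTimes <- seq(config@firstBeatTime, durationS - 0.3, by = rr)
  if (length(qrsTimes) < 5)
    abortArgument("trace duration must cover at least 5 beats")
  n <- as.integer(round(durationS * fs))
  t <- (seq_len(n) - 1) / fs

  cfBase <- cfProfile(t)
  if (length(cfBase) != n)
    abortArgument("cfProfile must return one value per time point")
  if (any(!is.finite(cfBase)) || any(cfBase < 0))
    abortArgument("cfProfile must return finite non-negative forces")

  withSeed(config@seed, {
    respPhase <- 2 * pi * t / config@respirationPeriod
    respOn <- !config@breathHold
    cfTrue <- cfBase +
      (if (respOn) config@respirationForceAmplitude * sin(respPhase) else 0)
    cfTrue <- pmax(cfTrue, 0)

    ecg <- numeric(n)
    map <- if (respOn) config@respirationAmplitude * sin(respPhase) else numeric(n)

    onsetIdx <- pmin(pmax(round((qrsTimes + config@mapOnsetDelay) * fs) + 1L, 1L), n)
    elicited <- logical(length(qrsTimes))
    viable <- isTRUE(site$viable)
    for (k in seq_along(qrsTimes)) {
      tk <- qrsTimes[k]
      span <- idxRange(tk - 0.1, tk + 0.45, fs, n)
      trelE <- t[span] - tk
      ecg[span] <- ecg[span] +
        gaussWave(trelE, config@ecgAmplitude, 0.008) -
        gaussWave(trelE - 0.022, 0.2 * config@ecgAmplitude, 0.008) +
        gaussWave(trelE - 0.25, 0.15 * config@ecgAmplitude, 0.05)

      elicited[k] <- viable && is.finite(site$cfThreshold) &&
        cfTrue[onsetIdx[k]] >= site$cfThreshold
      if (elicited[k]) {
        dur <- site$mapDuration
        wlen <- 0.002 + 0.6 * dur / 1000 + 6 * (0.4 * dur / 1000 / log(10))
        spanM <- idxRange(tk + config@mapOnsetDelay,
                          tk + config@mapOnsetDelay + wlen, fs, n)
        map[spanM] <- map[spanM] +
          mapTemplate(t[spanM] - tk - config@mapOnsetDelay,
                      site$mapAmplitude, dur)
      } else {
        spanF <- idxRange(tk - 0.05, tk + 0.2, fs, n)
        map[spanF] <- map[spanF] +
          gaussWave(t[spanF] - tk - 0.05, config@farFieldAmplitude, 0.025)
      }
    }

    map <- map + rnorm(n, 0, config@noiseSd)
    ecg <- ecg + rnorm(n, 0, config@noiseSd)
    sensor <- (cfTrue - config@fiberIntercept) / config@fiberSlope +
      rnorm(n, 0, config@sensorNoiseSd)

    newTrace(fs, map, ecg, sensor,
             qualityFlags = list(breathHold = config@breathHold),
             metadata = list(
               site = site,
               qrsTimes = qrsTimes,
               elicited = elicited,
               cfAtBeat = cfTrue[onsetIdx],
               fiberId = config@fiberId,
               seed = config@seed))
  })
}

# ---------------------------------------------------------------------------
# Lesion patterns and surveys
# ---------------------------------------------------------------------------

#' Describe a linear-lesion grid pattern with planted gaps
#'
#' Builds the layout table that [generateSurvey()] consumes: a grid of
#' anatomic sites labelled `A1`, `A2`, ... (letter = row), a set of sites on
#' the intended lesion line, and an optional subset of those left unablated
#' — the planted conduction gaps.
#'
#' @param rows,cols grid dimensions.
#' @param patternSites character vector of site labels on the lesion line.
#' @param gapSites subset of `patternSites` left viable (planted gaps).
#' @return data.frame with `siteId`, `row`, `col`, `inPattern`, `ablated`.
#' @examples
#' lesionPattern(4, 4, patternSites = c("B1", "B2", "B3", "B4"), gapSites = "B3")
#' @export
lesionPattern <- function(rows, cols, patternSites, gapSites = character(0)) {
  if (rows < 1 || cols < 1) abortArgument("grid must be at least 1 x 1")
  ids <- as.vector(t(outer(LETTERS[seq_len(rows)], seq_len(cols), paste0)))
  bad <- setdiff(c(patternSites, gapSites), ids)
  if (length(bad))
    abortArgument(paste("unknown site labels:", paste(bad, collapse = ", ")))
  if (!all(gapSites %in% patternSites))
    abortArgument("gapSites must be a subset of patternSites")
  data.frame(siteId = ids,
             row = rep(seq_len(rows), each = cols),
             col = rep(seq_len(cols), times = rows),
             inPattern = ids %in% patternSites,
             ablated = ids %in% setdiff(patternSites, gapSites),
             stringsAsFactors = FALSE)
}

# Operator-protocol force profile for one application: ramp at `rampStep`
# grams per beat and hold at the first beat-onset level that reaches
# `target` grams. Returns the profile, the hold level and the trace
# duration needed to fit `holdBeats` beats beyond the crossing.
protocolProfile <- function(target, config, rampStep = 0.25, holdBeats = 8L) {
  rr <- 60 / config@heartRate
  rate <- rampStep / rr
  onset <- function(k) config@firstBeatTime + (k - 1) * rr + config@mapOnsetDelay
  kCross <- max(1L, ceiling((target / rate - config@firstBeatTime -
                               config@mapOnsetDelay) / rr + 1))
  # respiration can depress the force at the nominal crossing beat; hold a
  # touch above target so elicitation is reached within the hold window
  hold <- max(rate * onset(kCross), target + config@respirationForceAmplitude)
  durationS <- onset(kCross) + holdBeats * rr + 0.5
  nBeatsMin <- config@firstBeatTime + 4 * rr + 0.5
  list(profile = cfRampHold(rate, hold),
       hold = hold,
       durationS = max(durationS, nBeatsMin + rr))
}

#' Generate a full pre/post-ablation synthetic survey
#'
#' For every site in the pattern, simulates one pre-ablation and one
#' post-ablation catheter application. Pre-ablation, all sites are viable
#' with thresholds drawn from the configured distribution; the applied
#' force follows the operator protocol (ramp, then hold once the site
#' threshold is reached). Post-ablation, sites marked `ablated` are
#' non-viable and the operator ramps to a supra-reference hold —
#' `max(postMaxCf, site threshold + 2 g)` — mirroring the practice of
#' pushing the force beyond the site's own pre-ablation requirement before
#' declaring it silent; unablated sites (outside the line, and planted
#' gaps) remain viable with their pre-ablation physiology.
#'
#' @param pattern a [lesionPattern()] data.frame.
#' @param config a [SimulationConfig-class]; per-site seeds are derived from
#'   `config@seed`, so the whole survey is reproducible.
#' @param rampStep force increment per beat during the ramp, grams.
#' @param holdBeats beats held after the ramp crosses its target.
#' @param postMaxCf minimum post-ablation hold force, grams.
#' @return list with `pattern`, `sites` (per-site list of `siteId`,
#'   `inPattern`, `ablatedTruth`, `pre` and `post` [Trace-class]s, and the
#'   drawn `physiology` row) and `config`.
#' @examples
#' pat <- lesionPattern(2, 2, patternSites = c("A1", "A2"), gapSites = "A2")
#' sv <- generateSurvey(pat, simulationConfig(seed = 4))
#' length(sv$sites)
#' @export
generateSurvey <- function(pattern, config = simulationConfig(),
                           rampStep = 0.25, holdBeats = 8L, postMaxCf = 15) {
  if (!is.data.frame(pattern) || nrow(pattern) == 0L)
    abortArgument("pattern must be a non-empty data.frame")
  need <- c("siteId", "inPattern", "ablated")
  if (!all(need %in% names(pattern)))
    abortArgument("pattern needs columns siteId, inPattern, ablated")

  phys <- drawSitePhysiology(nrow(pattern), 1.0, config)
  phys$siteId <- pattern$siteId
  phys$inLesionPattern <- pattern$inPattern

  sites <- vector("list", nrow(pattern))
  for (i in seq_len(nrow(pattern))) {
    p <- phys[i, ]
    preCfg <- config; preCfg@seed <- childSeed(config@seed, 2L * i)
    postCfg <- config; postCfg@seed <- childSeed(config@seed, 2L * i + 1L)

    prof <- protocolProfile(p$cfThreshold, config, rampStep, holdBeats)
    pre <- generateTrace(p, prof$profile, preCfg, prof$durationS)

    if (pattern$ablated[i]) {
      postSite <- p; postSite$viable <- FALSE
      target <- max(postMaxCf, p$cfThreshold + 2)
    } else {
      postSite <- p
      target <- p$cfThreshold
    }
    postProf <- protocolProfile(target, config, rampStep, holdBeats)
    post <- generateTrace(postSite, postProf$profile, postCfg,
                          postProf$durationS)

    sites[[i]] <- list(siteId = p$siteId, inPattern = pattern$inPattern[i],
                       ablatedTruth = pattern$ablated[i],
                       physiology = p, pre = pre, post = post)
  }
  list(pattern = pattern, sites = sites, config = config)
}

#' Simulate a pre-ablation reference survey of viable sites
#'
#' The in-silico analogue of collecting >200 MAP points on viable
#' epicardial septum: for `nSites` viable sites, a trace is generated under
#' the operator protocol (force ramp, hold at first threshold crossing) and
#' returned together with the drawn physiology, ready for the detection
#' pipeline and [buildReference()].
#'
#' @inheritParams generateSurvey
#' @param nSites number of viable sites.
#' @return list of per-site lists: `siteId`, `physiology`, `trace`.
#' @export
generateReferenceSurvey <- function(nSites, config = simulationConfig(),
                                    rampStep = 0.25, holdBeats = 8L) {
  phys <- drawSitePhysiology(nSites, 1.0, config)
  lapply(seq_len(nrow(phys)), function(i) {
    p <- phys[i, ]
    cfg <- config; cfg@seed <- childSeed(config@seed, i)
    prof <- protocolProfile(p$cfThreshold, config, rampStep, holdBeats)
    list(siteId = p$siteId, physiology = p,
         trace = generateTrace(p, prof$profile, cfg, prof$durationS))
  })
}
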