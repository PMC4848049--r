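#' @include AllClasses.R
NULL

# Full-precision numeric formatting so CSV round trips are bit-exact.
fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write / read a multichannel trace as CSV with a JSON sidecar
#'
#' The CSV carries columns `time_s,map_mv,ecg_mv,sensor_nm` (plus `force_g`
#' once calibrated); the sidecar `<path>.json` stores the sample rate,
#' quality flags and — for synthetic traces — the generator ground truth.
#' Numbers are written at full precision so a write/read cycle reproduces
#' the in-memory trace exactly.
#'
#' @param trace a [Trace-class].
#' @param path CSV path; the sidecar is written at `paste0(path, ".json")`.
#' @return `writeTrace()` returns `path` invisibly; `readTrace()` a
#'   [Trace-class].
#' @name trace-io
NULL

#' @rdname trace-io
#' @export
writeTrace <- function(trace, path) {
  df <- data.frame(time_s = fmtNum(traceTime(trace)),
                   map_mv = fmtNum(trace@map),
                   ecg_mv = fmtNum(trace@ecg),
                   sensor_nm = fmtNum(trace@sensor),
                   stringsAsFactors = FALSE)
  if (length(trace@force)) df$force_g <- fmtNum(trace@force)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(sample_rate_hz = trace@sampleRate,
               quality_flags = trace@qualityFlags,
               metadata = trace@metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname trace-io
#' @export
readTrace <- function(path) {
  df <- read.csv(path)
  need <- c("time_s", "map_mv", "ecg_mv", "sensor_nm")
  if (!all(need %in% names(df)))
    abortArgument(paste("trace CSV must contain columns:",
                        paste(need, collapse = ", ")))
  dt <- diff(df$time_s)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-9)
    abortArgument("trace time axis must be strictly increasing and uniform")
  fs <- 1 / median(dt)
  qualityFlags <- list(); metadata <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    fs <- side$sample_rate_hz %||% fs
    qualityFlags <- as.list(side$quality_flags %||% list())
    metadata <- as.list(side$metadata %||% list())
  }
  newTrace(fs, df$map_mv, df$ecg_mv, df$sensor_nm,
           force = if ("force_g" %in% names(df)) df$force_g else numeric(0),
           qualityFlags = qualityFlags, metadata = metadata)
}

#' Write / read a full synthetic survey directory
#'
#' One directory per survey: `sites.csv` (`site_id,phase,in_pattern,
#' trace_file`), one trace CSV (+ JSON sidecar) per site and phase, and
#' `ground_truth.json` holding the planted physiology for testing.
#'
#' @param survey a [generateSurvey()] result.
#' @param dir output directory (created if needed).
#' @return `writeSurvey()` returns `dir` invisibly; `readSurvey()` a list
#'   with `sites` (data.frame) and `traces` (named list of [Trace-class],
#'   keyed `siteId.phase`).
#' @name survey-io
NULL

#' @rdname survey-io
#' @export
writeSurvey <- function(survey, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in survey$sites) {
    for (phase in c("pre", "post")) {
      fn <- sprintf("%s_%s.csv", s$siteId, phase)
      writeTrace(s[[phase]], file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = s$siteId, phase = phase, in_pattern = s$inPattern,
        trace_file = fn, stringsAsFactors = FALSE)
    }
  }
  write.csv(do.call(rbind, rows), file.path(dir, "sites.csv"),
            row.names = FALSE, quote = FALSE)
  truth <- lapply(survey$sites, function(s) list(
    site_id = s$siteId, in_pattern = s$inPattern,
    ablated = s$ablatedTruth,
    cf_threshold = s$physiology$cfThreshold,
    map_amplitude = s$physiology$mapAmplitude,
    map_duration = s$physiology$mapDuration))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' @rdname survey-io
#' @export
readSurvey <- function(dir) {
  sitesFile <- file.path(dir, "sites.csv")
  if (!file.exists(sitesFile))
    abortArgument(paste("no sites.csv under", dir))
  sites <- read.csv(sitesFile, stringsAsFactors = FALSE)
  traces <- list()
  for (i in seq_len(nrow(sites))) {
    key <- paste(sites$site_id[i], sites$phase[i], sep = ".")
    traces[[key]] <- readTrace(file.path(dir, sites$trace_file[i]))
  }
  list(sites = sites, traces = traces)
}

# ---------------------------------------------------------------------------
# Worked-example fixtures
# ---------------------------------------------------------------------------

#' Load a packaged worked-example survey fixture
#'
#' Site-level summaries of the published worked examples, transcribed from
#' the running text: the three epicardial right-ventricular lesion-pattern
#' surveys (`"set1"`, `"set2"`, `"set3"`) and the 9-site endocardial mitral
#' isthmus survey (`"endocardial_mi"`). Only text-printed force values are
#' carried; forces described merely as exceeding the viable-tissue
#' reference appear as `supraReference` sentinels with `NA` grams. The
#' summaries feed [classifySurvey()] directly, without raw traces.
#'
#' @param name one of `"set1"`, `"set2"`, `"set3"`, `"endocardial_mi"`.
#' @return data.frame with `siteId`, `phase` (`"post"`), `inPattern`,
#'   `mapPresent`, `cfAtDetection`, `maxCfApplied`, `supraReference`;
#'   attribute `provenance` carries the citation note.
#' @examples
#' loadFixture("set1")
#' @export
loadFixture <- function(name) {
  valid <- c("set1", "set2", "set3", "endocardial_mi")
  if (!is.character(name) || length(name) != 1L || !name %in% valid)
    abortLookup(paste0("unknown fixture '", name, "'; available: ",
                       paste(valid, collapse = ", ")))
  path <- system.file("extdata", paste0("fixture_", name, ".csv"),
                      package = "mapgap", mustWork = TRUE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(
    siteId = as.character(raw$site_id),
    phase = "post",
    inPattern = raw$in_pattern,
    mapPresent = raw$map_present,
    cfAtDetection = ifelse(raw$map_present, raw$cf_g, NA_real_),
    maxCfApplied = raw$cf_g,
    supraReference = raw$supra_reference,
    stringsAsFactors = FALSE)
  manifest <- fixtureManifest()
  attr(out, "provenance") <- manifest[[name]]$provenance
  out
}

#' The fixture citation manifest
#'
#' Machine-readable record of where every fixture number comes from, used
#' by the fidelity tests that cross-check fixture contents against the
#' printed values.
#'
#' @return Named list, one entry per fixture, with `provenance` text and
#'   the printed per-site values.
#' @export
fixtureManifest <- function() {
  path <- system.file("extdata", "fixture_manifest.json",
                      package = "mapgap", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = FALSE)
}
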