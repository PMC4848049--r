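#' @include AllClasses.R
NULL

#' Build a cohort contact-force reference from pre-ablation surveys
#'
#' Mean and SD of the contact force at first sustained MAP detection over a
#' set of pre-ablation site assessments. Assessments without a detection
#' (no qualifying run of consecutive MAPs) are excluded and reported via a
#' message; a singleton yields SD 0.
#'
#' @param assessments data.frame with at least `siteId`, `phase`
#'   (`"pre"`/`"post"`) and `cfAtDetection` (grams, `NA` when no MAP was
#'   sustained).
#' @param source provenance label stored on the reference.
#' @return A [ReferenceThreshold-class].
#' @examples
#' df <- data.frame(siteId = c("a", "b", "c"), phase = "pre",
#'                  cfAtDetection = c(4, 8, 12))
#' buildReference(df)  # mean 8 g
#' @export
buildReference <- function(assessments, source = "pre-ablation survey") {
  if (!is.data.frame(assessments) ||
      !all(c("phase", "cfAtDetection") %in% names(assessments)))
    abortArgument("assessments must have columns phase and cfAtDetection")
  pre <- assessments[assessments$phase == "pre", , drop = FALSE]
  qual <- pre[is.finite(pre$cfAtDetection), , drop = FALSE]
  dropped <- nrow(pre) - nrow(qual)
  if (dropped > 0)
    message(sprintf("buildReference: excluded %d assessment(s) without a MAP detection",
                    dropped))
  if (nrow(qual) == 0L)
    abortReference("no pre-ablation assessment with a contact force at detection")
  cf <- qual$cfAtDetection
  referenceThreshold(mean(cf), if (length(cf) > 1L) sd(cf) else 0,
                     length(cf), source)
}

#' Classify one post-ablation site
#'
#' Applies the lesion-integrity decision rules to a post-ablation site
#' assessment:
#' \itemize{
#'   \item MAP present and the site lies on the intended lesion line: a
#'     conduction **gap**;
#'   \item MAP present outside the line: **conductive** (viable, non-ablated
#'     myocardium);
#'   \item no MAP and the applied force exceeded the reference force:
#'     **non_conductive**;
#'   \item no MAP but the applied force never exceeded the reference:
#'     **indeterminate** — sufficient contact was never proven, so a
#'     non-conductive call would be unsafe.
#' }
#' The comparator is the site-matched pre-ablation contact force when
#' available, else the cohort mean (`reference`); "exceeded" is strict, so
#' a tie falls to indeterminate. A `supraReference` sentinel marks
#' recordings where the force is known to have exceeded the reference even
#' though its exact value was not retained.
#'
#' @param siteId site label.
#' @param mapPresent logical: was a sustained MAP detected post-ablation?
#' @param inPattern logical: does the site lie on the intended lesion line?
#' @param maxCfApplied maximum contact force applied, grams (may be `NA`
#'   when `supraReference` is set).
#' @param cfAtDetectionPost force at detection post-ablation, grams (`NA`
#'   when no MAP or unknown).
#' @param preAblationCf site-matched pre-ablation force at detection, grams
#'   (`NA` when unavailable).
#' @param supraReference logical sentinel: force exceeded the reference,
#'   exact value unknown.
#' @param reference a [ReferenceThreshold-class] cohort fallback.
#' @return One-row data.frame: `siteId`, `label` (one of `conductive`,
#'   `non_conductive`, `gap`, `indeterminate`), `cfReferenceUsed`,
#'   `cfEvidence` (grams), `rationale`.
#' @examples
#' classifySite("B3", mapPresent = TRUE, inPattern = TRUE,
#'              maxCfApplied = 7.3, cfAtDetectionPost = 7.3,
#'              reference = septalReference())
#' @export
classifySite <- function(siteId, mapPresent, inPattern, maxCfApplied = NA,
                         cfAtDetectionPost = NA, preAblationCf = NA,
                         supraReference = FALSE,
                         reference = septalReference()) {
  if (!is(reference, "ReferenceThreshold"))
    abortArgument("reference must be a ReferenceThreshold")
  if (!is.logical(mapPresent) || is.na(mapPresent) ||
      !is.logical(inPattern) || is.na(inPattern))
    abortArgument("mapPresent and inPattern must be TRUE or FALSE")

  siteMatched <- is.finite(preAblationCf)
  refCf <- if (siteMatched) preAblationCf else referenceMean(reference)
  refSrc <- if (siteMatched) "site-matched pre-ablation CF" else
    sprintf("cohort mean (%s)", reference@source)

  if (mapPresent) {
    label <- if (inPattern) "gap" else "conductive"
    evidence <- if (is.finite(cfAtDetectionPost)) cfAtDetectionPost else
      maxCfApplied
    rationale <- if (inPattern)
      "MAP present within the lesion pattern: conduction gap" else
      "MAP present outside the lesion pattern: viable conductive tissue"
  } else {
    exceeded <- isTRUE(supraReference) ||
      (is.finite(maxCfApplied) && maxCfApplied > refCf)
    label <- if (exceeded) "non_conductive" else "indeterminate"
    evidence <- maxCfApplied
    rationale <- if (exceeded)
      sprintf("no MAP at forces exceeding the reference (%s)", refSrc) else
      sprintf("no MAP, but applied force never exceeded the reference (%s): contact unproven",
              refSrc)
  }
  data.frame(siteId = siteId, label = label,
             cfReferenceUsed = refCf,
             cfEvidence = if (is.finite(evidence)) evidence else NA_real_,
             rationale = rationale, stringsAsFactors = FALSE)
}

#' Classify every post-ablation site of a survey table
#'
#' Vectorized wrapper over [classifySite()]. Rows must be post-ablation
#' assessments; a pre-ablation row is an argument error.
#'
#' @param assessments data.frame with columns `siteId`, `phase` (all
#'   `"post"`), `inPattern`, `mapPresent`, and optionally `maxCfApplied`,
#'   `cfAtDetection`, `preAblationCf`, `supraReference`.
#' @param reference a [ReferenceThreshold-class].
#' @return data.frame of per-site classifications (one row per site).
#' @export
classifySurvey <- function(assessments, reference = septalReference()) {
  if (!all(c("siteId", "inPattern", "mapPresent") %in% names(assessments)))
    abortArgument("assessments need siteId, inPattern and mapPresent columns")
  if ("phase" %in% names(assessments) && any(assessments$phase != "post"))
    abortArgument("classification applies to post-ablation assessments only")
  grab <- function(col, default) {
    if (col %in% names(assessments)) assessments[[col]] else
      rep(default, nrow(assessments))
  }
  maxCf <- grab("maxCfApplied", NA_real_)
  cfDet <- grab("cfAtDetection", NA_real_)
  preCf <- grab("preAblationCf", NA_real_)
  supra <- grab("supraReference", FALSE)
  rows <- lapply(seq_len(nrow(assessments)), function(i)
    classifySite(assessments$siteId[i], assessments$mapPresent[i],
                 assessments$inPattern[i], maxCf[i], cfDet[i], preCf[i],
                 isTRUE(supra[i]), reference))
  out <- do.call(rbind, rows)
  out$inPattern <- assessments$inPattern
  out
}

#' Summarise site classifications into a lesion-pattern report
#'
#' Counts sites by label — separately for sites on and off the intended
#' lesion line — and lists the conduction gaps. The result prints as a
#' human-readable table and serialises to JSON via [writeReport()].
#'
#' @param classifications output of [classifySurvey()] (requires the
#'   `inPattern` column).
#' @param reference the [ReferenceThreshold-class] used, stored for audit.
#' @return An object of class `surveyReport`: list with `nSites`,
#'   `counts` (label x in/out-of-pattern table), `gapSites`,
#'   `mapPositiveSites`, `reference`, `classifications`.
#' @export
surveyReport <- function(classifications, reference = NULL) {
  if (nrow(classifications) == 0L)
    abortArgument("need at least one classification")
  if (!"inPattern" %in% names(classifications))
    abortArgument("classifications must carry the inPattern column")
  labels <- c("conductive", "non_conductive", "gap", "indeterminate")
  cls <- factor(classifications$label, levels = labels)
  counts <- table(label = cls,
                  pattern = factor(ifelse(classifications$inPattern,
                                          "in_pattern", "out_of_pattern"),
                                   levels = c("in_pattern",
                                              "out_of_pattern")))
  mapPos <- classifications$siteId[classifications$label %in%
                                     c("gap", "conductive")]
  structure(list(
    nSites = nrow(classifications),
    counts = counts,
    gapSites = classifications$siteId[classifications$label == "gap"],
    mapPositiveSites = mapPos,
    reference = if (is.null(reference)) NULL else
      list(meanCf = referenceMean(reference), sdCf = referenceSd(reference),
           n = reference@n, source = reference@source),
    classifications = classifications
  ), class = "surveyReport")
}

#' @export
print.surveyReport <- function(x, ...) {
  cat(sprintf("Lesion survey report: %d sites assessed\n", x$nSites))
  print(x$counts)
  if (length(x$gapSites)) {
    cat("Conduction gaps:", paste(x$gapSites, collapse = ", "), "\n")
  } else {
    cat("No conduction gaps detected.\n")
  }
  if (!is.null(x$reference))
    cat(sprintf("Reference CF: %.2f +/- %.2f g (%s, n = %d)\n",
                x$reference$meanCf, x$reference$sdCf, x$reference$source,
                x$reference$n))
  invisible(x)
}

#' Write / read a survey report as JSON
#'
#' @param report a `surveyReport`.
#' @param path output path.
#' @return `writeReport()` returns `path` invisibly; `readReport()` the
#'   parsed list.
#' @name report-io
NULL

#' @rdname report-io
#' @export
writeReport <- function(report, path) {
  payload <- list(
    n_sites = report$nSites,
    counts = as.list(as.data.frame(report$counts)),
    gap_sites = as.list(report$gapSites),
    map_positive_sites = as.list(report$mapPositiveSites),
    reference = report$reference,
    classifications = report$classifications[
      , c("siteId", "label", "cfReferenceUsed", "cfEvidence", "inPattern",
          "rationale")]
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname report-io
#' @export
readReport <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Plot a classified survey grid
#'
#' Red/green grid rendering of a classified survey: green for MAP-positive
#' sites (conductive tissue or gaps), red for non-conductive sites, grey
#' for indeterminate ones. Requires ggplot2.
#'
#' @param classifications output of [classifySurvey()].
#' @param pattern the [lesionPattern()] layout providing row/col positions.
#' @return A ggplot object.
#' @export
plotSurvey <- function(classifications, pattern) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotSurvey requires the ggplot2 package")
  df <- merge(classifications, pattern[, c("siteId", "row", "col")],
              by = "siteId")
  df$status <- ifelse(df$label %in% c("conductive", "gap"), "MAP recorded",
                      ifelse(df$label == "non_conductive", "no MAP",
                             "indeterminate"))
  ggplot2::ggplot(df, ggplot2::aes(x = col, y = row, fill = status)) +
    ggplot2::geom_tile(color = "white", linewidth = 1) +
    ggplot2::geom_text(ggplot2::aes(label = siteId)) +
    ggplot2::scale_fill_manual(values = c("MAP recorded" = "#2e9e4f",
                                          "no MAP" = "#c23b22",
                                          "indeterminate" = "grey70")) +
    ggplot2::scale_y_reverse() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL)
}
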