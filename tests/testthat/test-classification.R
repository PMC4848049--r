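# Lesion-site decision rules and survey reporting.

test_that("the reference builder summarises qualifying pre-ablation detections", {
  df <- data.frame(siteId = c("a", "b", "c"), phase = "pre",
                   cfAtDetection = c(4, 8, 12))
  ref <- buildReference(df)
  expect_equal(referenceMean(ref), 8)
  # closed-form cross-check of the SD
  expect_equal(referenceSd(ref), sqrt(sum((c(4, 8, 12) - 8)^2) / 2))
  expect_identical(ref@n, 3L)

  single <- buildReference(data.frame(siteId = "a", phase = "pre",
                                      cfAtDetection = 5))
  expect_equal(referenceMean(single), 5)
  expect_equal(referenceSd(single), 0)
  expect_identical(single@n, 1L)

  mixed <- data.frame(siteId = c("a", "b", "c"), phase = "pre",
                      cfAtDetection = c(6, NA, 10))
  expect_message(refMixed <- buildReference(mixed), "excluded 1")
  expect_identical(refMixed@n, 2L)
  expect_equal(referenceMean(refMixed), 8)

  expect_error(
    buildReference(data.frame(siteId = "a", phase = "pre",
                              cfAtDetection = NA_real_)),
    class = "mapgap_reference_error")
  expect_error(
    buildReference(data.frame(siteId = "a", phase = "post",
                              cfAtDetection = 7)),
    class = "mapgap_reference_error")
})

test_that("the classification truth table is total and correct", {
  ref <- referenceThreshold(7.6, 4.4, 200L)
  cases <- expand.grid(mapPresent = c(TRUE, FALSE),
                       inPattern = c(TRUE, FALSE),
                       exceeds = c(TRUE, FALSE))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    maxCf <- if (cs$exceeds) 10 else 5  # reference mean is 7.6
    got <- classifySite("s", cs$mapPresent, cs$inPattern, maxCf,
                        cfAtDetectionPost = if (cs$mapPresent) maxCf else NA,
                        reference = ref)
    want <- if (cs$mapPresent && cs$inPattern) "gap"
      else if (cs$mapPresent) "conductive"
      else if (cs$exceeds) "non_conductive"
      else "indeterminate"
    expect_identical(got$label, want)
    expect_true(nzchar(got$rationale))
  }
})

test_that("the site-matched pre-ablation force takes precedence over the cohort mean", {
  ref <- referenceThreshold(7.6, 4.4, 200L)
  # 10 g exceeds the cohort mean but not this site's own pre-ablation force
  got <- classifySite("s", FALSE, TRUE, maxCfApplied = 10,
                      preAblationCf = 12, reference = ref)
  expect_identical(got$label, "indeterminate")
  expect_equal(got$cfReferenceUsed, 12)
  cohort <- classifySite("s", FALSE, TRUE, maxCfApplied = 10, reference = ref)
  expect_identical(cohort$label, "non_conductive")
  expect_equal(cohort$cfReferenceUsed, 7.6)
})

test_that("a tie with the reference falls to indeterminate", {
  ref <- referenceThreshold(7.6, 4.4, 200L)
  got <- classifySite("s", FALSE, TRUE, maxCfApplied = 7.6, reference = ref)
  expect_identical(got$label, "indeterminate")
})

test_that("the supra-reference sentinel supports non-conductive calls without a printed force", {
  got <- classifySite("s", FALSE, TRUE, maxCfApplied = NA,
                      supraReference = TRUE, reference = septalReference())
  expect_identical(got$label, "non_conductive")
  expect_true(is.na(got$cfEvidence))
})

test_that("a viable site probed only below its threshold is never called non-conductive", {
  cfg <- simulationConfig(seed = 83)
  site <- drawSitePhysiology(1, 1, cfg)[1, ]
  site$cfThreshold <- 15
  tr <- generateTrace(site, cfConstant(4), cfg, 8)  # probe far below threshold
  det <- detectMAP(tr, calibration = idealCurve(cfg))
  expect_true(is.na(runStart(det)))
  got <- classifySite(site$siteId, mapPresent = FALSE, inPattern = TRUE,
                      maxCfApplied = maxCfApplied(det),
                      reference = septalReference())
  expect_identical(got$label, "indeterminate")
})

test_that("phase and argument validation fire", {
  ref <- septalReference()
  expect_error(
    classifySurvey(data.frame(siteId = "a", phase = "pre", inPattern = TRUE,
                              mapPresent = TRUE), ref),
    class = "mapgap_argument_error")
  expect_error(classifySite("a", NA, TRUE, 5, reference = ref),
               class = "mapgap_argument_error")
  expect_error(classifySite("a", TRUE, TRUE, 5, reference = "x"),
               class = "mapgap_argument_error")
})

test_that("the survey report separates in- and out-of-pattern counts and lists gaps", {
  cls <- data.frame(
    siteId = c("A1", "A2", "B1", "B2"),
    label = c("gap", "non_conductive", "conductive", "indeterminate"),
    cfReferenceUsed = 7.6, cfEvidence = c(7, 11, 9, 5),
    rationale = "r", inPattern = c(TRUE, TRUE, FALSE, TRUE))
  rep <- surveyReport(cls, septalReference())
  expect_s3_class(rep, "surveyReport")
  expect_identical(rep$gapSites, "A1")
  expect_identical(sort(rep$mapPositiveSites), c("A1", "B1"))
  expect_equal(unname(rep$counts["gap", "in_pattern"]), 1)
  expect_equal(unname(rep$counts["conductive", "out_of_pattern"]), 1)
  expect_output(print(rep), "Conduction gaps: A1")

  none <- cls; none$label <- "non_conductive"
  expect_length(surveyReport(none)$gapSites, 0)
})
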