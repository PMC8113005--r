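# Harvester: per-file extraction, per-series grouping and reconciliation,
# PHI screening.

test_that("harvest reproduces every manifest field of the fixture cohort", {
  co <- default_cohort()
  g <- groupSeries(cohort_paths(co$dir))
  expect_identical(g$report@seriesEmitted, nrow(co$manifest))
  expect_identical(g$report@filesSeen,
                   nrow(co$manifest) * co$spec@slicesPerSeries)
  expect_identical(nrow(g$report@rejected), 0L)

  by_uid <- setNames(g$series,
                     vapply(g$series, function(s) s@seriesUid, character(1)))
  for (i in seq_len(nrow(co$manifest))) {
    m <- co$manifest[i, ]
    s <- by_uid[[m$series_uid]]
    expect_false(is.null(s), info = m$series_uid)
    expect_identical(s@studyUid, m$study_uid)
    expect_identical(s@modality, m$modality)
    expect_identical(s@bodyPart, m$body_part)
    expect_identical(s@datasetType, m$dataset_type)
    expect_identical(s@donorRef, m$donor_ref)
    expect_identical(s@donorAgeYears, as.integer(m$age_years))
    expect_identical(s@donorSex, m$sex)
    expect_identical(s@nFiles, co$spec@slicesPerSeries)
    expect_equal(s@acquisition$kvp, m$kvp)
    expect_equal(s@acquisition$slice_thickness_mm, m$slice_thickness_mm)
    expect_equal(s@acquisition$exposure_time_ms, m$exposure_time_ms)
    expect_identical(s@acquisition$pixel_spacing_mm, m$pixel_spacing_mm)
    expect_identical(s@reconstruction$convolution_kernel,
                     m$convolution_kernel)
    expect_equal(s@reconstruction$reconstruction_diameter_mm,
                 m$reconstruction_diameter_mm)
    expect_true(s@deidentified)
    expect_length(s@nonConformant, 0L)
  }
})

test_that("harvest is order-insensitive", {
  co <- default_cohort()
  paths <- cohort_paths(co$dir)
  set.seed(42)
  g1 <- groupSeries(paths)
  g2 <- groupSeries(sample(paths))
  uids <- function(g) vapply(g$series, function(s) s@seriesUid, character(1))
  expect_identical(uids(g1), uids(g2))
  expect_equal(g1$series, g2$series)
})

test_that("multi-series input groups one record per series UID", {
  dir <- tempfile()
  spec <- cohortSpec(nPatients = 2L, slicesPerSeries = 10L, seed = 3L)
  generateCohort(spec, dir)
  g <- groupSeries(cohort_paths(dir))
  expect_length(g$series, 2L)
  expect_identical(g$report@filesSeen, 20L)
  expect_identical(g$report@seriesEmitted, 2L)
})

test_that("empty input yields an empty, reconciled report", {
  g <- groupSeries(character())
  expect_length(g$series, 0L)
  expect_identical(g$report@filesSeen, 0L)
  expect_identical(g$report@seriesEmitted, 0L)
  expect_identical(nrow(g$report@rejected), 0L)
})

test_that("conflicting per-file values within a series reject the series", {
  dir <- tempfile()
  dir.create(dir)
  for (i in 1:2) {
    els <- base_elements(SOPInstanceUID = sprintf(
      "1.2.826.0.1.3680043.10.424.99.1.%d", i))
    els$Modality <- if (i == 1) "CT" else "MR"
    writeDicomFile(file.path(dir, sprintf("s%d.dcm", i)), els)
  }
  g <- groupSeries(cohort_paths(dir))
  expect_length(g$series, 0L)
  expect_identical(nrow(g$report@rejected), 1L)
  expect_match(g$report@rejected$reason, "conflicting modality")
  # report counts reconcile: emitted + rejected series = series seen
  expect_identical(g$report@seriesEmitted + nrow(g$report@rejected), 1L)
})

test_that("per-file failures are collected, not raised", {
  dir <- tempfile()
  dir.create(dir)
  writeDicomFile(file.path(dir, "good.dcm"), base_elements())
  writeLines("junk", file.path(dir, "bad.dcm"))
  els <- base_elements()
  els$SeriesInstanceUID <- NULL
  writeDicomFile(file.path(dir, "nouid.dcm"), els)
  g <- groupSeries(cohort_paths(dir))
  expect_length(g$series, 1L)
  expect_identical(g$report@filesSeen, 3L)
  expect_identical(nrow(g$report@rejected), 2L)
  expect_error(harvestFile(file.path(dir, "bad.dcm")),
               class = "invalid_format_error")
  expect_error(harvestFile(file.path(dir, "nouid.dcm")),
               class = "missing_required_tag_error")
})

test_that("body part falls back to the anatomic region sequence", {
  path <- tempfile(fileext = ".dcm")
  els <- base_elements()
  els$BodyPartExamined <- NULL
  els$AnatomicRegionSequence <- list(list(
    CodeValue = "T-D4000", CodingSchemeDesignator = "SRT",
    CodeMeaning = "Abdomen"))
  writeDicomFile(path, els)
  f <- harvestFile(path)
  expect_identical(f$body_part, "ABDOMEN")
  expect_identical(f$body_part_source, "anatomic_region_sequence")
  expect_length(f$non_conformant, 0L)

  # both tag and sequence absent: null and flagged, not fatal
  els$AnatomicRegionSequence <- NULL
  writeDicomFile(path, els)
  f2 <- harvestFile(path)
  expect_true(is.na(f2$body_part))
  expect_true("body_part" %in% f2$non_conformant)
})

test_that("the explicit tag takes precedence over the sequence", {
  path <- tempfile(fileext = ".dcm")
  els <- base_elements(BodyPartExamined = "CHEST")
  els$AnatomicRegionSequence <- list(list(
    CodeValue = "T-D4000", CodingSchemeDesignator = "SRT",
    CodeMeaning = "Abdomen"))
  writeDicomFile(path, els)
  expect_identical(harvestFile(path)$body_part, "CHEST")
})

test_that("non-conformant coded values are flagged, not dropped", {
  path <- tempfile(fileext = ".dcm")
  writeDicomFile(path, base_elements(Modality = "QQ",
                                     BodyPartExamined = "NOWHERE"))
  f <- harvestFile(path)
  expect_identical(f$modality, "QQ")
  expect_true(all(c("modality", "body_part") %in% f$non_conformant))
})

test_that("DICOM age strings floor to whole years", {
  p <- dicomiabis:::.parse_age_years
  expect_identical(p("009Y"), 9L)
  expect_identical(p("017Y"), 17L)
  expect_identical(p("018M"), 1L)
  expect_identical(p("011M"), 0L)
  expect_identical(p("010W"), 0L)
  expect_identical(p("200D"), 0L)
  expect_identical(p(""), NA_integer_)
  expect_identical(p(NULL), NA_integer_)
})

test_that("phiScreen flags identifiers and clears the fixture records", {
  co <- default_cohort()
  g <- groupSeries(cohort_paths(co$dir))
  for (s in g$series) {
    expect_true(isValid(phiScreen(s)))
    expect_true(s@deidentified)
  }

  named <- g$series[[1]]
  named@patientName <- "Doe^Jane"
  rep1 <- phiScreen(named)
  expect_false(isValid(rep1))
  expect_identical(violations(rep1)$rule, "person_name")

  born <- g$series[[1]]
  born@birthDate <- "20120407"
  expect_identical(violations(phiScreen(born))$rule, "birth_date")

  # name-like content hiding in a free-text field
  sneaky <- g$series[[1]]
  sneaky@reconstruction$convolution_kernel <- "Doe^Jane"
  rep3 <- phiScreen(sneaky)
  expect_identical(violations(rep3)$rule, "person_name")

  dated <- g$series[[1]]
  dated@acquisition$pixel_spacing_mm <- "20140302"
  expect_identical(violations(phiScreen(dated))$rule, "birth_date")
})
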