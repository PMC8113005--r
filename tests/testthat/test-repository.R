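# Repository: store initialization, integrity-checked ingestion,
# atomicity, unified queries against a brute-force oracle, e-forms.

# Build a mixed-type fixture population and keep an independent
# record-by-record shadow copy as the query oracle.
populate_mixed_store <- function(store, n_extra_types = TRUE) {
  co <- default_cohort()
  clin <- generateClinical(co$spec)
  res <- ingestCohort(store, co$dir, clinical = clin,
                      biobankRef = "BB", studyRef = "ST")
  shadow <- list()
  g <- groupSeries(cohort_paths(co$dir))
  for (s in g$series) {
    shadow[[res$collections[[s@seriesUid]]]] <- list(
      collection_type = "ImageCollection", donor_ref = s@donorRef,
      donor_sex = s@donorSex, donor_age_years = s@donorAgeYears,
      modality = s@modality, body_part = s@bodyPart,
      biobank_ref = "BB", study_ref = "ST")
  }
  for (d in names(res$clinical)) {
    i <- match(d, clin$donor_ref)
    sm <- Filter(function(x) x$donor_ref == d, shadow)[[1]]
    shadow[[res$clinical[[d]]]] <- list(
      collection_type = "ClinicalVariableCollection", donor_ref = d,
      donor_sex = sm$donor_sex, donor_age_years = sm$donor_age_years,
      modality = NA, body_part = NA, biobank_ref = "BB", study_ref = "ST")
  }
  if (n_extra_types) {
    tid <- ingest(store, collectionRecord(
      "SampleTissueCollection", "BB", "ST", "DONOR_01",
      list(material_type = "Tumour tissue (frozen)",
           storage_temperature = "-80C")))
    shadow[[tid]] <- list(
      collection_type = "SampleTissueCollection", donor_ref = "DONOR_01",
      donor_sex = shadow[[1]]$donor_sex,
      donor_age_years = shadow[[1]]$donor_age_years,
      modality = NA, body_part = NA, biobank_ref = "BB", study_ref = "ST")
    shadow[[tid]]$donor_sex <-
      Filter(function(x) x$donor_ref == "DONOR_01", shadow)[[1]]$donor_sex
    shadow[[tid]]$donor_age_years <-
      Filter(function(x) x$donor_ref == "DONOR_01", shadow)[[1]]$donor_age_years
  }
  shadow
}

oracle_filter <- function(shadow, filters) {
  keep <- Filter(function(x) {
    all(vapply(names(filters), function(f) {
      v <- x[[f]]
      !is.null(v) && !is.na(v) && v %in% filters[[f]]
    }, logical(1)))
  }, shadow)
  sort(names(keep))
}

test_that("initStore executes the DDL and the catalog matches the plan", {
  store <- fresh_store()
  plan_tables <- dicomiabis:::.plan_table_names(
    dicomiabis:::.table_plan(buildIntegrationModel()))
  expect_setequal(DBI::dbListTables(store@con), plan_tables)

  # a second init at the same location is an explicit error without the
  # overwrite flag, and succeeds with it
  expect_error(initStore(buildIntegrationModel(), store@path),
               class = "store_error")
  store2 <- initStore(buildIntegrationModel(), store@path,
                      overwrite = TRUE)
  expect_setequal(DBI::dbListTables(store2@con), plan_tables)
  closeStore(store2)

  # invalid schemas never create a store
  broken <- buildIntegrationModel()
  broken@entities <- broken@entities[-1]
  expect_error(initStore(broken, tempfile()),
               class = "invalid_schema_error")
})

test_that("openStore recovers the model from the store file", {
  store <- fresh_store()
  ingestCohort(store, default_cohort()$dir,
               biobankRef = "BB", studyRef = "ST")
  path <- store@path
  closeStore(store)
  re <- openStore(path)
  expect_identical(re@schema@model, "integration")
  expect_identical(nrow(queryCollections(re)), 18L)
  closeStore(re)
})

test_that("the default cohort ingests into 18 image collections with distinct donors", {
  store <- fresh_store()
  co <- default_cohort()
  res <- ingestCohort(store, co$dir, biobankRef = "BB", studyRef = "ST")
  expect_length(res$collections, 18L)
  rows <- queryCollections(store,
                           list(collection_type = "ImageCollection"))
  expect_identical(nrow(rows), 18L)
  expect_identical(length(unique(rows$donor_ref)), 18L)
  # referential closure: biobank, study and donor rows exist
  expect_identical(
    DBI::dbGetQuery(store@con, "SELECT COUNT(*) n FROM donor")$n, 18L)
  expect_identical(
    DBI::dbGetQuery(store@con, "SELECT COUNT(*) n FROM biobank")$n, 1L)
  expect_identical(
    DBI::dbGetQuery(store@con, "SELECT COUNT(*) n FROM study")$n, 1L)
})

test_that("ingestion rejects broken references, bad vocab values and payload mismatches", {
  store <- fresh_store()
  co <- default_cohort()
  g <- groupSeries(cohort_paths(co$dir))
  sm <- g$series[[1]]
  registerBiobank(store, "BB")
  registerStudy(store, "ST", biobankRef = "BB")
  registerDonor(store, "D1", ageYears = 9, sex = "F")

  expect_error(
    ingest(store, collectionRecord("ImageCollection", "NOPE", "ST", "D1", sm)),
    class = "referential_integrity_error")
  expect_error(
    ingest(store, collectionRecord("ImageCollection", "BB", "NOPE", "D1", sm)),
    class = "referential_integrity_error")
  expect_error(
    ingest(store, collectionRecord("ImageCollection", "BB", "ST", "NOPE", sm)),
    class = "referential_integrity_error")

  bad <- sm
  bad@modality <- "XX"
  expect_error(
    ingest(store, collectionRecord("ImageCollection", "BB", "ST", "D1", bad)),
    class = "vocabulary_error")

  expect_error(
    ingest(store, collectionRecord("ImageCollection", "BB", "ST", "D1",
                                   list(not = "a series"))),
    class = "payload_mismatch_error")
  expect_error(
    ingest(store, collectionRecord("SampleTissueCollection", "BB", "ST",
                                   "D1", sm)),
    class = "payload_mismatch_error")

  # permissive mode stores the non-conformant value flagged instead
  perm <- fresh_store(strict = FALSE)
  registerBiobank(perm, "BB")
  registerStudy(perm, "ST", biobankRef = "BB")
  registerDonor(perm, "D1", ageYears = 9, sex = "F")
  cid <- ingest(perm, collectionRecord("ImageCollection", "BB", "ST",
                                       "D1", bad))
  flag <- DBI::dbGetQuery(perm@con, paste(
    "SELECT m.conformant FROM modality m",
    "JOIN modality_information mi ON m.modality_information_id = mi.id",
    "JOIN image_collection ic ON mi.image_collection_id = ic.id",
    "WHERE ic.collection_id = ?"), params = list(cid))
  expect_identical(flag$conformant, 0L)
})

test_that("strict mode refuses records that failed PHI screening", {
  store <- fresh_store()
  co <- default_cohort()
  sm <- groupSeries(cohort_paths(co$dir))$series[[1]]
  registerBiobank(store, "BB")
  registerStudy(store, "ST", biobankRef = "BB")
  registerDonor(store, sm@donorRef)
  tainted <- sm
  tainted@patientName <- "Doe^Jane"
  tainted@deidentified <- isValid(phiScreen(tainted))
  expect_false(tainted@deidentified)
  expect_error(
    ingest(store, collectionRecord("ImageCollection", "BB", "ST",
                                   sm@donorRef, tainted)),
    class = "deidentification_error")
})

test_that("a rejected record leaves the store contents identical", {
  store <- fresh_store()
  shadow <- populate_mixed_store(store)
  before <- store_dump(store)
  sm <- groupSeries(cohort_paths(default_cohort()$dir))$series[[1]]
  bad <- sm
  bad@datasetType <- "9.9.9"
  expect_error(
    ingest(store, collectionRecord("ImageCollection", "BB", "ST",
                                   sm@donorRef, bad)),
    class = "vocabulary_error")
  expect_error(
    ingest(store, collectionRecord("ImageCollection", "BB", "ST",
                                   "GHOST", sm)),
    class = "referential_integrity_error")
  expect_identical(store_dump(store), before)
})

test_that("queries equal a brute-force filter oracle over the fixtures", {
  store <- fresh_store()
  shadow <- populate_mixed_store(store)
  expect_true(length(shadow) <= 1000L)

  filter_sets <- list(
    list(),
    list(donor_sex = "F"),
    list(donor_sex = "M"),
    list(collection_type = "ImageCollection", modality = "CT"),
    list(collection_type = "ClinicalVariableCollection"),
    list(body_part = "ABDOMEN"),
    list(body_part = c("ABDOMEN", "CHEST"), donor_sex = "F"),
    list(donor_age_years = 0:5),
    list(donor_ref = "DONOR_07"),
    list(study_ref = "ST", biobank_ref = "BB"),
    list(modality = "MR"))
  for (f in filter_sets) {
    got <- queryCollections(store, f)
    expect_identical(sort(unique(got$collection_ref)), oracle_filter(shadow, f),
                     info = paste(deparse(f), collapse = ""))
  }

  # female-donor query returns all collection types mixed
  fem <- queryCollections(store, list(donor_sex = "F"))
  expect_true(all(c("ImageCollection", "ClinicalVariableCollection") %in%
                    fem$collection_type))

  expect_error(queryCollections(store, list(favourite_colour = "blue")),
               class = "unknown_filter_field_error")
})

test_that("queries on an empty store return an empty result", {
  store <- fresh_store()
  expect_identical(nrow(queryCollections(store)), 0L)
  expect_identical(nrow(queryCollections(store, list(donor_sex = "F"))),
                   0L)
})

test_that("payload type discipline holds across collection types", {
  store <- fresh_store()
  populate_mixed_store(store)
  # series payloads are only reachable under image collections
  rows <- DBI::dbGetQuery(store@con, paste(
    "SELECT c.collection_type FROM image_collection ic",
    "JOIN collection c ON ic.collection_id = c.id"))
  expect_true(all(rows$collection_type == "ImageCollection"))
  rows2 <- DBI::dbGetQuery(store@con, paste(
    "SELECT c.collection_type FROM clinical_variable_collection cvc",
    "JOIN collection c ON cvc.collection_id = c.id"))
  expect_true(all(rows2$collection_type == "ClinicalVariableCollection"))
})

test_that("e-forms carry diagnosis symptoms and laboratory tests and round-trip", {
  store <- fresh_store()
  populate_mixed_store(store)
  doc <- exportEform(store, "DONOR_01")
  expect_s4_class(doc, "EFormDocument")
  expect_true("diagnosis" %in% names(doc@sections))
  diag <- doc@sections$diagnosis
  expect_true(all(c("symptoms", "laboratory_tests") %in% names(diag)))
  expect_true(all(c("fever", "bone_pain") %in% names(diag$symptoms)))
  expect_true(all(c("ldh_u_l", "ferritin_ng_ml") %in%
                    names(diag$laboratory_tests)))
  expect_true(length(doc@provenance) >= 2L)

  # export -> import -> export is byte-identical
  j1 <- eformToJson(doc)
  j2 <- eformToJson(eformFromJson(j1))
  expect_identical(j1, j2)

  expect_error(exportEform(store, "GHOST"), class = "unknown_donor_error")
})

test_that("donors without clinical collections export identifier fields only", {
  store <- fresh_store()
  co <- default_cohort()
  ingestCohort(store, co$dir, biobankRef = "BB", studyRef = "ST")
  doc <- exportEform(store, "DONOR_02")
  expect_false("diagnosis" %in% names(doc@sections))
  expect_true("subject" %in% names(doc@sections))
  expect_identical(doc@sections$subject$donor_ref, "DONOR_02")
  j1 <- eformToJson(doc)
  expect_identical(eformToJson(eformFromJson(j1)), j1)
})
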