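# Embedded relational repository: the generated DDL executed on SQLite,
# integrity- and vocabulary-checked ingestion, provenance attachment,
# unified conjunctive queries. Single-writer, many-reader; every write is
# wrapped in one transaction so a rejected record leaves the store
# untouched.

.MODEL_VERSIONS <- c(miabis_core = 1L, integration = 2L)

.store_con <- function(store) {
  if (!DBI::dbIsValid(store@con))
    .err("store_error", "store connection is closed")
  store@con
}

.q <- function(store, sql, params = NULL) {
  DBI::dbGetQuery(.store_con(store), sql, params = params)
}

.x <- function(store, sql, params = NULL) {
  DBI::dbExecute(.store_con(store), sql, params = params)
}

.in_txn <- function(store, expr) {
  con <- .store_con(store)
  DBI::dbExecute(con, "BEGIN IMMEDIATE")
  ok <- FALSE
  on.exit(if (!ok) try(DBI::dbExecute(con, "ROLLBACK"), silent = TRUE))
  out <- expr
  DBI::dbExecute(con, "COMMIT")
  ok <- TRUE
  out
}

#' Initialize an embedded repository
#'
#' Creates a SQLite store at `location` by executing the schema's
#' [generateDDL()] script; afterwards the catalog table set equals the DDL
#' table set (entity tables plus junction tables). The model identity is
#' recorded in the database so [openStore()] can recover the schema.
#'
#' @param schema a valid [SchemaGraph].
#' @param location path of the store file to create.
#' @param overwrite `FALSE` (default): an existing file raises an
#'   already-exists error; `TRUE` replaces it.
#' @param strict vocabulary strictness for subsequent [ingest()] calls.
#' @return a [BiobankStore] handle.
#' @export
initStore <- function(schema, location, overwrite = FALSE, strict = TRUE) {
  .stopifnot_scalar_chr(location, "location")
  ddl <- generateDDL(schema) # raises invalid_schema_error if unfit
  if (file.exists(location)) {
    if (!overwrite)
      .err("store_error",
           sprintf("store already exists at %s (use overwrite = TRUE)",
                   location))
    unlink(location)
  }
  con <- tryCatch(DBI::dbConnect(RSQLite::SQLite(), location),
                  error = function(e)
                    .err("store_error",
                         sprintf("location not writable: %s (%s)", location,
                                 conditionMessage(e))))
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  for (stmt in .split_sql(ddl)) DBI::dbExecute(con, stmt)
  ver <- .MODEL_VERSIONS[schema@model]
  if (!is.na(ver))
    DBI::dbExecute(con, sprintf("PRAGMA user_version = %d", ver))
  new("BiobankStore", path = location, con = con, schema = schema,
      strict = strict)
}

.split_sql <- function(script) {
  stmts <- strsplit(script, ";[[:space:]]*\\n", perl = TRUE)[[1]]
  stmts <- trimws(stmts)
  stmts[nzchar(stmts)]
}

#' Open an existing repository
#'
#' @param location path of a store created by [initStore()].
#' @param strict vocabulary strictness for subsequent ingestion.
#' @return a [BiobankStore].
#' @export
openStore <- function(location, strict = TRUE) {
  if (!file.exists(location))
    .err("store_error", sprintf("no store at %s", location))
  con <- DBI::dbConnect(RSQLite::SQLite(), location)
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  ver <- DBI::dbGetQuery(con, "PRAGMA user_version")[[1]]
  model <- names(.MODEL_VERSIONS)[match(ver, .MODEL_VERSIONS)]
  if (is.na(model)) {
    DBI::dbDisconnect(con)
    .err("store_error",
         sprintf("%s does not carry a known model version", location))
  }
  schema <- if (model == "integration") buildIntegrationModel()
  else buildMiabisCore()
  new("BiobankStore", path = location, con = con, schema = schema,
      strict = strict)
}

#' Close a repository handle
#'
#' @param store a [BiobankStore].
#' @return `TRUE`, invisibly.
#' @export
closeStore <- function(store) {
  if (DBI::dbIsValid(store@con)) DBI::dbDisconnect(store@con)
  invisible(TRUE)
}

setMethod("show", "BiobankStore", function(object) {
  open <- DBI::dbIsValid(object@con)
  cat(sprintf("BiobankStore at %s (model '%s', %s, %s mode)\n",
              object@path, object@schema@model,
              if (open) "open" else "closed",
              if (object@strict) "strict" else "permissive"))
  if (open && "collection" %in% DBI::dbListTables(object@con)) {
    n <- DBI::dbGetQuery(object@con,
                         "SELECT COUNT(*) AS n FROM collection")$n
    cat(sprintf("  %d collection record(s)\n", n))
  }
})

.require_integration <- function(store) {
  if (!identical(store@schema@model, "integration"))
    .err("usage_error",
         "this operation requires a store built on the integration model")
}

.row_exists <- function(store, table, id) {
  nrow(.q(store, sprintf("SELECT id FROM %s WHERE id = ?", table),
          params = list(id))) > 0L
}

# ---- reference entities ------------------------------------------------

#' Register reference entities
#'
#' Biobank, study and donor rows must exist before any
#' [CollectionRecord] referencing them can be ingested. The supplied
#' reference doubles as the row's opaque identifier.
#'
#' @param store a [BiobankStore].
#' @param ref opaque identifier (unique within its entity).
#' @param name human-readable name.
#' @param country,contact optional biobank descriptors.
#' @return `ref`, invisibly.
#' @export
registerBiobank <- function(store, ref, name = ref, country = NA,
                            contact = NA) {
  .stopifnot_scalar_chr(ref, "ref")
  if (.row_exists(store, "biobank", ref)) return(invisible(ref))
  .in_txn(store, .x(store, paste(
    "INSERT INTO biobank (id, biobank_ref, name, country,",
    "contact_information) VALUES (?, ?, ?, ?, ?)"),
    params = list(ref, ref, name, country, contact)))
  invisible(ref)
}

#' @rdname registerBiobank
#' @param biobankRef the hosting biobank (must already be registered).
#' @export
registerStudy <- function(store, ref, name = ref, biobankRef) {
  .stopifnot_scalar_chr(ref, "ref")
  if (!.row_exists(store, "biobank", biobankRef))
    .err("referential_integrity_error",
         sprintf("biobank '%s' is not registered", biobankRef))
  if (.row_exists(store, "study", ref)) return(invisible(ref))
  .in_txn(store, .x(store,
    "INSERT INTO study (id, study_ref, name, biobank_id) VALUES (?, ?, ?, ?)",
    params = list(ref, ref, name, biobankRef)))
  invisible(ref)
}

#' @rdname registerBiobank
#' @param ageYears non-negative integer (<= 120) or `NA`.
#' @param sex one of `F`, `M`, `O`, `unknown`.
#' @export
registerDonor <- function(store, ref, ageYears = NA, sex = "unknown") {
  .require_integration(store)
  .stopifnot_scalar_chr(ref, "ref")
  if (!is.na(ageYears) && (ageYears < 0 || ageYears > 120))
    .err("usage_error", "donor age must lie in [0, 120] years")
  if (!sex %in% c("F", "M", "O", "unknown"))
    .err("usage_error", "donor sex must be F, M, O or unknown")
  if (.row_exists(store, "donor", ref)) return(invisible(ref))
  .in_txn(store, .x(store, paste(
    "INSERT INTO donor (id, donor_pseudonym, age_years, sex)",
    "VALUES (?, ?, ?, ?)"),
    params = list(ref, ref, as.integer(ageYears), sex)))
  invisible(ref)
}

# ---- collection records ------------------------------------------------

#' Assemble a collection record
#'
#' @param collectionType one of the five sub-collection types (see
#'   `COLLECTION_TYPES`).
#' @param biobankRef,studyRef,donorRef references that must resolve in
#'   the store at ingestion time.
#' @param payload type-specific payload (see [CollectionRecord]).
#' @param name optional collection label.
#' @return a [CollectionRecord] for [ingest()].
#' @export
collectionRecord <- function(collectionType, biobankRef, studyRef,
                             donorRef, payload, name = NA_character_) {
  new("CollectionRecord", collectionType = collectionType,
      biobankRef = biobankRef, studyRef = studyRef, donorRef = donorRef,
      name = name, payload = payload)
}

.payload_ok <- function(type, payload) {
  switch(type,
    ImageCollection = is(payload, "SeriesMetadata"),
    SampleTissueCollection = is.list(payload) &&
      !is.null(payload$material_type) &&
      !is.null(payload$storage_temperature),
    ClinicalVariableCollection = is.list(payload) &&
      (length(payload) == 0L || !is.null(names(payload))),
    MolecularBiomarkerCollection = is.list(payload) &&
      all(vapply(payload, function(b)
        is.list(b) && !is.null(b$name) && !is.null(b$value), logical(1))),
    SoftwareSourceCode = is.list(payload) && !is.null(payload$name),
    FALSE)
}

.json <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

.unjson <- function(x) {
  if (is.null(x) || is.na(x)) return(list())
  jsonlite::fromJSON(x, simplifyVector = FALSE)
}

#' Ingest a collection record
#'
#' Persists a [CollectionRecord] into the relational schema. The record
#' is written only if all references resolve, coded values validate
#' against the packaged vocabularies (strict mode; in permissive mode
#' non-conformant values are stored flagged) and the payload type matches
#' the collection type; otherwise a typed error is raised and -- the
#' write being a single transaction -- nothing is stored. In strict mode
#' an image record that failed PHI screening is rejected.
#'
#' @param store an integration-model [BiobankStore].
#' @param record a [CollectionRecord].
#' @return the new collection identifier (also its `collection_ref`).
#' @rdname ingest
#' @export
setMethod("ingest", c("BiobankStore", "CollectionRecord"),
          function(store, record) {
  .require_integration(store)
  validObject(record)
  for (chk in list(c("biobank", record@biobankRef),
                   c("study", record@studyRef),
                   c("donor", record@donorRef))) {
    if (!.row_exists(store, chk[1], chk[2]))
      .err("referential_integrity_error",
           sprintf("%s '%s' is not registered", chk[1], chk[2]))
  }
  if (!.payload_ok(record@collectionType, record@payload))
    .err("payload_mismatch_error",
         sprintf("payload does not match collection type %s",
                 record@collectionType))

  payload <- record@payload
  if (record@collectionType == "ImageCollection") {
    coded <- list(MODALITY = payload@modality,
                  DATASET_TYPE = payload@datasetType,
                  BODY_PART = payload@bodyPart)
    for (vid in names(coded)) {
      v <- coded[[vid]]
      if (!is.na(v) && !validateValue(vid, v) && store@strict)
        .err("vocabulary_error",
             sprintf("value '%s' is not in vocabulary %s", v, vid))
    }
    if (store@strict && !isTRUE(payload@deidentified))
      .err("deidentification_error",
           "record failed PHI screening; strict mode refuses it")
  }

  donor <- .q(store, "SELECT age_years, sex FROM donor WHERE id = ?",
              params = list(record@donorRef))
  cid <- .new_id("col")

  .in_txn(store, {
    .x(store, paste(
      "INSERT INTO collection (id, collection_ref, collection_type,",
      "name, biobank_id, donor_id) VALUES (?, ?, ?, ?, ?, ?)"),
      params = list(cid, cid, record@collectionType, record@name,
                    record@biobankRef, record@donorRef))
    .x(store, "INSERT INTO study__collection (study_id, collection_id) VALUES (?, ?)",
       params = list(record@studyRef, cid))
    .x(store, paste(
      "INSERT INTO donor_age (id, age_low, age_high, age_unit,",
      "collection_id) VALUES (?, ?, ?, 'years', ?)"),
      params = list(.new_id("age"), donor$age_years[1], donor$age_years[1],
                    cid))
    .x(store, "INSERT INTO donor_sex (id, sex, collection_id) VALUES (?, ?, ?)",
       params = list(.new_id("sex"), donor$sex[1], cid))
    switch(record@collectionType,
      ImageCollection = .ingest_image(store, cid, payload),
      SampleTissueCollection = .ingest_tissue(store, cid, payload),
      ClinicalVariableCollection = .x(store, paste(
        "INSERT INTO clinical_variable_collection (id, variables,",
        "collection_id) VALUES (?, ?, ?)"),
        params = list(.new_id("cvc"), .json(payload), cid)),
      MolecularBiomarkerCollection = .x(store, paste(
        "INSERT INTO molecular_biomarker_collection (id, biomarkers,",
        "collection_id) VALUES (?, ?, ?)"),
        params = list(.new_id("mbc"), .json(payload), cid)),
      SoftwareSourceCode = .x(store, paste(
        "INSERT INTO software_source_code (id, name, version,",
        "repository_url, license, collection_id) VALUES (?, ?, ?, ?, ?, ?)"),
        params = list(.new_id("ssc"), payload$name,
                      payload$version %||% NA, payload$repository_url %||% NA,
                      payload$license %||% NA, cid)))
  })
  cid
})

.conf_flag <- function(vocabulary_id, value) {
  if (is.na(value)) NA_integer_
  else as.integer(validateValue(vocabulary_id, value))
}

.ingest_image <- function(store, cid, sm) {
  icid <- .new_id("img")
  .x(store, paste(
    "INSERT INTO image_collection (id, study_instance_uid,",
    "series_instance_uid, n_files, deidentified, collection_id)",
    "VALUES (?, ?, ?, ?, ?, ?)"),
    params = list(icid, sm@studyUid, sm@seriesUid, sm@nFiles,
                  as.integer(sm@deidentified), cid))
  .x(store, paste(
    "INSERT INTO body_part_examined (id, body_part, conformant,",
    "image_collection_id) VALUES (?, ?, ?, ?)"),
    params = list(.new_id("bpe"), sm@bodyPart,
                  .conf_flag("BODY_PART", sm@bodyPart), icid))
  .x(store, paste(
    "INSERT INTO dataset_type (id, dataset_type, conformant,",
    "image_collection_id) VALUES (?, ?, ?, ?)"),
    params = list(.new_id("dst"), sm@datasetType,
                  .conf_flag("DATASET_TYPE", sm@datasetType), icid))
  mid <- .new_id("mod")
  .x(store, paste(
    "INSERT INTO modality_information (id, image_collection_id)",
    "VALUES (?, ?)"), params = list(mid, icid))
  .x(store, paste(
    "INSERT INTO modality (id, modality, conformant,",
    "modality_information_id) VALUES (?, ?, ?, ?)"),
    params = list(.new_id("mdl"), sm@modality,
                  .conf_flag("MODALITY", sm@modality), mid))
  acq <- sm@acquisition
  known <- c("kvp", "exposure_time_ms", "slice_thickness_mm",
             "pixel_spacing_mm")
  extra <- acq[setdiff(names(acq), known)]
  .x(store, paste(
    "INSERT INTO acquisition_parameters (id, kvp, exposure_time_ms,",
    "slice_thickness_mm, pixel_spacing_mm, parameters,",
    "modality_information_id) VALUES (?, ?, ?, ?, ?, ?, ?)"),
    params = list(.new_id("acq"), acq$kvp %||% NA,
                  acq$exposure_time_ms %||% NA,
                  acq$slice_thickness_mm %||% NA,
                  acq$pixel_spacing_mm %||% NA,
                  if (length(extra)) .json(extra) else NA, mid))
  rec <- sm@reconstruction
  .x(store, paste(
    "INSERT INTO reconstruction_parameters (id, convolution_kernel,",
    "reconstruction_diameter_mm, parameters, modality_information_id)",
    "VALUES (?, ?, ?, ?, ?)"),
    params = list(.new_id("rcp"), rec$convolution_kernel %||% NA,
                  rec$reconstruction_diameter_mm %||% NA, NA, mid))
  icid
}

.ingest_tissue <- function(store, cid, payload) {
  stid <- .new_id("stc")
  .x(store, paste(
    "INSERT INTO sample_tissue_collection (id, description,",
    "collection_id) VALUES (?, ?, ?)"),
    params = list(stid, payload$description %||% NA, cid))
  .x(store, paste(
    "INSERT INTO material_type (id, material_type,",
    "sample_tissue_collection_id) VALUES (?, ?, ?)"),
    params = list(.new_id("mat"), payload$material_type, stid))
  .x(store, paste(
    "INSERT INTO storage_temperature (id, storage_temperature,",
    "sample_tissue_collection_id) VALUES (?, ?, ?)"),
    params = list(.new_id("stt"), payload$storage_temperature, stid))
  stid
}

# ---- provenance persistence -------------------------------------------

.SEG_CHILD <- c(manual = "manual", semi_automatic = "semi_automatic",
                automatic = "automatic")
.FC_CHILD <- c(texture = "texture_features", deep = "deep_features",
               dynamic_signal = "dynamic_signal_features")
.SCOPE_CHILD <- c(intra_sequence = "intra_sequence",
                  inter_sequence = "inter_sequence",
                  inter_modal = "inter_modal")

.image_collection_id <- function(store, collectionRef) {
  .q(store,
     "SELECT id FROM image_collection WHERE collection_id = ?",
     params = list(collectionRef))$id
}

#' Attach analysis provenance to an ingested image collection
#'
#' Persists the preprocessing, segmentation, registration and biomarker
#' records of an [AnalysisProvenance] under the image collection it
#' references. Enumerations are re-checked (segmentation modality,
#' registration scope, feature class are closed three-value sets); the
#' write is one transaction.
#'
#' @param provenance an [AnalysisProvenance]; `imageCollectionRef` must
#'   be the identifier returned by [ingest()] for an image collection.
#' @param store an integration-model [BiobankStore].
#' @return the new image-analysis identifier.
#' @rdname attachAnalysis
#' @export
setMethod("attachAnalysis", c("AnalysisProvenance", "BiobankStore"),
          function(provenance, store) {
  .require_integration(store)
  icid <- .image_collection_id(store, provenance@imageCollectionRef)
  if (!length(icid))
    .err("dangling_reference_error",
         sprintf("no image collection for reference '%s'",
                 provenance@imageCollectionRef))
  icid <- icid[1]
  for (s in provenance@segmentations)
    .check_enum(s@modality, SEGMENTATION_MODALITIES, "segmentation modality")
  for (r in provenance@registrations)
    .check_enum(r@scope, REGISTRATION_SCOPES, "registration scope")
  for (b in provenance@biomarkers)
    .check_enum(b@featureClass, FEATURE_CLASSES, "biomarker feature class")

  aid <- .new_id("ana")
  pp <- provenance@preprocessing
  .in_txn(store, {
    .x(store, paste(
      "INSERT INTO image_analysis (id, software, version,",
      "image_collection_id) VALUES (?, ?, ?, ?)"),
      params = list(aid, pp@software, pp@version, icid))
    .x(store, paste(
      "INSERT INTO preprocessing_parameters (id, steps, software,",
      "version, image_analysis_id) VALUES (?, ?, ?, ?, ?)"),
      params = list(.new_id("pre"), .json(pp@steps), pp@software,
                    pp@version, aid))
    for (s in provenance@segmentations) {
      sid <- .new_id("seg")
      .x(store, paste(
        "INSERT INTO segmentation (id, modality, operator_or_algorithm,",
        "parameters, image_analysis_id) VALUES (?, ?, ?, ?, ?)"),
        params = list(sid, s@modality, s@operatorOrAlgorithm,
                      .json(s@parameters), aid))
      .x(store, sprintf(
        "INSERT INTO %s (id, detail, segmentation_id) VALUES (?, ?, ?)",
        .SEG_CHILD[[s@modality]]),
        params = list(.new_id("sgc"), s@operatorOrAlgorithm, sid))
    }
    for (b in provenance@biomarkers) {
      bid <- .new_id("bio")
      .x(store, paste(
        "INSERT INTO imaging_biomarkers (id, feature_class, name, value,",
        "units, image_analysis_id) VALUES (?, ?, ?, ?, ?, ?)"),
        params = list(bid, b@featureClass, b@name, b@value, b@units, aid))
      .x(store, sprintf(
        "INSERT INTO %s (id, detail, imaging_biomarkers_id) VALUES (?, ?, ?)",
        .FC_CHILD[[b@featureClass]]),
        params = list(.new_id("fcc"), b@name, bid))
    }
    for (r in provenance@registrations) {
      rid <- .new_id("reg")
      .x(store, paste(
        "INSERT INTO registration_parameters (id, scope, transform_type,",
        "parameters, image_collection_id) VALUES (?, ?, ?, ?, ?)"),
        params = list(rid, r@scope, r@transformType, .json(r@parameters),
                      icid))
      .x(store, sprintf(
        "INSERT INTO %s (id, detail, registration_parameters_id) VALUES (?, ?, ?)",
        .SCOPE_CHILD[[r@scope]]),
        params = list(.new_id("rgc"), r@transformType, rid))
    }
  })
  aid
})

#' Retrieve attached analysis provenance
#'
#' Rebuilds the [AnalysisProvenance] objects stored for an image
#' collection; retrieval is lossless with respect to
#' [attachAnalysis()].
#'
#' @param store an integration-model [BiobankStore].
#' @param collectionRef identifier of an ingested image collection.
#' @return list of [AnalysisProvenance] (possibly empty).
#' @export
retrieveAnalyses <- function(store, collectionRef) {
  .require_integration(store)
  icid <- .image_collection_id(store, collectionRef)
  if (!length(icid))
    .err("unknown_collection_error",
         sprintf("no image collection for reference '%s'", collectionRef))
  icid <- icid[1]
  analyses <- .q(store, paste(
    "SELECT id, software, version FROM image_analysis",
    "WHERE image_collection_id = ? ORDER BY id"), params = list(icid))
  regs <- .q(store, paste(
    "SELECT scope, transform_type, parameters FROM registration_parameters",
    "WHERE image_collection_id = ? ORDER BY id"), params = list(icid))
  lapply(seq_len(nrow(analyses)), function(i) {
    aid <- analyses$id[i]
    pp <- .q(store, paste(
      "SELECT steps, software, version FROM preprocessing_parameters",
      "WHERE image_analysis_id = ?"), params = list(aid))
    segs <- .q(store, paste(
      "SELECT modality, operator_or_algorithm, parameters FROM segmentation",
      "WHERE image_analysis_id = ? ORDER BY id"), params = list(aid))
    bios <- .q(store, paste(
      "SELECT feature_class, name, value, units FROM imaging_biomarkers",
      "WHERE image_analysis_id = ? ORDER BY id"), params = list(aid))
    analysisProvenance(
      imageCollectionRef = collectionRef,
      preprocessing = preprocessingRecord(
        steps = .unjson(pp$steps[1]),
        software = pp$software[1], version = pp$version[1]),
      segmentations = lapply(seq_len(nrow(segs)), function(j)
        segmentationRecord(segs$modality[j], segs$operator_or_algorithm[j],
                           .unjson(segs$parameters[j]))),
      registrations = lapply(seq_len(nrow(regs)), function(j)
        registrationRecord(regs$scope[j], regs$transform_type[j],
                           .unjson(regs$parameters[j]))),
      biomarkers = lapply(seq_len(nrow(bios)), function(j)
        biomarkerRecord(bios$feature_class[j], bios$name[j],
                        bios$value[j], bios$units[j])))
  })
}

#' Count stored biomarkers by feature class
#'
#' @param store an integration-model [BiobankStore].
#' @param collectionRef identifier of an ingested image collection;
#'   unknown references raise an unknown-collection error.
#' @return named integer vector over `texture`, `deep`,
#'   `dynamic_signal`; the total equals the stored record count.
#' @export
summarizeBiomarkers <- function(store, collectionRef) {
  .require_integration(store)
  icid <- .image_collection_id(store, collectionRef)
  if (!length(icid))
    .err("unknown_collection_error",
         sprintf("no image collection for reference '%s'", collectionRef))
  rows <- .q(store, paste(
    "SELECT ib.feature_class AS fc, COUNT(*) AS n",
    "FROM imaging_biomarkers ib",
    "JOIN image_analysis ia ON ib.image_analysis_id = ia.id",
    "WHERE ia.image_collection_id = ? GROUP BY ib.feature_class"),
    params = list(icid[1]))
  out <- setNames(integer(length(FEATURE_CLASSES)), FEATURE_CLASSES)
  out[rows$fc] <- as.integer(rows$n)
  out
}

# ---- unified query -----------------------------------------------------

.QUERY_FIELDS <- c("donor_sex", "donor_age_years", "collection_type",
                   "modality", "body_part", "study_ref", "biobank_ref",
                   "donor_ref")

#' Query collections across all types
#'
#' Unified conjunctive filtering over every stored collection record,
#' whatever its sub-collection type. Filters combine with AND; a filter
#' value of length > 1 means set membership. Supported fields:
#' `donor_sex`, `donor_age_years`, `collection_type`, `modality`,
#' `body_part`, `study_ref`, `biobank_ref`, `donor_ref`. Modality and
#' body-part filters only ever match image collections.
#'
#' @param store an integration-model [BiobankStore].
#' @param filters named list of field -> value(s); empty list returns
#'   every record. Unknown field names raise an unknown-filter-field
#'   error.
#' @return data.frame with one row per (collection, study) pair, ordered
#'   by collection identifier: `collection_ref`, `collection_type`,
#'   `name`, `biobank_ref`, `study_ref`, `donor_ref`, `donor_sex`,
#'   `donor_age_years`, `modality`, `body_part`.
#' @export
queryCollections <- function(store, filters = list()) {
  .require_integration(store)
  if (length(filters)) {
    bad <- setdiff(names(filters), .QUERY_FIELDS)
    if (length(bad) || is.null(names(filters)))
      .err("unknown_filter_field_error",
           sprintf("unknown filter field(s): %s",
                   paste(if (length(bad)) bad else "<unnamed>",
                         collapse = ", ")))
  }
  rows <- .q(store, paste(
    "SELECT c.id AS collection_ref, c.collection_type, c.name,",
    "c.biobank_id AS biobank_ref, sc.study_id AS study_ref,",
    "c.donor_id AS donor_ref, d.sex AS donor_sex,",
    "d.age_years AS donor_age_years, m.modality AS modality,",
    "bpe.body_part AS body_part",
    "FROM collection c",
    "LEFT JOIN study__collection sc ON sc.collection_id = c.id",
    "LEFT JOIN donor d ON d.id = c.donor_id",
    "LEFT JOIN image_collection ic ON ic.collection_id = c.id",
    "LEFT JOIN body_part_examined bpe ON bpe.image_collection_id = ic.id",
    "LEFT JOIN modality_information mi ON mi.image_collection_id = ic.id",
    "LEFT JOIN modality m ON m.modality_information_id = mi.id",
    "ORDER BY c.id, sc.study_id"))
  for (f in names(filters)) {
    vals <- filters[[f]]
    keep <- !is.na(rows[[f]]) & rows[[f]] %in% vals
    rows <- rows[keep, , drop = FALSE]
  }
  rownames(rows) <- NULL
  rows
}
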