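# S4 classes for the schema engine, vocabularies, harvested metadata,
# analysis provenance, the repository handle and the fixture generator.

#' Relationship cardinalities
#'
#' The closed set of relationship multiplicities representable in a
#' [SchemaGraph]: one-to-one, one-to-many and many-to-many. No other value
#' can be stored.
#'
#' @export
CARDINALITIES <- c("ONE_TO_ONE", "ONE_TO_MANY", "MANY_TO_MANY")

#' Entity stereotypes
#'
#' Broad roles an entity can play in the integration model: the three
#' MIABIS core categories, generic sub-entities, the five collection
#' sub-types, DICOM-derived imaging entities and image-analysis entities.
#'
#' @export
STEREOTYPES <- c("core", "sub_entity", "collection_type", "imaging",
                 "analysis")

.ATTR_DOMAIN_RE <- "^(text|integer|real|date|coded\\([A-Z_]+\\))$"

#' EntityDef: one entity of the ER model
#'
#' An entity (one table of the relational design) with its ordered
#' attribute list. Every entity additionally receives a surrogate `id`
#' primary key when DDL is generated; `id` is therefore reserved and never
#' appears among the declared attributes.
#'
#' @slot name entity identifier (CamelCase).
#' @slot stereotype one of [STEREOTYPES].
#' @slot attributes data.frame with columns `name`, `domain`
#'   (`text`, `integer`, `real`, `date` or `coded(VOCABULARY)`) and
#'   `nullable` (logical).
#' @export
setClass("EntityDef", representation(
  name = "character", stereotype = "character", attributes = "data.frame"))

setValidity("EntityDef", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "entity name must be a non-empty string")
  if (!(object@stereotype %in% STEREOTYPES))
    msg <- c(msg, sprintf("unknown stereotype '%s'", object@stereotype))
  a <- object@attributes
  if (!all(c("name", "domain", "nullable") %in% names(a)))
    msg <- c(msg, "attributes need columns name, domain, nullable")
  else {
    if (nrow(a) < 1L)
      msg <- c(msg, "an entity needs at least one attribute")
    if (anyDuplicated(a$name))
      msg <- c(msg, "duplicate attribute names")
    if (any(!nzchar(a$name)) || any(a$name == "id"))
      msg <- c(msg, "attribute names must be non-empty and not 'id'")
    if (any(!grepl(.ATTR_DOMAIN_RE, a$domain)))
      msg <- c(msg, "invalid attribute domain")
  }
  if (length(msg)) msg else TRUE
})

#' SchemaGraph: the executable entity-relationship model
#'
#' Entities plus typed, labelled relationships with cardinalities -- the
#' machine-readable form of an ER diagram. Structural slot shape is
#' enforced here; graph-level semantics (dangling endpoints, duplicate
#' names, connectivity) are checked by [validateSchema()] so that invalid
#' graphs can be represented and reported on rather than being
#' unconstructible.
#'
#' @slot model short model identifier (e.g. `"miabis_core"`,
#'   `"integration"`).
#' @slot hub name of the collection macro-category entity whose outgoing
#'   edges are treated as specialization links by [linkedEntities()].
#' @slot entities named list of [EntityDef] objects.
#' @slot relationships data.frame with columns `source`, `target`,
#'   `cardinality` (one of [CARDINALITIES]) and `label`.
#' @export
setClass("SchemaGraph", representation(
  model = "character", hub = "character", entities = "list",
  relationships = "data.frame"))

setValidity("SchemaGraph", function(object) {
  msg <- character()
  if (!all(vapply(object@entities, is, logical(1), "EntityDef")))
    msg <- c(msg, "entities must all be EntityDef objects")
  r <- object@relationships
  need <- c("source", "target", "cardinality", "label")
  if (!all(need %in% names(r)))
    msg <- c(msg, "relationships need columns source, target, cardinality, label")
  else if (nrow(r) && any(!r$cardinality %in% CARDINALITIES))
    msg <- c(msg, sprintf("cardinality outside {%s}",
                          paste(CARDINALITIES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' ValidationReport: collected invariant violations
#'
#' A tabular report of rule violations; an empty report means the checked
#' object is valid. Used both for schema validation and for PHI screening.
#'
#' @slot subject what was validated.
#' @slot violations data.frame with columns `rule` and `detail`.
#' @export
setClass("ValidationReport", representation(
  subject = "character", violations = "data.frame"))

#' TermList: a pinned controlled vocabulary
#'
#' A set of (code value, meaning) terms bound to the DICOM tag the model
#' reads them from, with a note recording the pinned standard edition.
#'
#' @slot vocabularyId one of `BODY_PART`, `DATASET_TYPE`, `MODALITY`.
#' @slot dicomTag the bound tag, e.g. `"(0018,0015)"`.
#' @slot editionNote provenance of the packaged list.
#' @slot terms data.frame with columns `code_value`, `meaning`.
#' @export
setClass("TermList", representation(
  vocabularyId = "character", dicomTag = "character",
  editionNote = "character", terms = "data.frame"))

setValidity("TermList", function(object) {
  t <- object@terms
  msg <- character()
  if (!all(c("code_value", "meaning") %in% names(t)))
    msg <- c(msg, "terms need columns code_value, meaning")
  else {
    if (any(!nzchar(t$code_value))) msg <- c(msg, "empty code_value")
    if (anyDuplicated(t$code_value)) msg <- c(msg, "duplicate code_value")
  }
  if (length(msg)) msg else TRUE
})

#' SeriesMetadata: harvested per-series DICOM header record
#'
#' One record per DICOM series, carrying the model's mapped header tags:
#' the study/series UIDs (stored as attributes, never used as record
#' keys), the three coded fields, acquisition and reconstruction parameter
#' maps, year-granular donor age, donor sex and the de-identification
#' verdict of [phiScreen()]. Coded values that fail vocabulary validation
#' are kept but listed in `nonConformant`.
#'
#' @slot studyUid,seriesUid DICOM instance UIDs (non-empty).
#' @slot datasetType SOP Class UID, coded against `DATASET_TYPE`.
#' @slot modality coded against `MODALITY`.
#' @slot bodyPart coded against `BODY_PART`; possibly resolved from the
#'   Anatomic Region Sequence; `NA` when absent from the header.
#' @slot acquisition,reconstruction named lists of parameter values
#'   (numeric values summarized per series as first value plus
#'   `<key>_min`/`<key>_max` range when slices disagree).
#' @slot donorRef pseudonymous subject identifier.
#' @slot donorAgeYears non-negative integer (<= 120) or `NA`.
#' @slot donorSex one of `F`, `M`, `O`, `unknown`.
#' @slot patientName,birthDate direct identifiers if present in the header
#'   (normally empty); inspected by [phiScreen()].
#' @slot deidentified `TRUE` only when [phiScreen()] finds nothing.
#' @slot nonConformant names of coded fields that failed validation.
#' @slot nFiles number of files contributing to the series.
#' @export
setClass("SeriesMetadata", representation(
  studyUid = "character", seriesUid = "character",
  datasetType = "character", modality = "character", bodyPart = "character",
  acquisition = "list", reconstruction = "list",
  donorRef = "character", donorAgeYears = "integer", donorSex = "character",
  patientName = "character", birthDate = "character",
  deidentified = "logical", nonConformant = "character",
  nFiles = "integer"))

setValidity("SeriesMetadata", function(object) {
  msg <- character()
  if (!nzchar(object@studyUid)) msg <- c(msg, "empty studyUid")
  if (!nzchar(object@seriesUid)) msg <- c(msg, "empty seriesUid")
  if (!is.na(object@donorAgeYears) &&
      (object@donorAgeYears < 0L || object@donorAgeYears > 120L))
    msg <- c(msg, "donorAgeYears outside [0, 120]")
  if (!object@donorSex %in% c("F", "M", "O", "unknown"))
    msg <- c(msg, "donorSex outside {F, M, O, unknown}")
  if (length(msg)) msg else TRUE
})

#' HarvestReport: bookkeeping of a harvest run
#'
#' @slot filesSeen number of files examined.
#' @slot seriesEmitted number of [SeriesMetadata] records produced.
#' @slot rejected data.frame with columns `path` and `reason`.
#' @export
setClass("HarvestReport", representation(
  filesSeen = "integer", seriesEmitted = "integer", rejected = "data.frame"))

# ---- analysis provenance ----------------------------------------------

SEGMENTATION_MODALITIES <- c("manual", "semi_automatic", "automatic")
REGISTRATION_SCOPES <- c("intra_sequence", "inter_sequence", "inter_modal")
FEATURE_CLASSES <- c("texture", "deep", "dynamic_signal")

#' PreprocessingRecord: ordered preprocessing steps
#'
#' @slot steps ordered list; each element a list with `name` and a
#'   schemaless `parameters` map (unique keys).
#' @slot software,version the tool that ran the steps.
#' @export
setClass("PreprocessingRecord", representation(
  steps = "list", software = "character", version = "character"))

#' SegmentationRecord: one segmentation of an image collection
#'
#' @slot modality `manual`, `semi_automatic` or `automatic`.
#' @slot operatorOrAlgorithm who or what produced the mask.
#' @slot parameters schemaless map (unique keys).
#' @export
setClass("SegmentationRecord", representation(
  modality = "character", operatorOrAlgorithm = "character",
  parameters = "list"))

#' RegistrationRecord: one spatial registration
#'
#' @slot scope `intra_sequence`, `inter_sequence` or `inter_modal`.
#' @slot transformType e.g. rigid, affine, deformable.
#' @slot parameters schemaless map (unique keys).
#' @export
setClass("RegistrationRecord", representation(
  scope = "character", transformType = "character", parameters = "list"))

#' BiomarkerRecord: one extracted imaging biomarker value
#'
#' @slot featureClass `texture`, `deep` or `dynamic_signal`.
#' @slot name feature name (vector-valued deep features are stored one
#'   record per component, index-suffixed).
#' @slot value numeric scalar.
#' @slot units unit string (may be empty for dimensionless features).
#' @export
setClass("BiomarkerRecord", representation(
  featureClass = "character", name = "character", value = "numeric",
  units = "character"))

#' AnalysisProvenance: the image-analysis branch for one image collection
#'
#' @slot imageCollectionRef collection identifier the analysis belongs to.
#' @slot preprocessing a [PreprocessingRecord].
#' @slot segmentations list of [SegmentationRecord].
#' @slot registrations list of [RegistrationRecord].
#' @slot biomarkers list of [BiomarkerRecord].
#' @export
setClass("AnalysisProvenance", representation(
  imageCollectionRef = "character", preprocessing = "PreprocessingRecord",
  segmentations = "list", registrations = "list", biomarkers = "list"))

# ---- repository --------------------------------------------------------

#' BiobankStore: handle on an embedded relational repository
#'
#' Wraps the SQLite connection, the schema graph the store was created
#' from, and the vocabulary strictness mode. Single-writer, many-reader.
#'
#' @slot path location of the store file.
#' @slot con DBI connection.
#' @slot schema the [SchemaGraph] whose DDL created the store.
#' @slot strict `TRUE` (default): non-conformant coded values are
#'   rejected at ingestion; `FALSE`: stored but flagged.
#' @export
setClass("BiobankStore", representation(
  path = "character", con = "ANY", schema = "SchemaGraph",
  strict = "logical"))

COLLECTION_TYPES <- c("ImageCollection", "SampleTissueCollection",
                      "ClinicalVariableCollection",
                      "MolecularBiomarkerCollection", "SoftwareSourceCode")

#' CollectionRecord: one record destined for the Collection macro-category
#'
#' @slot collectionType one of the five sub-collection types.
#' @slot biobankRef,studyRef,donorRef identifiers that must resolve in the
#'   store at ingestion time.
#' @slot name human-readable collection label.
#' @slot payload type-specific content: a [SeriesMetadata] for image
#'   collections; a list with `material_type` and `storage_temperature`
#'   for sample tissue collections; a variable map for clinical
#'   collections; a list of biomarker entries for molecular collections;
#'   an artifact descriptor (`name`, `version`, ...) for software
#'   collections.
#' @export
setClass("CollectionRecord", representation(
  collectionType = "character", biobankRef = "character",
  studyRef = "character", donorRef = "character", name = "character",
  payload = "ANY"))

setValidity("CollectionRecord", function(object) {
  if (!object@collectionType %in% COLLECTION_TYPES)
    sprintf("collectionType outside {%s}",
            paste(COLLECTION_TYPES, collapse = ", "))
  else TRUE
})

#' EFormDocument: structured clinical e-form
#'
#' An ordered map of sections (each a field map); carries a diagnosis
#' section with symptom fields and a laboratory-tests subsection whenever
#' the donor has clinical variables on record.
#'
#' @slot sections ordered named list of section field maps.
#' @slot provenance collection identifiers the document was built from.
#' @export
setClass("EFormDocument", representation(
  sections = "list", provenance = "list"))

# ---- fixtures ----------------------------------------------------------

#' CohortSpec: parameters of the synthetic CT cohort
#'
#' The default spec emulates the example set the model was designed
#' against: 18 paediatric donors, one anonymised multislice CT series
#' each.
#'
#' @slot nPatients number of donors (0 allowed, yields an empty cohort).
#' @slot seriesPerPatient,slicesPerSeries positive counts.
#' @slot modality coded modality written to every series.
#' @slot bodyPartPool coded body-part terms sampled per series.
#' @slot ageRange integer `(lo, hi)` in years; the default paediatric
#'   profile stays within `[0, 17]`.
#' @slot seed RNG seed; all generated values are deterministic in it.
#' @export
setClass("CohortSpec", representation(
  nPatients = "integer", seriesPerPatient = "integer",
  slicesPerSeries = "integer", modality = "character",
  bodyPartPool = "character", ageRange = "integer", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nPatients < 0L) msg <- c(msg, "nPatients must be >= 0")
  if (object@seriesPerPatient < 1L || object@slicesPerSeries < 1L)
    msg <- c(msg, "seriesPerPatient and slicesPerSeries must be positive")
  if (length(object@ageRange) != 2L || any(is.na(object@ageRange)) ||
      object@ageRange[1] > object@ageRange[2] ||
      object@ageRange[1] < 0L || object@ageRange[2] > 120L)
    msg <- c(msg, "ageRange must be (lo, hi) within [0, 120]")
  if (length(msg)) msg else TRUE
})
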