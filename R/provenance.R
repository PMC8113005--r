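# Image-analysis provenance: preprocessing, segmentation, registration
# and imaging-biomarker records attached to an image collection. The
# three-value enumerations (segmentation modality, registration scope,
# feature class) are closed sets; parameter maps are schemaless key->value
# stores validated only for key uniqueness.

.check_param_map <- function(parameters, what) {
  if (!is.list(parameters))
    .err("usage_error", sprintf("%s parameters must be a list", what))
  if (length(parameters)) {
    if (is.null(names(parameters)) || any(!nzchar(names(parameters))))
      .err("usage_error", sprintf("%s parameters must be named", what))
    if (anyDuplicated(names(parameters)))
      .err("usage_error", sprintf("%s parameter keys must be unique", what))
  }
  parameters
}

.check_enum <- function(value, allowed, what) {
  if (length(value) != 1L || !value %in% allowed)
    .err("invalid_enumeration_error",
         sprintf("%s must be one of {%s}, got '%s'", what,
                 paste(allowed, collapse = ", "), as.character(value)))
  value
}

#' Build a preprocessing record
#'
#' @param steps ordered list of steps; each either a step-name string or a
#'   list with `name` and a `parameters` map. Order is preserved.
#' @param software,version tool provenance.
#' @return a [PreprocessingRecord].
#' @export
preprocessingRecord <- function(steps = list(), software = "",
                                version = "") {
  steps <- lapply(steps, function(s) {
    if (is.character(s)) s <- list(name = s, parameters = list())
    if (is.null(s$name) || !nzchar(s$name))
      .err("usage_error", "preprocessing step names must be non-empty")
    list(name = s$name,
         parameters = .check_param_map(s$parameters %||% list(), "step"))
  })
  new("PreprocessingRecord", steps = steps, software = software,
      version = version)
}

#' Build a segmentation record
#'
#' @param modality `"manual"`, `"semi_automatic"` or `"automatic"`.
#' @param operatorOrAlgorithm operator (manual) or algorithm name.
#' @param parameters schemaless map with unique keys.
#' @return a [SegmentationRecord].
#' @export
segmentationRecord <- function(modality, operatorOrAlgorithm = "",
                               parameters = list()) {
  new("SegmentationRecord",
      modality = .check_enum(modality, SEGMENTATION_MODALITIES,
                             "segmentation modality"),
      operatorOrAlgorithm = operatorOrAlgorithm,
      parameters = .check_param_map(parameters, "segmentation"))
}

#' Build a registration record
#'
#' @param scope `"intra_sequence"`, `"inter_sequence"` or
#'   `"inter_modal"`.
#' @param transformType transform family (rigid, affine, ...).
#' @param parameters schemaless map with unique keys.
#' @return a [RegistrationRecord].
#' @export
registrationRecord <- function(scope, transformType = "",
                               parameters = list()) {
  new("RegistrationRecord",
      scope = .check_enum(scope, REGISTRATION_SCOPES, "registration scope"),
      transformType = transformType,
      parameters = .check_param_map(parameters, "registration"))
}

#' Build an imaging-biomarker record
#'
#' Biomarker values are dimensioned scalars; pass a vector-valued feature
#' as one record per component with an index-suffixed name.
#'
#' @param featureClass `"texture"`, `"deep"` or `"dynamic_signal"`.
#' @param name non-empty feature name.
#' @param value numeric scalar.
#' @param units unit string (may be empty).
#' @return a [BiomarkerRecord].
#' @export
biomarkerRecord <- function(featureClass, name, value, units = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    .err("usage_error", "biomarker name must be non-empty")
  new("BiomarkerRecord",
      featureClass = .check_enum(featureClass, FEATURE_CLASSES,
                                 "biomarker feature class"),
      name = name, value = as.numeric(value), units = units)
}

#' Assemble the provenance of one image collection
#'
#' @param imageCollectionRef identifier of an ingested image collection.
#' @param preprocessing a [PreprocessingRecord].
#' @param segmentations list of [SegmentationRecord].
#' @param registrations list of [RegistrationRecord].
#' @param biomarkers list of [BiomarkerRecord].
#' @return an [AnalysisProvenance]; persist with [attachAnalysis()].
#' @export
analysisProvenance <- function(imageCollectionRef,
                               preprocessing = preprocessingRecord(),
                               segmentations = list(),
                               registrations = list(),
                               biomarkers = list()) {
  .stopifnot_scalar_chr(imageCollectionRef, "imageCollectionRef")
  chk <- function(lst, cls) {
    for (x in lst) if (!is(x, cls))
      .err("usage_error", sprintf("expected a list of %s objects", cls))
    lst
  }
  new("AnalysisProvenance",
      imageCollectionRef = imageCollectionRef,
      preprocessing = preprocessing,
      segmentations = chk(segmentations, "SegmentationRecord"),
      registrations = chk(registrations, "RegistrationRecord"),
      biomarkers = chk(biomarkers, "BiomarkerRecord"))
}

setMethod("show", "AnalysisProvenance", function(object) {
  cat(sprintf(
    "AnalysisProvenance for %s: %d preprocessing step(s), %d segmentation(s), %d registration(s), %d biomarker(s)\n",
    object@imageCollectionRef, length(object@preprocessing@steps),
    length(object@segmentations), length(object@registrations),
    length(object@biomarkers)))
})
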