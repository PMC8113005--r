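# DICOM metadata harvest: per-file tag extraction, per-series grouping
# with value reconciliation, and PHI screening of the resulting records.

# DICOM age strings ("009Y", "018M", "010W", "200D") to whole years,
# flooring sub-year units; MIABIS donor age is year-granular.
.parse_age_years <- function(x) {
  if (is.null(x) || !length(x) || is.na(x) || !nzchar(x))
    return(NA_integer_)
  m <- regmatches(x, regexec("^([0-9]{1,3})([DWMY])$", toupper(trimws(x))))[[1]]
  if (length(m) != 3L) {
    n <- suppressWarnings(as.integer(x))
    return(if (!is.na(n) && n >= 0L) n else NA_integer_)
  }
  n <- as.integer(m[2])
  as.integer(floor(switch(m[3], D = n / 365.25, W = n / 52.18,
                          M = n / 12, Y = n)))
}

.parse_sex <- function(x) {
  x <- toupper(trimws(x %||% ""))
  if (x %in% c("F", "M", "O")) x else "unknown"
}

.num_or_na <- function(x) {
  if (is.null(x) || !length(x)) return(NA_real_)
  suppressWarnings(as.numeric(x[1]))
}

#' Harvest one DICOM file
#'
#' Extracts the model's mapped tags from a single Part-10 file into a
#' per-file fragment (later grouped per series by [groupSeries()]). The
#' body part is taken from Body Part Examined (0018,0015) first and, when
#' that tag is absent, resolved from the code meaning inside the Anatomic
#' Region Sequence (0008,2218); if both are absent the field is `NA` and
#' flagged, not fatal. Pixel data is never read into the record.
#'
#' @param path a readable DICOM Part-10 file.
#' @return a list of class `"dicom_fragment"` with the extracted fields
#'   (`study_uid`, `series_uid`, `dataset_type`, `modality`, `body_part`,
#'   acquisition/reconstruction parameters, donor fields) plus
#'   `non_conformant`, the names of coded fields failing vocabulary
#'   validation.
#' @seealso [groupSeries()], [phiScreen()]
#' @export
harvestFile <- function(path) {
  ds <- readDicomFile(path)
  el <- ds$elements
  study_uid <- el$StudyInstanceUID %||% ""
  series_uid <- el$SeriesInstanceUID %||% ""
  if (!nzchar(study_uid) || !nzchar(series_uid))
    .err("missing_required_tag_error",
         sprintf("%s: study or series instance UID is absent", path))

  non_conf <- character()
  body_part <- el$BodyPartExamined
  body_part_source <- "tag"
  if (is.null(body_part) || !nzchar(body_part)) {
    body_part <- NA_character_
    seq_items <- el$AnatomicRegionSequence
    if (length(seq_items)) {
      meaning <- seq_items[[1]]$CodeMeaning %||% seq_items[[1]]$CodeValue
      if (!is.null(meaning) && nzchar(meaning)) {
        code <- .meaning_to_code("BODY_PART", meaning)
        body_part <- if (!is.na(code)) code else normalizeTerm(meaning)
        body_part_source <- "anatomic_region_sequence"
      }
    }
  } else {
    body_part <- normalizeTerm(body_part)
  }
  if (is.na(body_part) || !validateValue("BODY_PART", body_part))
    non_conf <- c(non_conf, "body_part")

  modality <- normalizeTerm(el$Modality %||% NA_character_)
  if (is.na(modality) || !validateValue("MODALITY", modality))
    non_conf <- c(non_conf, "modality")
  dataset_type <- trimws(el$SOPClassUID %||% NA_character_)
  if (is.na(dataset_type) || !validateValue("DATASET_TYPE", dataset_type))
    non_conf <- c(non_conf, "dataset_type")

  frag <- list(
    path = path,
    study_uid = study_uid,
    series_uid = series_uid,
    dataset_type = dataset_type,
    modality = modality,
    body_part = body_part,
    body_part_source = body_part_source,
    acquisition = list(
      kvp = .num_or_na(el$KVP),
      exposure_time_ms = .num_or_na(el$ExposureTime),
      slice_thickness_mm = .num_or_na(el$SliceThickness),
      pixel_spacing_mm = if (is.null(el$PixelSpacing)) NA_character_
      else paste(el$PixelSpacing, collapse = "\\")),
    reconstruction = list(
      convolution_kernel = if (is.null(el$ConvolutionKernel)) NA_character_
      else as.character(el$ConvolutionKernel[1]),
      reconstruction_diameter_mm = .num_or_na(el$ReconstructionDiameter)),
    manufacturer = el$Manufacturer %||% NA_character_,
    model_name = el$ManufacturerModelName %||% NA_character_,
    donor_ref = el$PatientID %||% NA_character_,
    donor_age_years = .parse_age_years(el$PatientAge),
    donor_sex = .parse_sex(el$PatientSex),
    patient_name = el$PatientName %||% "",
    birth_date = el$PatientBirthDate %||% "",
    non_conformant = non_conf)
  class(frag) <- "dicom_fragment"
  frag
}

# fields that must be constant across the slices of one series
.SERIES_CONSTANT <- c("study_uid", "modality", "dataset_type", "body_part",
                      "donor_ref", "donor_sex")

.summarize_numeric <- function(values, key) {
  v <- values[!is.na(values)]
  out <- list()
  out[[key]] <- if (length(v)) v[1] else NA_real_
  if (length(unique(v)) > 1L) {
    out[[paste0(key, "_min")]] <- min(v)
    out[[paste0(key, "_max")]] <- max(v)
  }
  out
}

.fragments_to_series <- function(frags) {
  f1 <- frags[[1]]
  acq <- list()
  for (key in c("kvp", "exposure_time_ms", "slice_thickness_mm"))
    acq <- c(acq, .summarize_numeric(
      vapply(frags, function(f) f$acquisition[[key]], numeric(1)), key))
  acq$pixel_spacing_mm <- f1$acquisition$pixel_spacing_mm
  rec <- list(
    convolution_kernel = f1$reconstruction$convolution_kernel,
    reconstruction_diameter_mm = unlist(.summarize_numeric(
      vapply(frags, function(f) f$reconstruction$reconstruction_diameter_mm,
             numeric(1)), "d"))[["d"]])
  ages <- vapply(frags, function(f) f$donor_age_years, integer(1))
  sm <- new("SeriesMetadata",
            studyUid = f1$study_uid, seriesUid = f1$series_uid,
            datasetType = f1$dataset_type, modality = f1$modality,
            bodyPart = f1$body_part, acquisition = acq,
            reconstruction = rec,
            donorRef = f1$donor_ref %||% NA_character_,
            donorAgeYears = if (all(is.na(ages))) NA_integer_
            else as.integer(ages[!is.na(ages)][1]),
            donorSex = f1$donor_sex,
            patientName = f1$patient_name, birthDate = f1$birth_date,
            deidentified = FALSE,
            nonConformant = sort(unique(unlist(
              lapply(frags, `[[`, "non_conformant")))),
            nFiles = length(frags))
  sm@deidentified <- isValid(phiScreen(sm))
  validObject(sm)
  sm
}

#' Group harvested files into per-series records
#'
#' Harvests every path, groups the fragments by series instance UID and
#' reconciles per-file values: modality, dataset type, body part, study
#' UID and donor fields must be constant within a series (a conflict
#' rejects the series with a reason); numeric acquisition parameters may
#' vary per slice and are summarized as first value plus min/max range.
#' Per-file failures are collected in the report, never raised. The result
#' is order-insensitive: permuting `paths` yields the same series set.
#'
#' @param paths character vector of file paths (may be empty).
#' @return list with `series` (list of [SeriesMetadata], ordered by series
#'   UID) and `report` (a [HarvestReport]).
#' @export
groupSeries <- function(paths) {
  paths <- as.character(paths)
  rejected <- data.frame(path = character(), reason = character(),
                         stringsAsFactors = FALSE)
  frags <- list()
  for (p in paths) {
    f <- tryCatch(harvestFile(p), dicomiabis_error = function(e) e)
    if (inherits(f, "dicom_fragment")) frags[[length(frags) + 1L]] <- f
    else rejected <- rbind(rejected, data.frame(
      path = p, reason = conditionMessage(f), stringsAsFactors = FALSE))
  }
  by_series <- split(frags, vapply(frags, `[[`, character(1), "series_uid"))
  series <- list()
  for (uid in sort(names(by_series))) {
    grp <- by_series[[uid]]
    # deterministic intra-series order regardless of input permutation
    grp <- grp[order(vapply(grp, `[[`, character(1), "path"))]
    conflicts <- .SERIES_CONSTANT[vapply(.SERIES_CONSTANT, function(k) {
      length(unique(vapply(grp, function(f) {
        v <- f[[k]]
        if (is.null(v) || is.na(v)) "<NA>" else as.character(v)
      }, character(1)))) > 1L
    }, logical(1))]
    if (length(conflicts)) {
      rejected <- rbind(rejected, data.frame(
        path = grp[[1]]$path,
        reason = sprintf("series %s: conflicting %s across slices", uid,
                         paste(conflicts, collapse = ", ")),
        stringsAsFactors = FALSE))
    } else {
      series[[length(series) + 1L]] <- .fragments_to_series(grp)
    }
  }
  report <- new("HarvestReport", filesSeen = length(paths),
                seriesEmitted = length(series), rejected = rejected)
  list(series = series, report = report)
}

setMethod("show", "HarvestReport", function(object) {
  cat(sprintf("HarvestReport: %d file(s) seen, %d series emitted, %d rejection(s)\n",
              object@filesSeen, object@seriesEmitted, nrow(object@rejected)))
  if (nrow(object@rejected)) print(object@rejected)
})

setMethod("show", "SeriesMetadata", function(object) {
  cat(sprintf("SeriesMetadata %s\n  %s / %s / donor %s (%s, %s y), %d file(s), deidentified=%s\n",
              object@seriesUid, object@modality, object@bodyPart,
              object@donorRef, object@donorSex, object@donorAgeYears,
              object@nFiles, object@deidentified))
  if (length(object@nonConformant))
    cat("  non-conformant fields:",
        paste(object@nonConformant, collapse = ", "), "\n")
})

# name-like free text: DICOM PN caret convention or "Surname, Forename"
.PN_RE <- "[A-Za-z]+\\^[A-Za-z]+|^[A-Z][a-z]+,[ ]?[A-Z][a-z]+$"
# a full date: plausible YYYYMMDD
.DATE_RE <- "^(19|20)[0-9]{2}(0[1-9]|1[0-2])(0[1-9]|[12][0-9]|3[01])$"

#' Screen a series record for direct identifiers
#'
#' Flags person-name content and full birth dates anywhere in the record:
#' a populated patient-name or birth-date field, a caret- or
#' comma-delimited name pattern in any free-text field, or an
#' eight-digit date value in a free-text field. A record is considered
#' de-identified only when the report is empty.
#'
#' @param record a [SeriesMetadata].
#' @return a [ValidationReport] (one row per flag).
#' @rdname phiScreen
#' @export
setMethod("phiScreen", "SeriesMetadata", function(record) {
  rule <- character(); detail <- character()
  add <- function(r, d) { rule <<- c(rule, r); detail <<- c(detail, d) }
  if (nzchar(record@patientName))
    add("person_name", "patient name field is populated")
  if (nzchar(record@birthDate))
    add("birth_date", "patient birth date field is populated")
  free_text <- c(
    donor_ref = record@donorRef,
    unlist(Filter(is.character, record@acquisition)),
    unlist(Filter(is.character, record@reconstruction)))
  for (i in seq_along(free_text)) {
    v <- free_text[[i]]
    if (is.na(v)) next
    if (grepl(.PN_RE, v))
      add("person_name",
          sprintf("name-like pattern in field '%s'", names(free_text)[i]))
    if (grepl(.DATE_RE, v))
      add("birth_date",
          sprintf("full date in field '%s'", names(free_text)[i]))
  }
  .report(sprintf("series %s", record@seriesUid), rule, detail)
})
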