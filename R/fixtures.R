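# Synthetic fixture generator: seeded, standard-conformant DICOM CT
# series plus companion clinical records emulating an anonymised
# paediatric neuroblastoma cohort. The default spec mirrors the example
# set the model was designed against: 18 donors, one multislice CT series
# each. Parameter values are drawn uniformly from documented plausible
# ranges and carry no clinical claim; the manifest is the round-trip
# ground truth for the harvester.

.CT_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.2"
.MR_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.4"
.UID_ROOT <- "1.2.826.0.1.3680043.10.424"

.sop_class_for <- function(modality) {
  switch(modality, CT = .CT_SOP_CLASS, MR = .MR_SOP_CLASS, .CT_SOP_CLASS)
}

#' Specify a synthetic cohort
#'
#' @param nPatients number of donors; default 18, the example-set size
#'   the integration model was developed against.
#' @param seriesPerPatient,slicesPerSeries series and slice counts;
#'   defaults one multislice CT series of 4 slices per donor.
#' @param modality modality code written to every series (default CT).
#' @param bodyPartPool body-part terms sampled per series; the default
#'   pool covers typical paediatric neuroblastoma CT coverage.
#' @param ageRange integer years `(lo, hi)`; default paediatric 0-17.
#' @param seed RNG seed; the whole cohort is deterministic in it.
#' @return a [CohortSpec].
#' @export
cohortSpec <- function(nPatients = 18L, seriesPerPatient = 1L,
                       slicesPerSeries = 4L, modality = "CT",
                       bodyPartPool = c("ABDOMEN", "CHEST",
                                        "ABDOMENPELVIS"),
                       ageRange = c(0L, 17L), seed = 1L) {
  new("CohortSpec", nPatients = as.integer(nPatients),
      seriesPerPatient = as.integer(seriesPerPatient),
      slicesPerSeries = as.integer(slicesPerSeries),
      modality = modality, bodyPartPool = bodyPartPool,
      ageRange = as.integer(ageRange), seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d patient(s) x %d series x %d slice(s), %s, ages %d-%d, seed %d\n",
    object@nPatients, object@seriesPerPatient, object@slicesPerSeries,
    object@modality, object@ageRange[1], object@ageRange[2], object@seed))
})

#' Generate a synthetic DICOM cohort
#'
#' Writes valid DICOM Part-10 files (one directory per donor) with
#' coherent UIDs, vocabulary-conformant modality / body part / dataset
#' type, plausible CT acquisition and reconstruction parameters,
#' paediatric ages and no direct identifiers (no patient name, no birth
#' date), plus a minimal uniform pixel block. Identical spec and seed
#' reproduce the cohort exactly. The returned manifest lists every
#' written metadata value, one row per series, and is also saved as
#' `manifest.tsv` in `outDir`.
#'
#' @param spec a [CohortSpec].
#' @param outDir writable output directory (created if absent).
#' @return the manifest data.frame.
#' @rdname generateCohort
#' @export
setMethod("generateCohort", "CohortSpec", function(spec, outDir) {
  validObject(spec)
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    .err("unwritable_directory_error",
         sprintf("cannot create output directory %s", outDir))
  probe <- file.path(outDir, ".write_probe")
  ok <- tryCatch({ writeLines("x", probe); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    .err("unwritable_directory_error",
         sprintf("output directory %s is not writable", outDir))
  unlink(probe)

  rows <- list()
  .with_seed(spec@seed, {
    for (p in seq_len(spec@nPatients)) {
      donor <- sprintf("DONOR_%02d", p)
      age <- sample(seq(spec@ageRange[1], spec@ageRange[2]), 1L)
      sex <- sample(c("F", "M"), 1L)
      for (s in seq_len(spec@seriesPerPatient)) {
        study_uid <- sprintf("%s.%d.%d.1", .UID_ROOT, spec@seed, p)
        series_uid <- sprintf("%s.%d.%d.2.%d", .UID_ROOT, spec@seed, p, s)
        body_part <- sample(spec@bodyPartPool, 1L)
        kvp <- sample(c(80, 100, 120), 1L)
        st <- sample(c(1, 2, 2.5, 3, 5), 1L)
        ps <- round(runif(1, 0.4, 0.8), 3)
        kernel <- sample(c("STANDARD", "SOFT", "B30F", "LUNG"), 1L)
        rd <- round(runif(1, 200, 400), 1)
        et <- sample(500:1500, 1L)
        sdir <- file.path(outDir, donor, sprintf("series_%02d", s))
        dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
        for (k in seq_len(spec@slicesPerSeries)) {
          writeDicomFile(
            file.path(sdir, sprintf("slice_%03d.dcm", k)),
            list(
              SOPClassUID = .sop_class_for(spec@modality),
              SOPInstanceUID = sprintf("%s.3.%d", series_uid, k),
              Modality = spec@modality,
              BodyPartExamined = body_part,
              PatientID = donor,
              PatientSex = sex,
              PatientAge = sprintf("%03dY", age),
              KVP = format(kvp),
              SliceThickness = format(st),
              PixelSpacing = c(format(ps), format(ps)),
              ConvolutionKernel = kernel,
              ReconstructionDiameter = format(rd),
              ExposureTime = format(et),
              StudyInstanceUID = study_uid,
              SeriesInstanceUID = series_uid,
              InstanceNumber = format(k)))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          donor_ref = donor, age_years = age, sex = sex,
          study_uid = study_uid, series_uid = series_uid,
          modality = spec@modality, body_part = body_part,
          dataset_type = .sop_class_for(spec@modality),
          kvp = kvp, exposure_time_ms = et, slice_thickness_mm = st,
          pixel_spacing_mm = paste(format(ps), format(ps), sep = "\\"),
          convolution_kernel = kernel, reconstruction_diameter_mm = rd,
          n_slices = spec@slicesPerSeries, dir = sdir,
          stringsAsFactors = FALSE)
      }
    }
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else data.frame()
  write.table(manifest, file.path(outDir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  manifest
})

#' Generate companion clinical records
#'
#' One clinical-variable record per donor of the cohort, with diagnosis
#' symptoms (logical fields) and laboratory tests (numeric fields typical
#' of a neuroblastoma work-up: LDH, ferritin, NSE, urinary HVA/VMA) drawn
#' from seeded uniform distributions over documented plausible ranges.
#' Donor references are consistent with the imaging manifest of the same
#' spec.
#'
#' @param spec a [CohortSpec].
#' @param out optional TSV path for the records.
#' @return data.frame with one row per donor.
#' @rdname generateClinical
#' @export
setMethod("generateClinical", "CohortSpec", function(spec, out = NULL) {
  validObject(spec)
  recs <- .with_seed(spec@seed + 1L, {
    n <- spec@nPatients
    if (n == 0L) data.frame() else data.frame(
      donor_ref = sprintf("DONOR_%02d", seq_len(n)),
      fever = runif(n) < 0.3,
      bone_pain = runif(n) < 0.35,
      abdominal_distension = runif(n) < 0.5,
      weight_loss = runif(n) < 0.4,
      irritability = runif(n) < 0.25,
      ldh_u_l = round(runif(n, 200, 2000), 1),
      ferritin_ng_ml = round(runif(n, 20, 500), 1),
      nse_ng_ml = round(runif(n, 10, 200), 1),
      urinary_hva_mmol_mol_crea = round(runif(n, 5, 100), 1),
      urinary_vma_mmol_mol_crea = round(runif(n, 5, 80), 1),
      stringsAsFactors = FALSE)
  })
  if (!is.null(out))
    write.table(recs, out, sep = "\t", row.names = FALSE, quote = FALSE)
  recs
})

.SYMPTOM_FIELDS <- c("fever", "bone_pain", "abdominal_distension",
                     "weight_loss", "irritability")
.LAB_FIELDS <- c("ldh_u_l", "ferritin_ng_ml", "nse_ng_ml",
                 "urinary_hva_mmol_mol_crea", "urinary_vma_mmol_mol_crea")

#' Shape one clinical record as a collection payload
#'
#' @param row one row of the [generateClinical()] data.frame (or any
#'   data.frame with the same fields).
#' @return variable map with `symptoms` and `laboratory_tests` submaps,
#'   suitable as a ClinicalVariableCollection payload.
#' @export
clinicalPayload <- function(row) {
  list(symptoms = as.list(row[.SYMPTOM_FIELDS]),
       laboratory_tests = as.list(row[.LAB_FIELDS]))
}

#' Harvest and ingest a generated cohort
#'
#' End-to-end convenience: harvests every DICOM file under `dicomDir`,
#' registers the biobank, study and donors, ingests one image collection
#' per series and, when clinical records are supplied, one clinical
#' variable collection per donor.
#'
#' @param store an integration-model [BiobankStore].
#' @param dicomDir directory tree of DICOM files.
#' @param clinical optional [generateClinical()] data.frame.
#' @param biobankRef,studyRef reference-entity identifiers to register.
#' @return list with `collections` (image-collection ids named by series
#'   UID), `clinical` (clinical-collection ids named by donor) and
#'   `report` (the [HarvestReport]).
#' @export
ingestCohort <- function(store, dicomDir, clinical = NULL,
                         biobankRef = "BB_LOCAL", studyRef = "ST_LOCAL") {
  paths <- sort(list.files(dicomDir, pattern = "\\.dcm$", recursive = TRUE,
                           full.names = TRUE))
  grouped <- groupSeries(paths)
  registerBiobank(store, biobankRef)
  registerStudy(store, studyRef, biobankRef = biobankRef)
  cids <- character()
  for (sm in grouped$series) {
    registerDonor(store, sm@donorRef, ageYears = sm@donorAgeYears,
                  sex = sm@donorSex)
    cid <- ingest(store, collectionRecord(
      "ImageCollection", biobankRef, studyRef, sm@donorRef, sm,
      name = sprintf("CT series %s", sm@seriesUid)))
    cids[sm@seriesUid] <- cid
  }
  clin_ids <- character()
  if (!is.null(clinical) && nrow(clinical)) {
    known <- vapply(grouped$series, function(s) s@donorRef, character(1))
    for (i in seq_len(nrow(clinical))) {
      donor <- clinical$donor_ref[i]
      if (!donor %in% known) next
      clin_ids[donor] <- ingest(store, collectionRecord(
        "ClinicalVariableCollection", biobankRef, studyRef, donor,
        clinicalPayload(clinical[i, ]),
        name = sprintf("clinical variables %s", donor)))
    }
  }
  list(collections = cids, clinical = clin_ids, report = grouped$report)
}
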