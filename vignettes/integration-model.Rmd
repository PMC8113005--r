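---
title: "Describing DICOM image collections in a MIABIS biobank catalogue"
author: "dicomiabis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Describing DICOM image collections in a MIABIS biobank catalogue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dicomiabis)
```

## The problem

Biobank networks exchange catalogue information in MIABIS 2.0, a data
model whose core consists of three components — biobank, study and
sample collection — with sub-entities (donor age, donor sex, material
type, storage temperature) attached to the sample collection and every
relationship typed as 1:1, 1:N or N:M. The model was built for fluid and
tissue samples. Imaging biobanks, whose holdings are DICOM series and
biomarkers computed from them, have no place in it: the header metadata
that makes an image collection findable (modality, body part, dataset
type, acquisition parameters) and the provenance of derived radiomic
features are not representable.

`dicomiabis` implements one integration model that closes this gap, as
runnable software: the model is a machine-checked entity-relationship
graph, its relational form is generated rather than hand-written, and a
synthetic cohort exercises every layer.

## The model

The MIABIS core is kept intact and extended:

1. The sample collection is generalised to a **Collection**
   macro-category. Its five sub-collection types — ImageCollection,
   SampleTissueCollection, ClinicalVariableCollection,
   MolecularBiomarkerCollection, SoftwareSourceCode — let one catalogue
   hold heterogeneous holdings under one hub. Donor-level descriptors
   (age, sex) stay on the macro-category; tissue-specific descriptors
   (material type, storage temperature) move down to the sample-tissue
   sub-collection, where they belong.
2. **ImageCollection** is directly linked to exactly five entities:
   BodyPartExamined, ModalityInformation, DatasetType, ImageAnalysis and
   RegistrationParameters. The first three are grounded in DICOM tags
   (0018,0015), (0008,0060) via ModalityInformation, and (0008,0016).
   ModalityInformation additionally carries acquisition and
   reconstruction parameters.
3. The **analysis branch** records how biomarkers were produced:
   ImageAnalysis splits into preprocessing parameters, segmentation and
   imaging biomarkers; segmentation specialises into manual,
   semi-automatic and automatic; biomarkers into texture, deep and
   dynamic-signal features; registration into intra-sequence,
   inter-sequence and inter-modal. These three-value sets are closed
   enumerations everywhere in the package — no record can hold a value
   outside them.

```{r}
ig <- buildIntegrationModel()
ig
linkedEntities(ig, "ImageCollection")
```

### Design choices in the open spots

The source diagrams leave several things unstated; the choices below are
recorded per edge in the registry (`inst/extdata/registry/`) and can be
overridden there without code changes.

* **Cardinalities of the new edges.** Collection → sub-collection types
  are 1:N. ImageCollection → BodyPartExamined and → DatasetType are 1:1
  (a series has one body part and one SOP class); → ModalityInformation,
  → ImageAnalysis and → RegistrationParameters are 1:N (repeated
  analyses and registrations of the same collection are plausible).
  Study ↔ Collection is kept N:M, as a study can use several
  collections and a collection can serve several studies.
* **Attribute inventories.** Only the attributes legible from the model
  description are declared; acquisition/reconstruction/preprocessing
  entities additionally carry a schemaless `parameters` text attribute
  so richer tag sets can ride along without schema changes. The
  attribute registry is data, not code, and is deliberately minimal and
  extensible.
* **Surrogate keys.** Every table gets an opaque surrogate `id`; DICOM
  study/series UIDs are stored only as ordinary attributes. This keeps
  de-identification airtight: record identity never leaks instance
  UIDs.
* **Donor anchoring.** MIABIS models age and sex as aggregate
  sub-entities of a collection, and the extended diagram keeps them
  there (DonorAge, DonorSex). A repository, however, needs donor *rows*
  to enforce referential closure and to export per-donor e-forms, so
  the registry adds a pseudonymous Donor entity. Both views are
  maintained at ingestion: donor rows anchor the records, aggregate
  rows describe the collection.
* **linkedEntities and the hub.** The neighbourhood query excludes the
  Collection macro-category when it is the specialization parent of the
  queried entity (so ImageCollection reports exactly its five imaging
  neighbours) but keeps every other parent (so RegistrationParameters
  reports its three scopes *and* ImageCollection).

## Controlled vocabularies

Three term lists are packaged, bound to their tags, and pinned: 116
Body Part Examined terms, 120 Dataset Type terms (SOP Class UID as code
value, its name as meaning — the standard leaves open whether "dataset
type" means the UID or the name, so both are accepted at validation),
and 54 Modality terms. External standard editions drift; the pinned
counts are treated as normative and asserted when the package loads, so
a tampered list fails fast. Matching is performed after normalization
(upper-case, trimmed, internal whitespace collapsed), which is
idempotent. Strict mode rejects non-conformant values at ingestion; the
permissive mode stores them flagged (`conformant = 0`), preserving the
distinction between *absent* (NULL) and *non-conformant* (flagged).

```{r}
c(vocabularySize("BODY_PART"), vocabularySize("DATASET_TYPE"),
  vocabularySize("MODALITY"))
lookupTerm("MODALITY", "CT")
```

## From graph to database

`generateDDL()` compiles the graph to one ANSI-compatible SQL script:
one table per entity with a surrogate primary key, a foreign key on the
many side of each 1:N edge, a unique foreign key per 1:1 edge, one
junction table (`source__target`) per N:M edge. Statements are ordered
topologically (referenced tables first) with lexicographic tie-breaks,
so output is byte-stable; an empty or invalid schema is an error, not an
empty script. `"sqlite"` is accepted as an alias dialect; anything else
is refused. The repository executes this script on SQLite — the catalog
then contains exactly `entities + N:M edges` tables (34 for the
integration model) — and every subsequent write is one transaction:
a rejected record leaves the store contents identical.

## The DICOM harvester

`harvestFile()` reads Part-10 files (explicit VR little endian) and
extracts only the mapped header tags; pixel data is detected and
skipped, never decoded. Body part resolution prefers tag (0018,0015)
and falls back to the code meaning inside the Anatomic Region Sequence
(0008,2218); precedence is this package's choice, as the standard only
states replaceability. If both are absent the field is NULL and
flagged. Age strings are floored to whole years (MIABIS donor age is
year-granular). `groupSeries()` emits one record per series UID,
requiring modality, dataset type, body part, study UID and donor fields
to be constant across slices (conflicts reject the series, with the
reason in the report) while numeric acquisition parameters may vary and
are summarized as first value plus min/max range. `phiScreen()` flags
populated name/birth-date fields and name-like or date-like content in
free-text fields; a record counts as de-identified only when that
report is empty, and strict-mode ingestion refuses records that are
not.

## The synthetic cohort

`cohortSpec()` defaults encode the study conditions the model was
designed against: 18 paediatric donors, one anonymised multislice CT
series each (4 slices here), ages drawn uniformly from 0–17 years,
body parts from {ABDOMEN, CHEST, ABDOMENPELVIS} — typical coverage for
neuroblastoma imaging — with tube voltage in {80, 100, 120} kV, slice
thickness in {1, 2, 2.5, 3, 5} mm, pixel spacing uniform in 0.4–0.8 mm,
reconstruction diameter uniform in 200–400 mm. Companion clinical
records carry diagnosis symptoms and neuroblastoma work-up laboratory
tests (LDH, ferritin, NSE, urinary HVA/VMA) from seeded uniform ranges.

What the generator emulates: header-level structure — coherent UIDs,
vocabulary-conformant coded fields, plausible parameter magnitudes,
absence of direct identifiers, several files per series. What it does
not: real anatomy (the pixel block is uniform and untested), realistic
clinical distributions (uniform draws carry no clinical claim),
scanner-specific tag dialects, or non-CT modalities beyond the header
level. Green tests therefore demonstrate that the pipeline preserves
and validates metadata faithfully, not that it has been exercised
against the variability of hospital PACS exports.

All draws are deterministic in the spec's seed (the clinical stream is
offset by one so the two generators are independently reproducible),
and generation restores the caller's RNG state.

## Numerical and degenerate-input choices

* Identifiers are time/counter-based, never RNG-based, so record ids do
  not perturb seeded simulations.
* An empty path list harvests to an empty, reconciled report; an empty
  cohort spec (0 patients) writes an empty manifest and no files.
* Query filters are conjunctive with set-membership semantics; the
  filterable field set is closed and unknown fields are errors, matching
  the "simple query processing" a catalogue promises — free SQL is
  deliberately not exposed.
* e-form serialization is canonical (stable key order, unboxed scalar
  leaves, arrays as lists, full numeric precision), which is what makes
  export → import → export byte-identical.
* Problem sizes in the test suite stay small (the 18-series default
  cohort, 10-slice series for grouping checks) — they match the study
  conditions and keep the suite fast.

## Known limitations

* The DICOM layer supports explicit VR little endian Part-10 files —
  enough for the fixture generator and for typical anonymised exports,
  but not compressed transfer syntaxes or implicit VR; foreign files in
  other syntaxes are rejected cleanly rather than misread.
* The vocabulary lists are curated from a single pinned edition of the
  standard's term tables; editions with different counts must be
  supplied as override files.
* The repository is single-writer/many-reader by contract; there is no
  multi-node deployment, authentication or consent management.
* MIABIS 3.0 entities, pixel-level processing and the computation of
  radiomic features themselves are out of scope: only their provenance
  is modeled.
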