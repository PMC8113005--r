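Package: dicomiabis
Title: DICOM-MIABIS Integration Schema and Repository for Imaging Biobanks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Executable form of an entity-relationship model that extends the
    MIABIS biobanking core (biobank, study, sample collection) to medical
    imaging: a schema engine with relationship cardinalities and SQL DDL
    generation, three pinned DICOM controlled vocabularies (Body Part
    Examined, Dataset Type, Modality), a DICOM Part-10 header harvester that
    maps series metadata into the model, provenance records for image
    analysis (preprocessing, segmentation, registration, imaging
    biomarkers), an embedded relational repository with unified queries and
    e-form export, and a seeded synthetic CT cohort generator so the whole
    stack is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    DBI,
    RSQLite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
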