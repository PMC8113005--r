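# Shared fixtures and independent oracles.

# Default synthetic cohort (generated once per test run, reused read-only).
.fixture_cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.fixture_cache$cohort)) {
    dir <- file.path(tempdir(), "dicomiabis-default-cohort")
    unlink(dir, recursive = TRUE)
    spec <- cohortSpec(seed = 1L)
    manifest <- generateCohort(spec, dir)
    .fixture_cache$cohort <- list(dir = dir, spec = spec,
                                  manifest = manifest)
  }
  .fixture_cache$cohort
}

cohort_paths <- function(dir) {
  sort(list.files(dir, pattern = "\\.dcm$", recursive = TRUE,
                  full.names = TRUE))
}

fresh_store <- function(schema = buildIntegrationModel(), ...) {
  loc <- tempfile(fileext = ".sqlite")
  store <- initStore(schema, loc, ...)
  withr::defer_parent({ closeStore(store); unlink(loc) })
  store
}

# Independent DDL oracle: count CREATE TABLE statements by text parsing.
count_create_tables <- function(script) {
  length(gregexpr("CREATE TABLE", script, fixed = TRUE)[[1]])
}

# Independent DDL oracle: rebuild the table graph (table names plus
# foreign-key edges referenced_table -> referencing_table) from the
# script text alone.
parse_ddl_graph <- function(script) {
  stmts <- strsplit(script, ";[[:space:]]*\n")[[1]]
  stmts <- stmts[grepl("CREATE TABLE", stmts)]
  tables <- sub(".*CREATE TABLE ([a-z0-9_]+) .*", "\\1",
                vapply(stmts, function(s) strsplit(s, "\n")[[1]][1],
                       character(1), USE.NAMES = FALSE))
  fks <- do.call(rbind, lapply(seq_along(stmts), function(i) {
    m <- regmatches(stmts[i],
                    gregexpr("FOREIGN KEY \\(([a-z0-9_]+)\\) REFERENCES ([a-z0-9_]+)",
                             stmts[i]))[[1]]
    if (!length(m)) return(NULL)
    data.frame(
      table = tables[i],
      column = sub("FOREIGN KEY \\(([a-z0-9_]+)\\).*", "\\1", m),
      ref = sub(".*REFERENCES ([a-z0-9_]+)$", "\\1", m),
      stringsAsFactors = FALSE)
  }))
  list(tables = tables, fks = fks)
}

# Execute a SQL script on an independent embedded engine (the system
# Python's sqlite3 module) and return the resulting catalog table names.
sqlite3_python_tables <- function(script) {
  sql <- tempfile(fileext = ".sql")
  writeLines(script, sql)
  py <- paste(
    "import sqlite3, sys, json",
    "con = sqlite3.connect(':memory:')",
    "con.executescript(open(sys.argv[1]).read())",
    "rows = con.execute(\"SELECT name FROM sqlite_master WHERE type='table'\").fetchall()",
    "print(json.dumps(sorted(r[0] for r in rows)))",
    sep = "; ")
  out <- system2("python", c("-c", shQuote(py), shQuote(sql)),
                 stdout = TRUE, stderr = TRUE)
  jsonlite::fromJSON(paste(out, collapse = ""))
}

# Read one DICOM file with pydicom (independent of the package reader).
pydicom_read <- function(path) {
  py <- paste(
    "import pydicom, sys, json",
    "ds = pydicom.dcmread(sys.argv[1])",
    paste0("print(json.dumps({'Modality': str(ds.Modality), ",
           "'BodyPartExamined': str(ds.get('BodyPartExamined', '')), ",
           "'SeriesInstanceUID': str(ds.SeriesInstanceUID), ",
           "'StudyInstanceUID': str(ds.StudyInstanceUID), ",
           "'SOPClassUID': str(ds.SOPClassUID), ",
           "'PatientID': str(ds.get('PatientID', '')), ",
           "'PatientAge': str(ds.get('PatientAge', '')), ",
           "'PatientSex': str(ds.get('PatientSex', '')), ",
           "'KVP': str(ds.get('KVP', '')), ",
           "'SliceThickness': str(ds.get('SliceThickness', ''))}))"),
    sep = "\n")
  out <- system2("python", c("-c", shQuote(py), shQuote(path)),
                 stdout = TRUE, stderr = TRUE)
  jsonlite::fromJSON(paste(out, collapse = ""))
}

# Minimal hand-built DICOM element set for crafted-input tests.
base_elements <- function(...) {
  modifyList(list(
    SOPClassUID = "1.2.840.10008.5.1.4.1.1.2",
    SOPInstanceUID = "1.2.826.0.1.3680043.10.424.99.1",
    Modality = "CT",
    BodyPartExamined = "ABDOMEN",
    PatientID = "DONOR_X",
    PatientSex = "F",
    PatientAge = "009Y",
    StudyInstanceUID = "1.2.826.0.1.3680043.10.424.99",
    SeriesInstanceUID = "1.2.826.0.1.3680043.10.424.99.2"),
    list(...))
}

# Full logical dump of a store, for atomicity comparisons.
store_dump <- function(store) {
  tabs <- sort(DBI::dbListTables(store@con))
  setNames(lapply(tabs, function(t)
    DBI::dbGetQuery(store@con,
                    sprintf("SELECT * FROM %s ORDER BY 1", t))), tabs)
}
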