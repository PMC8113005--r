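# e-form export/import: per-donor structured clinical documents with a
# diagnosis section (symptoms + laboratory tests) whenever clinical
# variables exist. Serialization is canonical so export -> import ->
# export is byte-identical.

#' Export a donor's e-form document
#'
#' Builds the structured e-form for one donor: a subject section
#' (identifier fields), a diagnosis section carrying the symptom fields
#' and a laboratory-tests subsection whenever the donor has a clinical
#' variable collection on record, and a collections section listing the
#' donor's collections by type. The provenance slot names every
#' collection the document was built from.
#'
#' @param store an integration-model [BiobankStore].
#' @param donorRef registered donor identifier; unknown donors raise an
#'   unknown-donor error.
#' @return an [EFormDocument].
#' @seealso [eformToJson()], [eformFromJson()]
#' @export
exportEform <- function(store, donorRef) {
  .require_integration(store)
  donor <- .q(store,
              "SELECT id, age_years, sex FROM donor WHERE id = ?",
              params = list(donorRef))
  if (!nrow(donor))
    .err("unknown_donor_error", sprintf("unknown donor '%s'", donorRef))
  cols <- .q(store, paste(
    "SELECT id, collection_type FROM collection WHERE donor_id = ?",
    "ORDER BY id"), params = list(donorRef))

  subject <- list(donor_ref = donor$id[1])
  if (!is.na(donor$age_years[1]))
    subject$age_years <- as.integer(donor$age_years[1])
  if (!is.na(donor$sex[1])) subject$sex <- donor$sex[1]
  sections <- list(subject = subject)

  clin <- .q(store, paste(
    "SELECT cvc.variables AS v FROM clinical_variable_collection cvc",
    "JOIN collection c ON cvc.collection_id = c.id",
    "WHERE c.donor_id = ? ORDER BY c.id"), params = list(donorRef))
  if (nrow(clin)) {
    vars <- .unjson(clin$v[1])
    diagnosis <- list()
    diagnosis$symptoms <- vars$symptoms %||% list()
    extra <- vars[setdiff(names(vars), c("symptoms", "laboratory_tests"))]
    diagnosis <- c(diagnosis, extra)
    diagnosis$laboratory_tests <- vars$laboratory_tests %||% list()
    sections$diagnosis <- diagnosis
  }

  if (nrow(cols)) {
    by_type <- split(cols$id, cols$collection_type)
    sections$collections <-
      lapply(by_type[order(names(by_type))], as.list)
  }

  new("EFormDocument", sections = sections,
      provenance = as.list(sort(cols$id)))
}

#' Serialize an e-form document to JSON
#'
#' The serialization is canonical (stable key order, scalar leaves
#' unboxed, full numeric precision), which makes
#' `eformToJson(eformFromJson(x))` reproduce `x` byte for byte.
#'
#' @param doc an [EFormDocument].
#' @return a JSON string.
#' @export
eformToJson <- function(doc) {
  as.character(jsonlite::toJSON(
    list(sections = doc@sections, provenance = doc@provenance),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null"))
}

#' Parse an e-form document from JSON
#'
#' @param json a string produced by [eformToJson()] (or the same
#'   structured-document format from an external system).
#' @return an [EFormDocument].
#' @export
eformFromJson <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  new("EFormDocument", sections = x$sections %||% list(),
      provenance = x$provenance %||% list())
}

setMethod("show", "EFormDocument", function(object) {
  cat(sprintf("EFormDocument: sections [%s], %d provenance ref(s)\n",
              paste(names(object@sections), collapse = ", "),
              length(object@provenance)))
})
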