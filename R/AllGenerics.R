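# Generics. Accessors are preferred over direct slot access throughout.

#' @rdname SchemaGraph-class
#' @param x,object a [SchemaGraph].
#' @export
setGeneric("entityNames", function(x) standardGeneric("entityNames"))

#' @rdname SchemaGraph-class
#' @export
setGeneric("schemaEntities", function(x) standardGeneric("schemaEntities"))

#' @rdname SchemaGraph-class
#' @export
setGeneric("schemaRelationships",
           function(x) standardGeneric("schemaRelationships"))

#' @rdname validateSchema
#' @export
setGeneric("validateSchema", function(schema) standardGeneric("validateSchema"))

#' @rdname linkedEntities
#' @export
setGeneric("linkedEntities",
           function(schema, entity) standardGeneric("linkedEntities"))

#' @rdname generateDDL
#' @export
setGeneric("generateDDL", function(schema, dialect = "ansi")
  standardGeneric("generateDDL"))

#' @rdname ValidationReport-class
#' @param x a [ValidationReport].
#' @export
setGeneric("isValid", function(x) standardGeneric("isValid"))

#' @rdname ValidationReport-class
#' @export
setGeneric("violations", function(x) standardGeneric("violations"))

#' @rdname phiScreen
#' @export
setGeneric("phiScreen", function(record) standardGeneric("phiScreen"))

#' @rdname attachAnalysis
#' @export
setGeneric("attachAnalysis",
           function(provenance, store) standardGeneric("attachAnalysis"))

#' @rdname ingest
#' @export
setGeneric("ingest", function(store, record) standardGeneric("ingest"))

#' @rdname generateCohort
#' @export
setGeneric("generateCohort",
           function(spec, outDir) standardGeneric("generateCohort"))

#' @rdname generateClinical
#' @export
setGeneric("generateClinical",
           function(spec, out = NULL) standardGeneric("generateClinical"))
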