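# Schema engine: registry reader, the two model builders, graph queries
# and invariant validation.

.registry_path <- function(file) {
  system.file("extdata", "registry", file, package = "dicomiabis",
              mustWork = TRUE)
}

.as_attr_df <- function(attrs) {
  data.frame(
    name = vapply(attrs, function(a) as.character(a$name), character(1)),
    domain = vapply(attrs, function(a) as.character(a$domain), character(1)),
    nullable = vapply(attrs, function(a) isTRUE(a$nullable), logical(1)),
    stringsAsFactors = FALSE)
}

#' Read a schema registry file
#'
#' Parses a declarative YAML registry (entities with attributes and
#' stereotypes, relationships with cardinalities) into a [SchemaGraph].
#' The two packaged registries drive [buildMiabisCore()] and
#' [buildIntegrationModel()]; user-supplied registries in the same format
#' are accepted, which is how attribute inventories are extended without
#' code changes.
#'
#' @param path path to a registry YAML file.
#' @return a [SchemaGraph].
#' @seealso [validateSchema()]
#' @export
readSchemaRegistry <- function(path) {
  .stopifnot_scalar_chr(path, "path")
  reg <- yaml::read_yaml(path)
  ents <- lapply(reg$entities, function(e) {
    new("EntityDef", name = e$name, stereotype = e$stereotype,
        attributes = .as_attr_df(e$attributes))
  })
  names(ents) <- vapply(ents, function(e) e@name, character(1))
  rels <- if (length(reg$relationships)) {
    do.call(rbind, lapply(reg$relationships, function(r) {
      data.frame(source = r$source, target = r$target,
                 cardinality = r$cardinality, label = r$label,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(source = character(), target = character(),
               cardinality = character(), label = character(),
               stringsAsFactors = FALSE)
  }
  new("SchemaGraph", model = as.character(reg$model),
      hub = as.character(reg$hub %||% NA_character_),
      entities = ents, relationships = rels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the MIABIS core schema
#'
#' Returns the entity-relationship graph of the MIABIS 2.0 core: the three
#' main components Biobank, Study and SampleCollection on which the other
#' entities depend, plus the donor-age, donor-sex, material-type and
#' storage-temperature sub-entities attached to the sample collection,
#' with 1:1 / 1:N / N:M cardinalities on every edge.
#'
#' @return a valid [SchemaGraph].
#' @examples
#' core <- buildMiabisCore()
#' entityNames(core)
#' @export
buildMiabisCore <- function() {
  readSchemaRegistry(.registry_path("miabis_core.yaml"))
}

#' Build the DICOM-MIABIS integration schema
#'
#' Returns the extended model in which the generic Collection
#' macro-category replaces SampleCollection as hub, carries the five
#' sub-collection types (image, sample tissue, clinical variable,
#' molecular biomarker, software/source code), and ImageCollection is
#' expanded with the five directly-linked imaging entities and the
#' image-analysis branch (preprocessing, segmentation with its three
#' modality specializations, imaging biomarkers with three feature
#' classes, registration with three scopes). Tissue-specific descriptors
#' attach only to the sample-tissue sub-collection; donor-level
#' descriptors attach to Collection. Deterministic: repeated calls return
#' identical graphs.
#'
#' @return a valid [SchemaGraph].
#' @examples
#' ig <- buildIntegrationModel()
#' linkedEntities(ig, "ImageCollection")
#' @export
buildIntegrationModel <- function() {
  readSchemaRegistry(.registry_path("integration_model.yaml"))
}

# ---- accessors ---------------------------------------------------------

#' @rdname SchemaGraph-class
#' @export
setMethod("entityNames", "SchemaGraph", function(x) names(x@entities))

#' @rdname SchemaGraph-class
#' @export
setMethod("schemaEntities", "SchemaGraph", function(x) x@entities)

#' @rdname SchemaGraph-class
#' @export
setMethod("schemaRelationships", "SchemaGraph",
          function(x) x@relationships)

setMethod("show", "SchemaGraph", function(object) {
  cat(sprintf("SchemaGraph '%s': %d entities, %d relationships (hub: %s)\n",
              object@model, length(object@entities),
              nrow(object@relationships), object@hub))
  st <- table(vapply(object@entities, function(e) e@stereotype, character(1)))
  cat("  stereotypes:",
      paste(sprintf("%s=%d", names(st), as.integer(st)), collapse = ", "),
      "\n")
})

setMethod("show", "EntityDef", function(object) {
  cat(sprintf("EntityDef '%s' (%s), %d attributes: %s\n", object@name,
              object@stereotype, nrow(object@attributes),
              paste(object@attributes$name, collapse = ", ")))
})

# ---- graph queries -----------------------------------------------------

#' Entities directly linked to a named entity
#'
#' Returns the set of entities that share a direct relationship (in either
#' direction) with `entity`. The hub macro-category (Collection, or
#' SampleCollection in the core model) is excluded when it is the
#' specialization parent of `entity`, so that e.g. the entities linked to
#' ImageCollection are exactly its five imaging/analysis neighbours.
#'
#' @param schema a [SchemaGraph].
#' @param entity entity name; unknown names raise an unknown-entity error.
#' @return character vector of entity names (sorted, possibly empty).
#' @examples
#' linkedEntities(buildIntegrationModel(), "Segmentation")
#' @rdname linkedEntities
#' @export
setMethod("linkedEntities", "SchemaGraph", function(schema, entity) {
  .stopifnot_scalar_chr(entity, "entity")
  if (!entity %in% entityNames(schema))
    .err("unknown_entity_error",
         sprintf("entity '%s' is not in schema '%s'", entity, schema@model))
  r <- schema@relationships
  nb <- c(r$target[r$source == entity], r$source[r$target == entity])
  hub <- schema@hub
  if (!is.na(hub) && !identical(entity, hub)) {
    # drop the hub only when it is the directed parent of this entity
    parent_edge <- any(r$source == hub & r$target == entity)
    if (parent_edge) nb <- setdiff(nb, hub)
  }
  sort(unique(nb))
})

# ---- validation --------------------------------------------------------

.report <- function(subject, rule = character(), detail = character()) {
  new("ValidationReport", subject = subject,
      violations = data.frame(rule = rule, detail = detail,
                              stringsAsFactors = FALSE))
}

#' @rdname ValidationReport-class
#' @export
setMethod("isValid", "ValidationReport",
          function(x) nrow(x@violations) == 0L)

#' @rdname ValidationReport-class
#' @export
setMethod("violations", "ValidationReport", function(x) x@violations)

setMethod("show", "ValidationReport", function(object) {
  if (isValid(object)) {
    cat(sprintf("ValidationReport for %s: no violations\n", object@subject))
  } else {
    cat(sprintf("ValidationReport for %s: %d violation(s)\n",
                object@subject, nrow(object@violations)))
    print(object@violations)
  }
})

#' Validate a schema graph
#'
#' Checks every graph-level invariant and reports all violations (nothing
#' is raised): duplicate entity names, entities without attributes,
#' duplicate attribute names, relationships with dangling endpoints or
#' self-loops, duplicate (source, target, label) triples, cardinalities
#' outside the 1:1 / 1:N / N:M legend, coded attribute domains referencing
#' unregistered vocabularies, and disconnection of the graph. An empty
#' report means the schema is valid.
#'
#' @param schema a [SchemaGraph].
#' @return a [ValidationReport]; use [isValid()] / [violations()].
#' @rdname validateSchema
#' @export
setMethod("validateSchema", "SchemaGraph", function(schema) {
  rule <- character(); detail <- character()
  add <- function(r, d) {
    rule <<- c(rule, r); detail <<- c(detail, d)
  }
  nms <- vapply(schema@entities, function(e) e@name, character(1))
  for (d in unique(nms[duplicated(nms)]))
    add("duplicate_name", sprintf("entity '%s' defined more than once", d))
  keyed <- names(schema@entities)
  if (!is.null(keyed))
    for (d in unique(keyed[duplicated(keyed)]))
      if (!d %in% nms[duplicated(nms)])
        add("duplicate_name", sprintf("entity '%s' defined more than once", d))
  for (e in schema@entities) {
    v <- validObject(e, test = TRUE)
    if (!isTRUE(v))
      for (m in v) add("invalid_entity", sprintf("%s: %s", e@name, m))
    coded <- grep("^coded\\(", e@attributes$domain, value = TRUE)
    for (cd in coded) {
      vid <- sub("^coded\\(([A-Z_]+)\\)$", "\\1", cd)
      if (!vid %in% .vocab_ids())
        add("unknown_vocabulary",
            sprintf("%s: coded domain references unregistered '%s'",
                    e@name, vid))
    }
  }
  r <- schema@relationships
  if (nrow(r)) {
    for (i in seq_len(nrow(r))) {
      if (!r$source[i] %in% nms)
        add("dangling_endpoint",
            sprintf("relationship '%s' has unknown source '%s'",
                    r$label[i], r$source[i]))
      if (!r$target[i] %in% nms)
        add("dangling_endpoint",
            sprintf("relationship '%s' has unknown target '%s'",
                    r$label[i], r$target[i]))
      if (identical(r$source[i], r$target[i]))
        add("self_loop", sprintf("self-loop on '%s'", r$source[i]))
      if (!r$cardinality[i] %in% CARDINALITIES)
        add("invalid_cardinality",
            sprintf("'%s': cardinality '%s' outside the 1:1/1:N/N:M legend",
                    r$label[i], r$cardinality[i]))
    }
    key <- paste(r$source, r$target, r$label)
    for (d in unique(key[duplicated(key)]))
      add("duplicate_relationship", sprintf("duplicate edge (%s)", d))
  }
  # connectivity over the undirected graph (singleton graphs are connected)
  if (length(nms) > 1L) {
    adj <- unique(rbind(
      r[r$source %in% nms & r$target %in% nms, c("source", "target")],
      setNames(r[r$source %in% nms & r$target %in% nms,
                 c("target", "source")], c("source", "target"))))
    seen <- nms[1]
    frontier <- nms[1]
    while (length(frontier)) {
      nxt <- setdiff(adj$target[adj$source %in% frontier], seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    for (orphan in setdiff(nms, seen))
      add("disconnected", sprintf("entity '%s' unreachable", orphan))
  }
  .report(sprintf("schema '%s'", schema@model), rule, detail)
})
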