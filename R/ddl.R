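# Relational DDL generation: one table per entity with a surrogate
# primary key, foreign keys on the many-side of 1:N edges, unique foreign
# keys for 1:1 edges, and one junction table per N:M edge. Statement order
# is deterministic (topological on FK dependencies, then lexicographic) so
# output is byte-stable.

.SQL_TYPES <- c(text = "TEXT", integer = "INTEGER", real = "REAL",
                date = "DATE")

.sql_type <- function(domain) {
  if (grepl("^coded\\(", domain)) "TEXT" else .SQL_TYPES[[domain]]
}

# The relational plan behind both the DDL emitter and the repository:
# entity tables (with their FK columns) in deterministic order, then
# junction tables.
.table_plan <- function(schema) {
  r <- schema@relationships
  nms <- entityNames(schema)
  one_edges <- r[r$cardinality %in% c("ONE_TO_ONE", "ONE_TO_MANY"), ,
                 drop = FALSE]
  nm_edges <- r[r$cardinality == "MANY_TO_MANY", , drop = FALSE]

  # Kahn topological order on "referenced table first", lexicographic
  # tie-break.
  deps <- split(one_edges$source, one_edges$target)
  order <- character()
  remaining <- sort(nms)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(n) {
      length(setdiff(intersect(deps[[n]], nms), order)) == 0L
    }, logical(1))]
    if (!length(ready)) { # cycle: fall back to lexicographic for the rest
      ready <- remaining
    }
    order <- c(order, ready[1])
    remaining <- setdiff(remaining, ready[1])
  }

  tables <- lapply(order, function(nm) {
    e <- schema@entities[[nm]]
    in_edges <- one_edges[one_edges$target == nm, , drop = FALSE]
    fk <- if (nrow(in_edges)) {
      col <- paste0(.snake(in_edges$source), "_id")
      if (anyDuplicated(col))
        col <- ifelse(duplicated(col) | duplicated(col, fromLast = TRUE),
                      paste0(.snake(in_edges$source), "_",
                             in_edges$label, "_id"), col)
      data.frame(column = col, ref_table = .snake(in_edges$source),
                 unique = in_edges$cardinality == "ONE_TO_ONE",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(column = character(), ref_table = character(),
                 unique = logical(), stringsAsFactors = FALSE)
    }
    list(name = .snake(nm), entity = nm, attributes = e@attributes, fk = fk)
  })

  junctions <- if (nrow(nm_edges)) {
    nm_edges <- nm_edges[order(nm_edges$source, nm_edges$target,
                               nm_edges$label), , drop = FALSE]
    lapply(seq_len(nrow(nm_edges)), function(i) {
      list(name = paste0(.snake(nm_edges$source[i]), "__",
                         .snake(nm_edges$target[i])),
           left = .snake(nm_edges$source[i]),
           right = .snake(nm_edges$target[i]))
    })
  } else list()

  list(tables = tables, junctions = junctions)
}

.plan_table_names <- function(plan) {
  c(vapply(plan$tables, `[[`, character(1), "name"),
    vapply(plan$junctions, `[[`, character(1), "name"))
}

#' Generate SQL DDL for a schema
#'
#' Emits a plain-text SQL script realising the entity-relationship graph:
#' one `CREATE TABLE` per entity with a surrogate `id TEXT` primary key, a
#' foreign key on the many-side of every one-to-many relationship, a
#' unique foreign key for every one-to-one relationship, and one junction
#' table (named `source__target`) per many-to-many relationship. Entity
#' names map to snake_case table names; statements are ordered
#' topologically (referenced tables first), then lexicographically, so the
#' script is byte-stable and executes in order on an embedded relational
#' engine such as SQLite.
#'
#' @param schema a [SchemaGraph] that passes [validateSchema()].
#' @param dialect `"ansi"` (default) or its alias `"sqlite"`; anything
#'   else raises an unsupported-dialect error.
#' @return the DDL script as a single character string (UTF-8).
#' @examples
#' cat(substr(generateDDL(buildMiabisCore()), 1, 200))
#' @rdname generateDDL
#' @export
setMethod("generateDDL", "SchemaGraph", function(schema, dialect = "ansi") {
  if (!dialect %in% c("ansi", "sqlite"))
    .err("unsupported_dialect_error",
         sprintf("unsupported DDL dialect '%s'", dialect))
  if (!length(schema@entities))
    .err("invalid_schema_error", "cannot generate DDL for an empty schema")
  rep <- validateSchema(schema)
  if (!isValid(rep))
    .err("invalid_schema_error",
         sprintf("schema '%s' fails validation (%d violation(s)): %s",
                 schema@model, nrow(violations(rep)),
                 paste(head(violations(rep)$detail, 3), collapse = "; ")))
  plan <- .table_plan(schema)

  stmt_entity <- function(tb) {
    cols <- c("  id TEXT NOT NULL",
              sprintf("  %s %s%s", tb$attributes$name,
                      vapply(tb$attributes$domain, .sql_type, character(1)),
                      ifelse(tb$attributes$nullable, "", " NOT NULL")))
    if (nrow(tb$fk))
      cols <- c(cols, sprintf("  %s TEXT", tb$fk$column))
    constraints <- "  PRIMARY KEY (id)"
    if (nrow(tb$fk)) {
      uq <- tb$fk$column[tb$fk$unique]
      if (length(uq))
        constraints <- c(constraints, sprintf("  UNIQUE (%s)", uq))
      constraints <- c(constraints,
                       sprintf("  FOREIGN KEY (%s) REFERENCES %s (id)",
                               tb$fk$column, tb$fk$ref_table))
    }
    sprintf("CREATE TABLE %s (\n%s\n);", tb$name,
            paste(c(cols, constraints), collapse = ",\n"))
  }

  stmt_junction <- function(j) {
    lcol <- paste0(j$left, "_id")
    rcol <- paste0(j$right, "_id")
    sprintf(paste0(
      "CREATE TABLE %s (\n  %s TEXT NOT NULL,\n  %s TEXT NOT NULL,\n",
      "  PRIMARY KEY (%s, %s),\n",
      "  FOREIGN KEY (%s) REFERENCES %s (id),\n",
      "  FOREIGN KEY (%s) REFERENCES %s (id)\n);"),
      j$name, lcol, rcol, lcol, rcol, lcol, j$left, rcol, j$right)
  }

  stmts <- c(vapply(plan$tables, stmt_entity, character(1)),
             vapply(plan$junctions, stmt_junction, character(1)))
  paste0(paste(stmts, collapse = "\n\n"), "\n")
})
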