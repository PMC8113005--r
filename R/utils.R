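# Internal helpers: structured errors, identifier generation, seeded RNG.

# All package errors are errorCondition objects whose class vector carries a
# machine-readable category, so callers (and the CLI) can branch on
# condition class instead of matching message text.
.err <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "dicomiabis_error", "error")))
}

.is_err <- function(e, class) inherits(e, class)

#' Normalize a vocabulary token
#'
#' Case-folds to upper case, strips surrounding whitespace and collapses
#' internal whitespace runs, the conventional form of DICOM code strings.
#' The transformation is idempotent.
#'
#' @param x character vector of raw values.
#' @return character vector of normalized values.
#' @examples
#' normalizeTerm("  ct ")
#' @export
normalizeTerm <- function(x) {
  x <- toupper(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# Opaque surrogate identifier (UUID-style, RNG-independent so that record
# ids never perturb seeded simulations).
.uuid_counter <- new.env(parent = emptyenv())
.uuid_counter$n <- 0L

.new_id <- function(prefix = "id") {
  .uuid_counter$n <- .uuid_counter$n + 1L
  sprintf("%s-%s-%05x-%06x", prefix,
          format(Sys.time(), "%Y%m%d%H%M%S"),
          Sys.getpid() %% 0xfffff,
          .uuid_counter$n)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# snake_case table name from a CamelCase entity name.
.snake <- function(x) {
  s <- gsub("([a-z0-9])([A-Z])", "\\1_\\2", x)
  s <- gsub("([A-Z]+)([A-Z][a-z])", "\\1_\\2", s)
  tolower(s)
}

.stopifnot_scalar_chr <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    .err("usage_error", sprintf("%s must be a non-empty string", what))
  invisible(x)
}
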