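# Controlled vocabularies: the three pinned DICOM term lists bound to the
# imaging entities, loaded once per session and size-asserted at load.

.vocab_env <- new.env(parent = emptyenv())

.VOCAB_SPEC <- list(
  BODY_PART = list(file = "body_part_examined.tsv", size = 116L),
  DATASET_TYPE = list(file = "dataset_type.tsv", size = 120L),
  MODALITY = list(file = "modality.tsv", size = 54L))

.vocab_ids <- function() names(.VOCAB_SPEC)

.read_term_file <- function(path, vocabulary_id) {
  hdr <- readLines(path, n = 10L)
  meta <- grep("^#", hdr, value = TRUE)
  pick <- function(key) {
    ln <- grep(sprintf("^# %s:", key), meta, value = TRUE)
    if (length(ln)) trimws(sub(sprintf("^# %s:", key), "", ln[1])) else ""
  }
  terms <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                      colClasses = "character")
  new("TermList", vocabularyId = vocabulary_id, dicomTag = pick("dicom_tag"),
      editionNote = pick("edition"), terms = terms)
}

# Loads (or reloads) the packaged vocabularies. The paper-pinned sizes are
# normative: a modified file fails fast here, at package initialization.
.load_vocabularies <- function(dir = system.file("extdata", "vocab",
                                                 package = "dicomiabis")) {
  for (vid in .vocab_ids()) {
    spec <- .VOCAB_SPEC[[vid]]
    tl <- .read_term_file(file.path(dir, spec$file), vid)
    validObject(tl)
    if (nrow(tl@terms) != spec$size)
      stop(sprintf(
        "vocabulary %s: packaged list has %d terms, expected exactly %d",
        vid, nrow(tl@terms), spec$size), call. = FALSE)
    assign(vid, tl, envir = .vocab_env)
  }
  invisible(TRUE)
}

.vocab_get <- function(vocabulary_id) {
  .stopifnot_scalar_chr(vocabulary_id, "vocabulary_id")
  if (!exists(vocabulary_id, envir = .vocab_env, inherits = FALSE)) {
    if (!vocabulary_id %in% .vocab_ids())
      .err("unknown_vocabulary_error",
           sprintf("unknown vocabulary '%s'", vocabulary_id))
    .load_vocabularies()
  }
  get(vocabulary_id, envir = .vocab_env, inherits = FALSE)
}

#' Retrieve a packaged controlled vocabulary
#'
#' @param vocabulary_id `"BODY_PART"`, `"DATASET_TYPE"` or `"MODALITY"`.
#' @return the [TermList]; its `dicomTag` slot names the DICOM tag the
#'   vocabulary is bound to ((0018,0015), (0008,0016), (0008,0060)).
#' @export
termList <- function(vocabulary_id) .vocab_get(vocabulary_id)

#' Number of terms in a vocabulary
#'
#' The packaged lists are pinned to a single standard edition and carry
#' exactly 116 (Body Part Examined), 120 (Dataset Type) and 54 (Modality)
#' terms; these counts are asserted when the lists are loaded.
#'
#' @inheritParams termList
#' @return integer count of distinct terms.
#' @examples
#' vocabularySize("MODALITY")
#' @export
vocabularySize <- function(vocabulary_id) {
  length(unique(.vocab_get(vocabulary_id)@terms$code_value))
}

#' Validate a value against a vocabulary
#'
#' A value conforms when its normalized form (see [normalizeTerm()])
#' matches either a packaged code value or a packaged meaning.
#'
#' @inheritParams termList
#' @param value character value to check.
#' @return `TRUE` or `FALSE`.
#' @examples
#' validateValue("MODALITY", "CT")
#' @export
validateValue <- function(vocabulary_id, value) {
  tl <- .vocab_get(vocabulary_id)
  if (length(value) != 1L || is.na(value)) return(FALSE)
  v <- normalizeTerm(value)
  nzchar(v) && (v %in% normalizeTerm(tl@terms$code_value) ||
                  v %in% normalizeTerm(tl@terms$meaning))
}

#' Look up a term by code value
#'
#' @inheritParams termList
#' @param code_value the code to resolve (normalized before matching).
#' @return a one-row data.frame with `code_value` and `meaning`.
#' @examples
#' lookupTerm("MODALITY", "CT")
#' @export
lookupTerm <- function(vocabulary_id, code_value) {
  tl <- .vocab_get(vocabulary_id)
  v <- normalizeTerm(code_value)
  hit <- which(normalizeTerm(tl@terms$code_value) == v)
  if (!length(v) || is.na(v) || !nzchar(v) || !length(hit))
    .err("term_not_found_error",
         sprintf("no term with code '%s' in vocabulary %s",
                 as.character(code_value), vocabulary_id))
  tl@terms[hit[1], , drop = FALSE]
}

# Resolve a free-text meaning back to its code value, or NA.
.meaning_to_code <- function(vocabulary_id, meaning) {
  tl <- .vocab_get(vocabulary_id)
  hit <- which(normalizeTerm(tl@terms$meaning) == normalizeTerm(meaning))
  if (length(hit)) tl@terms$code_value[hit[1]] else NA_character_
}

setMethod("show", "TermList", function(object) {
  cat(sprintf("TermList %s: %d terms, DICOM tag %s\n  %s\n",
              object@vocabularyId, nrow(object@terms), object@dicomTag,
              object@editionNote))
})
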