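# Minimal DICOM Part-10 I/O: explicit VR little endian only, header
# metadata plus a minimal pixel block. Covers exactly what the harvester
# and the fixture generator need; it is not a general DICOM toolkit.

TRANSFER_SYNTAX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.IMPLEMENTATION_CLASS_UID <- "1.2.826.0.1.3680043.10.424.1"

# keyword -> (group, element, VR) for every tag the model maps
.DICOM_DICT <- local({
  d <- rbind(
    c("SOPClassUID",              0x0008, 0x0016, "UI"),
    c("SOPInstanceUID",           0x0008, 0x0018, "UI"),
    c("StudyDate",                0x0008, 0x0020, "DA"),
    c("Modality",                 0x0008, 0x0060, "CS"),
    c("Manufacturer",             0x0008, 0x0070, "LO"),
    c("ManufacturerModelName",    0x0008, 0x1090, "LO"),
    c("CodeValue",                0x0008, 0x0100, "SH"),
    c("CodingSchemeDesignator",   0x0008, 0x0102, "SH"),
    c("CodeMeaning",              0x0008, 0x0104, "LO"),
    c("AnatomicRegionSequence",   0x0008, 0x2218, "SQ"),
    c("PatientName",              0x0010, 0x0010, "PN"),
    c("PatientID",                0x0010, 0x0020, "LO"),
    c("PatientBirthDate",         0x0010, 0x0030, "DA"),
    c("PatientSex",               0x0010, 0x0040, "CS"),
    c("PatientAge",               0x0010, 0x1010, "AS"),
    c("BodyPartExamined",         0x0018, 0x0015, "CS"),
    c("SliceThickness",           0x0018, 0x0050, "DS"),
    c("KVP",                      0x0018, 0x0060, "DS"),
    c("ReconstructionDiameter",   0x0018, 0x1100, "DS"),
    c("ExposureTime",             0x0018, 0x1150, "IS"),
    c("ConvolutionKernel",        0x0018, 0x1210, "SH"),
    c("StudyInstanceUID",         0x0020, 0x000D, "UI"),
    c("SeriesInstanceUID",        0x0020, 0x000E, "UI"),
    c("InstanceNumber",           0x0020, 0x0013, "IS"),
    c("SamplesPerPixel",          0x0028, 0x0002, "US"),
    c("PhotometricInterpretation", 0x0028, 0x0004, "CS"),
    c("Rows",                     0x0028, 0x0010, "US"),
    c("Columns",                  0x0028, 0x0011, "US"),
    c("PixelSpacing",             0x0028, 0x0030, "DS"),
    c("BitsAllocated",            0x0028, 0x0100, "US"),
    c("BitsStored",               0x0028, 0x0101, "US"),
    c("HighBit",                  0x0028, 0x0102, "US"),
    c("PixelRepresentation",      0x0028, 0x0103, "US"),
    c("PixelData",                0x7FE0, 0x0010, "OW"))
  data.frame(keyword = d[, 1], group = as.integer(d[, 2]),
             element = as.integer(d[, 3]),
             vr = d[, 4], stringsAsFactors = FALSE)
})

.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.STRING_VRS <- c("UI", "CS", "LO", "SH", "PN", "DA", "TM", "AS", "IS",
                 "DS", "LT", "ST", "UT")

.dict_row <- function(keyword) {
  i <- match(keyword, .DICOM_DICT$keyword)
  if (is.na(i)) .err("usage_error",
                     sprintf("tag keyword '%s' not in the mapped set", keyword))
  .DICOM_DICT[i, ]
}

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                             endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                             endian = "little")

.enc_value <- function(vr, value) {
  if (vr %in% .STRING_VRS) {
    s <- paste(as.character(value), collapse = "\\")
    b <- charToRaw(enc2utf8(s))
    if (length(b) %% 2L == 1L)
      b <- c(b, if (vr == "UI") as.raw(0L) else charToRaw(" "))
    b
  } else if (vr == "US") {
    .u16(value)
  } else if (vr == "UL") {
    .u32(value)
  } else if (vr %in% c("OB", "OW")) {
    b <- if (is.raw(value)) value
    else writeBin(as.integer(value), raw(), size = 2, endian = "little")
    if (length(b) %% 2L == 1L) b <- c(b, as.raw(0L))
    b
  } else {
    .err("usage_error", sprintf("cannot encode VR '%s'", vr))
  }
}

.enc_element <- function(group, element, vr, value) {
  body <- if (vr == "SQ") {
    # defined-length sequence of defined-length items
    items <- lapply(value, function(item) {
      content <- .enc_dataset(item)
      c(.u16(0xFFFE), .u16(0xE000), .u32(length(content)), content)
    })
    do.call(c, c(list(raw(0)), items))
  } else {
    .enc_value(vr, value)
  }
  hdr <- c(.u16(group), .u16(element), charToRaw(vr))
  if (vr %in% .LONG_VRS) {
    c(hdr, raw(2), .u32(length(body)), body)
  } else {
    c(hdr, .u16(length(body)), body)
  }
}

# encode a named list of keyword -> value, in ascending tag order
.enc_dataset <- function(elements) {
  kws <- names(elements)
  rows <- lapply(kws, .dict_row)
  ord <- order(vapply(rows, function(r) r$group * 65536 + r$element,
                      numeric(1)))
  out <- lapply(ord, function(i) {
    r <- rows[[i]]
    .enc_element(r$group, r$element, r$vr, elements[[i]])
  })
  do.call(c, c(list(raw(0)), out))
}

#' Write a DICOM Part-10 file
#'
#' Serializes a named list of mapped tag keywords to a standard-conformant
#' Part-10 file (128-byte preamble, `DICM` magic, file meta group,
#' explicit VR little endian dataset). Values must use the keywords of the
#' internal tag dictionary (the tags the integration model maps); the
#' Anatomic Region Sequence is given as a list of item lists with
#' `CodeValue`, `CodingSchemeDesignator` and `CodeMeaning`.
#'
#' @param path output file path.
#' @param elements named list of keyword -> value. `SOPClassUID` and
#'   `SOPInstanceUID` are required (they feed the file meta header).
#' @param pixel `TRUE` to append a minimal uniform 8x8 16-bit pixel block
#'   (with its image-pixel description tags) so readers accept the file as
#'   an image; its content is arbitrary.
#' @return `path`, invisibly.
#' @seealso [readDicomFile()]
#' @export
writeDicomFile <- function(path, elements, pixel = TRUE) {
  for (req in c("SOPClassUID", "SOPInstanceUID"))
    if (is.null(elements[[req]]))
      .err("usage_error", sprintf("writeDicomFile: %s is required", req))
  if (pixel && is.null(elements$PixelData)) {
    elements <- modifyList(elements, list(
      SamplesPerPixel = 1L, PhotometricInterpretation = "MONOCHROME2",
      Rows = 8L, Columns = 8L, BitsAllocated = 16L, BitsStored = 16L,
      HighBit = 15L, PixelRepresentation = 0L,
      PixelData = rep(100L, 64L)))
  }
  meta <- c(
    .enc_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    .enc_element(0x0002, 0x0002, "UI", elements$SOPClassUID),
    .enc_element(0x0002, 0x0003, "UI", elements$SOPInstanceUID),
    .enc_element(0x0002, 0x0010, "UI", TRANSFER_SYNTAX_EXPLICIT_LE),
    .enc_element(0x0002, 0x0012, "UI", .IMPLEMENTATION_CLASS_UID))
  bytes <- c(raw(128), charToRaw("DICM"),
             .enc_element(0x0002, 0x0000, "UL", length(meta)),
             meta, .enc_dataset(elements))
  writeBin(bytes, path)
  invisible(path)
}

# ---- reading -----------------------------------------------------------

.reader <- function(bytes) {
  env <- new.env(parent = emptyenv())
  env$b <- bytes
  env$pos <- 1L
  env$n <- length(bytes)
  env
}

.take <- function(rd, k) {
  if (rd$pos + k - 1L > rd$n)
    .err("invalid_format_error", "truncated DICOM stream")
  out <- rd$b[rd$pos:(rd$pos + k - 1L)]
  rd$pos <- rd$pos + k
  out
}

.rd_u16 <- function(rd) readBin(.take(rd, 2L), "integer", size = 2,
                                signed = FALSE, endian = "little")
.rd_u32 <- function(rd) {
  v <- readBin(.take(rd, 4L), "integer", size = 4, endian = "little")
  if (v < 0) -1L else v # -1 marks undefined length 0xFFFFFFFF
}

.dec_value <- function(vr, body) {
  if (vr %in% .STRING_VRS) {
    s <- rawToChar(body[body != as.raw(0)])
    s <- sub("[ ]+$", "", s)
    v <- strsplit(s, "\\", fixed = TRUE)[[1]]
    if (!length(v)) "" else v
  } else if (vr == "US") {
    readBin(body, "integer", size = 2, signed = FALSE, endian = "little",
            n = length(body) %/% 2L)
  } else if (vr == "UL") {
    readBin(body, "integer", size = 4, endian = "little",
            n = length(body) %/% 4L)
  } else {
    body
  }
}

# parse one dataset until `end` byte position (or a delimiter tag);
# returns a named list keyed by dictionary keyword
.parse_dataset <- function(rd, end, stop_tag = NULL) {
  out <- list()
  while (rd$pos <= end) {
    group <- .rd_u16(rd); element <- .rd_u16(rd)
    if (!is.null(stop_tag) && group == stop_tag[1] &&
        element == stop_tag[2]) {
      .rd_u32(rd) # delimiter length (zero)
      break
    }
    vr <- rawToChar(.take(rd, 2L))
    if (!grepl("^[A-Z]{2}$", vr))
      .err("invalid_format_error",
           sprintf("bad VR at tag (%04X,%04X); only explicit VR little endian is supported",
                   group, element))
    len <- if (vr %in% .LONG_VRS) { .take(rd, 2L); .rd_u32(rd) }
    else .rd_u16(rd)
    i <- which(.DICOM_DICT$group == group & .DICOM_DICT$element == element)
    keyword <- if (length(i)) .DICOM_DICT$keyword[i] else NA_character_
    if (identical(keyword, "PixelData")) {
      # pixel data is skipped, never decoded into the record
      if (len < 0) .err("invalid_format_error",
                        "undefined-length pixel data is not supported")
      .take(rd, len)
      out[["PixelDataPresent"]] <- TRUE
    } else if (vr == "SQ") {
      out[[if (is.na(keyword)) sprintf("g%04Xe%04X", group, element)
           else keyword]] <- .parse_sequence(rd, len)
    } else {
      if (len < 0) .err("invalid_format_error", "unexpected undefined length")
      body <- .take(rd, len)
      if (!is.na(keyword)) out[[keyword]] <- .dec_value(vr, body)
    }
  }
  out
}

.parse_sequence <- function(rd, len) {
  end <- if (len < 0) rd$n else rd$pos + len - 1L
  items <- list()
  while (rd$pos <= end) {
    group <- .rd_u16(rd); element <- .rd_u16(rd)
    if (group == 0xFFFE && element == 0xE0DD) { .rd_u32(rd); break }
    if (!(group == 0xFFFE && element == 0xE000))
      .err("invalid_format_error", "malformed sequence item")
    ilen <- .rd_u32(rd)
    iend <- if (ilen < 0) rd$n else rd$pos + ilen - 1L
    items[[length(items) + 1L]] <-
      .parse_dataset(rd, iend, stop_tag = c(0xFFFE, 0xE00D))
  }
  items
}

#' Read a DICOM Part-10 file header
#'
#' Parses the file meta group and the dataset of an explicit VR little
#' endian Part-10 file, returning the mapped tag values. Pixel data is
#' detected and skipped, never decoded. Files without the `DICM` magic or
#' with a different transfer syntax raise an invalid-format error.
#'
#' @param path file to read.
#' @return list with components `meta` (file meta values), `elements`
#'   (named list of mapped keywords) and `hasPixelData`.
#' @export
readDicomFile <- function(path) {
  if (!file.exists(path))
    .err("invalid_format_error", sprintf("no such file: %s", path))
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 140L ||
      !identical(rawToChar(bytes[129:132]), "DICM"))
    .err("invalid_format_error",
         sprintf("not a DICOM Part-10 file: %s", path))
  rd <- .reader(bytes)
  rd$pos <- 133L
  # file meta group: always explicit VR little endian
  g <- .rd_u16(rd); e <- .rd_u16(rd)
  if (g != 2L || e != 0L)
    .err("invalid_format_error", "missing file meta group length")
  vr <- rawToChar(.take(rd, 2L))
  glen_len <- if (vr %in% .LONG_VRS) { .take(rd, 2L); .rd_u32(rd) }
  else .rd_u16(rd)
  glen <- .dec_value(vr, .take(rd, glen_len))
  meta <- .parse_meta(rd, rd$pos + glen - 1L)
  ts <- meta[["g0002e0010"]] %||% NA_character_
  if (!identical(ts, TRANSFER_SYNTAX_EXPLICIT_LE))
    .err("invalid_format_error",
         sprintf("unsupported transfer syntax '%s'", ts))
  elements <- .parse_dataset(rd, rd$n)
  has_pixel <- isTRUE(elements$PixelDataPresent)
  elements$PixelDataPresent <- NULL
  list(meta = meta, elements = elements, hasPixelData = has_pixel)
}

# parse the file meta group; every element is returned keyed gXXXXeXXXX
.parse_meta <- function(rd, end) {
  out <- list()
  while (rd$pos <= end) {
    group <- .rd_u16(rd); element <- .rd_u16(rd)
    evr <- rawToChar(.take(rd, 2L))
    len <- if (evr %in% .LONG_VRS) { .take(rd, 2L); .rd_u32(rd) }
    else .rd_u16(rd)
    body <- .take(rd, len)
    out[[sprintf("g%04Xe%04X", group, element)]] <-
      if (evr %in% c(.STRING_VRS, "US", "UL")) .dec_value(evr, body)
      else body
  }
  out
}
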