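# Minimal DICOM codec: Explicit VR Little Endian, defined or undefined
# sequence lengths.  Covers the tag subset needed for PET/CT image series
# and RTSTRUCT structure sets; unknown tags are carried through as raw.
# This is deliberately not a general DICOM implementation -- it exists so
# the phantom generator can emit series that the readers consume, and so
# vendor-style uncompressed Explicit-VR-LE files with the same tags parse.

DICOM_TX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

# VRs that use the 4-byte length form (2 reserved bytes precede the length)
.dcm_long_vrs <- c("OB", "OW", "OF", "OD", "SQ", "UT", "UN")

# tag dictionary: name -> (group, element, VR)
.dcm_tags <- list(
  MediaStorageSOPClassUID    = c(0x0002, 0x0002, "UI"),
  MediaStorageSOPInstanceUID = c(0x0002, 0x0003, "UI"),
  TransferSyntaxUID          = c(0x0002, 0x0010, "UI"),
  SOPClassUID                = c(0x0008, 0x0016, "UI"),
  SOPInstanceUID             = c(0x0008, 0x0018, "UI"),
  StudyDate                  = c(0x0008, 0x0020, "DA"),
  SeriesDate                 = c(0x0008, 0x0021, "DA"),
  AcquisitionDate            = c(0x0008, 0x0022, "DA"),
  StudyTime                  = c(0x0008, 0x0030, "TM"),
  SeriesTime                 = c(0x0008, 0x0031, "TM"),
  AcquisitionTime            = c(0x0008, 0x0032, "TM"),
  Modality                   = c(0x0008, 0x0060, "CS"),
  SeriesDescription          = c(0x0008, 0x103E, "LO"),
  PatientName                = c(0x0010, 0x0010, "PN"),
  PatientID                  = c(0x0010, 0x0020, "LO"),
  PatientWeight              = c(0x0010, 0x1030, "DS"),
  SliceThickness             = c(0x0018, 0x0050, "DS"),
  RadiopharmaceuticalStartTime = c(0x0018, 0x1072, "TM"),
  RadionuclideTotalDose      = c(0x0018, 0x1074, "DS"),
  RadionuclideHalfLife       = c(0x0018, 0x1075, "DS"),
  StudyInstanceUID           = c(0x0020, 0x000D, "UI"),
  SeriesInstanceUID          = c(0x0020, 0x000E, "UI"),
  InstanceNumber             = c(0x0020, 0x0013, "IS"),
  ImagePositionPatient       = c(0x0020, 0x0032, "DS"),
  ImageOrientationPatient    = c(0x0020, 0x0037, "DS"),
  FrameOfReferenceUID        = c(0x0020, 0x0052, "UI"),
  SamplesPerPixel            = c(0x0028, 0x0002, "US"),
  PhotometricInterpretation  = c(0x0028, 0x0004, "CS"),
  Rows                       = c(0x0028, 0x0010, "US"),
  Columns                    = c(0x0028, 0x0011, "US"),
  PixelSpacing               = c(0x0028, 0x0030, "DS"),
  BitsAllocated              = c(0x0028, 0x0100, "US"),
  BitsStored                 = c(0x0028, 0x0101, "US"),
  HighBit                    = c(0x0028, 0x0102, "US"),
  PixelRepresentation        = c(0x0028, 0x0103, "US"),
  RescaleIntercept           = c(0x0028, 0x1052, "DS"),
  RescaleSlope               = c(0x0028, 0x1053, "DS"),
  RadiopharmaceuticalInformationSequence = c(0x0054, 0x0016, "SQ"),
  Units                      = c(0x0054, 0x1001, "CS"),
  DecayCorrection            = c(0x0054, 0x1102, "CS"),
  StructureSetLabel          = c(0x3006, 0x0002, "SH"),
  StructureSetROISequence    = c(0x3006, 0x0020, "SQ"),
  ROINumber                  = c(0x3006, 0x0022, "IS"),
  ReferencedFrameOfReferenceUID = c(0x3006, 0x0024, "UI"),
  ROIName                    = c(0x3006, 0x0026, "LO"),
  ROIContourSequence         = c(0x3006, 0x0039, "SQ"),
  ContourSequence            = c(0x3006, 0x0040, "SQ"),
  ContourGeometricType       = c(0x3006, 0x0042, "CS"),
  NumberOfContourPoints      = c(0x3006, 0x0046, "IS"),
  ContourData                = c(0x3006, 0x0050, "DS"),
  ReferencedROINumber        = c(0x3006, 0x0084, "IS"),
  DoubleFloatPixelData       = c(0x7FE0, 0x0009, "OD"),
  PixelData                  = c(0x7FE0, 0x0010, "OW")
)

.dcm_tag_key <- function(group, element) sprintf("%04X%04X", group, element)

.dcm_name_by_key <- local({
  keys <- vapply(.dcm_tags, function(t)
    .dcm_tag_key(as.integer(t[1]), as.integer(t[2])), character(1))
  stats::setNames(names(.dcm_tags), keys)
})

.uid_counter <- local({
  n <- 0L
  function() {
    n <<- n + 1L
    n
  }
})

# deterministic-enough UIDs under an org root reserved for examples
dcm_new_uid <- function() {
  paste0("1.2.826.0.1.3680043.9999.",
         format(as.numeric(Sys.time()) * 1000, scientific = FALSE,
                trim = TRUE),
         ".", .uid_counter(), ".", sample.int(1e6, 1))
}

## ---- encoding -------------------------------------------------------------

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) {
  # lengths can exceed .Machine's int range in theory; ours never do
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

.dcm_encode_value <- function(vr, value) {
  pad <- as.raw(if (vr == "UI") 0x00 else 0x20)
  out <- switch(vr,
    US = writeBin(as.integer(value), raw(), size = 2, endian = "little"),
    SS = writeBin(as.integer(value), raw(), size = 2, endian = "little"),
    FL = writeBin(as.numeric(value), raw(), size = 4, endian = "little"),
    FD = ,
    OD = writeBin(as.numeric(value), raw(), size = 8, endian = "little"),
    OW = if (is.raw(value)) value else
      writeBin(as.integer(value), raw(), size = 2, endian = "little"),
    OB = if (is.raw(value)) value else as.raw(value),
    DS = charToRaw(paste(vapply(as.numeric(value), function(v)
      format(v, digits = 15, scientific = FALSE, trim = TRUE),
      character(1)), collapse = "\\")),
    IS = charToRaw(paste(as.integer(value), collapse = "\\")),
    charToRaw(paste(as.character(value), collapse = "\\")))
  if (length(out) %% 2L == 1L) out <- c(out, pad)
  out
}

.dcm_encode_element <- function(group, element, vr, value) {
  body <- if (vr == "SQ") {
    items <- lapply(value, function(item) {
      content <- .dcm_encode_dataset(item)
      c(.u16(0xFFFE), .u16(0xE000), .u32(length(content)), content)
    })
    do.call(c, c(items, list(raw(0))))
  } else {
    .dcm_encode_value(vr, value)
  }
  head <- c(.u16(group), .u16(element), charToRaw(vr))
  if (vr %in% .dcm_long_vrs) {
    c(head, as.raw(c(0, 0)), .u32(length(body)), body)
  } else {
    if (length(body) > 65534) stop("value too long for short VR ", vr)
    c(head, .u16(length(body)), body)
  }
}

# dataset: named list (names from .dcm_tags) of values; SQ values are lists
# of datasets.  Elements are sorted by tag as DICOM requires.
.dcm_encode_dataset <- function(ds) {
  if (length(ds) == 0L) return(raw(0))
  info <- lapply(names(ds), function(nm) {
    t <- .dcm_tags[[nm]]
    if (is.null(t)) stop("unknown DICOM tag name: ", nm)
    t
  })
  ord <- order(vapply(info, function(t)
    as.integer(t[1]) * 2^16 + as.integer(t[2]), numeric(1)))
  chunks <- lapply(ord, function(i) {
    t <- info[[i]]
    .dcm_encode_element(as.integer(t[1]), as.integer(t[2]), t[3],
                        ds[[names(ds)[i]]])
  })
  do.call(c, chunks)
}

#' @keywords internal
dcm_write_file <- function(path, dataset) {
  meta <- list(
    MediaStorageSOPClassUID = dataset$SOPClassUID %||% "1.2.840.10008.5.1.4.1.1.128",
    MediaStorageSOPInstanceUID = dataset$SOPInstanceUID %||% dcm_new_uid(),
    TransferSyntaxUID = DICOM_TX_EXPLICIT_LE)
  bytes <- c(raw(128), charToRaw("DICM"),
             .dcm_encode_dataset(meta),
             .dcm_encode_dataset(dataset))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(bytes, con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- decoding -------------------------------------------------------------

.dcm_decode_value <- function(vr, body) {
  switch(vr,
    US = readBin(body, integer(), n = length(body) / 2, size = 2,
                 signed = FALSE, endian = "little"),
    SS = readBin(body, integer(), n = length(body) / 2, size = 2,
                 signed = TRUE, endian = "little"),
    FL = readBin(body, numeric(), n = length(body) / 4, size = 4,
                 endian = "little"),
    FD = ,
    OD = readBin(body, numeric(), n = length(body) / 8, size = 8,
                 endian = "little"),
    OW = ,
    OB = ,
    UN = body,
    DS = as.numeric(strsplit(trimws(rawToChar(body)), "\\\\")[[1]]),
    IS = as.integer(strsplit(trimws(rawToChar(body)), "\\\\")[[1]]),
    trimws(rawToChar(body[body != as.raw(0)])))
}

# cursor-based recursive parser over a raw vector
.dcm_parse <- function(bytes, pos, end) {
  out <- list()
  while (pos + 7L <= end) {
    grp <- readBin(bytes[pos:(pos + 1L)], integer(), size = 2,
                   signed = FALSE, endian = "little")
    ele <- readBin(bytes[(pos + 2L):(pos + 3L)], integer(), size = 2,
                   signed = FALSE, endian = "little")
    pos <- pos + 4L
    if (grp == 0xFFFE) {
      # delimitation items carry a 4-byte length and no VR
      len <- readBin(bytes[pos:(pos + 3L)], integer(), size = 4,
                     endian = "little")
      pos <- pos + 4L
      if (ele == 0xE0DD || ele == 0xE00D) {
        return(list(elements = out, pos = pos, delimiter = ele))
      }
      stop("unexpected item tag outside sequence")
    }
    vr <- rawToChar(bytes[pos:(pos + 1L)])
    pos <- pos + 2L
    if (vr %in% .dcm_long_vrs) {
      pos <- pos + 2L  # reserved
      len <- readBin(bytes[pos:(pos + 3L)], integer(), size = 4,
                     endian = "little")
      pos <- pos + 4L
    } else {
      len <- readBin(bytes[pos:(pos + 1L)], integer(), size = 2,
                     signed = FALSE, endian = "little")
      pos <- pos + 2L
    }
    undefined <- !is.na(len) && len == -1L
    key <- .dcm_tag_key(grp, ele)
    name <- .dcm_name_by_key[[key]] %||% key
    if (vr == "SQ") {
      parsed <- .dcm_parse_sequence(bytes, pos,
                                    if (undefined) end else pos + len - 1L,
                                    undefined)
      out[[name]] <- parsed$items
      pos <- parsed$pos
    } else {
      if (undefined) stop("undefined length on non-SQ element ", key)
      body <- if (len > 0L) bytes[pos:(pos + len - 1L)] else raw(0)
      out[[name]] <- .dcm_decode_value(vr, body)
      pos <- pos + len
    }
  }
  list(elements = out, pos = pos, delimiter = NA)
}

.dcm_parse_sequence <- function(bytes, pos, end, undefined) {
  items <- list()
  repeat {
    if (pos + 7L > end + 1L) break
    grp <- readBin(bytes[pos:(pos + 1L)], integer(), size = 2,
                   signed = FALSE, endian = "little")
    ele <- readBin(bytes[(pos + 2L):(pos + 3L)], integer(), size = 2,
                   signed = FALSE, endian = "little")
    len <- readBin(bytes[(pos + 4L):(pos + 7L)], integer(), size = 4,
                   endian = "little")
    pos <- pos + 8L
    if (grp == 0xFFFE && ele == 0xE0DD) break        # sequence delimiter
    if (!(grp == 0xFFFE && ele == 0xE000))
      stop("malformed sequence item tag")
    item_undefined <- len == -1L
    if (item_undefined) {
      parsed <- .dcm_parse(bytes, pos, end)
      items[[length(items) + 1L]] <- parsed$elements
      pos <- parsed$pos
    } else {
      parsed <- .dcm_parse(bytes, pos, pos + len - 1L)
      items[[length(items) + 1L]] <- parsed$elements
      pos <- pos + len
    }
    if (!undefined && pos > end) break
  }
  list(items = items, pos = pos)
}

#' @keywords internal
dcm_read_file <- function(path) {
  bytes <- readBin(path, raw(), n = file.size(path))
  if (length(bytes) < 132L || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  ts <- NULL
  parsed <- .dcm_parse(bytes, 133L, length(bytes))
  ds <- parsed$elements
  ts <- ds$TransferSyntaxUID
  if (!is.null(ts) && ts != DICOM_TX_EXPLICIT_LE)
    stop("unsupported transfer syntax: ", ts, call. = FALSE)
  ds
}
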