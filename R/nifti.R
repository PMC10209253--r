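# NIfTI-1 single-file (.nii / .nii.gz) reader and writer.  Volumes are
# written as float64 so write->read round trips are bitwise exact; the
# package's unit tag and SUV factors travel in a JSON sidecar (the .nii
# header has no such field).

.nifti_datatypes <- c(`2` = "uint8", `4` = "int16", `8` = "int32",
                      `16` = "float32", `64` = "float64", `256` = "int8",
                      `512` = "uint16")

.sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write a volume to NIfTI-1 with a JSON sidecar
#'
#' Data are stored as float64 (lossless for R doubles).  Geometry goes into
#' `pixdim` and an sform with a diagonal direction matrix; the unit tag
#' (and, for SUV maps, optionally the conversion factors) goes into a JSON
#' sidecar next to the image (`.nii`/`.nii.gz` replaced by `.json`).
#'
#' @param image a [volume_image].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param suv_factors_obj optional [suv_factors] stored in the sidecar.
#' @return invisibly, `path`.
#' @export
write_nifti <- function(image, path, suv_factors_obj = NULL) {
  stopifnot(is_volume_image(image))
  d <- dim(image$data)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  ok <- tryCatch({
    wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
    wb(348L, 4)                                   # sizeof_hdr
    writeBin(raw(36), con)                        # unused + dim_info
    wb(as.integer(c(3, d, 1, 1, 1, 1)), 2)        # dim[8]
    wb(integer(3), 2)                             # intent params (as shorts x?) placeholder
    writeBin(raw(8), con)                         # intent_p1..p3 rest + intent_code
    wb(64L, 2)                                    # datatype = FLOAT64
    wb(64L, 2)                                    # bitpix
    wb(0L, 2)                                     # slice_start
    wb(c(1, image$spacing, 0, 0, 0, 0), 4)        # pixdim[8] (float32)
    wb(352, 4)                                    # vox_offset (float32)
    wb(c(1, 0), 4)                                # scl_slope, scl_inter
    wb(0L, 2); writeBin(raw(2), con)              # slice_end, slice_code+xyzt_units
    wb(c(0, 0, 0, 0), 4)                          # cal_max/min, slice_duration, toffset
    wb(c(0L, 0L), 4)                              # glmax, glmin
    writeBin(raw(104), con)                       # descrip(80) + aux_file(24)
    wb(c(0L, 1L), 2)                              # qform_code=0, sform_code=1
    wb(numeric(6), 4)                             # quatern b,c,d + qoffset x,y,z
    wb(c(image$spacing[1], 0, 0, image$origin[1]), 4)  # srow_x
    wb(c(0, image$spacing[2], 0, image$origin[2]), 4)  # srow_y
    wb(c(0, 0, image$spacing[3], image$origin[3]), 4)  # srow_z
    writeBin(charToRaw("osteoseg........")[1:16], con) # intent_name
    writeBin(c(charToRaw("n+1"), raw(1)), con)    # magic
    writeBin(raw(4), con)                         # extension flag
    writeBin(as.numeric(image$data), con, size = 8, endian = "little")
    TRUE
  }, error = function(e) {
    stop("I/O error writing NIfTI: ", conditionMessage(e), call. = FALSE)
  }, finally = close(con))
  sidecar <- list(units = image$units)
  if (!is.null(suv_factors_obj))
    sidecar$suv_factors <- unclass(suv_factors_obj)
  jsonlite::write_json(sidecar, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports single-file `.nii`/`.nii.gz`, little- or big-endian, common
#' datatypes (u)int8/16/32 and float32/64, and honours `scl_slope`/
#' `scl_inter`.  Units are restored from the JSON sidecar written by
#' [write_nifti()]; if no sidecar is found the units are recorded as the
#' given `default_units` with a warning.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param default_units unit tag used when no sidecar is present.
#' @return a [volume_image]; if the sidecar carried SUV factors they are
#'   attached as attribute `"suv_factors"`.
#' @export
read_nifti <- function(path, default_units = "SUV_BW") {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, raw(), n = 348)
  if (length(hdr) < 348) stop("I/O error: truncated NIfTI header",
                              call. = FALSE)
  endian <- "little"
  sz <- readBin(hdr[1:4], integer(), size = 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], integer(), size = 4, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file: ", path, call. = FALSE)
  }
  rd <- function(off, what, n, size)
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian)
  dims <- rd(40, integer(), 8, 2)
  ndim <- dims[1]
  if (ndim < 3) stop("expected a 3-D NIfTI volume", call. = FALSE)
  d <- dims[2:4]
  nvox <- prod(pmax(dims[2:(1 + ndim)], 1L))
  datatype <- rd(70, integer(), 1, 2)
  pixdim <- rd(76, numeric(), 8, 4)
  vox_offset <- rd(108, numeric(), 1, 4)
  scl_slope <- rd(112, numeric(), 1, 4)
  scl_inter <- rd(116, numeric(), 1, 4)
  sform_code <- rd(254, integer(), 1, 2)
  srow <- matrix(rd(280, numeric(), 12, 4), nrow = 3, byrow = TRUE)
  dt <- .nifti_datatypes[as.character(datatype)]
  if (is.na(dt)) stop("unsupported NIfTI datatype ", datatype, call. = FALSE)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, raw(), n = skip)
  vals <- switch(dt,
    uint8   = readBin(con, integer(), n = nvox, size = 1, signed = FALSE),
    int8    = readBin(con, integer(), n = nvox, size = 1, signed = TRUE),
    int16   = readBin(con, integer(), n = nvox, size = 2, endian = endian),
    uint16  = readBin(con, integer(), n = nvox, size = 2, signed = FALSE,
                      endian = endian),
    int32   = readBin(con, integer(), n = nvox, size = 4, endian = endian),
    float32 = readBin(con, numeric(), n = nvox, size = 4, endian = endian),
    float64 = readBin(con, numeric(), n = nvox, size = 8, endian = endian))
  if (length(vals) < nvox) stop("I/O error: truncated NIfTI data",
                                call. = FALSE)
  vals <- vals[seq_len(prod(d))]          # first 3-D frame
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  spacing <- pixdim[2:4]
  origin <- if (sform_code > 0) srow[, 4] else c(0, 0, 0)
  units <- NULL; factors <- NULL
  sc <- .sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    units <- meta$units
    if (!is.null(meta$suv_factors))
      factors <- do.call(suv_factors, meta$suv_factors[
        c("injected_dose", "half_life", "injection_time",
          "acquisition_time", "patient_weight", "decay_reference")])
  }
  if (is.null(units)) {
    warning("no JSON sidecar for ", path, "; units recorded as ",
            default_units)
    units <- default_units
  }
  vol <- volume_image(array(vals, dim = d), spacing = spacing,
                      origin = origin, units = units)
  if (!is.null(factors)) attr(vol, "suv_factors") <- factors
  vol
}
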