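#' Read a PET or CT DICOM series into a volume
#'
#' Reads every `.dcm` file in `directory`, keeps the slices of the requested
#' modality, sorts them by physical axial position and assembles a
#' [volume_image].  CT stored values are rescaled to Hounsfield units via
#' the header's rescale slope/intercept; PET values are rescaled to activity
#' concentration in Bq/ml.  Slice order is taken from
#' `ImagePositionPatient`, never from file names.
#'
#' Only uncompressed Explicit-VR-little-endian files are supported (the
#' encoding this package writes).  16-bit integer pixel data with rescale
#' tags and lossless 64-bit float pixel data are both accepted.
#'
#' @param directory path containing one series of the requested modality.
#' @param modality `"PET"` (matches DICOM modality `PT`) or `"CT"`.
#' @return a [volume_image] with units `"BQML"` (PET) or `"HU"` (CT), with
#'   attribute `"dicom_header"` holding the parsed header of the first
#'   slice (used by [extract_suv_factors()]) and attribute
#'   `"frame_of_reference"`.
#' @export
read_dicom_series <- function(directory, modality = c("PET", "CT")) {
  modality <- match.arg(modality)
  want <- if (modality == "PET") "PT" else "CT"
  files <- list.files(directory, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0L)
    stop("input error: no .dcm files in ", directory, call. = FALSE)
  headers <- lapply(files, dcm_read_file)
  mods <- vapply(headers, function(h) h$Modality %||% "", character(1))
  keep <- mods == want
  if (!any(keep))
    stop("input error: no ", modality, " slices found in ", directory,
         call. = FALSE)
  headers <- headers[keep]
  series <- unique(vapply(headers, function(h)
    h$SeriesInstanceUID %||% "", character(1)))
  if (length(series) != 1L)
    stop("input error: directory mixes ", length(series), " ", modality,
         " series", call. = FALSE)

  zpos <- vapply(headers, function(h) {
    ipp <- h$ImagePositionPatient
    if (is.null(ipp) || length(ipp) < 3L)
      stop("metadata error: missing ImagePositionPatient", call. = FALSE)
    ipp[3]
  }, numeric(1))
  ord <- order(zpos)
  headers <- headers[ord]
  zpos <- zpos[ord]

  if (length(zpos) > 1L) {
    gaps <- diff(zpos)
    if (any(gaps <= 0) || (max(gaps) - min(gaps)) > 1e-3 * mean(gaps) + 1e-6)
      stop("input error: non-uniform slice gap (",
           paste(signif(range(gaps), 6), collapse = " .. "), " mm)",
           call. = FALSE)
  }

  h1 <- headers[[1]]
  for (tag in c("Rows", "Columns", "PixelSpacing"))
    if (is.null(h1[[tag]]))
      stop("metadata error: missing tag ", tag, call. = FALSE)
  ny <- h1$Rows; nx <- h1$Columns
  # PixelSpacing is (row spacing, column spacing) = (y, x)
  sp_xy <- c(h1$PixelSpacing[2], h1$PixelSpacing[1])
  dz <- if (length(zpos) > 1L) mean(diff(zpos)) else
    (h1$SliceThickness %||% 1)
  ipp1 <- h1$ImagePositionPatient

  data <- array(0, dim = c(nx, ny, length(headers)))
  for (k in seq_along(headers)) {
    data[, , k] <- .dcm_slice_values(headers[[k]], nx, ny)
  }
  vol <- volume_image(data, spacing = c(sp_xy, dz),
                      origin = c(ipp1[1], ipp1[2], zpos[1]),
                      units = if (modality == "PET") "BQML" else "HU")
  attr(vol, "dicom_header") <- h1
  attr(vol, "frame_of_reference") <- h1$FrameOfReferenceUID
  vol
}

# decode one slice's pixel values (rescaled) as an [x, y] matrix
.dcm_slice_values <- function(h, nx, ny) {
  if (!is.null(h$DoubleFloatPixelData)) {
    vals <- h$DoubleFloatPixelData          # OD decodes straight to doubles
  } else if (!is.null(h$PixelData)) {
    bits <- h$BitsAllocated %||% 16L
    if (bits != 16L)
      stop("metadata error: unsupported BitsAllocated ", bits, call. = FALSE)
    signed <- (h$PixelRepresentation %||% 0L) == 1L
    stored <- readBin(h$PixelData, integer(), n = nx * ny, size = 2,
                      signed = signed, endian = "little")
    slope <- h$RescaleSlope
    inter <- h$RescaleIntercept
    if (is.null(slope))
      stop("metadata error: missing tag RescaleSlope", call. = FALSE)
    if (is.null(inter))
      stop("metadata error: missing tag RescaleIntercept", call. = FALSE)
    vals <- stored * slope + inter
  } else {
    stop("metadata error: missing tag PixelData", call. = FALSE)
  }
  if (length(vals) != nx * ny)
    stop("input error: pixel data length mismatch", call. = FALSE)
  matrix(vals, nrow = nx, ncol = ny)   # row-major stream, x fastest
}

## ---- SUV factors ----------------------------------------------------------

# "HHMMSS.ffff" -> seconds since midnight
.parse_tm <- function(tm) {
  tm <- trimws(tm)
  h <- as.numeric(substr(tm, 1, 2))
  m <- as.numeric(substr(tm, 3, 4))
  s <- as.numeric(substring(tm, 5))
  if (is.na(s)) s <- 0
  3600 * h + 60 * m + s
}

#' Extract body-weight SUV conversion factors from a PET header
#'
#' Pulls injected dose, radionuclide half-life, injection time, acquisition
#' time and patient weight out of a parsed PET DICOM header (the
#' `"dicom_header"` attribute attached by [read_dicom_series()]).  When the
#' header omits the half-life, the physical FDG half-life of 6586.2 s is
#' substituted with a warning.  `DecayCorrection` is honoured when present
#' and assumed `"START"` (decay-corrected to scan acquisition start)
#' otherwise.
#'
#' @param pet_header parsed header list, or a PET [volume_image] carrying
#'   one as attribute.
#' @return an [suv_factors] object.
#' @export
extract_suv_factors <- function(pet_header) {
  h <- if (is_volume_image(pet_header)) attr(pet_header, "dicom_header")
       else pet_header
  if (is.null(h)) stop("metadata error: no PET header available",
                       call. = FALSE)
  w <- h$PatientWeight
  if (is.null(w))
    stop("metadata error: missing field PatientWeight", call. = FALSE)
  rph <- h$RadiopharmaceuticalInformationSequence
  rph <- if (length(rph)) rph[[1]] else list()
  dose <- rph$RadionuclideTotalDose
  if (is.null(dose))
    stop("metadata error: missing field RadionuclideTotalDose", call. = FALSE)
  half <- rph$RadionuclideHalfLife
  if (is.null(half)) {
    warning("RadionuclideHalfLife absent; assuming FDG (6586.2 s)")
    half <- 6586.2
  }
  inj <- rph$RadiopharmaceuticalStartTime
  if (is.null(inj))
    stop("metadata error: missing field RadiopharmaceuticalStartTime",
         call. = FALSE)
  acq <- h$AcquisitionTime %||% h$SeriesTime
  if (is.null(acq))
    stop("metadata error: missing field AcquisitionTime", call. = FALSE)
  suv_factors(injected_dose = dose, half_life = half,
              injection_time = .parse_tm(inj),
              acquisition_time = .parse_tm(acq),
              patient_weight = w,
              decay_reference = h$DecayCorrection %||% "START")
}

## ---- writing series (phantom export, auto-contour export) -----------------

#' Write a volume as a DICOM image series
#'
#' One file per axial slice, Explicit VR Little Endian.  CT (`HU`) volumes
#' are stored as signed 16-bit integers with rescale slope 1 / intercept 0
#' (HU values are rounded to integers); PET (`BQML`) volumes are stored
#' losslessly as 64-bit float pixel data so a write/read round trip is
#' exact.  PET headers carry the radiopharmaceutical information needed by
#' [extract_suv_factors()].
#'
#' @param vol a [volume_image] with units `"HU"` or `"BQML"`.
#' @param directory output directory (created if needed).
#' @param suv_factors_obj for PET, the [suv_factors] written to the header.
#' @param frame_of_reference UID shared with the companion series/RTSTRUCT.
#' @param patient_id identifier written into the headers.
#' @return invisibly, the vector of files written.
#' @export
write_dicom_series <- function(vol, directory, suv_factors_obj = NULL,
                               frame_of_reference = dcm_new_uid(),
                               patient_id = "PHANTOM") {
  stopifnot(is_volume_image(vol))
  if (!vol$units %in% c("HU", "BQML"))
    stop("write_dicom_series supports HU or BQML volumes", call. = FALSE)
  is_pet <- vol$units == "BQML"
  if (is_pet && is.null(suv_factors_obj))
    stop("PET series need suv_factors_obj for the header", call. = FALSE)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  d <- dim(vol$data)
  series_uid <- dcm_new_uid()
  study_uid <- dcm_new_uid()
  files <- character(d[3])
  fmt_tm <- function(sec) {
    sec <- sec %% 86400
    sprintf("%02d%02d%09.6f", sec %/% 3600, (sec %% 3600) %/% 60, sec %% 60)
  }
  for (k in seq_len(d[3])) {
    ds <- list(
      SOPClassUID = if (is_pet) "1.2.840.10008.5.1.4.1.1.128"
                    else "1.2.840.10008.5.1.4.1.1.2",
      SOPInstanceUID = dcm_new_uid(),
      Modality = if (is_pet) "PT" else "CT",
      PatientName = patient_id, PatientID = patient_id,
      StudyInstanceUID = study_uid, SeriesInstanceUID = series_uid,
      FrameOfReferenceUID = frame_of_reference,
      InstanceNumber = k,
      StudyDate = "20200101", AcquisitionDate = "20200101",
      ImagePositionPatient = c(vol$origin[1], vol$origin[2],
                               vol$origin[3] + (k - 1) * vol$spacing[3]),
      ImageOrientationPatient = c(1, 0, 0, 0, 1, 0),
      SamplesPerPixel = 1L, PhotometricInterpretation = "MONOCHROME2",
      Rows = d[2], Columns = d[1],
      PixelSpacing = c(vol$spacing[2], vol$spacing[1]),  # row(y), col(x)
      SliceThickness = vol$spacing[3])
    slice <- vol$data[, , k]
    if (is_pet) {
      ds$Units <- "BQML"
      ds$DecayCorrection <- suv_factors_obj$decay_reference
      ds$AcquisitionTime <- fmt_tm(suv_factors_obj$acquisition_time)
      ds$PatientWeight <- suv_factors_obj$patient_weight
      ds$RadiopharmaceuticalInformationSequence <- list(list(
        RadiopharmaceuticalStartTime = fmt_tm(suv_factors_obj$injection_time),
        RadionuclideTotalDose = suv_factors_obj$injected_dose,
        RadionuclideHalfLife = suv_factors_obj$half_life))
      ds$BitsAllocated <- 64L
      ds$DoubleFloatPixelData <- as.numeric(slice)
    } else {
      ds$BitsAllocated <- 16L; ds$BitsStored <- 16L; ds$HighBit <- 15L
      ds$PixelRepresentation <- 1L
      ds$RescaleSlope <- 1; ds$RescaleIntercept <- 0
      stored <- as.integer(round(slice))
      if (any(stored > 32767 | stored < -32768))
        stop("HU values out of 16-bit range", call. = FALSE)
      ds$PixelData <- writeBin(stored, raw(), size = 2, endian = "little")
    }
    files[k] <- file.path(directory, sprintf("%s_%04d.dcm",
                                             if (is_pet) "PT" else "CT", k))
    dcm_write_file(files[k], ds)
  }
  invisible(files)
}

## ---- contours / RTSTRUCT --------------------------------------------------

#' Planar contour structures in patient coordinates
#'
#' @param structures named list; each entry is a list of planar polygons,
#'   every polygon an `n x 3` matrix of physical mm vertices (`n >= 3`)
#'   lying on one axial plane.
#' @param frame_of_reference UID string tying contours to an image grid.
#' @return object of class `contour_set`.
#' @export
contour_set <- function(structures, frame_of_reference = "unknown") {
  for (nm in names(structures)) {
    for (poly in structures[[nm]]) {
      if (!is.matrix(poly) || ncol(poly) != 3L || nrow(poly) < 3L)
        stop("every polygon must be an n>=3 x 3 matrix of mm vertices",
             call. = FALSE)
      if (max(poly[, 3]) - min(poly[, 3]) > 1e-6)
        stop("polygon vertices must lie on one axial plane", call. = FALSE)
    }
  }
  structure(list(structures = structures,
                 frame_of_reference = frame_of_reference),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set> %d structure(s), frame %s\n",
              length(x$structures), x$frame_of_reference))
  for (nm in names(x$structures))
    cat(sprintf("  %-12s %d polygon(s)\n", nm, length(x$structures[[nm]])))
  invisible(x)
}

#' Write a contour set as a DICOM RTSTRUCT file
#' @param contours a [contour_set].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_rtstruct <- function(contours, path) {
  stopifnot(inherits(contours, "contour_set"))
  rois <- list(); rcs <- list()
  nms <- names(contours$structures)
  for (i in seq_along(nms)) {
    rois[[i]] <- list(ROINumber = i,
                      ReferencedFrameOfReferenceUID =
                        contours$frame_of_reference,
                      ROIName = nms[i])
    polys <- contours$structures[[nms[i]]]
    rcs[[i]] <- list(
      ReferencedROINumber = i,
      ContourSequence = lapply(polys, function(p) list(
        ContourGeometricType = "CLOSED_PLANAR",
        NumberOfContourPoints = nrow(p),
        ContourData = as.numeric(t(p)))))
  }
  ds <- list(SOPClassUID = "1.2.840.10008.5.1.4.1.1.481.3",
             SOPInstanceUID = dcm_new_uid(),
             Modality = "RTSTRUCT",
             StructureSetLabel = "osteoseg",
             FrameOfReferenceUID = contours$frame_of_reference,
             StructureSetROISequence = rois,
             ROIContourSequence = rcs)
  dcm_write_file(path, ds)
  invisible(path)
}

#' Read a DICOM RTSTRUCT file into a contour set
#' @param path RTSTRUCT file path.
#' @return a [contour_set].
#' @export
read_rtstruct <- function(path) {
  ds <- dcm_read_file(path)
  if (!identical(ds$Modality, "RTSTRUCT"))
    stop("input error: not an RTSTRUCT file", call. = FALSE)
  roi_names <- list(); frame <- ds$FrameOfReferenceUID %||% "unknown"
  for (roi in ds$StructureSetROISequence %||% list()) {
    roi_names[[as.character(roi$ROINumber)]] <- roi$ROIName
    if (!is.null(roi$ReferencedFrameOfReferenceUID))
      frame <- roi$ReferencedFrameOfReferenceUID
  }
  structures <- list()
  for (rc in ds$ROIContourSequence %||% list()) {
    nm <- roi_names[[as.character(rc$ReferencedROINumber)]] %||%
      paste0("ROI_", rc$ReferencedROINumber)
    polys <- lapply(rc$ContourSequence %||% list(), function(cs)
      matrix(cs$ContourData, ncol = 3, byrow = TRUE))
    structures[[nm]] <- polys
  }
  contour_set(structures, frame_of_reference = frame)
}

# even-odd crossing test, vectorised over points
.point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterise planar contours onto an image grid
#'
#' Each structure becomes one integer label (in list order); a voxel
#' belongs to a structure when its centre lies inside the polygon on that
#' axial slice (even-odd rule).  Where structures overlap, the later
#' structure wins.  Polygons are assigned to the nearest slice; polygons
#' falling outside the grid's axial extent are ignored.
#'
#' @param contours a [contour_set].
#' @param grid a [volume_image] defining shape, spacing and origin.
#' @param frame_of_reference optional UID of the grid; if both this and the
#'   contour set's frame are known and differ, a geometry error is raised.
#' @return a [volume_image] with units `"LABEL"`, plus attribute
#'   `"label_names"`.
#' @export
rasterise_contours <- function(contours, grid, frame_of_reference = NULL) {
  stopifnot(inherits(contours, "contour_set"), is_volume_image(grid))
  if (!is.null(frame_of_reference) &&
      contours$frame_of_reference != "unknown" &&
      frame_of_reference != contours$frame_of_reference)
    stop("geometry error: frame-of-reference mismatch", call. = FALSE)
  d <- dim(grid$data)
  lab <- array(0L, dim = d)
  xc <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1]
  yc <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2]
  nms <- names(contours$structures)
  for (s in seq_along(nms)) {
    for (poly in contours$structures[[nms[s]]]) {
      zmm <- poly[1, 3]
      k <- round((zmm - grid$origin[3]) / grid$spacing[3]) + 1
      if (k < 1 || k > d[3]) next
      vx <- poly[, 1]; vy <- poly[, 2]
      ix <- which(xc >= min(vx) - grid$spacing[1] &
                  xc <= max(vx) + grid$spacing[1])
      iy <- which(yc >= min(vy) - grid$spacing[2] &
                  yc <= max(vy) + grid$spacing[2])
      if (!length(ix) || !length(iy)) next
      pts <- expand.grid(x = ix, y = iy)
      hit <- .point_in_polygon(xc[pts$x], yc[pts$y], vx, vy)
      if (any(hit)) {
        sel <- cbind(pts$x[hit], pts$y[hit], k)
        lab[sel] <- s
      }
    }
  }
  out <- volume_image(lab, spacing = grid$spacing, origin = grid$origin,
                      units = "LABEL")
  attr(out, "label_names") <- nms
  out
}
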