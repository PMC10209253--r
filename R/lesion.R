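# Lesion detection by absolute SUV thresholding within bone, and
# per-lesion quantification.

#' Segment lesions from a bone-masked SUV map
#'
#' Voxels with `SUV >= suv_threshold` (inclusive; boundary voxels are
#' deterministic) are grouped into connected components.  Components
#' smaller than `min_voxels` are discarded; the default of 1 applies no
#' size filter.  Labels are renumbered 1..K in order of decreasing volume
#' (ties broken by first raster-scan occurrence), so label 1 is always the
#' largest lesion.
#'
#' @param masked_suv [volume_image] with units `"SUV_BW"`, already
#'   restricted to bone by [apply_bone_mask()].
#' @param suv_threshold absolute SUV cut-off (> 0); 3.0 is the optimised
#'   operating point for FDG bone metastases.
#' @param connectivity 26 (default; merges diagonally touching uptake) or 6.
#' @param min_voxels minimum component size retained.
#' @return [volume_image] with units `"LABEL"` (integer labels, 0 =
#'   background), with attribute `"n_lesions"`.
#' @export
segment_lesions <- function(masked_suv, suv_threshold = 3.0,
                            connectivity = 26, min_voxels = 1L) {
  stopifnot(is_volume_image(masked_suv))
  if (masked_suv$units != "SUV_BW")
    stop("unit error: segment_lesions expects an SUV_BW volume",
         call. = FALSE)
  if (!is.numeric(suv_threshold) || suv_threshold <= 0)
    stop("parameter error: suv_threshold must be > 0", call. = FALSE)
  if (!connectivity %in% c(6, 26))
    stop("parameter error: connectivity must be 6 or 26", call. = FALSE)
  d <- dim(masked_suv$data)
  fg <- as.integer(masked_suv$data >= suv_threshold)
  lab <- .cc_label(fg, d, as.integer(connectivity))
  k <- attr(lab, "n_components")
  lab <- array(lab, dim = d)
  if (k > 0L) {
    sizes <- tabulate(lab, nbins = k)
    keep <- which(sizes >= min_voxels)
    # relabel by decreasing size; ties keep raster-scan (original) order
    keep <- keep[order(-sizes[keep], keep)]
    remap <- integer(k)
    remap[keep] <- seq_along(keep)
    nz <- lab > 0L
    lab[nz] <- remap[lab[nz]]
    k <- length(keep)
  }
  out <- volume_image(lab, spacing = masked_suv$spacing,
                      origin = masked_suv$origin, units = "LABEL")
  attr(out, "n_lesions") <- k
  out
}

#' Quantify labelled lesions on an SUV map
#'
#' For each label: volume in ml (`voxel count * voxel volume`), SUVmean
#' (sum of SUV over the lesion's voxels divided by the voxel count), SUVmax
#' and the SUVmax location.  Ties in SUVmax resolve to the smallest linear
#' (column-major) voxel index, so results are deterministic.
#'
#' @param labels [volume_image] with units `"LABEL"`.
#' @param suv [volume_image] with units `"SUV_BW"` on the same grid.
#' @return a `data.frame` with one row per label: `label`, `n_voxels`,
#'   `volume_ml`, `suv_mean`, `suv_max`, `max_x`, `max_y`, `max_z` (0-based
#'   voxel indices) and `max_x_mm`, `max_y_mm`, `max_z_mm`.  Empty label
#'   map gives a zero-row frame.
#' @export
quantify_lesions <- function(labels, suv) {
  stopifnot(is_volume_image(labels), is_volume_image(suv))
  check_same_grid(labels, suv)
  d <- dim(labels$data)
  vv <- voxel_volume_ml(labels)
  labs <- labels$data
  k <- max(labs)
  empty <- data.frame(label = integer(0), n_voxels = integer(0),
                      volume_ml = numeric(0), suv_mean = numeric(0),
                      suv_max = numeric(0), max_x = integer(0),
                      max_y = integer(0), max_z = integer(0),
                      max_x_mm = numeric(0), max_y_mm = numeric(0),
                      max_z_mm = numeric(0))
  if (k == 0L) return(empty)
  rows <- vector("list", k)
  for (lb in seq_len(k)) {
    idx <- which(labs == lb)
    if (!length(idx)) next
    vals <- suv$data[idx]
    imax <- idx[which.max(vals)]          # which.max: first = lowest index
    coord <- arrayInd(imax, d) - 1L       # 0-based
    mm <- labels$origin + coord * labels$spacing
    rows[[lb]] <- data.frame(
      label = lb, n_voxels = length(idx),
      volume_ml = length(idx) * vv,
      suv_mean = sum(vals) / length(idx),
      suv_max = max(vals),
      max_x = coord[1], max_y = coord[2], max_z = coord[3],
      max_x_mm = mm[1], max_y_mm = mm[2], max_z_mm = mm[3])
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) empty else out
}

#' Binary mask of one lesion (or of all lesions) from a label map
#'
#' @param labels [volume_image] with units `"LABEL"`.
#' @param label integer label to extract, or `NULL` for the union of all.
#' @return binary [volume_image].
#' @export
lesion_mask <- function(labels, label = NULL) {
  stopifnot(is_volume_image(labels))
  m <- if (is.null(label)) labels$data > 0 else labels$data == label
  binary_mask(m, labels)
}
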