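# Skeleton extraction from the resampled CT: HU threshold, edge smoothing,
# hole filling.  The smoothing operates on the binary mask (Gaussian blur
# of the 0/1 field, re-binarised at 0.5), which regularises the jagged
# threshold boundary without moving it systematically.

# separable Gaussian blur along one axis, sigma in voxels; replicate-edge
# normalisation via kernel-mass renormalisation rows
.gauss_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- stats::dnorm(-r:r, sd = sigma_vox)
  W <- matrix(0, n, n)
  for (m in -r:r) {
    idx <- seq_len(n) + m
    ok <- idx >= 1 & idx <= n
    W[cbind(which(ok), idx[ok])] <- W[cbind(which(ok), idx[ok])] +
      k[m + r + 1]
  }
  W / rowSums(W)
}

gaussian_blur_3d <- function(data, sigma_vox) {
  d <- dim(data)
  if (sigma_vox[1] > 0) {
    W <- .gauss_matrix(d[1], sigma_vox[1])
    data <- array(W %*% matrix(data, d[1]), dim = d)
  }
  if (sigma_vox[2] > 0) {
    W <- .gauss_matrix(d[2], sigma_vox[2])
    perm <- aperm(data, c(2, 1, 3))
    perm <- array(W %*% matrix(perm, d[2]), dim = c(d[2], d[1], d[3]))
    data <- aperm(perm, c(2, 1, 3))
  }
  if (sigma_vox[3] > 0) {
    W <- .gauss_matrix(d[3], sigma_vox[3])
    flat <- matrix(data, nrow = d[1] * d[2], ncol = d[3])
    data <- array(flat %*% t(W), dim = d)
  }
  data
}

# fill holes: background components not connected to the domain border
# become foreground.  2-D operates per axial slice (4-connectivity),
# 3-D on the whole volume (6-connectivity).
fill_holes <- function(mask, dims, mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  fill_one <- function(m, d) {
    bg <- as.integer(m == 0L)
    lab <- .cc_label(bg, d, 6L)
    lab <- array(lab, dim = d)
    border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ]))
    if (d[3] > 1L) border <- unique(c(border, lab[, , 1], lab[, , d[3]]))
    border <- setdiff(border, 0L)
    holes <- lab != 0L & !(lab %in% border)
    m[holes] <- 1L
    m
  }
  if (mode == "3d") return(fill_one(mask, dims))
  for (k in seq_len(dims[3])) {
    sl <- array(mask[, , k], dim = c(dims[1], dims[2], 1L))
    mask[, , k] <- fill_one(sl, c(dims[1], dims[2], 1L))
  }
  mask
}

#' Segment the skeleton from a CT volume on the PET grid
#'
#' Binarises the CT at `hu_threshold` (inclusive), Gaussian-smooths the
#' binary mask and re-binarises at 0.5 to regularise the edges, then fills
#' enclosed holes so low-HU marrow interior to the cortical shell belongs
#' to the bone mask.  The default threshold of 110 HU captures both bone
#' marrow and cortical bone.
#'
#' @param ct_on_pet [volume_image] in HU, already on the PET grid.
#' @param hu_threshold HU cut-off (default 110).
#' @param sigma_mm Gaussian sigma in mm per axis (scalar recycled); the
#'   default `NULL` uses one voxel per axis.  `0` disables smoothing.
#' @param fill `"2d"` fills holes per axial slice (default; closes marrow
#'   cavities without bridging across gaps), `"3d"` fills volumetrically,
#'   `"none"` skips hole filling.
#' @return a binary [volume_image] (units `"BINARY"`).
#' @export
segment_bone <- function(ct_on_pet, hu_threshold = 110, sigma_mm = NULL,
                         fill = c("2d", "3d", "none")) {
  fill <- match.arg(fill)
  stopifnot(is_volume_image(ct_on_pet))
  if (ct_on_pet$units != "HU")
    stop("unit error: segment_bone expects an HU volume", call. = FALSE)
  if (is.null(sigma_mm)) sigma_mm <- ct_on_pet$spacing
  sigma_mm <- rep(as.numeric(sigma_mm), length.out = 3)
  if (any(sigma_mm < 0))
    stop("parameter error: sigma_mm must be >= 0", call. = FALSE)
  d <- dim(ct_on_pet$data)
  m <- array(as.integer(ct_on_pet$data >= hu_threshold), dim = d)
  sigma_vox <- sigma_mm / ct_on_pet$spacing
  if (any(sigma_vox > 0)) {
    sm <- gaussian_blur_3d(m, sigma_vox)
    m <- array(as.integer(sm >= 0.5), dim = d)
  }
  if (fill != "none") m <- fill_holes(m, d, fill)
  binary_mask(m, ct_on_pet)
}

#' Restrict an SUV map to the bone mask
#'
#' Voxel-wise product: SUV outside bone becomes exactly 0, eliminating
#' physiologic extra-osseous uptake (bladder, liver, kidney, brain, ...)
#' before lesion thresholding.
#'
#' @param suv [volume_image] with units `"SUV_BW"`.
#' @param bone binary [volume_image] on the same grid.
#' @return [volume_image] with units `"SUV_BW"`.
#' @export
apply_bone_mask <- function(suv, bone) {
  stopifnot(is_volume_image(suv), is_volume_image(bone))
  if (suv$units != "SUV_BW")
    stop("unit error: apply_bone_mask expects an SUV_BW volume",
         call. = FALSE)
  check_same_grid(suv, bone)
  volume_image(suv$data * (bone$data != 0), spacing = suv$spacing,
               origin = suv$origin, units = "SUV_BW")
}

#' Surrogate automatic HU-threshold chooser
#'
#' The reference procedure tuned the bone-segmentation HU threshold by
#' visual inspection over 90-300 HU; as a reproducible surrogate this
#' utility sweeps the range and returns the threshold at which the mask
#' volume is most stable (smallest |d volume / d threshold|).  It is a
#' convenience, not a claim about the visual procedure.
#'
#' @param ct_on_pet [volume_image] in HU on the PET grid.
#' @param thresholds candidate HU values (default `seq(90, 300, by = 10)`).
#' @param ... passed to [segment_bone()].
#' @return list with `threshold`, and a data frame `profile` of mask volume
#'   (ml) per candidate.
#' @export
suggest_hu_threshold <- function(ct_on_pet,
                                 thresholds = seq(90, 300, by = 10), ...) {
  vols <- vapply(thresholds, function(th)
    sum(segment_bone(ct_on_pet, hu_threshold = th, ...)$data) *
      voxel_volume_ml(ct_on_pet), numeric(1))
  dv <- abs(diff(vols) / diff(thresholds))
  i <- which.min(dv)
  list(threshold = thresholds[i],
       profile = data.frame(hu_threshold = thresholds, volume_ml = vols))
}
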