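# Bicubic in-plane resampling of the CT volume onto the PET grid.
#
# The interpolation kernel is the cubic-convolution kernel with a = -0.5
# (Keys 1981), the same kernel behind MATLAB's imresize 'bicubic' and the
# common "bicubic" in image toolkits.  Resampling is separable: each output
# slice is W_x %*% slice %*% t(W_y) with per-axis weight matrices.

.cubic_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# weight matrix mapping n_in samples to the continuous 0-based input
# coordinates `u` (length n_out); rows are renormalised so that constants
# are preserved, with edge samples clamped (replicate padding).
# Rows whose coordinate lies outside [-0.5, n_in - 0.5] are flagged for the
# fill value.
.cubic_weights <- function(u, n_in) {
  n_out <- length(u)
  W <- matrix(0, n_out, n_in)
  outside <- u < -0.5 | u > n_in - 0.5
  base <- floor(u)
  for (m in -1:2) {
    idx <- base + m
    w <- .cubic_kernel(u - idx)
    idx_clamped <- pmin(pmax(idx, 0), n_in - 1)
    for (i in seq_len(n_out)) {
      if (w[i] != 0)
        W[i, idx_clamped[i] + 1] <- W[i, idx_clamped[i] + 1] + w[i]
    }
  }
  rs <- rowSums(W)
  rs[rs == 0] <- 1
  W <- W / rs
  W[outside, ] <- 0
  attr(W, "outside") <- outside
  W
}

# linear interpolation weights used for the z axis
.linear_weights <- function(u, n_in) {
  n_out <- length(u)
  W <- matrix(0, n_out, n_in)
  outside <- u < -0.5 | u > n_in - 0.5
  base <- floor(u)
  frac <- u - base
  for (i in seq_len(n_out)) {
    i0 <- min(max(base[i], 0), n_in - 1)
    i1 <- min(max(base[i] + 1, 0), n_in - 1)
    W[i, i0 + 1] <- W[i, i0 + 1] + (1 - frac[i])
    W[i, i1 + 1] <- W[i, i1 + 1] + frac[i]
  }
  W[outside, ] <- 0
  attr(W, "outside") <- outside
  W
}

#' Resample a CT volume onto the PET voxel grid
#'
#' Brings the higher-resolution CT onto the PET matrix slice by slice using
#' bicubic (cubic-convolution, a = -0.5) interpolation in-plane.  Two
#' coordinate conventions are available: `"physical"` maps voxel centres
#' through `origin + index * spacing` of both grids (the correct general
#' behaviour), while `"matrix"` reproduces plain matrix resizing
#' (`u = (i + 0.5) * n_in/n_out - 0.5`), ignoring origins — the behaviour
#' of toolbox `imresize` calls on co-registered matrices.  If the CT and
#' PET slice counts differ, the CT is first interpolated linearly along z
#' onto the PET slice positions (physical mode) or onto `n_z` equispaced
#' matrix positions (matrix mode).
#'
#' Voxels of the PET grid that fall outside the CT field of view are filled
#' with -1000 HU (air).  With `clamp = TRUE` (default) the bicubic
#' overshoot is clipped to the input value range so no spurious HU
#' excursions appear at bone edges.
#'
#' @param ct [volume_image] with units `"HU"`.
#' @param pet [volume_image] defining the target grid.
#' @param mode `"physical"` or `"matrix"`.
#' @param clamp clip output to the input min/max range.
#' @param fill value for out-of-field voxels (default -1000 HU).
#' @return [volume_image] with units `"HU"` on the PET grid.
#' @export
resample_ct_to_pet_grid <- function(ct, pet, mode = c("physical", "matrix"),
                                    clamp = TRUE, fill = -1000) {
  mode <- match.arg(mode)
  stopifnot(is_volume_image(ct), is_volume_image(pet))
  if (ct$units != "HU") stop("unit error: ct must be in HU", call. = FALSE)
  dct <- dim(ct$data); dpet <- dim(pet$data)

  coord <- function(axis) {
    if (mode == "physical") {
      (pet$origin[axis] + (seq_len(dpet[axis]) - 1) * pet$spacing[axis] -
         ct$origin[axis]) / ct$spacing[axis]
    } else {
      scale <- dct[axis] / dpet[axis]
      (seq_len(dpet[axis]) - 0.5) * scale - 0.5
    }
  }

  # z: pass through when counts match in matrix mode / positions coincide
  data <- ct$data
  if (mode == "physical") {
    uz <- coord(3)
    same_z <- dct[3] == dpet[3] &&
      max(abs(uz - (seq_len(dct[3]) - 1))) < 1e-6
  } else {
    same_z <- dct[3] == dpet[3]
  }
  if (!same_z) {
    uz <- if (mode == "physical") coord(3) else
      (seq_len(dpet[3]) - 0.5) * dct[3] / dpet[3] - 0.5
    Wz <- .linear_weights(uz, dct[3])
    flat <- matrix(data, nrow = dct[1] * dct[2], ncol = dct[3])
    data <- array(flat %*% t(Wz), dim = c(dct[1], dct[2], dpet[3]))
    out_z <- attr(Wz, "outside")
  } else {
    out_z <- rep(FALSE, dpet[3])
  }

  Wx <- .cubic_weights(coord(1), dct[1])
  Wy <- .cubic_weights(coord(2), dct[2])
  out_x <- attr(Wx, "outside"); out_y <- attr(Wy, "outside")

  res <- array(fill, dim = dpet)
  for (k in seq_len(dpet[3])) {
    if (out_z[k]) next
    res[, , k] <- Wx %*% data[, , k] %*% t(Wy)
  }
  if (any(out_x)) res[out_x, , ] <- fill
  if (any(out_y)) res[, out_y, ] <- fill
  if (clamp) {
    lo <- min(ct$data); hi <- max(ct$data)
    res[] <- pmin(pmax(res, min(lo, fill)), max(hi, fill))
  }
  volume_image(res, spacing = pet$spacing, origin = pet$origin, units = "HU")
}
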