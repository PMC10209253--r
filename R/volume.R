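#' 3-D scalar volume with physical geometry
#'
#' The basic container used throughout the package: a rectangular 3-D array
#' together with per-axis voxel spacing (mm), the physical position of voxel
#' `(0,0,0)` (mm) and a unit tag.  Axes are ordered `(x, y, z)` where `z` is
#' the axial (cranio-caudal) direction; voxel indices are 0-based in all
#' physical-coordinate formulas: `mm = origin + index * spacing`.
#'
#' @param data numeric 3-D array, axes `(x, y, z)`.
#' @param spacing numeric length-3, voxel size in mm per axis; all `> 0`.
#' @param origin numeric length-3, physical position (mm) of voxel
#'   `(0, 0, 0)`.
#' @param units one of `"HU"`, `"BQML"`, `"SUV_BW"`, `"BINARY"`, `"LABEL"`.
#' @return an object of class `volume_image`.
#' @examples
#' v <- volume_image(array(0, c(4, 4, 2)), spacing = c(2.7344, 2.7344, 3.27))
#' voxel_volume_ml(v)
#' @export
volume_image <- function(data, spacing, origin = c(0, 0, 0),
                         units = c("HU", "BQML", "SUV_BW", "BINARY", "LABEL")) {
  units <- match.arg(units)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin,
                 units = units),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_image> %d x %d x %d [%s]\n", d[1], d[2], d[3], x$units))
  cat(sprintf("  spacing: %.4f x %.4f x %.4f mm  (voxel %.5f ml)\n",
              x$spacing[1], x$spacing[2], x$spacing[3], voxel_volume_ml(x)))
  cat(sprintf("  origin : (%.2f, %.2f, %.2f) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  range  : [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Volume of one voxel in millilitres
#'
#' `spacing_x * spacing_y * spacing_z / 1000` (mm^3 to ml).
#'
#' @param x a `volume_image`, or a numeric length-3 spacing vector in mm.
#' @return voxel volume in ml.
#' @export
voxel_volume_ml <- function(x) {
  sp <- if (inherits(x, "volume_image")) x$spacing else as.numeric(x)
  if (length(sp) != 3L || any(sp <= 0))
    stop("need 3 positive spacing components", call. = FALSE)
  prod(sp) / 1000
}

#' @rdname volume_image
#' @param x object to test.
#' @export
is_volume_image <- function(x) inherits(x, "volume_image")

# Shared-grid check used by every voxel-wise operation.
check_same_grid <- function(a, b, tol = 1e-6) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("geometry error: volumes have different dimensions", call. = FALSE)
  if (max(abs(a$spacing - b$spacing)) > tol ||
      max(abs(a$origin - b$origin)) > tol)
    stop("geometry error: volumes are not on the same grid", call. = FALSE)
  invisible(TRUE)
}

# Physical coordinates (mm) of 0-based voxel indices (n x 3 matrix or vector).
voxel_to_mm <- function(vol, idx) {
  idx <- rbind(idx)
  sweep(sweep(idx, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' Binary mask on a reference grid
#'
#' Thin wrapper building a `volume_image` with `units = "BINARY"` from a
#' logical/0-1 array and a grid-defining volume.
#'
#' @param data logical or 0/1 3-D array.
#' @param like `volume_image` supplying spacing and origin.
#' @return `volume_image` with units `"BINARY"` and integer 0/1 data.
#' @export
binary_mask <- function(data, like) {
  m <- array(as.integer(data != 0), dim = dim(data))
  volume_image(m, spacing = like$spacing, origin = like$origin,
               units = "BINARY")
}
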