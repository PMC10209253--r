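# Deterministic digital PET/CT phantom: co-registered CT (HU) and PET
# (Bq/ml) volumes with a simple skeleton, physiologic extra-osseous
# uptake and planted osseous lesions of known volume and SUV, plus ground
# truth as label map, analytic statistics and axial contours.

#' Specification of a synthetic PET/CT phantom
#'
#' Geometry is stated in physical mm on a PET grid of (by default)
#' 64 x 64 x 48 voxels at 2.7344 x 2.7344 x 3.27 mm -- a scaled-down
#' whole-body grid keeping the clinical voxel size -- and a CT grid at
#' twice the in-plane resolution (the clinical 512-to-256 ratio).  The CT
#' contains air (-1000 HU), a soft-tissue body (40 HU) and skeleton
#' primitives with cortical shell (700 HU) and marrow (50 HU).  The PET
#' contains a soft-tissue background SUV, hot extra-osseous organs
#' (bladder/liver-like) and spherical lesions with a uniform SUV plateau.
#' Lesion SUVs are back-converted to activity concentration with
#' `suv_factors` so that SUV conversion of the generated PET recovers the
#' planted values exactly (noise aside).
#'
#' @param pet_dim,pet_spacing PET grid shape and spacing (mm).
#' @param ct_inplane_factor CT in-plane resolution multiplier (default 2).
#' @param skeleton list of primitives; a `cylinder` has `centre` (x,y mm),
#'   `radius`, optional `marrow_radius`, `cortical_hu`, `marrow_hu`; an
#'   `ellipsoid` has `centre` (x,y,z mm), `semiaxes`, `hu`.
#' @param organs list of extra-osseous hot spheres: `centre` (mm),
#'   `radius` (mm), `suv`.
#' @param lesions list of planted lesions: `centre` (mm), `radius` (mm),
#'   `suv` (plateau), `inside_bone` flag (checked geometrically).
#' @param background_suv soft-tissue SUV (default 1.0).
#' @param suv_noise_sd,hu_noise_sd additive Gaussian noise sigmas
#'   (defaults 0.1 SUV and 10 HU).
#' @param factors [suv_factors] used for the SUV-to-activity
#'   back-conversion and written into exported PET headers.
#' @param seed RNG seed making the phantom bit-reproducible.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(pet_dim = c(64, 64, 48),
                         pet_spacing = c(2.7344, 2.7344, 3.27),
                         ct_inplane_factor = 2L,
                         skeleton = NULL, organs = NULL, lesions = NULL,
                         background_suv = 1.0,
                         suv_noise_sd = 0.1, hu_noise_sd = 10,
                         factors = suv_factors(3.7e8, 6586.2,
                                               36000, 39600, 70),
                         seed = 1L) {
  fov <- (pet_dim - 1) * pet_spacing
  cx <- fov[1] / 2; cy <- fov[2] / 2; cz <- fov[3] / 2
  if (is.null(skeleton))
    skeleton <- list(list(type = "cylinder", centre = c(cx, cy),
                          radius = 16, marrow_radius = 10,
                          cortical_hu = 700, marrow_hu = 50))
  if (is.null(organs))
    organs <- list(list(name = "bladder", centre = c(cx, cy - 56, cz - 30),
                        radius = 15, suv = 8),
                   list(name = "liver", centre = c(cx - 46, cy - 26, cz + 35),
                        radius = 18, suv = 5))
  if (is.null(lesions))
    lesions <- list(list(centre = c(cx, cy, cz - 45), radius = 6, suv = 5,
                         inside_bone = TRUE),
                    list(centre = c(cx - 4, cy + 2, cz), radius = 5,
                         suv = 4, inside_bone = TRUE),
                    list(centre = c(cx + 4, cy - 2, cz + 45), radius = 7,
                         suv = 6, inside_bone = TRUE))
  for (les in lesions) {
    if (les$radius <= 0) stop("spec error: lesion radii must be > 0",
                              call. = FALSE)
    if (any(les$centre < 0) || any(les$centre > fov))
      stop("spec error: lesion outside grid", call. = FALSE)
  }
  structure(list(pet_dim = as.integer(pet_dim), pet_spacing = pet_spacing,
                 ct_inplane_factor = as.integer(ct_inplane_factor),
                 skeleton = skeleton, organs = organs, lesions = lesions,
                 background_suv = background_suv,
                 suv_noise_sd = suv_noise_sd, hu_noise_sd = hu_noise_sd,
                 factors = factors, seed = as.integer(seed)),
            class = "phantom_spec")
}

# voxel-centre coordinate arrays of a grid (mm)
.grid_coords <- function(d, spacing, origin) {
  list(x = origin[1] + (seq_len(d[1]) - 1) * spacing[1],
       y = origin[2] + (seq_len(d[2]) - 1) * spacing[2],
       z = origin[3] + (seq_len(d[3]) - 1) * spacing[3])
}

.inside_sphere <- function(co, centre, radius) {
  dx2 <- (co$x - centre[1])^2
  dy2 <- (co$y - centre[2])^2
  dz2 <- (co$z - centre[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= radius^2
}

.inside_cylinder <- function(co, centre, radius) {
  d2 <- outer((co$x - centre[1])^2, (co$y - centre[2])^2, "+")
  array(rep(d2 <= radius^2, length(co$z)),
        dim = c(length(co$x), length(co$y), length(co$z)))
}

.inside_ellipsoid <- function(co, centre, semi) {
  dx2 <- ((co$x - centre[1]) / semi[1])^2
  dy2 <- ((co$y - centre[2]) / semi[2])^2
  dz2 <- ((co$z - centre[3]) / semi[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

# is a point inside any skeleton primitive (full extent incl. cortex)?
.point_in_skeleton <- function(p, skeleton) {
  for (s in skeleton) {
    hit <- switch(s$type,
      cylinder = sum((p[1:2] - s$centre)^2) <= s$radius^2,
      ellipsoid = sum(((p - s$centre) / s$semiaxes)^2) <= 1,
      FALSE)
    if (hit) return(TRUE)
  }
  FALSE
}

#' Generate a synthetic PET/CT phantom
#'
#' Builds the CT and PET volumes described by a [phantom_spec], the
#' ground-truth lesion label map on the PET grid, analytic per-lesion
#' statistics (from the voxelised geometry and noiseless SUV), and axial
#' contour polygons of every lesion.  Noise (when enabled) is added after
#' the truth is recorded; with the same `seed` the output is
#' bit-reproducible.  The RNG state of the session is left untouched.
#'
#' @param spec a [phantom_spec].
#' @return list of class `phantom` with elements `ct` (HU), `pet` (Bq/ml),
#'   `suv_true` (noiseless SUV map), `truth_labels`, `truth_stats`,
#'   `contours`, `factors`, `frame_of_reference`, `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  dp <- spec$pet_dim; sp <- spec$pet_spacing
  f <- spec$ct_inplane_factor
  dc <- c(dp[1] * f, dp[2] * f, dp[3])
  sc <- c(sp[1] / f, sp[2] / f, sp[3])
  # align fields of view: same extent, voxel-centre convention
  oc <- c(-sp[1] / 2 + sc[1] / 2, -sp[2] / 2 + sc[2] / 2, 0)
  op <- c(0, 0, 0)
  fov <- (dp - 1) * sp
  centre <- fov / 2

  co_ct <- .grid_coords(dc, sc, oc)
  co_pet <- .grid_coords(dp, sp, op)

  ## CT ----------------------------------------------------------------
  hu <- array(-1000, dim = dc)
  body <- .inside_ellipsoid(co_ct, c(centre[1], centre[2], centre[3]),
                            c(fov[1] * 0.45, fov[2] * 0.45, fov[3]))
  hu[body] <- 40
  bone_ct <- array(FALSE, dim = dc)
  for (s in spec$skeleton) {
    if (s$type == "cylinder") {
      full <- .inside_cylinder(co_ct, s$centre, s$radius)
      hu[full] <- s$cortical_hu
      if (!is.null(s$marrow_radius) && s$marrow_radius > 0) {
        marrow <- .inside_cylinder(co_ct, s$centre, s$marrow_radius)
        hu[marrow] <- s$marrow_hu
      }
      bone_ct <- bone_ct | full
    } else if (s$type == "ellipsoid") {
      e <- .inside_ellipsoid(co_ct, s$centre, s$semiaxes)
      hu[e] <- s$hu
      bone_ct <- bone_ct | e
    } else stop("spec error: unknown skeleton primitive ", s$type)
  }

  ## PET (SUV first) ----------------------------------------------------
  suv <- array(0, dim = dp)
  body_pet <- .inside_ellipsoid(co_pet, c(centre[1], centre[2], centre[3]),
                                c(fov[1] * 0.45, fov[2] * 0.45, fov[3]))
  suv[body_pet] <- spec$background_suv
  for (org in spec$organs)
    suv[.inside_sphere(co_pet, org$centre, org$radius)] <- org$suv

  labels <- array(0L, dim = dp)
  for (i in seq_along(spec$lesions)) {
    les <- spec$lesions[[i]]
    if (isTRUE(les$inside_bone) &&
        !.point_in_skeleton(les$centre, spec$skeleton))
      stop("spec error: lesion ", i,
           " flagged inside-bone lies outside the skeleton", call. = FALSE)
    vox <- .inside_sphere(co_pet, les$centre, les$radius)
    suv[vox] <- les$suv
    labels[vox] <- i                      # later lesion wins on overlap
  }

  suv_true <- volume_image(suv, spacing = sp, origin = op, units = "SUV_BW")
  truth_labels <- volume_image(labels, spacing = sp, origin = op,
                               units = "LABEL")
  truth_stats <- quantify_lesions(truth_labels, suv_true)

  ## noise + back-conversion -------------------------------------------
  if (spec$hu_noise_sd > 0)
    hu <- hu + array(stats::rnorm(prod(dc), 0, spec$hu_noise_sd), dim = dc)
  suv_noisy <- suv
  if (spec$suv_noise_sd > 0)
    suv_noisy <- pmax(suv + array(stats::rnorm(prod(dp), 0,
                                               spec$suv_noise_sd), dim = dp),
                      0)
  ct <- volume_image(array(hu, dim = dc), spacing = sc, origin = oc,
                     units = "HU")
  pet <- suv_to_activity(
    volume_image(array(suv_noisy, dim = dp), spacing = sp, origin = op,
                 units = "SUV_BW"),
    spec$factors)

  ## lesion contours -----------------------------------------------------
  frame <- sprintf("1.2.826.0.1.3680043.9999.FOR.%d", spec$seed)
  structures <- list()
  for (i in seq_along(spec$lesions)) {
    les <- spec$lesions[[i]]
    polys <- list()
    for (k in seq_len(dp[3])) {
      zmm <- co_pet$z[k]
      dz <- zmm - les$centre[3]
      if (abs(dz) >= les$radius) next
      r <- sqrt(les$radius^2 - dz^2)
      if (r < 1e-3) next
      th <- seq(0, 2 * pi, length.out = 49)[-49]
      polys[[length(polys) + 1L]] <-
        cbind(les$centre[1] + r * cos(th), les$centre[2] + r * sin(th), zmm)
    }
    structures[[sprintf("lesion_%d", i)]] <- polys
  }
  contours <- contour_set(structures, frame_of_reference = frame)

  structure(list(ct = ct, pet = pet, suv_true = suv_true,
                 truth_labels = truth_labels, truth_stats = truth_stats,
                 contours = contours, factors = spec$factors,
                 frame_of_reference = frame, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> seed %d, %d lesion(s)\n", x$spec$seed,
              length(x$spec$lesions)))
  print(x$truth_stats[, c("label", "volume_ml", "suv_mean", "suv_max")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a phantom as DICOM PET/CT series plus RTSTRUCT
#'
#' @param phantom result of [generate_phantom()].
#' @param directory output root; creates `PET/`, `CT/` and
#'   `rtstruct.dcm`.
#' @return invisibly, a list of written paths.
#' @export
write_phantom_dicom <- function(phantom, directory) {
  stopifnot(inherits(phantom, "phantom"))
  pet_dir <- file.path(directory, "PET")
  ct_dir <- file.path(directory, "CT")
  write_dicom_series(phantom$pet, pet_dir,
                     suv_factors_obj = phantom$factors,
                     frame_of_reference = phantom$frame_of_reference)
  write_dicom_series(phantom$ct, ct_dir,
                     frame_of_reference = phantom$frame_of_reference)
  rt <- file.path(directory, "rtstruct.dcm")
  write_rtstruct(phantom$contours, rt)
  invisible(list(pet = pet_dir, ct = ct_dir, rtstruct = rt))
}

#' Turn a phantom into a validation case
#'
#' Runs the in-memory pipeline head (SUV conversion, CT resampling, bone
#' segmentation) and packages the result with the phantom's ground-truth
#' label map in the format [sweep_thresholds()] and [patient_report()]
#' expect.
#'
#' @param phantom result of [generate_phantom()].
#' @param hu_threshold bone-mask HU threshold (default 110).
#' @param ... passed to [segment_bone()].
#' @return list with `suv`, `bone`, `ref_labels`.
#' @export
phantom_case <- function(phantom, hu_threshold = 110, ...) {
  stopifnot(inherits(phantom, "phantom"))
  suv <- to_suv_map(phantom$pet, phantom$factors)
  ct_on_pet <- resample_ct_to_pet_grid(phantom$ct, phantom$pet)
  bone <- segment_bone(ct_on_pet, hu_threshold = hu_threshold, ...)
  list(suv = suv, bone = bone, ref_labels = phantom$truth_labels)
}

#' Generate a small phantom cohort
#'
#' Convenience wrapper producing `n` phantoms that differ in seed and in
#' planted lesion pattern (lesion SUV plateaus drawn from `plateaus`,
#' radii from `radii`, positions jittered along the spine), emulating a
#' cohort of patients with distinct metastatic spread.
#'
#' @param n number of phantoms.
#' @param seed base seed; phantom `i` uses `seed + i`.
#' @param plateaus candidate lesion SUV plateaus.
#' @param radii candidate lesion radii (mm).
#' @param n_lesions candidate lesion counts per phantom.
#' @param ... passed to [phantom_spec()].
#' @return list of `phantom` objects.
#' @export
phantom_cohort <- function(n = 5, seed = 1,
                           plateaus = c(3.5, 4, 4.5, 5, 6),
                           radii = c(5, 6, 7, 8),
                           n_lesions = 2:4, ...) {
  lapply(seq_len(n), function(i) {
    set.seed(seed + 1000L * i)
    k <- sample(n_lesions, 1)
    fov <- (c(64, 64, 48) - 1) * c(2.7344, 2.7344, 3.27)
    cx <- fov[1] / 2; cy <- fov[2] / 2
    zs <- seq(20, fov[3] - 20, length.out = k)
    lesions <- lapply(seq_len(k), function(j) {
      list(centre = c(cx + stats::runif(1, -4, 4),
                      cy + stats::runif(1, -4, 4), zs[j]),
           radius = sample(radii, 1),
           suv = sample(plateaus, 1), inside_bone = TRUE)
    })
    generate_phantom(phantom_spec(lesions = lesions, seed = seed + i, ...))
  })
}
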