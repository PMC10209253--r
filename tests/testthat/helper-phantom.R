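# Shared fixture builders.  Everything is generated in code; no binary
# fixtures on disk.

# uniform-valued volume on a simple grid
make_volume <- function(dims = c(8, 8, 4), value = 0, units = "HU",
                        spacing = c(2, 2, 3), origin = c(0, 0, 0)) {
  volume_image(array(value, dim = dims), spacing = spacing, origin = origin,
               units = units)
}

# binary mask from 0-based voxel index triples on the grid of `like`
mask_from_indices <- function(idx, like) {
  m <- array(0L, dim = dim(like$data))
  if (nrow(idx)) m[idx + 1L] <- 1L
  binary_mask(m, like)
}

default_factors <- function() suv_factors(3.7e8, 6586.2, 36000, 39600, 70)

# small, fast phantom: 32 x 32 x 24 PET grid, two well-separated lesions
small_spec <- function(seed = 1, lesion_suvs = c(4, 6),
                       radii = c(6, 7), suv_noise_sd = 0.1, ...) {
  dims <- c(32, 32, 24)
  sp <- c(2.7344, 2.7344, 3.27)
  fov <- (dims - 1) * sp
  cx <- fov[1] / 2; cy <- fov[2] / 2
  zs <- seq(fov[3] * 0.25, fov[3] * 0.75, length.out = length(lesion_suvs))
  lesions <- lapply(seq_along(lesion_suvs), function(i)
    list(centre = c(cx, cy, zs[i]), radius = radii[i],
         suv = lesion_suvs[i], inside_bone = TRUE))
  phantom_spec(pet_dim = dims, pet_spacing = sp,
               organs = list(list(name = "bladder",
                                  centre = c(cx, cy - 28, fov[3] / 2),
                                  radius = 8, suv = 8)),
               lesions = lesions, seed = seed,
               suv_noise_sd = suv_noise_sd, ...)
}
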