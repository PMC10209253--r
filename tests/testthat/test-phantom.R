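test_that("phantom generation is deterministic and validates its spec", {
  s <- small_spec(seed = 17)
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  expect_identical(a$ct$data, b$ct$data)
  expect_identical(a$pet$data, b$pet$data)
  expect_identical(a$truth_labels$data, b$truth_labels$data)
  # a lesion outside the grid is a spec error
  expect_error(phantom_spec(lesions = list(list(
    centre = c(-10, 0, 0), radius = 5, suv = 4, inside_bone = FALSE))),
    "outside grid")
  expect_error(phantom_spec(lesions = list(list(
    centre = c(50, 50, 50), radius = 0, suv = 4, inside_bone = FALSE))),
    "radii")
  # an inside-bone lesion far from the skeleton is caught geometrically
  bad <- phantom_spec(lesions = list(list(centre = c(10, 10, 70),
                                          radius = 4, suv = 4,
                                          inside_bone = TRUE)))
  expect_error(generate_phantom(bad), "outside the skeleton")
})

test_that("zero lesions give a background-only phantom", {
  s <- phantom_spec(lesions = list(), organs = list(), seed = 2,
                    suv_noise_sd = 0, hu_noise_sd = 0)
  ph <- generate_phantom(s)
  expect_true(all(ph$truth_labels$data == 0))
  expect_equal(nrow(ph$truth_stats), 0)
  suv <- to_suv_map(ph$pet, ph$factors)
  expect_lte(max(suv$data), ph$spec$background_suv + 1e-9)
})

test_that("phantom CT holds the stated tissue HU classes", {
  ph <- generate_phantom(small_spec(seed = 8, hu_noise_sd = 0))
  expect_equal(min(ph$ct$data), -1000)           # air
  expect_true(any(abs(ph$ct$data - 40) < 1e-9))  # soft tissue
  expect_true(any(abs(ph$ct$data - 50) < 1e-9))  # marrow
  expect_true(any(ph$ct$data >= 300))            # cortical bone
})

test_that("voxelised lesion volume approaches the analytic sphere volume", {
  sp <- c(2.7344, 2.7344, 3.27)
  fov <- (c(64, 64, 48) - 1) * sp
  r <- 8
  s <- phantom_spec(lesions = list(list(centre = fov / 2, radius = r,
                                        suv = 5, inside_bone = TRUE)),
                    seed = 4)
  ph <- generate_phantom(s)
  analytic_ml <- 4 / 3 * pi * r^3 / 1000
  expect_lt(abs(ph$truth_stats$volume_ml - analytic_ml) / analytic_ml, 0.15)
  expect_equal(ph$truth_stats$suv_max, 5)
  expect_equal(ph$truth_stats$suv_mean, 5)       # uniform plateau, no noise
})

test_that("SUV conversion of the generated PET recovers planted uptake", {
  ph <- generate_phantom(small_spec(seed = 9, suv_noise_sd = 0))
  suv <- to_suv_map(ph$pet, ph$factors)
  expect_equal(suv$data, ph$suv_true$data, tolerance = 1e-12)
  # with mild noise the lesion count is unchanged (sigma << plateau - th)
  phn <- generate_phantom(small_spec(seed = 9, suv_noise_sd = 0.1))
  for (p in list(ph, phn)) {
    case <- phantom_case(p)
    labs <- segment_lesions(apply_bone_mask(case$suv, case$bone), 3.0)
    expect_equal(attr(labs, "n_lesions"), 2L)
  }
})

test_that("full pipeline on the phantom recovers every planted lesion", {
  ph <- generate_phantom(small_spec(seed = 23))
  case <- phantom_case(ph)
  masked <- apply_bone_mask(case$suv, case$bone)
  labs <- segment_lesions(masked, 3.0)
  st <- quantify_lesions(labs, case$suv)
  truth <- ph$truth_stats
  expect_equal(nrow(st), nrow(truth))
  m <- match_lesions(st, truth)
  expect_equal(nrow(m$pairs), nrow(truth))
  # volumes agree within one boundary-voxel shell
  ia <- match(m$pairs$auto_label, st$label)
  ir <- match(m$pairs$ref_label, truth$label)
  shell <- truth$n_voxels[ir]^(2 / 3) * 4  # ~surface voxel count
  expect_true(all(abs(st$n_voxels[ia] - truth$n_voxels[ir]) <= shell))
})

test_that("RTSTRUCT export of a phantom lesion re-rasterises to DSC >= 0.95", {
  ph <- generate_phantom(small_spec(seed = 12))
  lab <- rasterise_contours(ph$contours, ph$suv_true)
  for (k in seq_along(ph$spec$lesions)) {
    dsc <- dice(binary_mask(lab$data == k, ph$suv_true),
                lesion_mask(ph$truth_labels, k))
    expect_gte(dsc, 0.95)
  }
})

test_that("phantom cohort varies lesion load and stays reproducible", {
  co <- phantom_cohort(3, seed = 100)
  co2 <- phantom_cohort(3, seed = 100)
  for (i in 1:3)
    expect_identical(co[[i]]$pet$data, co2[[i]]$pet$data)
  counts <- vapply(co, function(p) nrow(p$truth_stats), numeric(1))
  expect_true(all(counts >= 2 & counts <= 4))
})
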