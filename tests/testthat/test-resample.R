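make_ct_pet_pair <- function(nct = 16, npet = 8, nz = 4, value = NULL) {
  sp_pet <- c(2, 2, 3)
  sp_ct <- sp_pet * c(npet / nct, npet / nct, 1)
  oc <- c(-sp_pet[1] / 2 + sp_ct[1] / 2, -sp_pet[2] / 2 + sp_ct[2] / 2, 0)
  dat <- if (is.null(value)) array(0, c(nct, nct, nz)) else
    array(value, c(nct, nct, nz))
  list(ct = volume_image(dat, spacing = sp_ct, origin = oc, units = "HU"),
       pet = volume_image(array(0, c(npet, npet, nz)), spacing = sp_pet,
                          units = "BQML"))
}

test_that("a constant image resamples to the same constant", {
  pair <- make_ct_pet_pair(value = 100)
  for (mode in c("physical", "matrix")) {
    out <- resample_ct_to_pet_grid(pair$ct, pair$pet, mode = mode)
    expect_equal(dim(out$data), dim(pair$pet$data))
    expect_equal(unique(round(as.vector(out$data), 9)), 100)
    expect_identical(out$units, "HU")
  }
})

test_that("identity grids pass values through unchanged", {
  set.seed(9)
  ct <- volume_image(array(rnorm(8 * 8 * 4, 0, 300), c(8, 8, 4)),
                     spacing = c(2, 2, 3), units = "HU")
  pet <- volume_image(array(0, c(8, 8, 4)), spacing = c(2, 2, 3),
                      units = "BQML")
  out <- resample_ct_to_pet_grid(ct, pet, clamp = FALSE)
  expect_equal(out$data, ct$data, tolerance = 1e-9)
  out_m <- resample_ct_to_pet_grid(ct, pet, mode = "matrix", clamp = FALSE)
  expect_equal(out_m$data, ct$data, tolerance = 1e-9)
})

test_that("checkerboard downsampling stays within input range when clamped", {
  pair <- make_ct_pet_pair(nct = 32, npet = 8, nz = 3)
  chk <- outer(1:32, 1:32, function(i, j) ifelse((i + j) %% 2 == 0, 1000, -1000))
  ct <- pair$ct; ct$data <- array(rep(chk, 3), dim = c(32, 32, 3))
  out <- resample_ct_to_pet_grid(ct, pair$pet, clamp = TRUE)
  expect_gte(min(out$data), -1000)
  expect_lte(max(out$data), 1000)
  # cross-check bicubic against an independent 1-D reference on a ramp:
  # cubic convolution reproduces linear ramps exactly (order-3 kernel)
  ramp <- array(rep(seq(0, 310, length.out = 32), times = 32 * 3),
                dim = c(32, 32, 3))
  ct$data <- ramp
  out2 <- resample_ct_to_pet_grid(ct, pair$pet, clamp = FALSE)
  xs_pet <- (0:7) * 2                                # physical x of PET voxels
  xs_ct <- ct$origin[1] + (0:31) * ct$spacing[1]
  expected <- approx(xs_ct, seq(0, 310, length.out = 32), xout = xs_pet,
                     rule = 2)$y
  expect_equal(out2$data[, 4, 2], expected, tolerance = 1e-6)
})

test_that("z-count mismatch triggers linear z interpolation", {
  sp_pet <- c(2, 2, 3)
  ct <- volume_image(array(rep(c(0, 100, 200, 300), each = 16),
                           dim = c(4, 4, 4)),
                     spacing = c(2, 2, 1.5), origin = c(0, 0, 0),
                     units = "HU")
  pet <- volume_image(array(0, c(4, 4, 2)), spacing = c(2, 2, 3),
                      origin = c(0, 0, 0), units = "BQML")
  out <- resample_ct_to_pet_grid(ct, pet)
  # PET slices at z = 0, 3 mm; CT slices at 0, 1.5, 3, 4.5 -> values 0, 200
  expect_equal(unique(round(as.vector(out$data[, , 1]), 6)), 0)
  expect_equal(unique(round(as.vector(out$data[, , 2]), 6)), 200)
})

test_that("out-of-field voxels are filled with air", {
  ct <- volume_image(array(500, c(4, 4, 2)), spacing = c(1, 1, 3),
                     origin = c(0, 0, 0), units = "HU")
  pet <- volume_image(array(0, c(8, 8, 2)), spacing = c(1, 1, 3),
                      origin = c(0, 0, 0), units = "BQML")
  out <- resample_ct_to_pet_grid(ct, pet)
  expect_equal(out$data[8, 8, 1], -1000)
  expect_equal(out$data[2, 2, 1], 500)
})
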