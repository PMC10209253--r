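# geometry helpers on a 24^3-ish grid with 2 mm voxels
grid_coords <- function(d, sp = c(2, 2, 2)) {
  list(x = (seq_len(d[1]) - 1) * sp[1], y = (seq_len(d[2]) - 1) * sp[2],
       z = (seq_len(d[3]) - 1) * sp[3])
}

test_that("an ellipsoid of bone-like HU is recovered (DSC >= 0.9)", {
  d <- c(24, 24, 16); sp <- c(2, 2, 2)
  co <- grid_coords(d, sp)
  inside <- outer(outer(((co$x - 23) / 14)^2, ((co$y - 23) / 10)^2, "+"),
                  ((co$z - 15) / 8)^2, "+") <= 1
  hu <- array(-1000, d); hu[inside] <- 400
  ct <- volume_image(hu, spacing = sp, units = "HU")
  mask <- segment_bone(ct, hu_threshold = 110)
  truth <- binary_mask(inside, ct)
  expect_gte(dice(mask, truth), 0.9)
})

test_that("hole filling claims the marrow cavity of a hollow cylinder", {
  d <- c(24, 24, 8); sp <- c(2, 2, 3)
  co <- grid_coords(d, sp)
  r2 <- outer((co$x - 23)^2, (co$y - 23)^2, "+")
  shell <- r2 <= 16^2 & r2 > 9^2
  lumen <- r2 <= 9^2
  hu <- array(-1000, d)
  hu[array(rep(shell, d[3]), d)] <- 700    # cortical shell
  hu[array(rep(lumen, d[3]), d)] <- 50     # marrow below threshold
  ct <- volume_image(hu, spacing = sp, units = "HU")
  mask <- segment_bone(ct, hu_threshold = 110, fill = "2d")
  lumen_idx <- which(array(rep(lumen, d[3]), d))
  expect_true(all(mask$data[lumen_idx] == 1))
  # without filling, the deep lumen interior stays out
  open_mask <- segment_bone(ct, hu_threshold = 110, fill = "none")
  deep_idx <- which(array(rep(r2 <= 6^2, d[3]), d))
  expect_true(all(open_mask$data[deep_idx] == 0))
  # filling never removes voxels
  expect_true(all(mask$data >= open_mask$data))
})

test_that("all-soft-tissue volumes give an empty mask; sigma is validated", {
  ct <- make_volume(c(10, 10, 6), value = 40, units = "HU")
  expect_equal(sum(segment_bone(ct)$data), 0)
  expect_error(segment_bone(ct, sigma_mm = -1), "sigma")
})

test_that("mask is monotone in the HU threshold before hole filling", {
  set.seed(21)
  ct <- volume_image(array(rnorm(12 * 12 * 6, 100, 300), c(12, 12, 6)),
                     spacing = c(2, 2, 3), units = "HU")
  ths <- c(90, 150, 210, 300)
  masks <- lapply(ths, function(t)
    segment_bone(ct, hu_threshold = t, fill = "none"))
  for (i in seq_len(length(ths) - 1)) {
    expect_true(all(masks[[i + 1]]$data <= masks[[i]]$data))
  }
})

test_that("apply_bone_mask zeroes everything outside bone and is idempotent", {
  suv <- volume_image(array(runif(8 * 8 * 4, 0, 10), c(8, 8, 4)),
                      spacing = c(2, 2, 3), units = "SUV_BW")
  m <- array(0L, c(8, 8, 4)); m[3:5, 3:5, 2:3] <- 1L
  bone <- binary_mask(m, suv)
  out <- apply_bone_mask(suv, bone)
  expect_true(all(out$data[m == 0L] == 0))
  expect_equal(out$data[m == 1L], suv$data[m == 1L])
  expect_equal(apply_bone_mask(out, bone)$data, out$data)   # idempotent
  ones <- binary_mask(array(1L, c(8, 8, 4)), suv)
  expect_equal(apply_bone_mask(suv, ones)$data, suv$data)   # identity
  wrong <- make_volume(c(4, 4, 4), units = "BINARY")
  expect_error(apply_bone_mask(suv, wrong), "geometry error")
})

test_that("a hot sphere outside bone never survives masking", {
  ph <- generate_phantom(small_spec(seed = 5))
  case <- phantom_case(ph)
  masked <- apply_bone_mask(case$suv, case$bone)
  labs <- segment_lesions(masked, 3.0)
  # only the two planted osseous lesions remain; the SUV-8 bladder is gone
  expect_equal(attr(labs, "n_lesions"), 2L)
})
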