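suv_vol <- function(data, sp = c(2.7344, 2.7344, 3.27)) {
  volume_image(data, spacing = sp, units = "SUV_BW")
}

test_that("thresholding is inclusive and strict below", {
  v <- suv_vol(array(2.9, c(6, 6, 4)))
  expect_equal(attr(segment_lesions(v, 3.0), "n_lesions"), 0L)
  v2 <- suv_vol(array(3.0, c(6, 6, 4)))
  expect_equal(attr(segment_lesions(v2, 3.0), "n_lesions"), 1L)
  expect_error(segment_lesions(v, -1), "suv_threshold")
})

test_that("disjoint hot blocks become labels ordered by size", {
  a <- array(0, c(12, 12, 4))
  a[2:3, 2:3, 2] <- 5         # 4 voxels
  a[8:11, 8:11, 2:3] <- 4     # 32 voxels
  labs <- segment_lesions(suv_vol(a), 3.0)
  expect_equal(attr(labs, "n_lesions"), 2L)
  expect_equal(sum(labs$data == 1), 32)   # label 1 = largest
  expect_equal(sum(labs$data == 2), 4)
  # min_voxels filter removes the small one and relabels contiguously
  labs2 <- segment_lesions(suv_vol(a), 3.0, min_voxels = 10)
  expect_equal(attr(labs2, "n_lesions"), 1L)
  expect_equal(sort(unique(as.vector(labs2$data))), c(0L, 1L))
})

test_that("connectivity 26 merges diagonal contact, 6 does not", {
  a <- array(0, c(6, 6, 4))
  a[2, 2, 2] <- 5
  a[3, 3, 3] <- 5           # corner-touching voxel
  expect_equal(attr(segment_lesions(suv_vol(a), 3, connectivity = 26),
                    "n_lesions"), 1L)
  expect_equal(attr(segment_lesions(suv_vol(a), 3, connectivity = 6),
                    "n_lesions"), 2L)
})

test_that("quantification reproduces the clinical voxel volume", {
  # 10 voxels on the clinical PET grid -> 10 * 0.02445 ml
  a <- array(0, c(8, 8, 4)); a[2:6, 3, 2] <- 4; a[2:6, 4, 2] <- 4
  labs <- segment_lesions(suv_vol(a), 3.0)
  st <- quantify_lesions(labs, suv_vol(a))
  expect_equal(st$n_voxels, 10)
  expect_equal(st$volume_ml, 10 * 0.02445, tolerance = 2e-4)
  expect_equal(st$suv_mean, 4)            # uniform lesion
  expect_equal(st$suv_max, 4)
})

test_that("suv_mean matches brute-force summation and ties break low", {
  a <- array(0, c(8, 8, 4))
  vals <- c(2, 3, 4, 5)
  a[3, 3, 2] <- 2; a[4, 3, 2] <- 3; a[3, 4, 2] <- 4; a[4, 4, 2] <- 5
  labs <- segment_lesions(suv_vol(a), 2.0)
  st <- quantify_lesions(labs, suv_vol(a))
  # oracle: direct summation over the labelled voxels
  idx <- which(labs$data == 1)
  expect_equal(st$suv_mean, sum(a[idx]) / length(idx))
  expect_equal(st$suv_mean, mean(vals))
  expect_equal(st$suv_max, 5)
  expect_equal(c(st$max_x, st$max_y, st$max_z), c(3, 3, 1))  # 0-based
  # SUVmax tie inside one lesion: lowest linear (column-major) index wins
  b <- array(0, c(8, 8, 4)); b[5:6, 5, 2] <- 7
  lb <- segment_lesions(suv_vol(b), 3, connectivity = 26)
  stb <- quantify_lesions(lb, suv_vol(b))
  expect_equal(c(stb$max_x, stb$max_y, stb$max_z), c(4, 4, 1))
  # empty label map -> empty frame, not an error
  expect_equal(nrow(quantify_lesions(segment_lesions(suv_vol(array(0, c(4, 4, 2))), 3),
                                     suv_vol(array(0, c(4, 4, 2))))), 0)
})

test_that("raising the threshold shrinks lesions monotonically", {
  ph <- generate_phantom(small_spec(seed = 13, lesion_suvs = c(3.5, 5.5)))
  case <- phantom_case(ph)
  masked <- apply_bone_mask(case$suv, case$bone)
  prev <- NULL
  for (th in c(2, 3, 4, 5, 6)) {
    m <- segment_lesions(masked, th)$data > 0
    if (!is.null(prev)) expect_true(all(m <= prev))
    prev <- m
  }
  # sum of per-lesion volumes = voxel volume * labelled voxel count
  labs <- segment_lesions(masked, 3.0)
  st <- quantify_lesions(labs, case$suv)
  expect_equal(sum(st$volume_ml),
               voxel_volume_ml(labs) * sum(labs$data > 0))
})
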