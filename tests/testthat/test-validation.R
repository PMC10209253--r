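fake_stats <- function(suv_max, x, y = 0, z = 0, volume = 1, mean = NULL) {
  data.frame(label = seq_along(suv_max), n_voxels = 10,
             volume_ml = rep(volume, length.out = length(suv_max)),
             suv_mean = if (is.null(mean)) suv_max * 0.8 else mean,
             suv_max = suv_max,
             max_x = 0, max_y = 0, max_z = 0,
             max_x_mm = x, max_y_mm = rep(y, length.out = length(suv_max)),
             max_z_mm = rep(z, length.out = length(suv_max)))
}

test_that("identical lesion lists match perfectly at zero cost", {
  a <- fake_stats(c(4, 5, 6), x = c(0, 40, 80))
  m <- match_lesions(a, a)
  expect_equal(nrow(m$pairs), 3)
  expect_equal(m$pairs$cost, rep(0, 3))
  expect_equal(m$pairs$auto_label, m$pairs$ref_label)
  expect_equal(nrow(m$unmatched_auto), 0)
  expect_equal(nrow(m$unmatched_ref), 0)
})

test_that("cost ties break to the lower reference label", {
  auto <- fake_stats(5, x = 10)
  ref <- fake_stats(c(5, 5), x = c(0, 20))   # equidistant, equal SUVmax
  m <- match_lesions(auto, ref)
  expect_equal(m$pairs$ref_label, 1)
  expect_equal(m$unmatched_ref$label, 2)
})

test_that("matching respects the distance gate and input order", {
  auto <- fake_stats(c(4, 6), x = c(0, 100))
  ref <- fake_stats(c(4.1, 6.2), x = c(2, 130))   # second is 30 mm away
  m <- match_lesions(auto, ref, max_distance_mm = 20)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$auto_label, 1)
  expect_equal(m$unmatched_auto$label, 2)
  expect_equal(m$unmatched_ref$label, 2)
  # permuting rows changes nothing (labels sorted internally)
  m2 <- match_lesions(auto[2:1, ], ref[2:1, ], max_distance_mm = 20)
  expect_equal(m2$pairs, m$pairs)
  # empty inputs give empty outputs
  e <- match_lesions(auto[0, ], ref)
  expect_equal(nrow(e$pairs), 0)
  expect_equal(nrow(e$unmatched_ref), 2)
})

test_that("voxel confusion equals brute-force set arithmetic", {
  grid <- make_volume(c(6, 6, 4), units = "SUV_BW")
  set.seed(31)
  for (trial in 1:25) {
    av <- array(runif(144) < 0.3, c(6, 6, 4))
    rv <- array(runif(144) < 0.3, c(6, 6, 4))
    dv <- array(runif(144) < 0.7, c(6, 6, 4))
    cf <- voxel_confusion(binary_mask(av, grid), binary_mask(rv, grid),
                          binary_mask(dv, grid))
    # oracle: explicit voxel-by-voxel loop
    tp <- tn <- fp <- fn <- 0L
    for (i in seq_along(av)) {
      if (!dv[i]) next
      if (av[i] && rv[i]) tp <- tp + 1L
      else if (av[i] && !rv[i]) fp <- fp + 1L
      else if (!av[i] && rv[i]) fn <- fn + 1L
      else tn <- tn + 1L
    }
    expect_identical(c(cf$tp, cf$tn, cf$fp, cf$fn), c(tp, tn, fp, fn))
    expect_equal(cf$tp + cf$tn + cf$fp + cf$fn, sum(dv))
  }
})

test_that("confusion edge cases follow the contracts", {
  grid <- make_volume(c(4, 4, 2), units = "SUV_BW")
  a <- binary_mask(array(c(rep(1, 8), rep(0, 24)), c(4, 4, 2)), grid)
  cf <- voxel_confusion(a, a)
  expect_equal(cf$fp + cf$fn, 0)
  expect_equal(cf$sensitivity, 1)
  expect_equal(cf$specificity, 1)
  none <- binary_mask(array(0, c(4, 4, 2)), grid)
  cf2 <- voxel_confusion(none, a)
  expect_equal(cf2$sensitivity, 0)
  expect_equal(cf2$specificity, 1)
  expect_error(voxel_confusion(a, make_volume(c(3, 3, 2), units = "BINARY")),
               "geometry error")
})

test_that("dice follows hand counts and the Jaccard identity", {
  grid <- make_volume(c(6, 6, 4), units = "SUV_BW")
  a <- array(0, c(6, 6, 4)); b <- array(0, c(6, 6, 4))
  a[1:8] <- 1; b[3:10] <- 1                  # |A|=8, |B|=8, |A&B|=6
  ma <- binary_mask(a, grid); mb <- binary_mask(b, grid)
  expect_equal(dice(ma, mb), 12 / 16)
  expect_equal(dice(ma, ma), 1)
  z <- binary_mask(array(0, c(6, 6, 4)), grid)
  expect_equal(dice(ma, z), 0)
  expect_equal(dice(z, z), 1)                # both-empty convention
  set.seed(7)
  for (i in 1:10) {
    av <- array(runif(144) < 0.4, c(6, 6, 4))
    rv <- array(runif(144) < 0.4, c(6, 6, 4))
    dsc <- dice(binary_mask(av, grid), binary_mask(rv, grid))
    jac <- sum(av & rv) / max(1, sum(av | rv))
    expect_equal(dsc, 2 * jac / (1 + jac), tolerance = 1e-12)
    expect_gte(dsc, 0); expect_lte(dsc, 1)
  }
})

test_that("concordance_r matches the textbook formula and rejects degeneracy", {
  x <- c(1, 2, 4, 7, 11); y <- c(2.2, 2.9, 5.4, 6.8, 12.1)
  # oracle: explicit sum formula
  n <- length(x)
  r_hand <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(concordance_r(x, y), r_hand, tolerance = 1e-12)
  expect_equal(concordance_r(x, 2 * x + 1), 1)
  expect_equal(concordance_r(x, -x), -1)
  expect_error(concordance_r(1, 2), "at least 2")
  expect_error(concordance_r(c(1, 1), c(1, 2)), "zero variance")
  expect_error(concordance_r(1:3, 1:4), "equal length")
})

test_that("threshold sweep pools metrics and behaves monotonically", {
  cohort <- lapply(1:2, function(i)
    phantom_case(generate_phantom(
      small_spec(seed = 40 + i, lesion_suvs = c(3.2, 5), radii = c(6, 7)))))
  sw <- sweep_thresholds(cohort, thresholds = c(2, 2.5, 3, 3.5, 4, 6))
  m <- sw$metrics
  expect_true(all(diff(m$sensitivity) <= 1e-12))   # non-increasing
  expect_true(all(m$sensitivity >= 0 & m$sensitivity <= 1))
  expect_true(all(m$specificity >= 0 & m$specificity <= 1))
  # uniform plateaus: thresholds below every plateau give identical metrics
  expect_equal(m$sensitivity[1], m$sensitivity[2], tolerance = 1e-12)
  # optimum <= 3.2 because higher thresholds lose the 3.2 plateau entirely
  opt <- select_optimum_threshold(sw)
  expect_lte(opt$threshold, 3.2)
  expect_named(opt$report,
               c("threshold", "sensitivity", "one_minus_specificity",
                 "youden", "dsc_median"))
  expect_error(sweep_thresholds(cohort, thresholds = numeric(0)),
               "empty threshold")
  expect_error(sweep_thresholds(cohort, thresholds = c(3, 2)),
               "strictly increasing")
  expect_error(sweep_thresholds(list(), thresholds = 3), "one case")
})

test_that("optimum selection follows argmax and documented tie-breaks", {
  mk <- function(th, sens, spec, dscm) {
    structure(list(thresholds = th,
                   metrics = data.frame(threshold = th, sensitivity = sens,
                                        specificity = spec,
                                        dsc_median = dscm,
                                        dsc_iqr = 0, volume_r = 1,
                                        suvmean_r = 1, n_auto = 1,
                                        n_matched = 1),
                   dsc = rep(list(numeric(0)), length(th))),
              class = "sweep_result")
  }
  s1 <- mk(c(2, 3, 4), c(0.9, 0.8, 0.4), c(0.8, 1.0, 1.0), c(0.5, 0.7, 0.6))
  expect_equal(select_optimum_threshold(s1)$threshold, 3)  # strict peak
  s2 <- mk(c(2, 3), c(0.9, 0.9), c(0.9, 0.9), c(0.5, 0.8))
  expect_equal(select_optimum_threshold(s2)$threshold, 3)  # DSC tie-break
  s3 <- mk(c(2, 3), c(0.9, 0.9), c(0.9, 0.9), c(0.6, 0.6))
  expect_equal(select_optimum_threshold(s3)$threshold, 2)  # lower threshold
})

test_that("patient report mirrors per-case performance", {
  ph <- generate_phantom(small_spec(seed = 55, lesion_suvs = c(4, 6)))
  case <- phantom_case(ph)
  rep1 <- patient_report(list(case), threshold = 3.0)
  tab <- rep1$table
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n_ref, 2)
  expect_equal(tab$n_auto, 2)
  expect_equal(tab$sensitivity_pct, 100)
  expect_equal(tab$specificity_pct, 100)
  expect_equal(tab$dsc_median, 1)
  expect_equal(tab$volume_r, 1)
  # single-lesion patient: correlation undefined, reported as NA
  ph1 <- generate_phantom(small_spec(seed = 56, lesion_suvs = 5,
                                     radii = 6))
  rep2 <- patient_report(list(phantom_case(ph1)), threshold = 3.0)
  expect_true(is.na(rep2$table$volume_r))
  # cohort row count and pooled lesion-count correlation
  cohort <- lapply(c(57, 58, 59), function(s) phantom_case(
    generate_phantom(small_spec(seed = s,
                                lesion_suvs = if (s %% 2) c(4, 6) else 5,
                                radii = if (s %% 2) c(6, 7) else 6))))
  rep3 <- patient_report(cohort, threshold = 3.0)
  expect_equal(nrow(rep3$table), 3)
  expect_equal(rep3$lesion_count_r, 1)
})

test_that("unmatched lesions feed the audit report", {
  ph <- generate_phantom(small_spec(seed = 60, lesion_suvs = c(2.2, 6)))
  case <- phantom_case(ph)
  masked <- apply_bone_mask(case$suv, case$bone)
  auto <- quantify_lesions(segment_lesions(masked, 3.0), case$suv)
  ref <- quantify_lesions(case$ref_labels, case$suv)
  m <- match_lesions(auto, ref)
  aud <- unmatched_report(m)
  # the SUV-2.2 lesion is below threshold: undetected, ref-only
  expect_equal(aud$side, "ref_only")
  expect_equal(nrow(aud), 1)
  expect_lt(aud$suv_mean, 3.0)
})
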