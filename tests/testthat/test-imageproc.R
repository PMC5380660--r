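test_that("per-slice correction inverts a known exponential decay", {
  base <- array(50 + 10 * runif(16 * 16 * 24), c(16, 16, 24))
  vol0 <- image_volume(base, c(1, 1, 1), depth_axis = 3)
  decayed <- sweep(base, 3, exp(-(0:23) / 30), `*`)
  vol <- image_volume(decayed, c(1, 1, 1), depth_axis = 3)
  corr <- correct_attenuation(vol)
  means <- apply(corr$intensity, 3, mean)
  expect_equal(means / means[1], rep(1, 24), tolerance = 1e-6)
  expect_true(all(corr$intensity >= 0))
})

test_that("an already-flat volume passes through unchanged", {
  vol <- image_volume(array(7, c(8, 8, 8)), c(1, 1, 1))
  expect_equal(correct_attenuation(vol)$intensity, vol$intensity,
               tolerance = 1e-12)
  expect_equal(correct_attenuation(vol, "exponential")$intensity,
               vol$intensity, tolerance = 1e-12)
})

test_that("attenuation correction rejects volumes with an all-zero slice", {
  arr <- array(1, c(8, 8, 8))
  arr[, , 4] <- 0
  expect_error(correct_attenuation(image_volume(arr, c(1, 1, 1))),
               "all-zero")
})

test_that("correction flattens the depth profile of a rendered volume", {
  m <- small_preset_micro("baseline", seed = 4, n = 32, spacing = 1)
  vol <- render_confocal(m, confocal_params(attenuation_length = 40,
                                            noise_sd = 5, seed = 2))
  corr <- correct_attenuation(vol)
  # < 1% of the mean intensity per 10 um
  expect_lt(abs(attenuation_profile(corr)$relative_slope) * 10, 0.01)
})

test_that("zero rotation only relabels axes", {
  vol <- image_volume(array(runif(8^3), c(8, 8, 8)), c(1, 1, 1),
                      axes = c("z", "r", "theta"))
  out <- rotate_to_cylindrical(vol, c(0, 0, 0))
  expect_identical(out$intensity, vol$intensity)
  expect_identical(out$axes, c("r", "z", "theta"))
})

test_that("quarter turns are lattice exact and invertible", {
  vol <- image_volume(array(runif(10 * 12 * 14), c(10, 12, 14)), c(1, 1, 1))
  r <- vol
  for (i in 1:4) r <- rotate_to_cylindrical(r, c(0, 0, 90))
  expect_identical(r$intensity, vol$intensity)
  once <- rotate_to_cylindrical(vol, c(0, 90, 0))
  back <- rotate_to_cylindrical(once, c(0, 270, 0))
  expect_identical(back$intensity, vol$intensity)
  expect_identical(sort(as.vector(once$intensity)),
                   sort(as.vector(vol$intensity)))
})

test_that("small rotations round trip within interpolation tolerance", {
  g <- expand.grid(i = 1:32, j = 1:32, k = 1:32)
  sm <- array(exp(-((g$i - 16)^2 + (g$j - 18)^2 + (g$k - 14)^2) / 60),
              c(32, 32, 32))
  vol <- image_volume(sm, c(1, 1, 1))
  rot <- rotate_to_cylindrical(vol, c(5, -7, 3))
  back <- rotate_to_cylindrical(rot, c(-5, 7, -3), order = 3:1)
  interior <- abs(back$intensity - sm)[8:24, 8:24, 8:24]
  expect_lt(max(interior), 0.02 * diff(range(sm)))
  expect_lt(abs(sum(rot$intensity) / sum(sm) - 1), 0.01)
})

test_that("noiseless rendered volumes threshold back to the exact mask", {
  m <- small_preset_micro("baseline", seed = 8, n = 16, spacing = 1)
  vol <- render_confocal(m, confocal_params(attenuation_length = Inf,
                                            noise_sd = 0, blur_sigma = 0))
  rec <- threshold_volume(vol)
  expect_identical(rec$mask, m$mask)
  recf <- threshold_volume(vol, "fixed", value = 60)
  expect_identical(recf$mask, m$mask)
  expect_identical(recf$threshold_used, 60)
})

test_that("thresholding a noisy render agrees with the generating mask", {
  m <- generate_microstructure(preset_params("baseline", seed = 6))
  # noise at 10% of the intensity gap
  vol <- render_confocal(m, confocal_params(attenuation_length = Inf,
                                            noise_sd = 8, blur_sigma = 0.3,
                                            seed = 3))
  rec <- threshold_volume(vol)
  expect_gte(mean(rec$mask == m$mask), 0.97)
})

test_that("phi is insensitive to plausible manual threshold shifts", {
  m <- generate_microstructure(preset_params("baseline", seed = 9))
  vol <- render_confocal(m, confocal_params(attenuation_length = Inf,
                                            noise_sd = 8, blur_sigma = 0.3,
                                            seed = 4))
  auto <- threshold_volume(vol)
  for (shift in c(0.95, 1.05)) {
    shifted <- threshold_volume(vol, "fixed",
                                value = auto$threshold_used * shift)
    expect_lte(abs(phi_ecm(shifted) - phi_ecm(auto)), 0.03)
  }
})

test_that("constant volumes cannot be thresholded", {
  vol <- image_volume(array(5, c(8, 8, 8)), c(1, 1, 1))
  expect_error(threshold_volume(vol), "constant")
})

test_that("ECM fraction is exact integer counting", {
  mask <- array(FALSE, c(10, 10, 10))
  mask[seq_len(400)] <- TRUE
  res <- compute_ecm_fraction(microstructure(mask, c(2, 2, 2)))
  expect_identical(res$phi_ecm, 0.4)
  expect_identical(res$v_ecm, 400 * 8)
  expect_identical(res$v_total, 1000 * 8)
  all_true <- compute_ecm_fraction(
    microstructure(array(TRUE, c(4, 4, 4)), c(1, 1, 1)), baseline_phi = 1)
  expect_identical(all_true$phi_ecm, 1)
  expect_identical(all_true$j_strain, 1)
})

test_that("volumetric strain reproduces the published group ratio", {
  res <- compute_ecm_fraction(
    microstructure(array(c(rep(TRUE, 68), rep(FALSE, 32)), c(100, 2, 2)) ,
                   c(1, 1, 1)), baseline_phi = 0.60)
  expect_equal(res$phi_ecm, 0.68)
  expect_equal(res$j_strain, 0.68 / 0.60, tolerance = 1e-12)
})

test_that("phi is invariant to translation and lattice-exact rotation", {
  m <- small_preset_micro("baseline", seed = 10, n = 16, spacing = 1)
  phi0 <- phi_ecm(m)
  shifted <- microstructure(m$mask[c(9:16, 1:8), , ], m$voxel_spacing)
  expect_identical(phi_ecm(shifted), phi0)
  vol <- image_volume(m$mask * 1, m$voxel_spacing)
  rot <- rotate_to_cylindrical(vol, c(90, 0, 0))
  expect_identical(mean(rot$intensity > 0.5), phi0)
})

test_that("thickness measurement fails without tissue signal", {
  arr <- array(0, c(16, 16, 8))
  arr[4:10, 1:4, ] <- 1   # tissue in only a quarter of the columns
  expect_error(measure_medial_thickness(image_volume(arr, c(1, 1, 1))),
               "no tissue signal")
})
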