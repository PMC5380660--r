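test_that("generated volumes hit the target ECM fraction within the band", {
  for (preset in c("baseline", "constricted")) {
    target <- preset_params(preset)$target_phi_ecm
    for (seed in 1:3) {
      m <- generate_microstructure(preset_params(preset, seed = seed))
      expect_lt(abs(phi_ecm(m) - target), 0.02)
      expect_gt(phi_ecm(m), 0)
      expect_lt(phi_ecm(m), 1)
    }
  }
})

test_that("identical parameters and seed reproduce a bit-identical volume", {
  p <- preset_params("baseline", seed = 42, grid_shape = c(32, 32, 32))
  m1 <- generate_microstructure(p)
  m2 <- generate_microstructure(p)
  expect_identical(m1$mask, m2$mask)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_microstructure(preset_params("baseline", seed = 5,
                                                  grid_shape = c(16, 16, 16))))
  expect_identical(runif(1), before)
})

test_that("zero cells requested yields the all-ECM identity volume", {
  p <- preset_params("baseline", seed = 1, grid_shape = c(16, 16, 16))
  p$max_cells <- 0L
  m <- generate_microstructure(p)
  expect_true(all(m$mask))
  expect_identical(phi_ecm(m), 1)
})

test_that("an unreachable target fraction fails with a clear message", {
  p <- synth_params(grid_shape = c(8, 8, 8), voxel_spacing = c(1, 1, 1),
                    target_phi_ecm = 0.5,
                    cell_semi_axes = c(30, 10, 10), seed = 1)
  expect_error(generate_microstructure(p), "unreachable")
})

test_that("parameter invariants are enforced", {
  expect_error(synth_params(target_phi_ecm = 0), "strictly in")
  expect_error(synth_params(target_phi_ecm = 1), "strictly in")
  expect_error(synth_params(grid_shape = c(4, 64, 64)), ">= 8")
  expect_error(synth_params(cell_semi_axes = c(-1, 2, 2)), "positive")
})

test_that("contraction with identity scales reproduces the baseline", {
  p <- preset_params("baseline")
  ident <- list(long_axis_scale = 1, transverse_scale = 1,
                radial_flattening = 1, thickness_scale = 1)
  expect_equal(apply_contraction(p, ident), p)
})

test_that("the default contraction derives the constricted target fraction", {
  p <- preset_params("baseline")
  pc <- apply_contraction(p)
  expect_gt(pc$target_phi_ecm, p$target_phi_ecm)
  m <- generate_microstructure(pc)
  expect_gt(phi_ecm(m), 0.66)
  expect_lt(phi_ecm(m), 0.70)
})

test_that("contraction rejects scale combinations leaving (0,1)", {
  p <- preset_params("baseline")
  expect_error(
    apply_contraction(p, list(long_axis_scale = 0.9, transverse_scale = 1,
                              radial_flattening = 1, thickness_scale = 1e-3)),
    "out of \\(0, 1\\)")
  expect_error(
    apply_contraction(p, list(long_axis_scale = 1.2, transverse_scale = 1.3,
                              radial_flattening = 1, thickness_scale = 1)),
    "long_axis_scale")
})

test_that("constriction raises phi and lowers the median aspect ratio", {
  for (seed in 1:2) {
    mb <- generate_microstructure(preset_params("baseline", seed = seed))
    mc <- generate_microstructure(preset_params("constricted", seed = seed))
    expect_gt(phi_ecm(mc), phi_ecm(mb))
    expect_lt(segment_smcs(mc)$median_ar, segment_smcs(mb)$median_ar)
  }
})

test_that("slab volumes reproduce their nominal thickness", {
  slab <- generate_slab_volume(30, c(1, 1, 1), c(48, 48, 16))
  expect_equal(measure_medial_thickness(slab)$thickness_T, 30)
  rippled <- generate_slab_volume(20, c(1, 1, 1), c(48, 48, 16),
                                  ripple_amplitude_um = 2)
  expect_lt(abs(measure_medial_thickness(rippled)$thickness_T - 20), 0.5)
})

test_that("preset slab thicknesses reproduce the published ~1.2 ratio", {
  tb <- preset_params("baseline")$thickness_um
  tc <- preset_params("constricted")$thickness_um
  mb <- measure_medial_thickness(
    generate_slab_volume(tb, c(0.5, 0.5, 0.5), c(96, 48, 16)))
  mc <- measure_medial_thickness(
    generate_slab_volume(tc, c(0.5, 0.5, 0.5), c(96, 48, 16)))
  expect_equal(mc$thickness_T / mb$thickness_T, 1.2, tolerance = 0.02)
})
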