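cfg <- solver_config()
darcy_u <- function(g, cfg) cfg$k_ecm * g / cfg$viscosity_mu

test_that("the all-ECM periodic domain reproduces the Darcy limit", {
  m <- cube_inclusion_micro(16, inclusion = FALSE)
  s <- solve_brinkman(m, cfg, "r", gradient_magnitude = 1000)
  expect_equal(mean(s$velocity$r), darcy_u(1000, cfg), tolerance = 1e-6)
  expect_lt(max(abs(s$velocity$z)), 1e-10 * darcy_u(1000, cfg))
  expect_lt(s$diagnostics$divergence_relative, 1e-10)
})

test_that("the fixed-pressure mode reproduces the Darcy limit too", {
  cfgf <- solver_config(bc_mode = "fixed-pressure-faces")
  m <- cube_inclusion_micro(12, inclusion = FALSE)
  s <- solve_brinkman(m, cfgf, "z", gradient_magnitude = 500)
  expect_equal(mean(s$velocity$z), darcy_u(500, cfgf), tolerance = 1e-6)
  expect_lt(s$diagnostics$divergence_relative, 1e-8)
})

test_that("an all-solid domain is penalty suppressed", {
  m_ecm <- cube_inclusion_micro(12, inclusion = FALSE)
  m_solid <- microstructure(array(FALSE, c(12, 12, 12)), c(1, 1, 1))
  u_ecm <- mean(solve_brinkman(m_ecm, cfg, "r", 1000)$velocity$r)
  u_solid <- mean(solve_brinkman(m_solid, cfg, "r", 1000)$velocity$r)
  expect_lt(u_solid, 1e-3 * u_ecm)
})

test_that("velocities inside solid voxels are negligible", {
  m <- cube_inclusion_micro(16)
  s <- solve_brinkman(m, cfg, "r", 1000)
  expect_lt(s$diagnostics$mean_speed_solid,
            1e-3 * s$diagnostics$mean_speed_ecm)
  expect_lt(s$diagnostics$divergence_relative, 1e-9)
})

test_that("the solution is linear in the driving gradient", {
  m <- cube_inclusion_micro(12)
  ops <- brinkman_operators(m, cfg)
  u1 <- sapply(solve_brinkman(m, cfg, "z", 100, ops)$velocity, mean)
  u2 <- sapply(solve_brinkman(m, cfg, "z", 200, ops)$velocity, mean)
  expect_equal(u2, 2 * u1, tolerance = 1e-8)
})

test_that("the penalty is converged: 1e6 to 1e8 changes <u> by < 1%", {
  m <- cube_inclusion_micro(16)
  u6 <- mean(solve_brinkman(m, solver_config(penalty_ratio = 1e6), "r",
                            1000)$velocity$r)
  u8 <- mean(solve_brinkman(m, solver_config(penalty_ratio = 1e8), "r",
                            1000)$velocity$r)
  expect_lt(abs(u8 - u6) / u6, 0.01)
})

test_that("volume averages match an independent voxel-sum oracle", {
  m <- cube_inclusion_micro(12)
  s <- solve_brinkman(m, cfg, "r", 1000)
  hs <- volume_average(s)
  brute <- vapply(s$velocity, function(a) sum(a) / length(a), numeric(1))
  expect_equal(unname(hs$mean_velocity), unname(brute), tolerance = 1e-12)
  expect_identical(unname(hs$mean_pressure_gradient),
                   unname(s$applied_gradient))
})

test_that("flux never increases when an inclusion is added", {
  base <- array(TRUE, c(12, 12, 12))
  one <- base; one[4:7, 4:7, 4:7] <- FALSE
  two <- one; two[8:11, 8:11, 8:11] <- FALSE
  flux <- function(mask) mean(solve_brinkman(
    microstructure(mask, c(1, 1, 1)), cfg, "r", 1000)$velocity$r)
  f0 <- flux(base); f1 <- flux(one); f2 <- flux(two)
  expect_lt(f1, f0)
  expect_lte(f2, f1 * (1 + 1e-10))
})

test_that("an r-z symmetric microstructure gives swap-symmetric averages", {
  set.seed(31)
  half <- array(runif(12^3) > 0.8, c(12, 12, 12))
  mask <- !(half | aperm(half, c(2, 1, 3)))   # symmetric under r <-> z
  if (!phase_percolates(mask, 1)) skip("fixture does not percolate")
  m <- microstructure(mask, c(1, 1, 1))
  ops <- brinkman_operators(m, cfg)
  ur <- sapply(solve_brinkman(m, cfg, "r", 1000, ops)$velocity, mean)
  uz <- sapply(solve_brinkman(m, cfg, "z", 1000, ops)$velocity, mean)
  expect_equal(unname(ur[c("z", "r", "theta")]), unname(uz),
               tolerance = 1e-6)
})

test_that("the cube-inclusion flux self-converges under grid refinement", {
  u_coarse <- mean(solve_brinkman(cube_inclusion_micro(16), cfg, "r",
                                  1000)$velocity$r)
  u_fine <- mean(solve_brinkman(cube_inclusion_micro(32, spacing = 0.5),
                                cfg, "r", 1000)$velocity$r)
  expect_lt(u_fine, darcy_u(1000, cfg))        # strictly below the open flux
  expect_lt(abs(u_coarse - u_fine) / u_fine, 0.05)
})

test_that("a non-percolating pore phase raises a clear error", {
  mask <- array(TRUE, c(12, 12, 12))
  mask[6, , ] <- FALSE                        # wall blocks the r direction
  m <- microstructure(mask, c(1, 1, 1))
  expect_error(solve_brinkman(m, cfg, "r", 1000), "percolating")
  expect_no_error(ignore <- phase_percolates(mask, 2))
})

test_that("solver config invariants are enforced", {
  expect_error(solver_config(penalty_ratio = 10), ">= 1e3")
  expect_error(solver_config(tolerance = 1e-6), "<= 1e-8")
  expect_error(solver_config(k_ecm = 0), "> 0")
})
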