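mu <- 6.913e-4

test_that("wall resistance is the reciprocal of conductance", {
  dec <- decompose_resistance(1e-10, 27.7, 4.33e-18, mu)
  expect_identical(dec$r_wall, 1e10)
})

test_that("medial resistance reproduces the hand-computed group value", {
  # mu * T / K11 with the published group means (1e-18 m^2 scale assumed)
  dec <- decompose_resistance(1e-10, 27.7, 4.33e-18, mu)
  expect_equal(dec$r_med, 6.913e-4 * 27.7e-6 / 4.33e-18, tolerance = 1e-12)
  expect_equal(dec$r_med, 4.422e9, tolerance = 1e-3)
})

test_that("additivity r_wall = r_med + r_int holds to machine precision", {
  set.seed(5)
  lp <- 10^runif(50, -11, -9)
  tum <- runif(50, 15, 45)
  k11 <- 10^runif(50, -18.5, -17.2)
  dec <- suppressWarnings(decompose_resistance(lp, tum, k11, mu))
  expect_equal(dec$r_wall, dec$r_med + dec$r_int, tolerance = 1e-15)
  expect_equal(dec$frac_med + dec$frac_int, rep(1, 50), tolerance = 1e-12)
})

test_that("the decomposition is homogeneous in each input", {
  base <- decompose_resistance(2e-11, 30, 5e-19, mu)
  scaled <- suppressWarnings(list(
    lp = decompose_resistance(2e-11 * 3, 30, 5e-19, mu),
    t = decompose_resistance(2e-11, 30 * 3, 5e-19, mu),
    k = decompose_resistance(2e-11, 30, 5e-19 * 4, mu)))
  expect_equal(scaled$lp$r_wall, base$r_wall / 3, tolerance = 1e-12)
  expect_equal(scaled$t$r_med, base$r_med * 3, tolerance = 1e-12)
  expect_equal(scaled$k$r_med, base$r_med / 4, tolerance = 1e-12)
})

test_that("r_med equal to r_wall gives exactly zero intimal resistance", {
  lp <- 2e-11
  k11 <- mu * 30e-6 * lp
  dec <- suppressWarnings(decompose_resistance(lp, 30, k11, mu))
  expect_equal(dec$r_int, 0, tolerance = 1e-6 * dec$r_wall)
})

test_that("negative intimal resistance is flagged, not clamped", {
  expect_warning(dec <- decompose_resistance(1e-10, 30, 1e-19, mu),
                 "exceeds R_WALL")
  expect_lt(dec$r_int, 0)
})

test_that("invalid inputs are rejected", {
  expect_error(decompose_resistance(0, 30, 1e-18), "positive")
  expect_error(decompose_resistance(1e-10, -3, 1e-18), "positive")
  expect_error(decompose_resistance(1e-10, 30, 0), "positive")
})

test_that("group means and SEMs are exact on a hand-computed fixture", {
  rec <- data.frame(specimen_id = c("a", "b", "c"), condition = "x",
                    v = c(1, 2, 6))
  gs <- summarize_groups(rec, "v")
  expect_identical(gs$summary$mean, 3)
  expect_identical(gs$summary$sem, sd(c(1, 2, 6)) / sqrt(3))
  expect_identical(gs$summary$n, 3L)
})

test_that("published permeability blocks reproduce the printed means", {
  tabs <- load_published_tables()
  perm <- tabs$permeability
  gs <- summarize_groups(perm, "k11", id_col = "block", test = "unpaired")
  m <- setNames(gs$summary$mean, gs$summary$condition)
  expect_equal(round(m[["baseline"]], 2), 4.33)
  expect_equal(round(m[["constricted"]], 2), 6.97)
  expect_lt(gs$tests$p_value, 1e-6)
  # Welch variant agrees that the difference is overwhelming
  gw <- summarize_groups(perm, "k11", id_col = "block", test = "unpaired",
                         var_equal = FALSE)
  expect_lt(gw$tests$p_value, 1e-6)
})

test_that("identical groups give p = 1 under the unpaired test", {
  rec <- data.frame(specimen_id = c("a", "b", "c", "d", "e", "f"),
                    condition = rep(c("x", "y"), each = 3),
                    v = c(1, 2, 3, 1, 2, 3))
  gs <- summarize_groups(rec, "v", test = "unpaired")
  expect_equal(gs$tests$p_value, 1)
})

test_that("pairing with unmatched ids is an error", {
  rec <- data.frame(specimen_id = c("a", "b", "c", "d"),
                    condition = rep(c("x", "y"), each = 2), v = 1:4)
  expect_error(summarize_groups(rec, "v", test = "paired"),
               "do not match")
})

test_that("matched ids trigger the paired test automatically", {
  rec <- data.frame(specimen_id = rep(c("a", "b", "c"), 2),
                    condition = rep(c("x", "y"), each = 3),
                    v = c(1, 2, 3, 2.5, 3.1, 4.2))
  gs <- summarize_groups(rec, "v")
  expect_match(gs$tests$method, "paired")
  expect_equal(gs$tests$p_value,
               t.test(c(1, 2, 3), c(2.5, 3.1, 4.2), paired = TRUE)$p.value)
})

test_that("identity k_ECM scaling reproduces the plain decomposition", {
  rec <- load_demo_specimens()
  sens <- kecm_sensitivity(rec, mu, scalings = 1)
  dec <- decompose_resistance(rec$lp, rec$thickness_um, rec$k11_m2, mu)
  agg <- aggregate(cbind(frac_med, frac_int) ~ condition,
                   cbind(rec["condition"], dec), mean)
  expect_equal(sens$frac_med, agg$frac_med, tolerance = 1e-12)
  expect_equal(sens$frac_int, agg$frac_int, tolerance = 1e-12)
})

test_that("proportional scaling follows the series-resistance algebra", {
  rec <- load_demo_specimens()
  sens <- kecm_sensitivity(rec, mu, scalings = c(1, 1.2))
  base <- sens[sens$scaling == 1, ]
  up <- sens[sens$scaling == 1.2, ]
  dec <- decompose_resistance(rec$lp, rec$thickness_um, rec$k11_m2 * 1.2, mu)
  agg <- aggregate(cbind(frac_med, frac_int) ~ condition,
                   cbind(rec["condition"], dec), mean)
  expect_equal(up$frac_med, agg$frac_med, tolerance = 1e-12)
  expect_true(all(up$frac_med < base$frac_med))
  expect_true(all(up$frac_int > base$frac_int))
})

test_that("re-solving the flow scales K11 nearly proportionally in k_ECM", {
  m <- cube_inclusion_micro(16)
  k_base <- fit_permeability_tensor(m, solver_config())$K11
  k_up <- fit_permeability_tensor(
    m, solver_config(k_ecm = 1.32e-18 * 1.2))$K11
  expect_equal(k_up / k_base, 1.2, tolerance = 0.02)
})

test_that("the published geometry fixture matches its source summary", {
  geom <- load_published_tables()$geometry
  phi <- geom[geom$quantity == "phi_ecm", ]
  expect_identical(phi$mean[phi$condition == "baseline"], 0.60)
  expect_identical(phi$mean[phi$condition == "constricted"], 0.68)
})
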