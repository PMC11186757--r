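# Elementary accounting operations: unit arithmetic, degenerate inputs,
# clamping policies.

test_that("plant_pool does the concentration-by-biomass conversion", {
  expect_equal(plant_pool(0.5, 460), 0.23)
  expect_equal(plant_pool(0, 1e6), 0)
  expect_equal(plant_pool(c(0.5, 0.4), c(460, 600)), c(0.23, 0.24))
  expect_error(plant_pool(-0.1, 10), class = "pbudget_domain_error")
})

test_that("soil_pool converts depth-resolved concentrations and is additive over contiguous layers", {
  expect_equal(soil_pool(100, 1.5, c(0, 10)), 15.0)
  x <- 80
  bd <- 1.4
  expect_equal(
    soil_pool(x, bd, c(0, 10)) + soil_pool(x, bd, c(10, 30)) +
      soil_pool(x, bd, c(30, 60)),
    soil_pool(x, bd, c(0, 60)))
  expect_error(soil_pool(10, 1.5, c(10, 0)), class = "pbudget_domain_error")
})

test_that("microbial_p applies the fumigation conversion factor and clamps negative differences", {
  expect_equal(as.numeric(microbial_p(3.0, 1.8, 0.4)), 3.0)
  expect_equal(as.numeric(microbial_p(2.0, 2.0, 0.4)), 0)
  expect_warning(out <- microbial_p(1.0, 2.0, 0.4),
                 class = "pbudget_clamp_warning")
  expect_equal(as.numeric(out), 0)
  expect_equal(attr(out, "n_clamped"), 1L)
  expect_error(microbial_p(1, 0.5, kEP = 0), class = "pbudget_domain_error")
})

test_that("hedley_group computes the residual by difference and floors it at zero", {
  g <- hedley_group(2, 1, 3, total_p = 10)
  expect_equal(g$residual, 4)
  expect_false(g$flagged)
  g2 <- hedley_group(4, 3, 3, total_p = 10)
  expect_equal(g2$residual, 0)
  expect_false(g2$flagged)
  g3 <- hedley_group(5, 4, 3, total_p = 10)
  expect_equal(g3$residual, 0)
  expect_true(g3$flagged)
  expect_error(hedley_group(1, 1, 1, total_p = -1), class = "pbudget_domain_error")
})

test_that("annualize sums complete years and scales incomplete coverage", {
  m <- seq(as.Date("2014-01-01"), by = "month", length.out = 12)
  m_end <- seq(as.Date("2014-02-01"), by = "month", length.out = 12)
  full <- annualize(m, m_end, rep(0.02, 12))
  expect_equal(as.numeric(full), 0.24)
  expect_equal(attr(full, "coverage"), 1)
  half <- annualize(m[1:6], m_end[1:6], rep(0.02, 6))
  expect_equal(as.numeric(half), 0.24, tolerance = 0.02)
  expect_equal(as.numeric(half), 0.12 * 365 / 181, tolerance = 1e-12)
  expect_lt(attr(half, "coverage"), 1)
  # a leap year covers 366 days and must not be scaled down
  l <- seq(as.Date("2016-01-01"), by = "month", length.out = 12)
  l_end <- seq(as.Date("2016-02-01"), by = "month", length.out = 12)
  expect_equal(as.numeric(annualize(l, l_end, rep(0.02, 12))), 0.24)
  expect_error(annualize(m[c(1, 1)], m_end[c(1, 1)], c(1, 1)),
               class = "pbudget_data_error")
})

test_that("canopy production adds the herbivory flux to the litterfall-derived flux", {
  expect_equal(canopy_production(0.24, 0.04), 0.28)
  expect_equal(canopy_production(0.3, 0), 0.3)
})

test_that("resorption_fraction handles the full range including clamping", {
  expect_equal(as.numeric(resorption_fraction(1.0, 0.45)), 0.55)
  expect_equal(as.numeric(resorption_fraction(1.0, 1.0)), 0)
  expect_equal(as.numeric(resorption_fraction(1.0, 0)), 1)
  over <- resorption_fraction(1.0, 1.2)
  expect_equal(as.numeric(over), 0)
  expect_true(attr(over, "flagged"))
  expect_error(resorption_fraction(0, 0.1), class = "pbudget_domain_error")
})

test_that("plant demand is an exact sum and uptake is demand minus resorption", {
  expect_equal(plant_demand(c(a = 0.28, b = 0.28, c = 0.15)), 0.71)
  expect_equal(plant_demand(numeric(0)), 0)
  expect_equal(plant_demand(0.4), 0.4)
  expect_equal(plant_uptake(0.71, 0.32), 0.39)
  expect_equal(plant_uptake(0.5, 0), 0.5)
  expect_equal(plant_uptake(0.5, 0.5), 0)
  expect_warning(u <- plant_uptake(0.3, 0.4),
                 class = "pbudget_negative_uptake_warning")
  expect_equal(u, -0.1)
})

test_that("profile_scale is proportional with the surface unchanged", {
  expect_equal(profile_scale(0.5, c(1.0, 0.6, 0.2)), c(0.5, 0.3, 0.1))
  expect_equal(profile_scale(0.7, c(2, 2, 2)), rep(0.7, 3))
  expect_error(profile_scale(1, c(0, 1)), class = "pbudget_domain_error")
})

test_that("leaching flux converts lysimeter concentration under assumed drainage", {
  expect_equal(leaching_flux(0.01, 20), 7.3e-5)
  expect_equal(leaching_flux(0, 20), 0)
  expect_equal(leaching_flux(1.0, 20), 7.3e-3)
})

test_that("mean residence time and P-use efficiencies follow their definitions", {
  mrt <- mean_residence_time(0.23, 0.36, 0.24, 0.23, uptake = 0.39)
  expect_equal(mrt, 1.06 / 0.39, tolerance = 1e-12)
  expect_equal(mrt, 2.72, tolerance = 0.005)
  expect_equal(mean_residence_time(0.25, 0.25, 0.25, 0.25, uptake = 1), 1)
  expect_equal(mean_residence_time(1, 1, 1, 1, uptake = 2),
               mean_residence_time(1, 1, 1, 1, uptake = 1) / 2)
  expect_error(mean_residence_time(1, 1, 1, 1, uptake = 0),
               class = "pbudget_domain_error")

  pue <- p_use_efficiencies(1500, 400, 507, 0.284, 0.28, uptake = 0.39)
  expect_equal(unname(pue["pue_gpp_overstorey"]), 1500 / 0.284, tolerance = 1e-12)
  expect_equal(unname(pue["pue_gpp_overstorey"]), 5282, tolerance = 0.001)
  expect_equal(unname(pue["pue_growth"]), 1300, tolerance = 1e-6)
  pue2 <- p_use_efficiencies(3000, 800, 507, 0.284, 0.28, uptake = 0.39)
  expect_equal(unname(pue2["pue_gpp_total"]), 2 * unname(pue["pue_gpp_total"]))
  expect_error(p_use_efficiencies(1, 1, 1, 0, 1, 1),
               class = "pbudget_domain_error")
})
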