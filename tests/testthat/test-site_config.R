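# Configuration validation and the calibration of the default synthetic site.

test_that("default configuration is valid and its truth matches the published ambient budget", {
  cfg <- site_config()
  expect_s3_class(cfg, "site_config")
  tr <- budget_truth(cfg, "ambient")

  # pools (g P m-2), to printed rounding
  printed_pools <- c(
    canopy_p = 0.23, sapwood_p = 0.36, heartwood_p = 0.30, fine_root_p = 0.24,
    coarse_root_p = 0.15, understorey_p = 0.23, forest_floor_litter_p = 0.06,
    standing_dead_p = 0.04, soil_organic_p = 25.1, soil_inorganic_p = 6.7,
    soil_total_p = 31.8, microbial_p = 5.97, labile_p = 1.15
  )
  for (v in names(printed_pools)) {
    expect_equal(budget_value(tr, v), printed_pools[[v]], tolerance = 0.005,
                 label = v)
  }
  # fluxes (g P m-2 yr-1)
  expect_equal(budget_value(tr, "demand_p"), 0.71, tolerance = 0.005)
  expect_equal(budget_value(tr, "resorption_p"), 0.32, tolerance = 0.005)
  expect_equal(budget_value(tr, "uptake_p"), 0.39, tolerance = 0.005)
  expect_equal(budget_value(tr, "frass_p"), 0.04, tolerance = 0.005)
  expect_equal(budget_value(tr, "netmin_p"), 0.67, tolerance = 0.005)
  # plant-and-litter pool ~ 1.60-1.61 (component sum)
  expect_equal(budget_value(tr, "plant_litter_p"), 1.61, tolerance = 0.015)
  # canopy resorption fraction 55%
  expect_equal(budget_value(tr, "resorption_fraction_canopy"), 0.55,
               tolerance = 1e-12)
})

test_that("with no multipliers the elevated truth equals the ambient truth", {
  cfg <- site_config()
  expect_identical(budget_truth(cfg, "ambient"), budget_truth(cfg, "elevated"))
})

test_that("truth obeys the budget identities", {
  for (mult in list(numeric(), c(uptake = 1.08), co2_preset_observed())) {
    cfg <- site_config(co2_multipliers = mult)
    for (tr_name in c("ambient", "elevated")) {
      tr <- budget_truth(cfg, tr_name)
      v <- function(x) budget_value(tr, x)
      expect_equal(v("demand_p"), v("resorption_p") + v("uptake_p"),
                   tolerance = 1e-12)
      expect_equal(v("soil_total_p"),
                   v("soil_organic_p") + v("soil_inorganic_p"),
                   tolerance = 1e-12)
      expect_equal(v("soil_total_p"),
                   v("soil_total_p_0_10") + v("soil_total_p_10_30") +
                     v("soil_total_p_30_60"), tolerance = 1e-12)
      expect_equal(v("demand_p"),
                   v("canopy_production_p") + v("understorey_production_p") +
                     v("wood_production_p") + v("reproduction_production_p") +
                     v("coarse_root_production_p") + v("fine_root_production_p"),
                   tolerance = 1e-12)
    }
  }
})

test_that("multiplier semantics: a derived-flux multiplier scales its truth exactly", {
  cfg <- site_config(co2_multipliers = c(uptake = 1.08))
  trA <- budget_truth(cfg, "ambient")
  trE <- budget_truth(cfg, "elevated")
  expect_equal(budget_value(trE, "uptake_p"),
               1.08 * budget_value(trA, "uptake_p"), tolerance = 1e-12)
  # primitive multiplier scales only its own variable family
  cfg2 <- site_config(co2_multipliers = c(conc_fine_root = 1.1))
  trE2 <- budget_truth(cfg2, "elevated")
  expect_equal(budget_value(trE2, "fine_root_p"), 0.24 * 1.1, tolerance = 1e-12)
  expect_equal(budget_value(trE2, "canopy_p"), 0.23, tolerance = 1e-12)
})

test_that("derived ratio: microbial P over organic soil P is 0.238", {
  tr <- budget_truth(site_config(), "ambient")
  expect_equal(budget_value(tr, "microbial_p") / budget_value(tr, "soil_organic_p"),
               0.238, tolerance = 0.001)
})

test_that("invalid configurations fail with errors naming the offending field", {
  expect_error(site_config(depth_layers = list(c(0, 10), c(20, 30))),
               "depth_layers", class = "pbudget_config_error")
  expect_error(site_config(depth_layers = list(c(10, 0))),
               "depth_layers", class = "pbudget_config_error")
  cp <- default_component_params()
  cp$cv[1] <- -1
  expect_error(site_config(component_params = cp),
               "component_params", class = "pbudget_config_error")
  cp2 <- default_component_params()
  cp2$cv[3] <- 1.2
  expect_error(site_config(component_params = cp2),
               "component_params", class = "pbudget_config_error")
  expect_error(site_config(co2_multipliers = c(uptake = -2)),
               "co2_multipliers", class = "pbudget_config_error")
  expect_error(site_config(co2_multipliers = c(no_such_key = 1.1)),
               "co2_multipliers", class = "pbudget_config_error")
  expect_error(site_config(co2_multipliers = setNames(1.1, "")),
               "co2_multipliers", class = "pbudget_config_error")
})

test_that("configurations round-trip through YAML", {
  cfg <- site_config(co2_multipliers = co2_preset_observed(), seed = 99)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$co2_multipliers, cfg$co2_multipliers)
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(cfg2$component_params, cfg$component_params, tolerance = 1e-12)
  expect_equal(budget_truth(cfg2, "elevated"), budget_truth(cfg, "elevated"),
               tolerance = 1e-12)
})
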