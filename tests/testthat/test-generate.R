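# Properties of the synthetic measurement generator.

test_that("identical (config, seed) gives bit-identical tables", {
  cfg <- small_config()
  t1 <- generate_measurements(cfg, seed = 11)
  t2 <- generate_measurements(cfg, seed = 11)
  expect_identical(t1, t2)
  t3 <- generate_measurements(cfg, seed = 12)
  expect_false(identical(t1$litterfall$value, t3$litterfall$value))
})

test_that("all ten measurement tables are produced with the fixed schema", {
  tabs <- generate_measurements(small_config(), seed = 1)
  expect_named(tabs, c("tissue_concentration", "biomass", "litterfall", "frass",
                       "soil_chemistry", "fumigation_pairs", "incubation_pairs",
                       "lysimeter", "bulk_density", "carbon_fluxes"))
  cols <- c("plot_id", "treatment", "date", "component", "depth_top_cm",
            "depth_bottom_cm", "subrep", "variable", "value", "unit")
  for (nm in names(tabs)) {
    expect_identical(names(tabs[[nm]]), cols, label = nm)
    expect_true(all(tabs[[nm]]$unit %in% unit_vocabulary()), label = nm)
    # plot-treatment pairing constant
    pairing <- unique(tabs[[nm]][, c("plot_id", "treatment")])
    expect_equal(nrow(pairing), 6, label = nm)
    expect_true(all(startsWith(pairing$plot_id[pairing$treatment == "elevated"], "e")))
  }
})

test_that("no negative measurement values under the truncated-normal model", {
  # high CVs to stress the truncation
  cfg <- set_all_cv(small_config(), 0.6)
  tabs <- generate_measurements(cfg, seed = 3)
  for (nm in names(tabs)) {
    expect_true(all(tabs[[nm]]$value >= 0), label = nm)
  }
})

test_that("zero CV collapses all values onto the configured means", {
  cfg <- cv0_config()
  tabs <- generate_measurements(cfg, seed = 21)
  conc <- tabs$tissue_concentration
  canopy <- conc$value[conc$component == "canopy_green"]
  expect_true(all(canopy == 0.5))
  bd <- tabs$bulk_density
  expect_equal(sort(unique(bd$value)), c(1.5, 1.6, 1.7))
  lys <- tabs$lysimeter
  expect_true(all(lys$value == 0.05))
})

test_that("changing one table's parameters does not shift another table's draws", {
  cfg <- small_config()
  cfg2 <- cfg
  i <- cfg2$component_params$quantity == "production" &
    cfg2$component_params$component == "frass"
  cfg2$component_params$mean[i] <- 70
  t1 <- generate_measurements(cfg, seed = 5)
  t2 <- generate_measurements(cfg2, seed = 5)
  expect_identical(t1$litterfall, t2$litterfall)
  expect_identical(t1$soil_chemistry, t2$soil_chemistry)
  expect_false(identical(t1$frass, t2$frass))
})

test_that("lognormal noise model is supported and mean-unbiased in the large-n limit", {
  cfg <- small_config(noise_model = "lognormal", n_plots_per_treatment = 150)
  cfg <- set_all_cv(cfg, 0.2)
  lev <- pbudget:::draw_plot_levels(cfg, seed = 8)
  x <- lev[["conc.canopy_green"]]
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 0.5), 3 * se)
  expect_true(all(x > 0))
})

test_that("treatment means of generated data converge to the generator truth (3 SE at n = 200)", {
  # the field design is n = 3; n = 200 only sharpens the Monte-Carlo check
  cfg <- set_all_cv(small_config(n_plots_per_treatment = 200,
                                 co2_multipliers = c(uptake = 1.1)), 0.1)
  tabs <- generate_measurements(cfg, seed = 17)
  budgets <- assemble_budgets(tabs)
  for (trt in c("ambient", "elevated")) {
    tr <- budget_truth(cfg, trt)
    b <- budgets[budgets$treatment == trt, ]
    for (v in c("canopy_p", "soil_total_p", "microbial_p", "demand_p",
                "resorption_p", "uptake_p", "netmin_p", "mrt_years",
                "plant_litter_p")) {
      x <- b$value[b$variable == v]
      se <- sd(x) / sqrt(length(x))
      expect_lt(abs(mean(x) - budget_value(tr, v)), 3 * se + 1e-3,
                label = paste(trt, v))
    }
  }
})

test_that("measurement CSVs round-trip through write/read", {
  cfg <- small_config()
  tabs <- generate_measurements(cfg, seed = 2)
  dir <- withr::local_tempdir()
  write_measurements(tabs, dir)
  expect_length(list.files(dir, pattern = "\\.csv$"), 10)
  tabs2 <- read_measurements(dir)
  for (nm in names(tabs)) {
    expect_equal(as.data.frame(tabs2[[nm]]), as.data.frame(tabs[[nm]]),
                 tolerance = 1e-12, label = nm)
  }
})
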