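# Pipeline correctness: oracle equivalence at CV = 0, accounting identities,
# scale equivariance, aggregation rules.

test_that("on CV = 0 data every assembled pool and flux equals the generator truth", {
  cfg <- cv0_config()
  tabs <- generate_measurements(cfg, seed = 4)
  budgets <- assemble_budgets(tabs)
  truth <- budget_truth(cfg, "ambient")
  expect_budget_equals_truth(budgets, truth, tol = 1e-9)
})

test_that("CV = 0 equivalence also holds under CO2 multipliers, per treatment", {
  cfg <- cv0_config(co2_multipliers = c(uptake = 1.08, conc_fine_root = 1.05,
                                        soil_microbial_p = 1.1))
  tabs <- generate_measurements(cfg, seed = 4)
  budgets <- assemble_budgets(tabs)
  for (trt in c("ambient", "elevated")) {
    expect_budget_equals_truth(budgets[budgets$treatment == trt, ],
                               budget_truth(cfg, trt), tol = 1e-9)
  }
})

test_that("per-plot budgets satisfy the closure identities on noisy data", {
  cfg <- site_config()
  tabs <- generate_measurements(cfg, seed = 31)
  budgets <- assemble_budgets(tabs)
  val <- validate_budgets(budgets, tol = 1e-9)
  expect_true(val$pass)
  expect_true(all(val$checks$pass))
  # openness: the P cycle is essentially closed relative to uptake
  expect_true(all(val$openness$openness_ratio < 0.05))
})

test_that("multiplying all concentrations by k scales pools and fluxes by k, leaving MRT and fractions invariant", {
  k <- 3
  cfg <- cv0_config()
  cfg_k <- cfg
  i <- cfg_k$component_params$quantity == "conc"
  cfg_k$component_params$mean[i] <- cfg_k$component_params$mean[i] * k
  lay_cols <- c("total_p", "inorganic_p", "labile_p", "microbial_p")
  for (cc in lay_cols) cfg_k$soil_params$layers[[cc]] <-
      cfg_k$soil_params$layers[[cc]] * k
  site_i <- cfg_k$soil_params$site$variable != "lysimeter_p"
  cfg_k$soil_params$site$mean <- cfg_k$soil_params$site$mean *
    ifelse(site_i, k, 1)
  # netmin and lysimeter scale too for full equivariance
  cfg_k$soil_params$site$mean[!site_i] <- cfg$soil_params$site$mean[!site_i] * k

  b1 <- assemble_budgets(generate_measurements(cfg, seed = 9))
  bk <- assemble_budgets(generate_measurements(cfg_k, seed = 9))
  m <- merge(b1, bk, by = c("plot_id", "variable"))
  scaled <- m$type.x %in% c("pool", "flux") & m$variable != "deposition_p"
  expect_equal(m$value.y[scaled], k * m$value.x[scaled], tolerance = 1e-9)
  inv <- m$variable %in% c("mrt_years", "resorption_fraction_canopy",
                           "resorption_fraction_understorey",
                           "resorption_fraction_sapwood")
  expect_equal(m$value.y[inv], m$value.x[inv], tolerance = 1e-9)
})

test_that("negative fumigation differences are clamped and counted in the flags", {
  cfg <- cv0_config()
  tabs <- generate_measurements(cfg, seed = 2)
  fum <- tabs$fumigation_pairs
  i <- which(fum$variable == "fumigated_p" & fum$plot_id == "a1")[1:3]
  fum$value[i] <- 0 # fumigated < unfumigated
  tabs$fumigation_pairs <- fum
  budgets <- assemble_budgets(tabs)
  flags <- attr(budgets, "flags")
  expect_equal(flags$n_clamped_fumigation[flags$plot_id == "a1"], 3L)
  expect_true(all(flags$n_clamped_fumigation[flags$plot_id != "a1"] == 0L))
})

test_that("a missing required table raises a data error naming it", {
  tabs <- generate_measurements(small_config(), seed = 1)
  tabs$lysimeter <- NULL
  expect_error(assemble_budgets(tabs), "lysimeter",
               class = "pbudget_data_error")
})

test_that("overlapping litter intervals raise a data error", {
  tabs <- generate_measurements(small_config(), seed = 1)
  lf <- tabs$litterfall
  dup <- lf[lf$component == "canopy_litter" & lf$subrep == 1, ][1, ]
  dup$date <- dup$date + 10 # overlaps the first monthly interval
  dup$subrep <- 99L
  tabs$litterfall <- rbind(lf, dup)
  expect_error(assemble_budgets(tabs), class = "pbudget_data_error")
})

test_that("treatment aggregation uses plots as replicates and sums aggregates within plot", {
  toy <- tibble::tibble(
    plot_id = rep(c("a1", "a2", "a3"), 2),
    treatment = "ambient",
    variable = rep(c("x", "y"), each = 3),
    value = c(1, 2, 3, 4, 5, 6),
    unit = "g_P_per_m2", type = "pool"
  )
  toy2 <- dplyr::mutate(toy, treatment = "elevated",
                        plot_id = sub("a", "e", plot_id), value = value + 1)
  ag <- aggregate_treatments(dplyr::bind_rows(toy, toy2))
  amb_x <- ag[ag$variable == "x" & ag$treatment == "ambient", ]
  expect_equal(amb_x$mean, 2)
  expect_equal(amb_x$sd, 1)
  expect_equal(amb_x$n, 3L)

  # within-plot aggregate: SD of (x + y) per plot, not sum of SDs
  cfg <- site_config()
  budgets <- assemble_budgets(generate_measurements(cfg, seed = 12))
  ag2 <- aggregate_treatments(budgets)
  amb <- budgets[budgets$treatment == "ambient", ]
  per_plot_sum <- tapply(
    amb$value[amb$variable %in% c("sapwood_p", "heartwood_p")],
    amb$plot_id[amb$variable %in% c("sapwood_p", "heartwood_p")], sum)
  expect_equal(ag2$sd[ag2$variable == "wood_p" & ag2$treatment == "ambient"],
               sd(per_plot_sum), tolerance = 1e-12)
  # means add across components even though SDs do not
  expect_equal(ag2$mean[ag2$variable == "wood_p" & ag2$treatment == "ambient"],
               sum(ag2$mean[ag2$variable %in% c("sapwood_p", "heartwood_p") &
                              ag2$treatment == "ambient"]), tolerance = 1e-12)
})
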