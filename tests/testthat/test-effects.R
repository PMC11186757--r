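# The effect-size machinery: pooled SD, t-based intervals, relative effects,
# bootstrap.

test_that("pooled_sd matches its formula, is symmetric and degree-1 homogeneous", {
  expect_equal(pooled_sd(0.03, 0.04), sqrt((0.03^2 + 0.04^2) / 2))
  expect_equal(pooled_sd(0.03, 0.04), 0.035355, tolerance = 1e-5)
  expect_equal(pooled_sd(1, 1), 1)
  expect_equal(pooled_sd(0, 0), 0)
  for (s in list(c(0.1, 0.7), c(2, 5), c(0, 3))) {
    expect_equal(pooled_sd(s[1], s[2]), pooled_sd(s[2], s[1]))
    expect_equal(pooled_sd(10 * s[1], 10 * s[2]), 10 * pooled_sd(s[1], s[2]))
  }
  expect_error(pooled_sd(-1, 1), class = "pbudget_domain_error")
})

test_that("ci_eff reproduces the tabulated t critical value at n1 = n2 = 3", {
  # t(0.975, 4 df) = 2.7764 from standard tables
  expect_equal(ci_eff(1, 3, 3, 95), 2.7764 * sqrt(2 / 3), tolerance = 1e-4)
  expect_equal(ci_eff(1, 3, 3, 95), 2.2669, tolerance = 1e-3)
  expect_equal(ci_eff(0, 3, 3, 95), 0)
  hw <- vapply(c(75, 85, 95), function(l) ci_eff(0.5, 3, 3, l), numeric(1))
  expect_true(all(diff(hw) > 0))
  expect_error(ci_eff(1, 1, 1, 95), class = "pbudget_domain_error")
  expect_error(ci_eff(1, 3, 3, 0), class = "pbudget_domain_error")
})

test_that("the t-based interval approaches the normal interval as df grows", {
  n <- 5e5 # df = 1e6 - 2
  hw <- ci_eff(1, n, n, 95)
  normal_hw <- 1.959964 * sqrt(2 / n) # z(0.975) from normal tables
  expect_equal(hw, normal_hw, tolerance = 1e-5)
})

test_that("effect_estimate reports delta, pooled uncertainty and stacked CIs", {
  est <- effect_estimate(c(1, 2, 3), c(2, 3, 4))
  expect_equal(est$delta, 1)
  expect_equal(est$sd_eff, 1)
  expect_equal(est$sem, sqrt(2 / 3))
  expect_equal(est$rel_pct, 50)
  expect_equal(est$ci95_hi - est$delta, ci_eff(1, 3, 3, 95))
  expect_true(est$ci75_hi < est$ci85_hi && est$ci85_hi < est$ci95_hi)

  ident <- effect_estimate(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$delta, 0)
  expect_equal(ident$ci95_lo, -ident$ci95_hi)
  expect_false(ident$sig95)
  expect_error(effect_estimate(1, c(1, 2)), class = "pbudget_data_error")
})

test_that("published effect ratios are reproduced from printed means and deltas", {
  # uptake: ambient 0.39, delta +0.033 -> +8%
  a <- 0.39 + c(-0.01, 0, 0.01)
  e <- a + 0.033
  est <- effect_estimate(a, e)
  expect_equal(est$rel_pct, 100 * 0.033 / 0.39, tolerance = 1e-9)
  expect_equal(round(est$rel_pct), 8)
  # demand: ambient 0.71, delta +0.043 -> +6%
  a2 <- 0.71 + c(-0.01, 0, 0.01)
  est2 <- effect_estimate(a2, a2 + 0.043)
  expect_equal(round(est2$rel_pct), 6)
})

test_that("relative effect is invariant under common rescaling of both arms", {
  a <- c(1.1, 0.9, 1.0)
  e <- c(1.3, 1.1, 1.2)
  r1 <- effect_estimate(a, e)$rel_pct
  r2 <- effect_estimate(100 * a, 100 * e)$rel_pct
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("bootstrap_effect is deterministic for a fixed seed and degenerate for constant arms", {
  b1 <- bootstrap_effect(c(1, 2, 3), c(2, 3, 5), n_resamples = 500, seed = 7)
  b2 <- bootstrap_effect(c(1, 2, 3), c(2, 3, 5), n_resamples = 500, seed = 7)
  expect_identical(b1$deltas, b2$deltas)
  expect_identical(b1$ci, b2$ci)
  b3 <- bootstrap_effect(c(1, 2, 3), c(2, 3, 5), n_resamples = 500, seed = 8)
  expect_false(identical(b1$deltas, b3$deltas))

  const <- bootstrap_effect(rep(2, 3), rep(2, 3), n_resamples = 200, seed = 1)
  expect_true(all(const$deltas == 0))
  expect_true(all(const$ci$lo == 0 & const$ci$hi == 0))

  # percentile bounds lie within the resampled delta range, nested by level
  expect_true(all(b1$ci$lo >= min(b1$deltas) & b1$ci$hi <= max(b1$deltas)))
  expect_true(all(diff(b1$ci$hi - b1$ci$lo) >= 0))
})

test_that("bootstrap percentile CI midpoint agrees with the t interval midpoint for large balanced samples", {
  set.seed(42)
  a <- rnorm(100, 10, 1)
  e <- rnorm(100, 11, 1)
  est <- effect_estimate(a, e)
  bs <- bootstrap_effect(a, e, n_resamples = 2000, seed = 5)
  t_mid <- (est$ci95_lo + est$ci95_hi) / 2
  b_mid <- mean(c(bs$ci$lo[bs$ci$level == 95], bs$ci$hi[bs$ci$level == 95]))
  # both midpoints estimate delta; Monte-Carlo error ~ sem / sqrt(n_boot)
  expect_equal(b_mid, t_mid, tolerance = 3 * est$sem / sqrt(20))
})

test_that("effect_table covers every budget variable with optional bootstrap columns", {
  cfg <- small_config(co2_multipliers = c(uptake = 1.08))
  budgets <- assemble_budgets(generate_measurements(cfg, seed = 3))
  et <- effect_table(budgets, n_boot = 200, seed = 2)
  expect_setequal(et$variable, unique(budgets$variable))
  expect_true(all(c("delta", "sd_eff", "sem", "rel_pct", "ci95_lo", "ci95_hi",
                    "sig75", "sig85", "sig95", "boot_ci95_lo", "boot_ci95_hi")
                  %in% names(et)))
  et2 <- effect_table(budgets, n_boot = 200, seed = 2)
  expect_identical(et, et2)
  # model-ready adapter
  mt <- effects_model_table(budgets)
  expect_named(mt, c("variable", "plot_id", "treatment", "value"))
  expect_equal(nrow(mt), nrow(budgets))
})
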