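# Shared fixtures, all built in code.

# Configuration with every CV forced to zero: the generator becomes
# noise-free and the assembled pipeline must reproduce the truth exactly.
cv0_config <- function(...) {
  cfg <- site_config(...)
  set_all_cv(cfg, 0)
}

set_all_cv <- function(cfg, cv) {
  cfg$component_params$cv <- cv
  cv_cols <- grep("_cv$", names(cfg$soil_params$layers), value = TRUE)
  for (cc in cv_cols) cfg$soil_params$layers[[cc]] <- cv
  cfg$soil_params$site$cv <- cv
  cfg$carbon_params$cv <- cv
  validate_config(cfg)
  cfg
}

# Reduced design (fewer years, traps and subplots) for tests that iterate
# the full pipeline many times.
small_config <- function(...) {
  site_config(years = 2013:2016, n_litter_traps = 3, n_soil_subplots = 2, ...)
}

expect_budget_equals_truth <- function(budgets, truth, tol = 1e-9) {
  for (pl in unique(budgets$plot_id)) {
    b <- budgets[budgets$plot_id == pl, ]
    m <- merge(truth, b, by = "variable")
    expect_equal(nrow(m), nrow(truth))
    expect_equal(m$value.y, m$value.x, tolerance = tol,
                 ignore_attr = TRUE)
  }
}
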