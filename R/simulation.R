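# Monte-Carlo harnesses for the interval procedures: coverage of the t-based
# and bootstrap CIs against a configured true effect, null calibration of the
# significance flags, and recovery of configured multiplicative effects
# through the full pipeline.

# Truth values for one variable under both treatments.
truth_pair <- function(config, variable) {
  c(ambient = budget_value(budget_truth(config, "ambient"), variable),
    elevated = budget_value(budget_truth(config, "elevated"), variable))
}

#' Coverage simulation for the CO2 effect intervals
#'
#' Repeatedly simulates plot-level data for a variable under a configured
#' multiplicative CO2 effect, computes the t-based (and optionally bootstrap
#' percentile) confidence intervals, and reports the fraction of simulations
#' whose interval contains the true effect, per confidence level.
#'
#' Two simulation routes are available. `method = "plot"` draws plot-level
#' values directly from the configured noise model around the closed-form
#' truth of the variable — fast, and exactly matched to the interval's
#' sampling assumptions. `method = "pipeline"` generates full measurement
#' tables and assembles budgets per simulation — slow, but exercises the
#' entire accounting chain.
#'
#' @param config A [site_config()]; its `co2_multipliers` define the true
#'   effect.
#' @param variable Budget variable to test (e.g. `"uptake_p"`).
#' @param n_sims Number of simulated experiments (>= 100 recommended).
#' @param seed Integer seed.
#' @param levels Confidence levels in percent.
#' @param n_plots Plots per arm (default from `config`).
#' @param cv Plot-level CV of the variable under `method = "plot"`.
#' @param n_boot Bootstrap resamples per simulation (0 disables bootstrap
#'   coverage).
#' @param method `"plot"` or `"pipeline"`.
#' @return A tibble: `level`, `t_coverage`, and `boot_coverage` when
#'   `n_boot > 0`, plus attribute `true_delta`.
#' @export
coverage_simulation <- function(config, variable, n_sims = 200, seed = 1L,
                                levels = c(75, 85, 95),
                                n_plots = config$n_plots_per_treatment,
                                cv = 0.1, n_boot = 0,
                                method = c("plot", "pipeline")) {
  method <- match.arg(method)
  levels <- sort(levels)
  tp <- truth_pair(config, variable)
  true_delta <- tp[["elevated"]] - tp[["ambient"]]
  t_hits <- matrix(FALSE, n_sims, length(levels))
  b_hits <- matrix(FALSE, n_sims, length(levels))
  with_substream(seed, "simulation", {
    for (s in seq_len(n_sims)) {
      if (method == "plot") {
        a <- rnoise(n_plots, tp[["ambient"]], cv, config$noise_model)
        e <- rnoise(n_plots, tp[["elevated"]], cv, config$noise_model)
      } else {
        sim_seed <- (substream_seed(seed, "simulation") + s * 131L) %% .Machine$integer.max
        tabs <- generate_measurements(config, seed = sim_seed)
        b <- assemble_budgets(tabs, config$flux_constants)
        a <- b$value[b$variable == variable & b$treatment == "ambient"]
        e <- b$value[b$variable == variable & b$treatment == "elevated"]
      }
      est <- effect_estimate(a, e, levels)
      for (j in seq_along(levels)) {
        lo <- est[[sprintf("ci%d_lo", levels[j])]]
        hi <- est[[sprintf("ci%d_hi", levels[j])]]
        t_hits[s, j] <- lo <= true_delta && true_delta <= hi
      }
      if (n_boot > 0) {
        bs <- bootstrap_effect(a, e, n_resamples = n_boot, seed = s,
                               levels = levels)
        for (j in seq_along(levels)) {
          b_hits[s, j] <- bs$ci$lo[j] <= true_delta && true_delta <= bs$ci$hi[j]
        }
      }
    }
  })
  out <- tibble::tibble(level = levels, t_coverage = colMeans(t_hits))
  if (n_boot > 0) out$boot_coverage <- colMeans(b_hits)
  attr(out, "true_delta") <- true_delta
  out
}

#' Null calibration of the significance flags
#'
#' With all CO2 multipliers equal to 1 (no true effect), the fraction of
#' simulated experiments in which the level-L confidence interval excludes
#' zero should be close to `1 - L/100`. Simulates many experiments and
#' reports the flag fraction per level.
#'
#' @param config A [site_config()]; any configured multipliers are removed.
#' @param n_sims Number of simulated experiments (>= 500 recommended).
#' @param seed Integer seed.
#' @param levels Confidence levels in percent.
#' @param cv Plot-level CV under `method = "plot"`.
#' @param method `"plot"` (draws a single variable's plot values directly) or
#'   `"pipeline"` (full pipeline; the flag fraction is then pooled over all
#'   budget variables).
#' @return A tibble: `level`, `flag_rate`, `n` (experiments, or
#'   experiment-variable pairs under `"pipeline"`).
#' @export
null_calibration <- function(config, n_sims = 500, seed = 1L,
                             levels = c(75, 85, 95), cv = 0.15,
                             method = c("plot", "pipeline")) {
  method <- match.arg(method)
  levels <- sort(levels)
  config$co2_multipliers <- numeric()
  if (method == "plot") {
    n_plots <- config$n_plots_per_treatment
    flags <- matrix(FALSE, n_sims, length(levels))
    with_substream(seed, "simulation", {
      for (s in seq_len(n_sims)) {
        a <- rnoise(n_plots, 1, cv, config$noise_model)
        e <- rnoise(n_plots, 1, cv, config$noise_model)
        est <- effect_estimate(a, e, levels)
        for (j in seq_along(levels)) {
          flags[s, j] <- est[[sprintf("sig%d", levels[j])]]
        }
      }
    })
    return(tibble::tibble(level = levels, flag_rate = colMeans(flags),
                          n = n_sims))
  }
  rates <- vector("list", n_sims)
  nv <- 0L
  for (s in seq_len(n_sims)) {
    sim_seed <- (substream_seed(seed, "simulation") + s * 131L) %% .Machine$integer.max
    tabs <- generate_measurements(config, seed = sim_seed)
    b <- assemble_budgets(tabs, config$flux_constants)
    et <- effect_table(b, levels = levels)
    et <- et[et$sd_eff > 0, ] # constants (e.g. the deposition flux) carry no test
    nv <- nrow(et)
    rates[[s]] <- vapply(levels, function(lv) {
      mean(et[[sprintf("sig%d", lv)]])
    }, numeric(1))
  }
  m <- do.call(rbind, rates)
  tibble::tibble(level = levels, flag_rate = colMeans(m), n = n_sims * nv)
}

#' Recovery of a configured CO2 effect across seeds
#'
#' Runs the full generate-assemble-effect pipeline once per seed and collects
#' the estimated absolute and relative effect of one variable, so that the
#' across-seed mean can be compared with the truth implied by the configured
#' multipliers (parameter recovery).
#'
#' @param config A [site_config()] with the multipliers under test.
#' @param variable Budget variable to recover (e.g. `"uptake_p"`).
#' @param n_seeds Number of independent simulated experiments.
#' @param seed Base seed.
#' @return A tibble with one row per simulation: `sim`, `delta`, `rel_pct`;
#'   attributes `true_delta` and `true_rel_pct`.
#' @export
effect_recovery <- function(config, variable, n_seeds = 50, seed = 1L) {
  tp <- truth_pair(config, variable)
  rows <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    sim_seed <- (substream_seed(seed, "simulation") + s * 977L) %% .Machine$integer.max
    tabs <- generate_measurements(config, seed = sim_seed)
    b <- assemble_budgets(tabs, config$flux_constants)
    a <- b$value[b$variable == variable & b$treatment == "ambient"]
    e <- b$value[b$variable == variable & b$treatment == "elevated"]
    est <- effect_estimate(a, e)
    rows[[s]] <- tibble::tibble(sim = s, delta = est$delta, rel_pct = est$rel_pct)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "true_delta") <- tp[["elevated"]] - tp[["ambient"]]
  attr(out, "true_rel_pct") <- 100 * (tp[["elevated"]] / tp[["ambient"]] - 1)
  out
}
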