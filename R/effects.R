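# CO2 effect-size machinery for small-n two-treatment designs: pooled SD,
# t-based confidence intervals at stacked confidence levels, relative effects,
# and percentile-bootstrap counterparts.

#' Pooled standard deviation of a treatment difference
#'
#' `SD_eff = sqrt((sd_amb^2 + sd_ele^2) / 2)`: the SDs of the two treatment
#' arms pooled with equal weight (balanced design).
#'
#' @param sd_amb,sd_ele Arm standard deviations (>= 0).
#' @return The pooled SD. Symmetric in its arguments and homogeneous of
#'   degree 1.
#' @examples
#' pooled_sd(0.03, 0.04) # 0.03536
#' @export
pooled_sd <- function(sd_amb, sd_ele) {
  if (any(sd_amb < 0) || any(sd_ele < 0)) {
    abort_domain("pooled_sd: standard deviations must be >= 0")
  }
  sqrt((sd_amb^2 + sd_ele^2) / 2)
}

#' t-based confidence-interval half-width for a treatment effect
#'
#' `CI_eff = t_crit(level, n1 + n2 - 2) * sd_eff * sqrt(1/n1 + 1/n2)` with a
#' two-tailed critical value.
#'
#' @param sd_eff Pooled SD, see [pooled_sd()].
#' @param n1,n2 Plots per arm (>= 2).
#' @param level Confidence level in percent, in (0, 100); default 95.
#' @return The CI half-width.
#' @examples
#' ci_eff(1, 3, 3, 95) # t(0.975, 4) * sqrt(2/3) = 2.2669
#' @export
ci_eff <- function(sd_eff, n1, n2, level = 95) {
  if (any(sd_eff < 0)) abort_domain("ci_eff: sd_eff must be >= 0")
  df <- n1 + n2 - 2
  if (any(df <= 0)) abort_domain("ci_eff: degrees of freedom must be > 0")
  if (any(level <= 0 | level >= 100)) {
    abort_domain("ci_eff: level must be in (0, 100)")
  }
  stats::qt(1 - (1 - level / 100) / 2, df) * sd_eff * sqrt(1 / n1 + 1 / n2)
}

#' CO2 treatment effect estimate for one variable
#'
#' The treatment effect is the net difference of the arm means (elevated
#' minus ambient), with uncertainty from the pooled arm SDs: standard error
#' `sd_eff * sqrt(1/n1 + 1/n2)`, t-based confidence intervals at the
#' requested levels, and the relative effect `100 * delta / ambient mean`.
#' The effect is flagged "significant at level L" when the level-L interval
#' excludes zero.
#'
#' @param ambient,elevated Numeric vectors of plot-level values (>= 2 each).
#' @param levels Confidence levels in percent (default 75, 85, 95).
#' @return A one-row tibble: `ambient_mean`, `elevated_mean`, `delta`,
#'   `sd_eff`, `sem`, `rel_pct`, and `ci<level>_lo/hi`, `sig<level>` per
#'   level.
#' @examples
#' effect_estimate(c(0.38, 0.39, 0.40), c(0.41, 0.42, 0.44))
#' @export
effect_estimate <- function(ambient, elevated, levels = c(75, 85, 95)) {
  if (length(ambient) < 2 || length(elevated) < 2) {
    abort_data("effect_estimate: need >= 2 plots per treatment arm")
  }
  levels <- sort(levels)
  n1 <- length(ambient)
  n2 <- length(elevated)
  m1 <- mean(ambient)
  m2 <- mean(elevated)
  delta <- m2 - m1
  sd_eff <- pooled_sd(stats::sd(ambient), stats::sd(elevated))
  sem <- sd_eff * sqrt(1 / n1 + 1 / n2)
  out <- tibble::tibble(
    ambient_mean = m1, elevated_mean = m2, delta = delta,
    sd_eff = sd_eff, sem = sem,
    rel_pct = if (m1 != 0) 100 * delta / m1 else NA_real_,
    n1 = n1, n2 = n2
  )
  for (lv in levels) {
    hw <- ci_eff(sd_eff, n1, n2, lv)
    out[[sprintf("ci%d_lo", lv)]] <- delta - hw
    out[[sprintf("ci%d_hi", lv)]] <- delta + hw
    out[[sprintf("sig%d", lv)]] <- (delta - hw) > 0 | (delta + hw) < 0
  }
  out
}

#' Percentile-bootstrap CO2 effect
#'
#' Resamples the datapoints of each treatment arm independently with
#' replacement `n_resamples` times, recomputes the arm-mean difference per
#' draw, and summarizes the resulting effect distribution with percentile
#' confidence intervals. Deterministic for a fixed seed. The default
#' datapoints are plot-level values (the plot is the experimental unit);
#' callers may pass finer-grained records (e.g. plot-year values) for a
#' sensitivity analysis.
#'
#' @param ambient,elevated Numeric vectors of datapoints per arm (non-empty).
#' @param n_resamples Number of bootstrap draws (default 1000).
#' @param seed Integer seed.
#' @param levels Confidence levels in percent.
#' @return A list of class `bootstrap_effect`: `delta` (observed), `deltas`
#'   (resampled), `ci` (tibble of level, lo, hi), `n_resamples`, `seed`.
#' @export
bootstrap_effect <- function(ambient, elevated, n_resamples = 1000, seed = 1L,
                             levels = c(75, 85, 95)) {
  if (!length(ambient) || !length(elevated)) {
    abort_data("bootstrap_effect: both treatment arms must be non-empty")
  }
  levels <- sort(levels)
  deltas <- with_substream(seed, "bootstrap", {
    a <- matrix(sample(ambient, length(ambient) * n_resamples, replace = TRUE),
                nrow = n_resamples)
    e <- matrix(sample(elevated, length(elevated) * n_resamples, replace = TRUE),
                nrow = n_resamples)
    rowMeans(e) - rowMeans(a)
  })
  ci <- dplyr::bind_rows(lapply(levels, function(lv) {
    q <- stats::quantile(deltas, c((1 - lv / 100) / 2, 1 - (1 - lv / 100) / 2),
                         names = FALSE, type = 7)
    tibble::tibble(level = lv, lo = q[1], hi = q[2])
  }))
  structure(
    list(delta = mean(elevated) - mean(ambient), deltas = deltas, ci = ci,
         n_resamples = n_resamples, seed = as.integer(seed)),
    class = "bootstrap_effect"
  )
}

#' @export
print.bootstrap_effect <- function(x, ...) {
  cat(sprintf("<bootstrap_effect> delta = %.4g (%d resamples, seed %d)\n",
              x$delta, x$n_resamples, x$seed))
  print(x$ci)
  invisible(x)
}

#' Effect table over all budget variables
#'
#' Applies [effect_estimate()] (and optionally [bootstrap_effect()]) to every
#' budget variable of an assembled per-plot budget table.
#'
#' @param budgets Output of [assemble_budgets()].
#' @param levels Confidence levels in percent.
#' @param n_boot Bootstrap resamples per variable (0 disables the bootstrap
#'   columns).
#' @param seed Seed for the bootstrap.
#' @return A tibble with one row per variable: the [effect_estimate()]
#'   columns plus `boot_ci<level>_lo/hi` when `n_boot > 0`.
#' @export
effect_table <- function(budgets, levels = c(75, 85, 95), n_boot = 0,
                         seed = 1L) {
  wide <- budgets |>
    dplyr::select(plot_id, treatment, variable, value) |>
    tidyr::pivot_wider(names_from = treatment, values_from = value,
                       values_fn = list) |>
    dplyr::summarise(ambient = list(unlist(ambient)),
                     elevated = list(unlist(elevated)), .by = variable)
  if (any(vapply(wide$ambient, is.null, logical(1))) ||
      any(vapply(wide$elevated, is.null, logical(1)))) {
    abort_data("effect_table: both treatments must be present for every variable")
  }
  rows <- lapply(seq_len(nrow(wide)), function(i) {
    a <- wide$ambient[[i]]
    e <- wide$elevated[[i]]
    est <- effect_estimate(a, e, levels)
    if (n_boot > 0) {
      bs <- bootstrap_effect(a, e, n_resamples = n_boot,
                             seed = seed + i, levels = levels)
      for (j in seq_len(nrow(bs$ci))) {
        lv <- bs$ci$level[j]
        est[[sprintf("boot_ci%d_lo", lv)]] <- bs$ci$lo[j]
        est[[sprintf("boot_ci%d_hi", lv)]] <- bs$ci$hi[j]
      }
      est$boot_seed <- seed + i
    }
    est$variable <- wide$variable[i]
    est
  })
  dplyr::bind_rows(rows) |>
    dplyr::relocate(variable)
}

#' Model-ready long table for external mixed-model confirmation
#'
#' Emits plot-level budget values in the long layout expected by linear
#' mixed-effect modelling tools (CO2 treatment and year as fixed factors,
#' plot as a random factor). The model itself is deliberately not fitted
#' here; this is an adapter for external confirmatory analysis.
#'
#' @param budgets Output of [assemble_budgets()].
#' @return A tibble: `variable`, `plot_id`, `treatment`, `value`.
#' @export
effects_model_table <- function(budgets) {
  budgets |>
    dplyr::select(variable, plot_id, treatment, value) |>
    dplyr::arrange(variable, treatment, plot_id)
}
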