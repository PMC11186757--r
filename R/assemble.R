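# Assembly of per-plot budgets from raw measurement tables, following the
# plot-then-treatment aggregation principle: sub-replicates are averaged to a
# plot mean first; repeated measurements are annualized within year and then
# averaged across years; the budget accounting then runs per plot.

utils::globalVariables(c(
  "plot_id", "treatment", "component", "variable", "value", "date", "subrep",
  "depth_top_cm", "depth_bottom_cm", "year", "layer", "unit", "type", "delta",
  "quarter", "mean_value", "n_plots", "ambient", "elevated"
))

require_table <- function(tables, name) {
  d <- tables[[name]]
  if (is.null(d)) abort_data(sprintf("required measurement table '%s' is missing", name))
  d
}

# plot x component mean of a long table (sub-replicates and dates pooled by
# stage: subrep -> date -> year).
plot_component_mean <- function(d) {
  d |>
    dplyr::mutate(year = as.integer(format(date, "%Y"))) |>
    dplyr::summarise(value = mean(value), .by = c(plot_id, component, year, date)) |>
    dplyr::summarise(value = mean(value), .by = c(plot_id, component, year)) |>
    dplyr::summarise(value = mean(value), .by = c(plot_id, component))
}

# Annual litter mass flux per plot and component: trap mean per month, annual
# total per year via annualize(), then cross-year mean.
annual_litter_flux <- function(d) {
  monthly <- d |>
    dplyr::summarise(value = mean(value), .by = c(plot_id, component, date)) |>
    dplyr::mutate(year = as.integer(format(date, "%Y")))
  annual <- monthly |>
    dplyr::group_by(plot_id, component, year) |>
    dplyr::summarise(value = as.numeric(annualize(
      date, seq_dates_next_month(date), value)), .groups = "drop")
  annual |>
    dplyr::summarise(value = mean(value), .by = c(plot_id, component))
}

seq_dates_next_month <- function(d) {
  d <- as.Date(d)
  as.Date(vapply(as.character(d), function(x) {
    as.character(seq(as.Date(x), by = "1 month", length.out = 2L)[2L])
  }, character(1)), origin = "1970-01-01")
}

seq_dates_next_quarter <- function(d) {
  d <- as.Date(d)
  as.Date(vapply(as.character(d), function(x) {
    as.character(seq(as.Date(x), by = "3 months", length.out = 2L)[2L])
  }, character(1)), origin = "1970-01-01")
}

#' Assemble per-plot P budgets from measurement tables
#'
#' Runs the full accounting pipeline on a set of long-format measurement
#' tables (as produced by [generate_measurements()] or user-supplied files
#' matching their schema): plot means of tissue concentrations, biomass and
#' production rates; annualized litterfall, frass and incubation series;
#' soil pools from depth-resolved concentrations and bulk density; microbial P
#' from fumigation pairs; depth extrapolation of surface-only measurements via
#' [profile_scale()]; and the vegetation flux accounting (demand, resorption,
#' uptake) with derived indicators.
#'
#' @param tables Named list of measurement tibbles.
#' @param constants Accounting constants, see [default_flux_constants()].
#' @return A tibble of per-plot budgets: `plot_id`, `treatment`, `variable`,
#'   `value`, `unit`, `type`, with attribute `flags` (a tibble counting
#'   clamped fumigation differences, floored Hedley residuals and negative
#'   uptake values per plot).
#' @seealso [aggregate_treatments()], [validate_budgets()]
#' @export
assemble_budgets <- function(tables, constants = default_flux_constants()) {
  tissue <- require_table(tables, "tissue_concentration")
  biomass <- require_table(tables, "biomass")
  litterfall <- require_table(tables, "litterfall")
  frass <- require_table(tables, "frass")
  soil <- require_table(tables, "soil_chemistry")
  fum <- require_table(tables, "fumigation_pairs")
  incu <- require_table(tables, "incubation_pairs")
  lys <- require_table(tables, "lysimeter")
  bd <- require_table(tables, "bulk_density")
  carbon <- require_table(tables, "carbon_fluxes")

  plots <- unique(tissue[, c("plot_id", "treatment")])
  layers <- bd |>
    dplyr::distinct(depth_top_cm, depth_bottom_cm) |>
    dplyr::arrange(depth_top_cm) |>
    dplyr::rename(top_cm = depth_top_cm, bottom_cm = depth_bottom_cm)
  lab <- layer_label(layers$top_cm, layers$bottom_cm)
  add_layer <- function(d) {
    dplyr::mutate(d, layer = layer_label(depth_top_cm, depth_bottom_cm))
  }
  campaign_yr <- soil |>
    add_layer() |>
    dplyr::filter(layer != lab[1]) |>
    dplyr::pull(date)
  if (!length(campaign_yr) && length(lab) > 1) {
    abort_data("soil_chemistry: no deep-profile campaign records found")
  }
  campaign_yr <- if (length(campaign_yr)) {
    max(as.integer(format(campaign_yr, "%Y")))
  } else {
    max(as.integer(format(soil$date, "%Y")))
  }

  conc_tbl <- plot_component_mean(tissue)
  bm_tbl <- plot_component_mean(dplyr::filter(biomass, variable == "standing_pool"))
  pr_tbl <- plot_component_mean(dplyr::filter(biomass, variable == "production_rate"))
  litter_tbl <- annual_litter_flux(litterfall)
  frass_tbl <- annual_litter_flux(frass)

  bd_tbl <- bd |>
    add_layer() |>
    dplyr::summarise(value = mean(value), .by = c(plot_id, layer))

  # layer-resolved concentration mean pooling every available record
  soil_layer_mean <- function(var) {
    soil |>
      dplyr::filter(variable == var) |>
      add_layer() |>
      dplyr::summarise(value = mean(value), .by = c(plot_id, layer, date)) |>
      dplyr::summarise(value = mean(value), .by = c(plot_id, layer))
  }
  # surface time series mean (pre-campaign years) + deep-campaign profile,
  # combined through profile_scale
  profiled_conc <- function(d, plot) {
    d <- d[d$plot_id == plot, ]
    surf <- d$value[d$layer == lab[1] & d$year < campaign_yr]
    if (!length(surf)) surf <- d$value[d$layer == lab[1]]
    camp <- d[d$year == campaign_yr, ]
    weights <- camp$value[match(lab, camp$layer)]
    if (anyNA(weights)) {
      abort_data(sprintf("missing deep-campaign records for plot %s", plot))
    }
    profile_scale(mean(surf), weights)
  }
  soil_series <- function(var) {
    soil |>
      dplyr::filter(variable == var) |>
      add_layer() |>
      dplyr::mutate(year = as.integer(format(date, "%Y"))) |>
      dplyr::summarise(value = mean(value), .by = c(plot_id, layer, year, date)) |>
      dplyr::summarise(value = mean(value), .by = c(plot_id, layer, year))
  }

  total_tbl <- soil_layer_mean("total_p")
  inorg_tbl <- soil_layer_mean("inorganic_p")
  soilc_tbl <- soil_layer_mean("soil_c")
  labile_series <- soil_series("labile_p")

  # microbial P concentrations from fumigation pairs
  fum_wide <- fum |>
    add_layer() |>
    tidyr::pivot_wider(names_from = variable, values_from = value)
  if (!all(c("fumigated_p", "unfumigated_p") %in% names(fum_wide))) {
    abort_data("fumigation_pairs: need paired 'fumigated_p' and 'unfumigated_p' records")
  }
  mic_conc <- microbial_p(fum_wide$fumigated_p, fum_wide$unfumigated_p,
                          kEP = constants[["kEP"]], warn = FALSE)
  fum_wide$value <- as.numeric(mic_conc)
  fum_wide$clamped <- fum_wide$fumigated_p < fum_wide$unfumigated_p
  clamp_counts <- fum_wide |>
    dplyr::summarise(n_clamped_fumigation = sum(clamped), .by = plot_id)
  mic_series <- fum_wide |>
    dplyr::mutate(year = as.integer(format(date, "%Y"))) |>
    dplyr::summarise(value = mean(value), .by = c(plot_id, layer, year, date)) |>
    dplyr::summarise(value = mean(value), .by = c(plot_id, layer, year))

  hed_tbl <- soil |>
    dplyr::filter(grepl("^hedley_", variable)) |>
    dplyr::summarise(value = mean(value), .by = c(plot_id, variable))

  # net mineralization: quarterly extract deltas -> areal flux per year
  incu_wide <- incu |>
    tidyr::pivot_wider(names_from = variable, values_from = value)
  if (!all(c("initial_p", "final_p") %in% names(incu_wide))) {
    abort_data("incubation_pairs: need paired 'initial_p' and 'final_p' records")
  }
  netmin_tbl <- incu_wide |>
    dplyr::mutate(delta = final_p - initial_p) |>
    dplyr::summarise(delta = mean(delta), .by = c(plot_id, date)) |>
    dplyr::mutate(year = as.integer(format(date, "%Y"))) |>
    dplyr::left_join(dplyr::filter(bd_tbl, layer == lab[1]) |>
                       dplyr::select(plot_id, bd1 = value), by = "plot_id") |>
    dplyr::mutate(flux = delta * bd1 * (layers$bottom_cm[1] - layers$top_cm[1]) * 0.01) |>
    dplyr::group_by(plot_id, year) |>
    dplyr::summarise(value = as.numeric(annualize(
      date, seq_dates_next_quarter(date), flux)), .groups = "drop") |>
    dplyr::summarise(value = mean(value), .by = plot_id)

  lys_tbl <- lys |>
    dplyr::summarise(value = mean(value), .by = plot_id)
  carbon_tbl <- carbon |>
    dplyr::mutate(year = as.integer(format(date, "%Y"))) |>
    dplyr::summarise(value = mean(value), .by = c(plot_id, variable, year)) |>
    dplyr::summarise(value = mean(value), .by = c(plot_id, variable))

  named <- function(d, key, val = "value") stats::setNames(d[[val]], d[[key]])

  budgets <- vector("list", nrow(plots))
  flags <- vector("list", nrow(plots))
  for (i in seq_len(nrow(plots))) {
    pl <- plots$plot_id[i]
    take <- function(d) d[d$plot_id == pl, ]
    co <- named(take(conc_tbl), "component")
    bm_p <- named(take(bm_tbl), "component")
    pr_p <- named(take(pr_tbl), "component")
    lit <- named(take(litter_tbl), "component")
    fra <- named(take(frass_tbl), "component")
    production <- c(pr_p, canopy_litter = unname(lit["canopy_litter"]),
                    reproduction = unname(lit["reproduction"]),
                    frass = unname(fra["frass"]))

    bd_p <- named(take(bd_tbl), "layer")[lab]
    tot_p <- named(take(total_tbl), "layer")[lab]
    ino_p <- named(take(inorg_tbl), "layer")[lab]
    soc_p <- named(take(soilc_tbl), "layer")[lab]
    lab_prof <- profiled_conc(labile_series, pl)
    mic_prof <- profiled_conc(mic_series, pl)

    prim <- list(
      conc = co,
      biomass = bm_p,
      production = production,
      soil = list(bulk_density = bd_p, total_p = tot_p, inorganic_p = ino_p,
                  labile_p = stats::setNames(lab_prof, lab),
                  microbial_p = stats::setNames(mic_prof, lab),
                  soil_c = soc_p),
      hedley = c(
        exchangeable_pi = unname(named(take(hed_tbl), "variable")["hedley_exchangeable_pi"]),
        exchangeable_po = unname(named(take(hed_tbl), "variable")["hedley_exchangeable_po"]),
        moderately_labile_po = unname(named(take(hed_tbl), "variable")["hedley_moderately_labile_po"])),
      netmin_surface = take(netmin_tbl)$value,
      lysimeter_p = take(lys_tbl)$value,
      carbon = named(take(carbon_tbl), "variable")
    )
    b <- compute_budget(prim, layers, constants)
    b$plot_id <- pl
    b$treatment <- plots$treatment[i]
    budgets[[i]] <- b
    n_cl <- clamp_counts$n_clamped_fumigation[match(pl, clamp_counts$plot_id)]
    flags[[i]] <- tibble::tibble(
      plot_id = pl,
      n_clamped_fumigation = ifelse(is.na(n_cl), 0L, n_cl),
      hedley_residual_floored = budget_value(b, "hedley_residual") == 0 &&
        budget_value(b, "soil_total_p_0_10") > 0,
      negative_uptake = budget_value(b, "uptake_p") < 0
    )
  }
  out <- dplyr::bind_rows(budgets) |>
    dplyr::select(plot_id, treatment, variable, value, unit, type)
  attr(out, "flags") <- dplyr::bind_rows(flags)
  out
}

#' Validate assembled budgets against the accounting identities
#'
#' Per-plot closure checks: `demand - (resorption + uptake) = 0` (exact by
#' construction), soil layer additivity (0-60 cm totals equal the sum of the
#' layer pools), `organic + inorganic = total` per layer, and non-negativity
#' of all pools. Also reports the ecosystem openness summary (deposition
#' minus leaching relative to uptake).
#'
#' @param budgets Output of [assemble_budgets()].
#' @param tol Absolute tolerance (g P m\eqn{^{-2}} or per yr) for the exact
#'   identities.
#' @return A list with `checks` (tibble: plot, check, residual, pass),
#'   `openness` (tibble per plot), `flags` (carried over from assembly) and
#'   `pass` (scalar logical).
#' @export
validate_budgets <- function(budgets, tol = 1e-9) {
  val <- function(pl, v) budgets$value[budgets$plot_id == pl & budgets$variable == v]
  plots <- unique(budgets$plot_id)
  lay_suffix <- unique(sub("^soil_total_p_", "",
                           grep("^soil_total_p_\\d", budgets$variable, value = TRUE)))
  checks <- list()
  openness <- list()
  for (pl in plots) {
    closure <- val(pl, "demand_p") - (val(pl, "resorption_p") + val(pl, "uptake_p"))
    additivity <- val(pl, "soil_total_p") -
      sum(vapply(paste0("soil_total_p_", lay_suffix), function(v) val(pl, v),
                 numeric(1)))
    org_inorg <- max(abs(vapply(lay_suffix, function(l) {
      val(pl, paste0("soil_organic_p_", l)) + val(pl, paste0("soil_inorganic_p_", l)) -
        val(pl, paste0("soil_total_p_", l))
    }, numeric(1))))
    pools <- budgets[budgets$plot_id == pl & budgets$type == "pool", ]
    checks[[pl]] <- tibble::tibble(
      plot_id = pl,
      check = c("demand_resorption_uptake_closure", "soil_layer_additivity",
                "organic_plus_inorganic_total", "non_negative_pools"),
      residual = c(closure, additivity, org_inorg, min(0, min(pools$value))),
      pass = abs(residual) <= tol
    )
    openness[[pl]] <- tibble::tibble(
      plot_id = pl,
      deposition = val(pl, "deposition_p"),
      leaching = val(pl, "leaching_p"),
      net_input = val(pl, "deposition_p") - val(pl, "leaching_p"),
      uptake = val(pl, "uptake_p"),
      openness_ratio = abs(val(pl, "deposition_p") - val(pl, "leaching_p")) /
        val(pl, "uptake_p")
    )
  }
  checks <- dplyr::bind_rows(checks)
  list(checks = checks,
       openness = dplyr::bind_rows(openness),
       flags = attr(budgets, "flags"),
       pass = all(checks$pass))
}
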