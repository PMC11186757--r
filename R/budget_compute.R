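# The budget engine: maps a set of plot-level primitive quantities
# (concentrations, biomasses, production rates, soil concentrations, carbon
# fluxes) to the full set of named budget variables. Both the closed-form
# generator truth and the measurement-table assembly route through this one
# function, so pipeline-vs-truth equivalence is structural.

# `prim` is a list with elements:
#   conc        named vector, mg P g-1 (components of default_component_params)
#   biomass     named vector, g m-2
#   production  named vector, g m-2 yr-1
#   soil        list of named per-layer vectors (names = layer labels):
#               bulk_density, total_p, inorganic_p, labile_p, microbial_p,
#               soil_c
#   hedley      named vector: exchangeable_pi, exchangeable_po,
#               moderately_labile_po (surface layer, mg P kg-1)
#   netmin_surface  scalar areal flux at the surface layer, g P m-2 yr-1
#   lysimeter_p     scalar, mg P L-1
#   carbon      named vector: gpp_overstorey, gpp_understorey, npp_total
# `layers` is a tibble with top_cm, bottom_cm.
compute_budget <- function(prim, layers, constants = default_flux_constants()) {
  co <- prim$conc
  bm <- prim$biomass
  pr <- prim$production
  need_conc <- c("canopy_green", "canopy_senesced", "understorey_green",
                 "understorey_senesced", "sapwood", "heartwood", "fine_root",
                 "dead_wood", "frass")
  missing_c <- setdiff(need_conc, names(co))
  if (length(missing_c)) {
    abort_data(sprintf("missing tissue concentration(s): %s",
                       paste(missing_c, collapse = ", ")))
  }
  need_bm <- c("canopy", "sapwood", "heartwood", "fine_root", "coarse_root",
               "understorey", "forest_floor_litter", "dead_wood")
  missing_b <- setdiff(need_bm, names(bm))
  if (length(missing_b)) {
    abort_data(sprintf("missing biomass pool(s): %s",
                       paste(missing_b, collapse = ", ")))
  }
  need_pr <- c("canopy_litter", "frass", "reproduction", "wood", "coarse_root",
               "fine_root", "understorey")
  missing_p <- setdiff(need_pr, names(pr))
  if (length(missing_p)) {
    abort_data(sprintf("missing production flux(es): %s",
                       paste(missing_p, collapse = ", ")))
  }

  lab <- layer_label(layers$top_cm, layers$bottom_cm)
  laymat <- cbind(layers$top_cm, layers$bottom_cm)

  row <- function(variable, value, unit, type) {
    tibble::tibble(variable = variable, value = unname(value), unit = unit,
                   type = type)
  }
  pool <- function(v, x) row(v, x, "g_P_per_m2", "pool")
  flux <- function(v, x) row(v, x, "g_P_per_m2_per_yr", "flux")

  ## ---- plant and litter pools -------------------------------------------
  pools <- c(
    canopy_p = plant_pool(co[["canopy_green"]], bm[["canopy"]]),
    sapwood_p = plant_pool(co[["sapwood"]], bm[["sapwood"]]),
    heartwood_p = plant_pool(co[["heartwood"]], bm[["heartwood"]]),
    fine_root_p = plant_pool(co[["fine_root"]], bm[["fine_root"]]),
    coarse_root_p = plant_pool(co[["sapwood"]], bm[["coarse_root"]]),
    understorey_p = plant_pool(co[["understorey_green"]], bm[["understorey"]]),
    forest_floor_litter_p = plant_pool(co[["canopy_senesced"]], bm[["forest_floor_litter"]]),
    standing_dead_p = plant_pool(co[["dead_wood"]], bm[["dead_wood"]])
  )
  plant_litter_p <- sum(pools)
  wood_p <- pools[["sapwood_p"]] + pools[["heartwood_p"]]

  ## ---- soil pools --------------------------------------------------------
  sl <- prim$soil
  tot_l <- soil_pool(sl$total_p, sl$bulk_density, laymat)
  inorg_l <- soil_pool(sl$inorganic_p, sl$bulk_density, laymat)
  org_l <- tot_l - inorg_l # organic P by difference, at the pool level
  mic_l <- soil_pool(sl$microbial_p, sl$bulk_density, laymat)
  labp_l <- soil_pool(sl$labile_p, sl$bulk_density, laymat)

  hed <- hedley_group(prim$hedley[["exchangeable_pi"]],
                      prim$hedley[["exchangeable_po"]],
                      prim$hedley[["moderately_labile_po"]],
                      total_p = sl$total_p[1])
  hed_pool <- vapply(
    hed[c("exchangeable_pi", "exchangeable_po", "moderately_labile_po", "residual")],
    function(x) soil_pool(x, sl$bulk_density[1], laymat[1, , drop = TRUE]),
    numeric(1))

  ## ---- vegetation fluxes -------------------------------------------------
  frass_p <- co[["frass"]] * pr[["frass"]] / 1000
  prod <- c(
    canopy_production_p = canopy_production(
      co[["canopy_green"]] * pr[["canopy_litter"]] / 1000, frass_p),
    understorey_production_p = co[["understorey_green"]] * pr[["understorey"]] / 1000,
    wood_production_p = co[["sapwood"]] * pr[["wood"]] / 1000,
    reproduction_production_p = co[["sapwood"]] * pr[["reproduction"]] / 1000,
    coarse_root_production_p = co[["sapwood"]] * pr[["coarse_root"]] / 1000,
    fine_root_production_p = co[["fine_root"]] * pr[["fine_root"]] / 1000
  )
  demand <- plant_demand(prod)

  rf_canopy <- resorption_fraction(co[["canopy_green"]], co[["canopy_senesced"]])
  rf_under <- resorption_fraction(co[["understorey_green"]], co[["understorey_senesced"]])
  rf_sap <- resorption_fraction(co[["sapwood"]], co[["heartwood"]])
  rf_fine <- constants[["fine_root_resorption"]]
  resorp <- c(
    resorption_canopy_p = as.numeric(rf_canopy) * prod[["canopy_production_p"]],
    resorption_understorey_p = as.numeric(rf_under) * prod[["understorey_production_p"]],
    resorption_wood_p = as.numeric(rf_sap) * prod[["wood_production_p"]],
    resorption_coarse_root_p = as.numeric(rf_sap) * prod[["coarse_root_production_p"]],
    resorption_fine_root_p = rf_fine * prod[["fine_root_production_p"]]
  )
  resorption <- sum(resorp)
  uptake <- suppressWarnings(plant_uptake(demand, resorption))

  canopy_litter_p <- co[["canopy_senesced"]] * pr[["canopy_litter"]] / 1000

  ## ---- soil fluxes -------------------------------------------------------
  c_stock <- soil_pool(sl$soil_c, sl$bulk_density, laymat)
  netmin_l <- profile_scale(prim$netmin_surface, c_stock)
  leach <- leaching_flux(prim$lysimeter_p, constants[["drainage_ml_m2_d"]])
  depo <- constants[["deposition_g_m2_yr"]]

  ## ---- indicators --------------------------------------------------------
  mrt <- mean_residence_time(pools[["canopy_p"]], pools[["sapwood_p"]],
                             pools[["fine_root_p"]], pools[["understorey_p"]],
                             uptake)
  cb <- prim$carbon
  pue <- p_use_efficiencies(cb[["gpp_overstorey"]], cb[["gpp_understorey"]],
                            cb[["npp_total"]],
                            prod[["canopy_production_p"]],
                            prod[["understorey_production_p"]], uptake)
  cf <- constants[["carbon_frac_mg_g"]]

  dplyr::bind_rows(
    pool(names(pools), pools),
    pool("wood_p", wood_p),
    pool("plant_litter_p", plant_litter_p),
    pool(paste0("soil_total_p_", lab), tot_l),
    pool("soil_total_p", sum(tot_l)),
    pool(paste0("soil_organic_p_", lab), org_l),
    pool("soil_organic_p", sum(org_l)),
    pool(paste0("soil_inorganic_p_", lab), inorg_l),
    pool("soil_inorganic_p", sum(inorg_l)),
    pool(paste0("microbial_p_", lab), mic_l),
    pool("microbial_p", sum(mic_l)),
    pool(paste0("labile_p_", lab), labp_l),
    pool("labile_p", sum(labp_l)),
    pool("organic_residual_p", sum(org_l) - sum(mic_l)),
    pool("inorganic_residual_p", sum(inorg_l) - sum(labp_l)),
    pool("ecosystem_total_p", plant_litter_p + sum(tot_l)),
    pool(paste0("hedley_", names(hed_pool)), hed_pool),
    flux(names(prod), prod),
    flux("frass_p", frass_p),
    flux("canopy_litter_p", canopy_litter_p),
    flux("demand_p", demand),
    flux(names(resorp), resorp),
    flux("resorption_p", resorption),
    flux("uptake_p", uptake),
    flux(paste0("netmin_p_", lab), netmin_l),
    flux("netmin_p", sum(netmin_l)),
    flux("leaching_p", leach),
    flux("deposition_p", depo),
    row("mrt_years", mrt, "yr", "indicator"),
    row(names(pue), pue, "g_C_per_g_P", "indicator"),
    row(c("cp_canopy", "cp_sapwood", "cp_fine_root", "cp_understorey"),
        cp_ratio(co[c("canopy_green", "sapwood", "fine_root", "understorey_green")], cf),
        "g_C_per_g_P", "indicator"),
    row(c("resorption_fraction_canopy", "resorption_fraction_understorey",
          "resorption_fraction_sapwood"),
        c(rf_canopy, rf_under, rf_sap), "fraction", "indicator")
  )
}

# Expected (noise-free) plot-level primitives for one treatment, with CO2
# multipliers applied when treatment == "elevated".
config_primitives <- function(config, treatment = c("ambient", "elevated")) {
  treatment <- match.arg(treatment)
  cp <- config$component_params
  sp <- config$soil_params
  mult <- config$co2_multipliers
  m <- function(key) {
    if (treatment == "ambient" || !length(mult)) return(1)
    out <- if (key %in% names(mult)) unname(mult[[key]]) else 1
    # convenience keys scale every production rate uniformly
    if (grepl("^prod_", key)) {
      for (k in c("uptake", "demand", "production")) {
        if (k %in% names(mult)) out <- out * unname(mult[[k]])
      }
    }
    out
  }
  pick <- function(q) {
    d <- cp[cp$quantity == q, ]
    stats::setNames(d$mean, d$component)
  }
  conc <- pick("conc")
  biomass <- pick("biomass")
  production <- pick("production")
  for (nm in names(conc)) conc[nm] <- conc[nm] * m(paste0("conc_", nm))
  for (nm in names(biomass)) biomass[nm] <- biomass[nm] * m(paste0("mass_", nm))
  for (nm in names(production)) production[nm] <- production[nm] * m(paste0("prod_", nm))

  lay <- sp$layers
  lab <- layer_label(lay$top_cm, lay$bottom_cm)
  soil <- list(
    bulk_density = stats::setNames(lay$bulk_density, lab),
    total_p = stats::setNames(lay$total_p * m("soil_total_p"), lab),
    inorganic_p = stats::setNames(lay$inorganic_p * m("soil_inorganic_p"), lab),
    labile_p = stats::setNames(lay$labile_p * m("soil_labile_p"), lab),
    microbial_p = stats::setNames(lay$microbial_p * m("soil_microbial_p"), lab),
    soil_c = stats::setNames(lay$soil_c * m("soil_c"), lab)
  )
  site <- stats::setNames(sp$site$mean, sp$site$variable)
  hedley <- c(
    exchangeable_pi = unname(site["hedley_exchangeable_pi"]) * m("hedley_exchangeable_pi"),
    exchangeable_po = unname(site["hedley_exchangeable_po"]) * m("hedley_exchangeable_po"),
    moderately_labile_po = unname(site["hedley_moderately_labile_po"]) *
      m("hedley_moderately_labile_po")
  )
  carbon <- stats::setNames(config$carbon_params$mean, config$carbon_params$variable)
  for (nm in names(carbon)) carbon[nm] <- carbon[nm] * m(nm)

  list(
    conc = conc, biomass = biomass, production = production, soil = soil,
    hedley = hedley,
    netmin_surface = unname(site["netmin_surface"]) * m("netmin"),
    lysimeter_p = unname(site["lysimeter_p"]) * m("lysimeter_p"),
    carbon = carbon
  )
}

#' Noise-free expected budget (generator truth)
#'
#' Computes, in closed form from a [site_config()], the expected value of
#' every budget variable for one treatment: the values the full pipeline
#' recovers exactly when all CVs are zero, and in expectation otherwise. The
#' truth obeys all budget identities (demand = resorption + uptake; totals =
#' sums of parts) by construction.
#'
#' @param config A [site_config()] object.
#' @param treatment `"ambient"` or `"elevated"` (applies `co2_multipliers`).
#' @return A tibble with columns `variable`, `value`, `unit`, `type`.
#' @examples
#' tr <- budget_truth(site_config())
#' tr$value[tr$variable == "soil_total_p"] # 31.8
#' @export
budget_truth <- function(config, treatment = c("ambient", "elevated")) {
  validate_config(config)
  treatment <- match.arg(treatment)
  lay <- tibble::tibble(
    top_cm = vapply(config$depth_layers, `[`, numeric(1), 1L),
    bottom_cm = vapply(config$depth_layers, `[`, numeric(1), 2L)
  )
  compute_budget(config_primitives(config, treatment), lay,
                 config$flux_constants)
}

#' Look up one variable in a budget table
#'
#' @param budget A tibble with `variable` and `value` columns (as returned by
#'   [budget_truth()], or one plot of [assemble_budgets()]).
#' @param variable Variable name.
#' @return The scalar value.
#' @export
budget_value <- function(budget, variable) {
  i <- match(variable, budget$variable)
  if (is.na(i)) abort_data(sprintf("unknown budget variable '%s'", variable))
  budget$value[i]
}
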