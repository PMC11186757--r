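# Flux-level accounting operations. Canonical internal units are
# g P m-2 yr-1 for fluxes.

#' Annualize an interval flux series
#'
#' Sums non-overlapping interval measurements (g m\eqn{^{-2}} per interval)
#' into an annual total. When the intervals do not cover the full year the sum
#' is scaled by `365 / covered_days`; coverage at or above a full year is
#' never scaled down.
#'
#' @param start,end Interval start and end `Date`s (end exclusive).
#' @param value Flux measured over each interval, g m\eqn{^{-2}} per interval.
#' @return Annual flux (g m\eqn{^{-2}} yr\eqn{^{-1}}) with attribute
#'   `coverage` (covered days / 365).
#' @examples
#' m <- seq(as.Date("2014-01-01"), by = "month", length.out = 12)
#' annualize(m, seq(as.Date("2014-02-01"), by = "month", length.out = 12),
#'           rep(0.02, 12)) # 0.24
#' @export
annualize <- function(start, end, value) {
  start <- as.Date(start)
  end <- as.Date(end)
  if (length(start) != length(end) || length(start) != length(value)) {
    abort_data("annualize: start, end and value must have equal length")
  }
  if (any(end <= start)) abort_data("annualize: intervals must have end > start")
  ord <- order(start)
  if (any(as.numeric(start[ord][-1]) < as.numeric(end[ord][-length(end)]))) {
    abort_data("annualize: overlapping measurement intervals")
  }
  covered <- sum(as.numeric(end - start))
  coverage <- covered / 365
  total <- sum(value)
  if (coverage < 1) total <- total * 365 / covered
  structure(total, coverage = coverage)
}

#' Canopy leaf P production flux
#'
#' The canopy P production flux is the litterfall-derived production flux plus
#' the independently estimated herbivory (frass) consumption flux, both in
#' g P m\eqn{^{-2}} yr\eqn{^{-1}}.
#'
#' @param litterfall_p Litterfall-derived canopy production P flux.
#' @param herbivory_p Herbivory (frass) P flux.
#' @return Total canopy leaf P production flux.
#' @examples
#' canopy_production(0.24, 0.04) # 0.28
#' @export
canopy_production <- function(litterfall_p, herbivory_p) {
  if (any(litterfall_p < 0) || any(herbivory_p < 0)) {
    abort_domain("canopy_production: fluxes must be >= 0")
  }
  litterfall_p + herbivory_p
}

#' Leaf P resorption fraction
#'
#' `(green - senesced) / green`, clamped to `[0, 1]` with a flag when the
#' senesced concentration exceeds the green one.
#'
#' @param green_conc Fully expanded live leaf P concentration, mg P
#'   g\eqn{^{-1}}.
#' @param senesced_conc Senesced leaf P concentration, mg P g\eqn{^{-1}}.
#' @return Resorption fraction in `[0, 1]` with attribute `flagged`.
#' @examples
#' resorption_fraction(1.0, 0.45) # 0.55
#' @export
resorption_fraction <- function(green_conc, senesced_conc) {
  if (any(green_conc <= 0)) {
    abort_domain("resorption_fraction: green_conc must be > 0")
  }
  if (any(senesced_conc < 0)) {
    abort_domain("resorption_fraction: senesced_conc must be >= 0")
  }
  frac <- (green_conc - senesced_conc) / green_conc
  flagged <- frac < 0
  structure(pmin(pmax(frac, 0), 1), flagged = flagged)
}

#' Total plant P demand
#'
#' The exact sum of all component P production fluxes needed to support one
#' year's biomass growth.
#'
#' @param production_fluxes Named numeric vector of component production P
#'   fluxes, g P m\eqn{^{-2}} yr\eqn{^{-1}}.
#' @return Total demand, g P m\eqn{^{-2}} yr\eqn{^{-1}}.
#' @export
plant_demand <- function(production_fluxes) {
  if (any(production_fluxes < 0)) {
    abort_domain("plant_demand: production fluxes must be >= 0")
  }
  sum(production_fluxes)
}

#' Plant P uptake
#'
#' Uptake is defined by difference: `demand - total resorption`. A negative
#' result (resorption exceeding demand) is retained but flagged with a
#' warning, as it indicates inconsistent inputs rather than a physical flux.
#'
#' @param demand Total plant P demand, g P m\eqn{^{-2}} yr\eqn{^{-1}}.
#' @param total_resorption Total plant P resorption flux.
#' @return Uptake flux, g P m\eqn{^{-2}} yr\eqn{^{-1}}.
#' @examples
#' plant_uptake(0.71, 0.32) # 0.39
#' @export
plant_uptake <- function(demand, total_resorption) {
  if (any(demand < 0) || any(total_resorption < 0)) {
    abort_domain("plant_uptake: inputs must be >= 0")
  }
  uptake <- demand - total_resorption
  if (any(uptake < 0)) {
    rlang::warn("plant_uptake: resorption exceeds demand; negative uptake retained",
                class = "pbudget_negative_uptake_warning")
  }
  uptake
}

#' Extrapolate a surface measurement down a depth profile
#'
#' Scales a surface-layer (0-10 cm) measurement to deeper layers in proportion
#' to a per-layer reference profile: `value(layer) = surface_value *
#' weight(layer) / weight(surface)`. Used both for the net-mineralization flux
#' (weights = per-layer soil carbon stocks) and for microbial / labile P
#' concentrations (weights = deep-campaign concentrations).
#'
#' @param surface_value The measured surface-layer value.
#' @param weights Per-layer reference values, surface layer first.
#' @return Per-layer values; the surface layer returns `surface_value`
#'   unchanged.
#' @examples
#' profile_scale(0.5, c(1.0, 0.6, 0.2)) # 0.5 0.3 0.1
#' @export
profile_scale <- function(surface_value, weights) {
  if (length(weights) < 1 || weights[1] <= 0) {
    abort_domain("profile_scale: surface reference weight must be > 0")
  }
  if (any(weights < 0)) abort_domain("profile_scale: weights must be >= 0")
  surface_value * weights / weights[1]
}

#' Soil P leaching flux
#'
#' Converts a lysimeter phosphate concentration into an annual areal flux
#' under an assumed constant drainage water efflux:
#' `flux = conc (mg P L-1) * drainage (ml m-2 d-1) * 365 * 1e-6`.
#'
#' @param phosphate_conc Lysimeter phosphate concentration, mg P L\eqn{^{-1}}.
#' @param drainage Drainage water efflux, ml m\eqn{^{-2}} d\eqn{^{-1}}
#'   (default 20).
#' @return Leaching flux, g P m\eqn{^{-2}} yr\eqn{^{-1}}.
#' @examples
#' leaching_flux(0.01) # 7.3e-05
#' @export
leaching_flux <- function(phosphate_conc, drainage = 20) {
  if (any(phosphate_conc < 0) || any(drainage < 0)) {
    abort_domain("leaching_flux: inputs must be >= 0")
  }
  phosphate_conc * drainage * 365 * 1e-6
}
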