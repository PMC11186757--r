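# Derived whole-plant indicators.

#' Mean residence time of P in the standing vegetation
#'
#' The standing vegetation P pool — canopy, sapwood, fine roots and
#' understorey aboveground, excluding heartwood and coarse roots — divided by
#' the annual plant P uptake flux.
#'
#' @param canopy_p,sapwood_p,fine_root_p,understorey_p Component pools,
#'   g P m\eqn{^{-2}}.
#' @param uptake Plant P uptake flux, g P m\eqn{^{-2}} yr\eqn{^{-1}}; must be
#'   > 0.
#' @return Mean residence time, years.
#' @examples
#' mean_residence_time(0.23, 0.36, 0.24, 0.23, uptake = 0.39) # ~2.72 yr
#' @export
mean_residence_time <- function(canopy_p, sapwood_p, fine_root_p, understorey_p,
                                uptake) {
  if (any(uptake <= 0)) {
    abort_domain("mean_residence_time: uptake must be > 0")
  }
  (canopy_p + sapwood_p + fine_root_p + understorey_p) / uptake
}

#' Phosphorus-use efficiencies
#'
#' Carbon fixed or produced per unit P (g C g\eqn{^{-1}} P):
#' * `pue_gpp_overstorey`: overstorey GPP over the canopy leaf P production
#'   flux;
#' * `pue_gpp_understorey`: understorey GPP over the understorey leaf P
#'   production flux;
#' * `pue_gpp_total`: combined GPP over the combined leaf P production flux;
#' * `pue_growth`: total net primary production over the plant P uptake flux.
#'
#' @param gpp_overstorey,gpp_understorey,npp_total Carbon fluxes, g C
#'   m\eqn{^{-2}} yr\eqn{^{-1}}.
#' @param canopy_production_p,understorey_production_p Leaf P production
#'   fluxes, g P m\eqn{^{-2}} yr\eqn{^{-1}}; must be > 0.
#' @param uptake Plant P uptake flux; must be > 0.
#' @return Named numeric vector of the four efficiencies.
#' @export
p_use_efficiencies <- function(gpp_overstorey, gpp_understorey, npp_total,
                               canopy_production_p, understorey_production_p,
                               uptake) {
  if (any(c(canopy_production_p, understorey_production_p, uptake) <= 0)) {
    abort_domain("p_use_efficiencies: P flux denominators must be > 0")
  }
  c(
    pue_gpp_overstorey = gpp_overstorey / canopy_production_p,
    pue_gpp_understorey = gpp_understorey / understorey_production_p,
    pue_gpp_total = (gpp_overstorey + gpp_understorey) /
      (canopy_production_p + understorey_production_p),
    pue_growth = npp_total / uptake
  )
}

#' Tissue C:P mass ratio
#'
#' `carbon content (mg C g-1) / P concentration (mg P g-1)`, i.e.
#' g C g\eqn{^{-1}} P.
#'
#' @param p_conc Tissue P concentration, mg P g\eqn{^{-1}}; must be > 0.
#' @param carbon_frac Tissue carbon content, mg C g\eqn{^{-1}} (default 480).
#' @return C:P mass ratio, g C g\eqn{^{-1}} P.
#' @export
cp_ratio <- function(p_conc, carbon_frac = 480) {
  if (any(p_conc <= 0)) abort_domain("cp_ratio: p_conc must be > 0")
  carbon_frac / p_conc
}
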