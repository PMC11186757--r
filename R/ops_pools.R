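# Pool-level accounting operations. Canonical internal units are
# g P m-2 for pools; conversion from measurement units happens here, once.

#' Plant P pool from tissue concentration and biomass
#'
#' The concentration-by-biomass approach:
#' `pool (g P m-2) = concentration (mg P g-1) * biomass (g m-2) / 1000`.
#'
#' @param concentration Tissue P concentration, mg P g\eqn{^{-1}} dry mass.
#' @param biomass Standing biomass, g m\eqn{^{-2}}.
#' @return Pool size, g P m\eqn{^{-2}}. Vectorized.
#' @examples
#' plant_pool(0.5, 460) # 0.23 g P m-2
#' @export
plant_pool <- function(concentration, biomass) {
  if (any(concentration < 0) || any(biomass < 0)) {
    abort_domain("plant_pool: concentration and biomass must be >= 0")
  }
  concentration * biomass / 1000
}

#' Soil P pool from concentration, bulk density and layer depth
#'
#' `pool (g P m-2) = concentration (mg P kg-1) * bulk density (g cm-3) *
#' thickness (cm) * 0.01`. The 0.01 collects the unit conversions
#' (mg/kg x g/cm3 x cm -> g/m2).
#'
#' @param concentration Soil P concentration, mg P kg\eqn{^{-1}} dry soil.
#' @param bulk_density Bulk density, g cm\eqn{^{-3}}.
#' @param layer Numeric `c(top_cm, bottom_cm)`, or a two-column matrix for the
#'   vectorized case.
#' @return Pool size, g P m\eqn{^{-2}}.
#' @examples
#' soil_pool(100, 1.5, c(0, 10)) # 15 g P m-2
#' @export
soil_pool <- function(concentration, bulk_density, layer) {
  if (any(concentration < 0) || any(bulk_density < 0)) {
    abort_domain("soil_pool: concentration and bulk_density must be >= 0")
  }
  if (is.matrix(layer)) {
    top <- layer[, 1]
    bottom <- layer[, 2]
  } else {
    top <- layer[1]
    bottom <- layer[2]
  }
  if (any(bottom <= top)) {
    abort_domain("soil_pool: layer must have bottom_cm > top_cm")
  }
  concentration * bulk_density * (bottom - top) * 0.01
}

#' Microbial biomass P from a chloroform-fumigation extract pair
#'
#' `(fumigated - unfumigated) / kEP`, with the extraction-efficiency factor
#' `kEP = 0.4` by default. A negative fumigation difference is clamped to zero
#' and flagged with a warning (condition class `pbudget_clamp_warning`), since
#' a negative microbial pool is not physical.
#'
#' @param fumigated_extract,unfumigated_extract Extractable P, mg P
#'   kg\eqn{^{-1}}; vectorized.
#' @param kEP Extraction efficiency, in (0, 1].
#' @param warn Emit the clamp warning (set `FALSE` for bulk use; clamped
#'   counts are then reported by the caller).
#' @return Microbial biomass P concentration, mg P kg\eqn{^{-1}}, with
#'   attribute `n_clamped`.
#' @examples
#' microbial_p(3.0, 1.8) # (3.0 - 1.8) / 0.4 = 3.0
#' @export
microbial_p <- function(fumigated_extract, unfumigated_extract, kEP = 0.4,
                        warn = TRUE) {
  if (kEP <= 0) abort_domain("microbial_p: kEP must be > 0")
  if (any(fumigated_extract < 0) || any(unfumigated_extract < 0)) {
    abort_domain("microbial_p: extract concentrations must be >= 0")
  }
  diff <- fumigated_extract - unfumigated_extract
  n_clamped <- sum(diff < 0)
  if (n_clamped > 0 && warn) {
    rlang::warn(sprintf(
      "microbial_p: %d fumigation difference(s) < 0 clamped to 0", n_clamped),
      class = "pbudget_clamp_warning")
  }
  out <- pmax(diff, 0) / kEP
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Group Hedley fractionation measurements
#'
#' Groups sequential-extraction fractions into exchangeable inorganic P,
#' exchangeable organic P, moderately labile organic P, and a residual
#' (occluded) pool defined by difference from total P:
#' `residual = total - sum(other fractions)`, floored at zero with a flag
#' when the fractions over-sum the total.
#'
#' @param exchangeable_pi,exchangeable_po,moderately_labile_po Fraction
#'   concentrations, mg P kg\eqn{^{-1}}.
#' @param total_p Total soil P (aqua-regia), mg P kg\eqn{^{-1}}.
#' @return A list with the four grouped fractions (same units as the inputs)
#'   and `flagged` (`TRUE` when the residual was floored).
#' @examples
#' hedley_group(2, 1, 3, total_p = 10)$residual # 4
#' @export
hedley_group <- function(exchangeable_pi, exchangeable_po, moderately_labile_po,
                         total_p) {
  if (any(total_p < 0)) abort_domain("hedley_group: total_p must be >= 0")
  fr <- c(exchangeable_pi, exchangeable_po, moderately_labile_po)
  if (any(fr < 0)) abort_domain("hedley_group: fraction values must be >= 0")
  residual <- total_p - (exchangeable_pi + exchangeable_po + moderately_labile_po)
  flagged <- residual < 0
  list(
    exchangeable_pi = exchangeable_pi,
    exchangeable_po = exchangeable_po,
    moderately_labile_po = moderately_labile_po,
    residual = pmax(residual, 0),
    flagged = flagged
  )
}
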