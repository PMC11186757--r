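#' Default plant-component parameters
#'
#' Plot-level means and between-plot coefficients of variation (CV) for every
#' measured plant quantity the generator emulates: tissue P concentrations
#' (mg P g\eqn{^{-1}}), standing biomass pools (g m\eqn{^{-2}}) and annual
#' biomass production or litter mass fluxes (g m\eqn{^{-2}} yr\eqn{^{-1}}).
#'
#' The defaults are calibrated so that the noise-free budget implied by
#' [site_config()] reproduces the ambient-treatment pools and fluxes of a
#' mature P-limited eucalypt woodland: canopy 0.23, sapwood 0.36, heartwood
#' 0.30, fine-root 0.24, coarse-root 0.15, understorey 0.23, forest-floor
#' litter 0.06 and standing dead wood 0.04 g P m\eqn{^{-2}}; plant P demand
#' 0.71, resorption 0.32 and uptake 0.39 g P m\eqn{^{-2}} yr\eqn{^{-1}}.
#' CVs are back-computed from the reported between-plot SD/mean ratios where
#' available, split evenly (in quadrature) between the concentration and the
#' mass term of each pool.
#'
#' @return A tibble with columns `quantity` (`"conc"`, `"biomass"` or
#'   `"production"`), `component`, `mean`, `cv` and `unit`.
#' @export
default_component_params <- function() {
  tibble::tribble(
    ~quantity,    ~component,            ~mean,        ~cv,  ~unit,
    "conc",       "canopy_green",        0.5,          0.05, "mg_P_per_g",
    "conc",       "canopy_senesced",     0.225,        0.05, "mg_P_per_g",
    "conc",       "understorey_green",   0.5,          0.08, "mg_P_per_g",
    "conc",       "understorey_senesced", 23 / 70,     0.08, "mg_P_per_g",
    "conc",       "sapwood",             0.09,         0.15, "mg_P_per_g",
    "conc",       "heartwood",           0.045,        0.03, "mg_P_per_g",
    "conc",       "fine_root",           0.4,          0.08, "mg_P_per_g",
    "conc",       "dead_wood",           0.062,        0.10, "mg_P_per_g",
    "conc",       "frass",               0.8,          0.10, "mg_P_per_g",
    "biomass",    "canopy",              460,          0.06, "g_per_m2",
    "biomass",    "sapwood",             4000,         0.15, "g_per_m2",
    "biomass",    "heartwood",           20000 / 3,    0.03, "g_per_m2",
    "biomass",    "fine_root",           600,          0.09, "g_per_m2",
    "biomass",    "coarse_root",         5000 / 3,     0.12, "g_per_m2",
    "biomass",    "understorey",         460,          0.12, "g_per_m2",
    "biomass",    "forest_floor_litter", 800 / 3,      0.07, "g_per_m2",
    "biomass",    "dead_wood",           40 / 0.062,   0.35, "g_per_m2",
    "production", "canopy_litter",       480,          0.05, "g_per_m2_per_interval",
    "production", "frass",               50,           0.15, "g_per_m2_per_interval",
    "production", "reproduction",        1000 / 9,     0.20, "g_per_m2_per_interval",
    "production", "wood",                1000 / 3,     0.15, "g_per_m2_per_interval",
    "production", "coarse_root",         1000 / 9,     0.15, "g_per_m2_per_interval",
    "production", "fine_root",           250,          0.10, "g_per_m2_per_interval",
    "production", "understorey",         560,          0.12, "g_per_m2_per_interval"
  )
}

#' Default soil parameters by depth layer
#'
#' Per-layer concentration means (mg P kg\eqn{^{-1}} soil except where noted),
#' bulk density (g cm\eqn{^{-3}}) and between-plot CVs for the three default
#' depth layers 0-10, 10-30 and 30-60 cm. Calibrated so that the implied soil
#' pools over the top 60 cm are 31.8 g P m\eqn{^{-2}} total (25.1 organic +
#' 6.7 inorganic), 5.97 microbial and 1.15 labile, the 0-10 cm net
#' mineralization flux extrapolates to 0.67 g P m\eqn{^{-2}} yr\eqn{^{-1}}
#' over 0-60 cm with soil-carbon stock weights 1 : 0.55 : 0.25, and leaching
#' is negligible.
#'
#' @return A list with elements `layers` (tibble of per-layer values) and
#'   `site` (tibble of single-valued soil quantities: surface net
#'   mineralization, lysimeter phosphate, Hedley fraction concentrations).
#' @export
default_soil_params <- function() {
  layers <- tibble::tibble(
    top_cm = c(0, 10, 30),
    bottom_cm = c(10, 30, 60),
    bulk_density = c(1.5, 1.6, 1.7),
    bulk_density_cv = 0.05,
    total_p = c(80, 33.75, 300 / 17),
    total_p_cv = 0.18,
    inorganic_p = c(2.2 / 0.15, 2.3 / 0.32, 2.2 / 0.51),
    inorganic_p_cv = 0.17,
    labile_p = c(4.0, 0.35 / 0.32, 0.2 / 0.51),
    labile_p_cv = 0.24,
    microbial_p = c(3.2 / 0.15, 1.9 / 0.32, 0.87 / 0.51),
    microbial_p_cv = 0.24,
    soil_c = c(20, 1.65 / 0.32, 0.75 / 0.51), # g C kg-1; stock weights 1:0.55:0.25
    soil_c_cv = 0.10
  )
  site <- tibble::tribble(
    ~variable,                     ~mean,            ~cv,  ~unit,
    "netmin_surface",              0.67 / 1.8,       0.21, "g_per_m2_per_interval",
    "lysimeter_p",                 0.05,             0.30, "mg_P_per_L",
    "hedley_exchangeable_pi",      2.5,              0.20, "mg_P_per_kg",
    "hedley_exchangeable_po",      3.5,              0.20, "mg_P_per_kg",
    "hedley_moderately_labile_po", 14.0,             0.20, "mg_P_per_kg"
  )
  list(layers = layers, site = site)
}

#' Default per-plot carbon fluxes
#'
#' Overstorey and understorey gross primary production and total net primary
#' production (g C m\eqn{^{-2}} yr\eqn{^{-1}}), used only for the P-use
#' efficiency indicators.
#'
#' @return A tibble with columns `variable`, `mean`, `cv`.
#' @export
default_carbon_params <- function() {
  tibble::tribble(
    ~variable,          ~mean, ~cv,
    "gpp_overstorey",   1500,  0.06,
    "gpp_understorey",  400,   0.10,
    "npp_total",        507,   0.05
  )
}

#' Accounting constants of the budget
#'
#' `kEP`: chloroform-fumigation extraction efficiency used to convert the
#' fumigated-minus-unfumigated extractable P difference into microbial biomass
#' P. `fine_root_resorption`: fixed fine-root resorption coefficient.
#' `drainage_ml_m2_d`: assumed drainage water efflux (ml m\eqn{^{-2}}
#' d\eqn{^{-1}}) converting lysimeter phosphate concentration into the
#' leaching flux. `deposition_g_m2_yr`: atmospheric P deposition constant.
#' `carbon_frac_mg_g`: tissue carbon content used for C:P ratios.
#'
#' @return A named numeric vector.
#' @export
default_flux_constants <- function() {
  c(
    kEP = 0.4,
    fine_root_resorption = 0.5,
    drainage_ml_m2_d = 20,
    deposition_g_m2_yr = 0.004,
    carbon_frac_mg_g = 480
  )
}

#' Synthetic site configuration
#'
#' Full parameterization of the synthetic FACE site: experimental design
#' (plots, sub-replicates, years, depth layers), component and soil parameter
#' tables, carbon fluxes, accounting constants, multiplicative CO2 treatment
#' effects, and the noise model.
#'
#' @param n_plots_per_treatment Number of plots per CO2 treatment (default 3).
#' @param years Calendar years covered by the campaign (default 2013-2018).
#' @param depth_layers List of `c(top_cm, bottom_cm)` soil layers; must be
#'   contiguous, non-overlapping and ascending.
#' @param n_litter_traps Litter traps per plot (default 8).
#' @param n_soil_subplots Soil subplots per plot (default 4).
#' @param component_params See [default_component_params()].
#' @param soil_params See [default_soil_params()]. Layer rows must match
#'   `depth_layers`.
#' @param carbon_params See [default_carbon_params()].
#' @param flux_constants See [default_flux_constants()].
#' @param co2_multipliers Named numeric vector of multiplicative effects
#'   applied to elevated-treatment expectations. Names are generator variable
#'   keys (`conc_<component>`, `mass_<component>`, `prod_<component>`,
#'   `soil_total_p`, `soil_inorganic_p`, `soil_labile_p`, `soil_microbial_p`,
#'   `soil_c`, `netmin`, `lysimeter_p`, `hedley_*`, `gpp_overstorey`,
#'   `gpp_understorey`, `npp_total`) or one of the convenience keys `uptake`,
#'   `demand`, `production`, each of which scales every biomass-production
#'   rate uniformly (so demand, resorption and uptake all scale by the same
#'   factor and the budget identities are preserved). Default: none (all 1).
#' @param noise_model `"truncated-normal"` (zero-truncated, the default) or
#'   `"lognormal"` (exactly mean-unbiased).
#' @param subrep_cv_factor Sub-replicate (and repeated-measurement) CV as a
#'   fraction of the plot-level CV (default 0.5).
#' @param seed Master seed stored with the configuration.
#'
#' @return An object of class `site_config` (a validated list).
#' @seealso [budget_truth()], [generate_measurements()], [co2_preset_observed()]
#' @export
site_config <- function(n_plots_per_treatment = 3,
                        years = 2013:2018,
                        depth_layers = list(c(0, 10), c(10, 30), c(30, 60)),
                        n_litter_traps = 8,
                        n_soil_subplots = 4,
                        component_params = default_component_params(),
                        soil_params = default_soil_params(),
                        carbon_params = default_carbon_params(),
                        flux_constants = default_flux_constants(),
                        co2_multipliers = numeric(),
                        noise_model = c("truncated-normal", "lognormal"),
                        subrep_cv_factor = 0.5,
                        seed = 1L) {
  cfg <- structure(
    list(
      n_plots_per_treatment = as.integer(n_plots_per_treatment),
      years = sort(as.integer(years)),
      depth_layers = depth_layers,
      n_litter_traps = as.integer(n_litter_traps),
      n_soil_subplots = as.integer(n_soil_subplots),
      component_params = component_params,
      soil_params = soil_params,
      carbon_params = carbon_params,
      flux_constants = flux_constants,
      co2_multipliers = co2_multipliers,
      noise_model = match.arg(noise_model),
      subrep_cv_factor = subrep_cv_factor,
      seed = as.integer(seed)
    ),
    class = "site_config"
  )
  validate_config(cfg)
  cfg
}

#' Validate a site configuration
#'
#' Checks the design invariants (positive means, CV < 1, contiguous ascending
#' depth layers, strictly positive multipliers with known keys) and signals a
#' `pbudget_config_error` naming the offending field on failure.
#'
#' @param config A [site_config()] object.
#' @return `config`, invisibly.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "site_config")) {
    abort_config("config must be created by site_config()")
  }
  if (config$n_plots_per_treatment < 1) {
    abort_config("n_plots_per_treatment must be >= 1", field = "n_plots_per_treatment")
  }
  if (length(config$years) < 1) abort_config("years must be non-empty", field = "years")
  lay <- config$depth_layers
  if (!length(lay)) abort_config("depth_layers must be non-empty", field = "depth_layers")
  tops <- vapply(lay, `[`, numeric(1), 1L)
  bots <- vapply(lay, `[`, numeric(1), 2L)
  if (any(bots <= tops)) {
    abort_config("depth_layers must have bottom > top", field = "depth_layers")
  }
  if (is.unsorted(tops, strictly = TRUE) ||
      any(tops[-1] != bots[-length(bots)])) {
    abort_config("depth_layers must be contiguous, non-overlapping and ascending",
                 field = "depth_layers")
  }
  cp <- config$component_params
  if (any(cp$mean < 0) || any(!is.finite(cp$mean))) {
    abort_config("component_params means must be finite and >= 0",
                 field = "component_params")
  }
  if (any(cp$cv < 0 | cp$cv >= 1)) {
    abort_config("component_params CVs must satisfy 0 <= CV < 1",
                 field = "component_params")
  }
  sp <- config$soil_params
  if (nrow(sp$layers) != length(lay)) {
    abort_config("soil_params layers must match depth_layers", field = "soil_params")
  }
  num_cols <- vapply(sp$layers, is.numeric, logical(1))
  if (any(as.matrix(sp$layers[, num_cols]) < 0)) {
    abort_config("soil_params values must be >= 0", field = "soil_params")
  }
  cv_cols <- grep("_cv$", names(sp$layers), value = TRUE)
  if (any(as.matrix(sp$layers[, cv_cols]) >= 1)) {
    abort_config("soil_params CVs must be < 1", field = "soil_params")
  }
  if (any(sp$site$mean < 0) || any(sp$site$cv < 0 | sp$site$cv >= 1)) {
    abort_config("soil_params site-level means/CVs out of range", field = "soil_params")
  }
  if (any(config$carbon_params$mean < 0) ||
      any(config$carbon_params$cv < 0 | config$carbon_params$cv >= 1)) {
    abort_config("carbon_params means/CVs out of range", field = "carbon_params")
  }
  mult <- config$co2_multipliers
  if (length(mult)) {
    if (is.null(names(mult)) || any(!nzchar(names(mult)))) {
      abort_config("co2_multipliers must be a named numeric vector",
                   field = "co2_multipliers")
    }
    if (any(mult <= 0)) {
      abort_config("co2_multipliers must be strictly > 0", field = "co2_multipliers")
    }
    unknown <- setdiff(names(mult), multiplier_keys(config))
    if (length(unknown)) {
      abort_config(sprintf("unknown co2_multipliers key(s): %s",
                           paste(unknown, collapse = ", ")),
                   field = "co2_multipliers")
    }
  }
  if (config$subrep_cv_factor < 0 || config$subrep_cv_factor > 1) {
    abort_config("subrep_cv_factor must be in [0, 1]", field = "subrep_cv_factor")
  }
  invisible(config)
}

# All recognized multiplier keys for a configuration.
multiplier_keys <- function(config) {
  cp <- config$component_params
  c(
    paste0("conc_", cp$component[cp$quantity == "conc"]),
    paste0("mass_", cp$component[cp$quantity == "biomass"]),
    paste0("prod_", cp$component[cp$quantity == "production"]),
    "soil_total_p", "soil_inorganic_p", "soil_labile_p", "soil_microbial_p",
    "soil_c", "netmin", "lysimeter_p",
    "hedley_exchangeable_pi", "hedley_exchangeable_po", "hedley_moderately_labile_po",
    config$carbon_params$variable,
    "uptake", "demand", "production"
  )
}

#' CO2 multiplier preset mirroring the observed response pattern
#'
#' A convenience preset qualitatively matching the reported response
#' directions of a mature-forest FACE experiment: increased understorey
#' production and fine-root P concentration (driving plant P demand and
#' uptake upward), increased overstorey GPP (driving leaf-level P-use
#' efficiency upward), and essentially unchanged soil pools. Exact effect
#' magnitudes implied by a preset can be computed with [budget_truth()].
#'
#' @return A named numeric vector usable as `co2_multipliers`.
#' @export
co2_preset_observed <- function() {
  c(
    prod_understorey = 1.10,
    conc_fine_root = 1.07,
    gpp_overstorey = 1.10,
    gpp_understorey = 1.03,
    npp_total = 1.02,
    netmin = 1.02
  )
}

#' @export
print.site_config <- function(x, ...) {
  cat("<site_config>\n")
  cat(sprintf("  %d plots/treatment, years %d-%d, %d litter traps, %d soil subplots\n",
              x$n_plots_per_treatment, min(x$years), max(x$years),
              x$n_litter_traps, x$n_soil_subplots))
  lay <- vapply(x$depth_layers, function(l) sprintf("%g-%g", l[1], l[2]), character(1))
  cat(sprintf("  depth layers (cm): %s\n", paste(lay, collapse = ", ")))
  cat(sprintf("  noise model: %s; seed: %d\n", x$noise_model, x$seed))
  if (length(x$co2_multipliers)) {
    cat("  CO2 multipliers:",
        paste(sprintf("%s=%.3g", names(x$co2_multipliers), x$co2_multipliers),
              collapse = ", "), "\n")
  } else {
    cat("  CO2 multipliers: none (elevated = ambient)\n")
  }
  invisible(x)
}

#' Write / read a site configuration as YAML
#'
#' @param config A [site_config()] object.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `site_config`.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  obj <- list(
    n_plots_per_treatment = config$n_plots_per_treatment,
    years = config$years,
    depth_layers = lapply(config$depth_layers, as.numeric),
    n_litter_traps = config$n_litter_traps,
    n_soil_subplots = config$n_soil_subplots,
    component_params = lapply(as.data.frame(config$component_params), as.vector),
    soil_params = list(
      layers = lapply(as.data.frame(config$soil_params$layers), as.vector),
      site = lapply(as.data.frame(config$soil_params$site), as.vector)
    ),
    carbon_params = lapply(as.data.frame(config$carbon_params), as.vector),
    flux_constants = as.list(config$flux_constants),
    co2_multipliers = as.list(config$co2_multipliers),
    noise_model = config$noise_model,
    subrep_cv_factor = config$subrep_cv_factor,
    seed = config$seed
  )
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  site_config(
    n_plots_per_treatment = obj$n_plots_per_treatment,
    years = obj$years,
    depth_layers = obj$depth_layers,
    n_litter_traps = obj$n_litter_traps,
    n_soil_subplots = obj$n_soil_subplots,
    component_params = tibble::as_tibble(obj$component_params),
    soil_params = list(
      layers = tibble::as_tibble(obj$soil_params$layers),
      site = tibble::as_tibble(obj$soil_params$site)
    ),
    carbon_params = tibble::as_tibble(obj$carbon_params),
    flux_constants = unlist(obj$flux_constants),
    co2_multipliers = unlist(obj$co2_multipliers) %||% numeric(),
    noise_model = obj$noise_model,
    subrep_cv_factor = obj$subrep_cv_factor,
    seed = obj$seed
  )
}
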