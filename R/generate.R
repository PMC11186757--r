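# The synthetic measurement generator. It emulates the sampling design of a
# two-treatment (ambient / elevated CO2), three-plots-per-treatment FACE
# experiment: monthly litter traps, quarterly surface-soil campaigns in the
# first three years, one deep-profile campaign in the penultimate year,
# fumigation extract pairs, in-situ incubation pairs, lysimeters, and annual
# biomass / carbon records.
#
# Noise structure: each plot draws a plot-level value for every primitive
# quantity around the treatment expectation (configured CV); individual
# records (sub-replicates, repeated dates) are drawn around the plot value at
# `subrep_cv_factor` times the plot CV. Elevated-treatment expectations are
# the ambient ones times `co2_multipliers`. All draws are organized in fixed
# per-table RNG substreams of the master seed, so output is bit-identical for
# identical (config, seed) and adding records to one table never shifts the
# draws of another.

measurement_cols <- c("plot_id", "treatment", "date", "component",
                      "depth_top_cm", "depth_bottom_cm", "subrep",
                      "variable", "value", "unit")

#' Controlled unit vocabulary of measurement tables
#' @return Character vector of the accepted `unit` strings.
#' @export
unit_vocabulary <- function() {
  c("mg_P_per_g", "mg_P_per_kg", "g_per_m2", "g_per_m2_per_interval",
    "g_per_cm3", "mg_P_per_L", "g_C_per_m2_per_yr", "g_C_per_kg")
}

plot_frame <- function(config) {
  n <- config$n_plots_per_treatment
  tibble::tibble(
    plot_id = c(paste0("a", seq_len(n)), paste0("e", seq_len(n))),
    treatment = rep(c("ambient", "elevated"), each = n)
  )
}

# Flat registry of plot-level primitives: key, ambient/elevated expectation,
# plot-level CV. Row order is fixed by the parameter tables.
level_registry <- function(config) {
  pa <- config_primitives(config, "ambient")
  pe <- config_primitives(config, "elevated")
  cp <- config$component_params
  lay <- config$soil_params$layers
  lab <- layer_label(lay$top_cm, lay$bottom_cm)
  site <- config$soil_params$site

  rows <- list()
  add <- function(key, amb, ele, cv) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      key = key, mean_amb = unname(amb), mean_ele = unname(ele),
      cv = unname(cv))
  }
  for (q in c("conc", "biomass", "production")) {
    d <- cp[cp$quantity == q, ]
    add(paste0(q, ".", d$component), pa[[q]][d$component], pe[[q]][d$component],
        d$cv)
  }
  for (v in c("bulk_density", "total_p", "inorganic_p", "labile_p",
              "microbial_p", "soil_c")) {
    add(paste0("soil.", v, ".", lab), pa$soil[[v]], pe$soil[[v]],
        lay[[paste0(v, "_cv")]])
  }
  add("site.netmin_surface", pa$netmin_surface, pe$netmin_surface,
      site$cv[site$variable == "netmin_surface"])
  add("site.lysimeter_p", pa$lysimeter_p, pe$lysimeter_p,
      site$cv[site$variable == "lysimeter_p"])
  hed_keys <- c("exchangeable_pi", "exchangeable_po", "moderately_labile_po")
  add(paste0("site.hedley_", hed_keys), pa$hedley[hed_keys], pe$hedley[hed_keys],
      site$cv[match(paste0("hedley_", hed_keys), site$variable)])
  add(paste0("carbon.", config$carbon_params$variable), pa$carbon, pe$carbon,
      config$carbon_params$cv)
  dplyr::bind_rows(rows)
}

# Draw the plot-level values for every primitive (substream "plot_levels").
# Returns a list keyed by primitive, each a named (by plot_id) numeric vector.
draw_plot_levels <- function(config, seed) {
  plots <- plot_frame(config)
  reg <- level_registry(config)
  with_substream(seed, "plot_levels", {
    out <- vector("list", nrow(reg))
    names(out) <- reg$key
    for (i in seq_len(nrow(reg))) {
      mu <- ifelse(plots$treatment == "ambient", reg$mean_amb[i], reg$mean_ele[i])
      out[[i]] <- stats::setNames(
        rnoise(nrow(plots), mu, reg$cv[i], config$noise_model), plots$plot_id)
    }
    out
  })
}

date_ymd <- function(y, m, d = 1L) as.Date(sprintf("%d-%02d-%02d", y, m, d))

dates_monthly <- function(years, day = 1L) {
  as.Date(unlist(lapply(years, function(y)
    as.character(date_ymd(y, 1:12, day)))))
}

dates_quarterly <- function(years, day = 1L) {
  as.Date(unlist(lapply(years, function(y)
    as.character(date_ymd(y, c(1L, 4L, 7L, 10L), day)))))
}

#' Generate synthetic measurement tables
#'
#' Draws the full set of raw measurement tables for a configured synthetic
#' site. The expected value of every assembled budget variable equals the
#' corresponding [budget_truth()] value; with all CVs set to zero the tables
#' are exactly noise-free and the assembled pipeline reproduces the truth to
#' floating-point tolerance.
#'
#' @param config A [site_config()] object.
#' @param seed Master seed (defaults to `config$seed`). Identical
#'   `(config, seed)` gives bit-identical output.
#' @return A named list of ten tibbles (`tissue_concentration`, `biomass`,
#'   `litterfall`, `frass`, `soil_chemistry`, `fumigation_pairs`,
#'   `incubation_pairs`, `lysimeter`, `bulk_density`, `carbon_fluxes`), each
#'   with columns `plot_id, treatment, date, component, depth_top_cm,
#'   depth_bottom_cm, subrep, variable, value, unit`.
#' @export
generate_measurements <- function(config, seed = config$seed) {
  validate_config(config)
  plots <- plot_frame(config)
  lev <- draw_plot_levels(config, seed)
  pv <- function(key) {
    v <- lev[[key]]
    if (is.null(v)) abort_config(sprintf("no plot level for key '%s'", key))
    v
  }
  sub_cv <- function(cv) cv * config$subrep_cv_factor
  model <- config$noise_model
  cp <- config$component_params
  cv_of <- function(q, comp) cp$cv[cp$quantity == q & cp$component == comp]
  lay <- config$soil_params$layers
  lab <- layer_label(lay$top_cm, lay$bottom_cm)
  site <- config$soil_params$site
  site_cv <- function(v) site$cv[site$variable == v]

  yrs <- config$years
  y1 <- min(yrs)
  quarterly_yrs <- yrs[yrs < y1 + 3]
  fum_yrs <- yrs[yrs >= y1 + 1 & yrs < y1 + 3]
  if (!length(fum_yrs)) fum_yrs <- quarterly_yrs
  frass_yrs <- yrs[yrs < y1 + 2]
  campaign_yr <- if (length(yrs) > 1) sort(yrs, decreasing = TRUE)[2] else yrs
  underst_yrs <- yrs[yrs >= y1 + 1 & yrs <= y1 + 4]
  if (!length(underst_yrs)) underst_yrs <- yrs

  # A record spec: grid columns + scalar metadata; values drawn around the
  # plot-level value (times `scale`) at the record-level CV.
  spec_grid <- function(dates, level_key, rec_cv, variable, component = NA_character_,
                        subrep = NA_integer_, layer_i = NA_integer_) {
    g <- tidyr::expand_grid(plot_id = plots$plot_id, date = dates, subrep = subrep)
    g$component <- component
    g$variable <- variable
    g$level_key <- level_key
    g$rec_cv <- rec_cv
    if (!is.na(layer_i)) {
      g$depth_top_cm <- lay$top_cm[layer_i]
      g$depth_bottom_cm <- lay$bottom_cm[layer_i]
    }
    g
  }

  draw_records <- function(spec, unit, scale = 1) {
    mu <- numeric(nrow(spec))
    for (k in unique(spec$level_key)) {
      i <- spec$level_key == k
      mu[i] <- pv(k)[spec$plot_id[i]]
    }
    spec$value <- rnoise(nrow(spec), mu * scale, spec$rec_cv, model)
    spec$unit <- unit
    spec
  }

  finish <- function(d) {
    d$treatment <- plots$treatment[match(d$plot_id, plots$plot_id)]
    for (col in measurement_cols) {
      if (!col %in% names(d)) {
        d[[col]] <- switch(col,
          component = NA_character_,
          depth_top_cm = NA_real_, depth_bottom_cm = NA_real_,
          subrep = NA_integer_, NA)
      }
    }
    tibble::as_tibble(d[measurement_cols])
  }

  ## ---- tissue_concentration ---------------------------------------------
  tissue <- with_substream(seed, "tissue_concentration", {
    tgrid <- function(component, dates, subrep = NA_integer_) {
      spec_grid(dates, paste0("conc.", component),
                sub_cv(cv_of("conc", component)), "tissue_p",
                component = component, subrep = subrep)
    }
    spec <- dplyr::bind_rows(
      tgrid("canopy_green", as.Date(unlist(lapply(yrs, function(y)
        as.character(date_ymd(y, c(2, 5, 10), 15)))))),
      tgrid("canopy_senesced", date_ymd(yrs, 2, 15)),
      tgrid("understorey_green",
            date_ymd(intersect(yrs, c(y1, y1 + 2, y1 + 4)), 2, 15)),
      tgrid("understorey_senesced", date_ymd(campaign_yr, 6, 15)),
      tgrid("sapwood", date_ymd(y1 + 2, 11, 15)),
      tgrid("heartwood", date_ymd(y1 + 2, 11, 15)),
      tgrid("dead_wood", date_ymd(y1 + 2, 11, 15)),
      tgrid("fine_root",
            c(date_ymd(y1 + 1, c(2, 6, 9, 12), 15),
              date_ymd(y1 + 2, c(5, 9), 15), date_ymd(y1 + 3, 2, 15)),
            subrep = seq_len(config$n_soil_subplots)),
      tgrid("frass", dates_monthly(frass_yrs, 15)))
    draw_records(spec, "mg_P_per_g")
  })

  ## ---- biomass (standing pools and production rates) ---------------------
  biomass <- with_substream(seed, "biomass", {
    pool_grid <- function(component, subrep = NA_integer_) {
      spec_grid(date_ymd(yrs, 7), paste0("biomass.", component),
                sub_cv(cv_of("biomass", component)), "standing_pool",
                component = component, subrep = subrep)
    }
    prod_grid <- function(component, years, subrep = NA_integer_) {
      spec_grid(date_ymd(years, 12, 31), paste0("production.", component),
                sub_cv(cv_of("production", component)), "production_rate",
                component = component, subrep = subrep)
    }
    pools <- dplyr::bind_rows(
      lapply(c("canopy", "sapwood", "heartwood", "coarse_root", "understorey",
               "forest_floor_litter", "dead_wood"), pool_grid),
      pool_grid("fine_root", subrep = seq_len(config$n_soil_subplots)))
    prods <- dplyr::bind_rows(
      prod_grid("wood", yrs), prod_grid("coarse_root", yrs),
      prod_grid("fine_root", yrs, subrep = seq_len(config$n_soil_subplots)),
      prod_grid("understorey", underst_yrs,
                subrep = seq_len(config$n_soil_subplots)))
    dplyr::bind_rows(draw_records(pools, "g_per_m2"),
                     draw_records(prods, "g_per_m2_per_interval"))
  })

  ## ---- litterfall and frass traps ---------------------------------------
  litterfall <- with_substream(seed, "litterfall", {
    spec <- dplyr::bind_rows(lapply(c("canopy_litter", "reproduction"),
      function(component) {
        spec_grid(dates_monthly(yrs), paste0("production.", component),
                  sub_cv(cv_of("production", component)), "litter_mass",
                  component = component,
                  subrep = seq_len(config$n_litter_traps))
      }))
    draw_records(spec, "g_per_m2_per_interval", scale = 1 / 12)
  })

  frass <- with_substream(seed, "frass", {
    spec <- spec_grid(dates_monthly(frass_yrs), "production.frass",
                      sub_cv(cv_of("production", "frass")), "frass_mass",
                      component = "frass",
                      subrep = seq_len(config$n_litter_traps))
    draw_records(spec, "g_per_m2_per_interval", scale = 1 / 12)
  })

  ## ---- soil chemistry ----------------------------------------------------
  soil_chem <- with_substream(seed, "soil_chemistry", {
    subs <- seq_len(config$n_soil_subplots)
    qdates <- dates_quarterly(quarterly_yrs, 15)
    camp_date <- date_ymd(campaign_yr, 7, 20)
    sgrid <- function(var, layer_i, dates) {
      spec_grid(dates, paste0("soil.", var, ".", lab[layer_i]),
                sub_cv(lay[[paste0(var, "_cv")]][layer_i]), var,
                subrep = subs, layer_i = layer_i)
    }
    quarterly <- dplyr::bind_rows(sgrid("total_p", 1L, qdates),
                                  sgrid("labile_p", 1L, qdates))
    camp <- dplyr::bind_rows(lapply(seq_len(nrow(lay)), function(li) {
      dplyr::bind_rows(sgrid("total_p", li, camp_date),
                       sgrid("inorganic_p", li, camp_date),
                       sgrid("labile_p", li, camp_date),
                       sgrid("soil_c", li, camp_date))
    }))
    hed <- dplyr::bind_rows(lapply(
      c("hedley_exchangeable_pi", "hedley_exchangeable_po",
        "hedley_moderately_labile_po"),
      function(v) {
        spec_grid(date_ymd(y1, 7, 15), paste0("site.", v),
                  sub_cv(site_cv(v)), v, subrep = subs, layer_i = 1L)
      }))
    out <- draw_records(dplyr::bind_rows(quarterly, camp, hed), "mg_P_per_kg")
    out$unit[out$variable == "soil_c"] <- "g_C_per_kg"
    out
  })

  ## ---- fumigation pairs --------------------------------------------------
  fumigation <- with_substream(seed, "fumigation_pairs", {
    subs <- seq_len(config$n_soil_subplots)
    kEP <- config$flux_constants[["kEP"]]
    fdates <- dates_quarterly(fum_yrs, 15)
    camp_date <- date_ymd(campaign_yr, 7, 20)
    pair_grid <- function(layer_i, dates) {
      g <- tidyr::expand_grid(plot_id = plots$plot_id, date = dates,
                              subrep = subs)
      unfum <- rnoise(nrow(g), pv(paste0("soil.labile_p.", lab[layer_i]))[g$plot_id],
                      sub_cv(lay$labile_p_cv[layer_i]), model)
      mic <- rnoise(nrow(g), pv(paste0("soil.microbial_p.", lab[layer_i]))[g$plot_id],
                    sub_cv(lay$microbial_p_cv[layer_i]), model)
      g$depth_top_cm <- lay$top_cm[layer_i]
      g$depth_bottom_cm <- lay$bottom_cm[layer_i]
      g$unit <- "mg_P_per_kg"
      dplyr::bind_rows(
        dplyr::mutate(g, variable = "unfumigated_p", value = unfum),
        dplyr::mutate(g, variable = "fumigated_p", value = unfum + kEP * mic))
    }
    dplyr::bind_rows(
      pair_grid(1L, fdates),
      dplyr::bind_rows(lapply(seq_len(nrow(lay)), pair_grid, dates = camp_date)))
  })

  ## ---- incubation pairs (in-situ net mineralization, surface layer) ------
  incubation <- with_substream(seed, "incubation_pairs", {
    subs <- seq_len(config$n_soil_subplots)
    g <- tidyr::expand_grid(plot_id = plots$plot_id,
                            date = dates_quarterly(quarterly_yrs), subrep = subs)
    bd1 <- pv(paste0("soil.bulk_density.", lab[1]))[g$plot_id]
    netmin <- pv("site.netmin_surface")[g$plot_id]
    thick1 <- lay$bottom_cm[1] - lay$top_cm[1]
    delta_mu <- netmin / 4 / (bd1 * thick1 * 0.01) # quarterly conc change
    init <- rnoise(nrow(g), pv(paste0("soil.labile_p.", lab[1]))[g$plot_id],
                   sub_cv(lay$labile_p_cv[1]), model)
    delta <- rnoise(nrow(g), delta_mu, sub_cv(site_cv("netmin_surface")), model)
    g$depth_top_cm <- lay$top_cm[1]
    g$depth_bottom_cm <- lay$bottom_cm[1]
    g$unit <- "mg_P_per_kg"
    dplyr::bind_rows(
      dplyr::mutate(g, variable = "initial_p", value = init),
      dplyr::mutate(g, variable = "final_p", value = pmax(init + delta, 0)))
  })

  ## ---- lysimeter, bulk density, carbon -----------------------------------
  lysimeter <- with_substream(seed, "lysimeter", {
    spec <- spec_grid(dates_quarterly(quarterly_yrs, 15), "site.lysimeter_p",
                      sub_cv(site_cv("lysimeter_p")), "phosphate_conc")
    draw_records(spec, "mg_P_per_L")
  })

  bulkdens <- with_substream(seed, "bulk_density", {
    g <- tidyr::expand_grid(plot_id = plots$plot_id, layer_i = seq_len(nrow(lay)))
    g$value <- vapply(seq_len(nrow(g)), function(i) {
      pv(paste0("soil.bulk_density.", lab[g$layer_i[i]]))[[g$plot_id[i]]]
    }, numeric(1))
    g$date <- date_ymd(y1, 7, 15)
    g$depth_top_cm <- lay$top_cm[g$layer_i]
    g$depth_bottom_cm <- lay$bottom_cm[g$layer_i]
    g$variable <- "bulk_density"
    g$unit <- "g_per_cm3"
    g$layer_i <- NULL
    g
  })

  carbon <- with_substream(seed, "carbon_fluxes", {
    spec <- dplyr::bind_rows(lapply(seq_len(nrow(config$carbon_params)),
      function(i) {
        spec_grid(date_ymd(yrs, 12, 31),
                  paste0("carbon.", config$carbon_params$variable[i]),
                  sub_cv(config$carbon_params$cv[i]),
                  config$carbon_params$variable[i])
      }))
    draw_records(spec, "g_C_per_m2_per_yr")
  })

  lapply(list(
    tissue_concentration = tissue, biomass = biomass, litterfall = litterfall,
    frass = frass, soil_chemistry = soil_chem, fumigation_pairs = fumigation,
    incubation_pairs = incubation, lysimeter = lysimeter,
    bulk_density = bulkdens, carbon_fluxes = carbon
  ), finish)
}

#' Write / read measurement tables as CSV
#'
#' One CSV per table with the fixed column order `plot_id, treatment, date,
#' component, depth_top_cm, depth_bottom_cm, subrep, variable, value, unit`
#' and ISO-8601 dates.
#'
#' @param tables Named list of measurement tibbles
#'   (from [generate_measurements()]).
#' @param dir Directory (created if needed).
#' @return `write_measurements` returns the written file paths invisibly;
#'   `read_measurements` returns the named list of tibbles.
#' @export
write_measurements <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    d <- tables[[nm]]
    d$date <- format(as.Date(d$date), "%Y-%m-%d")
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(d, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[!basename(files) %in% c("plot_budget.csv",
                                         "treatment_summary.csv", "effects.csv")]
  if (!length(files)) abort_data(sprintf("no measurement CSVs found in %s", dir))
  col_classes <- c(
    plot_id = "character", treatment = "character", date = "character",
    component = "character", depth_top_cm = "numeric",
    depth_bottom_cm = "numeric", subrep = "integer", variable = "character",
    value = "numeric", unit = "character")
  out <- lapply(files, function(p) {
    d <- utils::read.csv(p, stringsAsFactors = FALSE, colClasses = col_classes)
    missing <- setdiff(measurement_cols, names(d))
    if (length(missing)) {
      abort_data(sprintf("%s: missing column(s) %s", basename(p),
                         paste(missing, collapse = ", ")))
    }
    d$date <- as.Date(d$date)
    bad <- setdiff(unique(d$unit), unit_vocabulary())
    if (length(bad)) {
      abort_data(sprintf("%s: unit(s) outside the controlled vocabulary: %s",
                         basename(p), paste(bad, collapse = ", ")))
    }
    tibble::as_tibble(d)
  })
  stats::setNames(out, sub("\\.csv$", "", basename(files)))
}
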