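# Reporting: treatment-level budget JSON mirror and a human-readable
# markdown rendering of the pool/flux diagram.

#' Nested JSON mirror of the budget diagram
#'
#' Writes (or returns) the pools, fluxes and indicators per treatment as a
#' nested list `treatment -> type -> variable -> {mean, sd, n, unit}`.
#'
#' @param summary Output of [aggregate_treatments()].
#' @param path Optional file path; when given, pretty JSON is written there.
#' @return The nested list, invisibly when `path` is given.
#' @export
budget_json <- function(summary, path = NULL) {
  out <- list()
  for (tr in unique(summary$treatment)) {
    st <- summary[summary$treatment == tr, ]
    out[[tr]] <- list()
    for (ty in unique(st$type)) {
      sty <- st[st$type == ty, ]
      out[[tr]][[ty]] <- stats::setNames(lapply(seq_len(nrow(sty)), function(i) {
        list(mean = sty$mean[i], sd = sty$sd[i], n = sty$n[i], unit = sty$unit[i])
      }), sty$variable)
    }
  }
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(out))
  }
  out
}

fmt_ms <- function(summary, tr, v, digits = 3) {
  i <- which(summary$treatment == tr & summary$variable == v)
  if (!length(i)) return("--")
  sprintf("%s ± %s", signif(summary$mean[i], digits),
          signif(summary$sd[i], digits))
}

mean_of <- function(summary, tr, v) {
  i <- which(summary$treatment == tr & summary$variable == v)
  if (!length(i)) NA_real_ else summary$mean[i]
}

#' Markdown budget report
#'
#' Renders the assembled budget as readable markdown: pools and fluxes as
#' treatment mean +/- SD, the share percentages that characterize the P
#' economy (woody / litter / fast-turnover shares of the plant-and-litter
#' pool; resorption and uptake shares of demand; microbial share of organic
#' soil P), and the effect table with text CI bars.
#'
#' @param summary Output of [aggregate_treatments()].
#' @param effects Optional output of [effect_table()].
#' @param validation Optional output of [validate_budgets()].
#' @return A character vector of markdown lines.
#' @export
budget_report <- function(summary, effects = NULL, validation = NULL) {
  trs <- intersect(c("ambient", "elevated"), unique(summary$treatment))
  lines <- c("# Ecosystem phosphorus budget", "")
  lines <- c(lines, sprintf("Treatments: %s (n = %d plots each).",
                            paste(trs, collapse = ", "),
                            summary$n[1]), "")

  section <- function(title, vars, unit_note) {
    tab <- c(sprintf("## %s", title), "",
             sprintf("Values are treatment mean ± s.d. (%s).", unit_note), "",
             paste0("| variable | ", paste(trs, collapse = " | "), " |"),
             paste0("|---|", paste(rep("---|", length(trs)), collapse = "")))
    for (v in vars) {
      if (!v %in% summary$variable) next
      tab <- c(tab, paste0("| ", v, " | ",
                           paste(vapply(trs, fmt_ms, character(1),
                                        summary = summary, v = v),
                                 collapse = " | "), " |"))
    }
    c(tab, "")
  }

  pool_vars <- unique(summary$variable[summary$type == "pool"])
  flux_vars <- unique(summary$variable[summary$type == "flux"])
  ind_vars <- unique(summary$variable[summary$type == "indicator"])
  lines <- c(lines,
             section("P pools", pool_vars, "g P m-2"),
             section("P fluxes", flux_vars, "g P m-2 yr-1"),
             section("Derived indicators", ind_vars, "mixed units"))

  ## share percentages (ambient)
  amb <- function(v) mean_of(summary, trs[1], v)
  plant <- amb("plant_litter_p")
  woody <- amb("sapwood_p") + amb("heartwood_p") + amb("coarse_root_p") +
    amb("standing_dead_p")
  fast <- amb("canopy_p") + amb("understorey_p") + amb("fine_root_p")
  shares <- c(
    sprintf("- woody share of the plant-and-litter P pool: %.0f%%",
            100 * woody / plant),
    sprintf("- forest-floor litter share: %.0f%%",
            100 * amb("forest_floor_litter_p") / plant),
    sprintf("- fast-turnover (canopy, understorey, fine root) share: %.0f%%",
            100 * fast / plant),
    sprintf("- resorption share of plant P demand: %.0f%%",
            100 * amb("resorption_p") / amb("demand_p")),
    sprintf("- uptake share of plant P demand: %.0f%%",
            100 * amb("uptake_p") / amb("demand_p")),
    sprintf("- microbial share of organic soil P: %.0f%%",
            100 * amb("microbial_p") / amb("soil_organic_p")),
    sprintf("- microbial : plant P pool ratio: %.1f",
            amb("microbial_p") / amb("plant_litter_p")),
    sprintf("- labile share of total soil P: %.0f%%",
            100 * amb("labile_p") / amb("soil_total_p"))
  )
  lines <- c(lines, "## P economy shares (ambient)", "", shares, "")

  if (!is.null(effects)) {
    lines <- c(lines, "## CO2 effects", "",
               "Effect = elevated - ambient; bars span the 95% CI; `*` marks",
               "intervals excluding zero at the stated level.", "",
               "| variable | delta | rel % | 95% CI | sig (75/85/95) |",
               "|---|---|---|---|---|")
    for (i in seq_len(nrow(effects))) {
      e <- effects[i, ]
      sig <- paste0(ifelse(isTRUE(e$sig75), "*", "."),
                    ifelse(isTRUE(e$sig85), "*", "."),
                    ifelse(isTRUE(e$sig95), "*", "."))
      lines <- c(lines, sprintf("| %s | %+.3g | %+.1f | [%+.3g, %+.3g] | %s |",
                                e$variable, e$delta,
                                ifelse(is.na(e$rel_pct), NA, e$rel_pct),
                                e$ci95_lo, e$ci95_hi, sig))
    }
    lines <- c(lines, "")
  }

  if (!is.null(validation)) {
    lines <- c(lines, "## Validation", "",
               sprintf("- identity checks: %s",
                       ifelse(validation$pass, "all pass", "FAILURES present")),
               sprintf("- ecosystem openness |deposition - leaching| / uptake: %.2g (essentially closed when << 1)",
                       mean(validation$openness$openness_ratio)),
               sprintf("- clamped fumigation differences: %d",
                       sum(validation$flags$n_clamped_fumigation)),
               sprintf("- floored Hedley residuals: %d",
                       sum(validation$flags$hedley_residual_floored)),
               sprintf("- negative uptake plots: %d",
                       sum(validation$flags$negative_uptake)),
               "")
  }
  lines
}
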