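#' Aggregate plot budgets to treatment summaries
#'
#' Treatment mean and standard deviation of every budget variable, with the
#' plot as the unit of replication (n = plots per treatment). Aggregated
#' variables (for example the total plant-and-litter pool) are summed within
#' each plot during assembly, so their cross-plot SD correctly reflects
#' between-plot variation of the aggregate rather than a sum of component
#' SDs.
#'
#' @param budgets Output of [assemble_budgets()] (or [budget_truth()] rows
#'   with `plot_id`/`treatment` columns added).
#' @return A tibble: `variable`, `treatment`, `mean`, `sd`, `n`, `unit`,
#'   `type`.
#' @export
aggregate_treatments <- function(budgets) {
  if (!all(c("plot_id", "treatment", "variable", "value") %in% names(budgets))) {
    abort_data("aggregate_treatments: budgets must have plot_id, treatment, variable, value")
  }
  n_by <- budgets |>
    dplyr::distinct(treatment, plot_id) |>
    dplyr::count(treatment)
  if (any(n_by$n < 2)) {
    abort_data("aggregate_treatments: need >= 2 plots per treatment for an SD")
  }
  budgets |>
    dplyr::summarise(
      mean = mean(value),
      sd = stats::sd(value),
      n = dplyr::n(),
      .by = c(variable, treatment, unit, type)
    ) |>
    dplyr::select(variable, treatment, mean, sd, n, unit, type)
}
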