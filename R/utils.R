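# Internal helpers: error conditions, random-number primitives, seed substreams.

abort_config <- function(msg, field = NULL) {
  rlang::abort(msg, class = "pbudget_config_error", field = field)
}

abort_data <- function(msg) {
  rlang::abort(msg, class = "pbudget_data_error")
}

abort_domain <- function(msg) {
  rlang::abort(msg, class = "pbudget_domain_error")
}

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# Draw n values with mean `mean` and coefficient of variation `cv` under the
# configured noise model. The zero-truncated normal uses the inverse-CDF so the
# draw count per call is deterministic; the lognormal is parameterized to be
# exactly mean-unbiased. cv = 0 or mean = 0 short-circuits to the mean.
rnoise <- function(n, mean, cv, model = "truncated-normal") {
  stopifnot(length(mean) %in% c(1L, n), length(cv) %in% c(1L, n))
  mean <- rep_len(mean, n)
  cv <- rep_len(cv, n)
  out <- mean
  live <- cv > 0 & mean != 0
  if (!any(live)) {
    runif(n) # keep the RNG stream advancing uniformly per value
    return(out)
  }
  u <- runif(n)
  m <- mean[live]
  s <- cv[live] * abs(m)
  if (model == "truncated-normal") {
    p0 <- pnorm(0, m, s)
    out[live] <- qnorm(p0 + u[live] * (1 - p0), m, s)
  } else if (model == "lognormal") {
    sdlog <- sqrt(log1p(cv[live]^2))
    meanlog <- log(m) - sdlog^2 / 2
    out[live] <- qlnorm(u[live], meanlog, sdlog)
  } else {
    abort_config(sprintf("unknown noise_model '%s'", model), field = "noise_model")
  }
  out
}

# Deterministic substream seed for a named stage, derived from the master seed.
# Stages have fixed indices so adding records to one table never shifts the
# draws of another.
substream_seed <- function(seed, stage) {
  idx <- match(stage, c(
    "plot_levels", "tissue_concentration", "biomass", "litterfall", "frass",
    "soil_chemistry", "fumigation_pairs", "incubation_pairs", "lysimeter",
    "bulk_density", "carbon_fluxes", "bootstrap", "simulation"
  ))
  if (is.na(idx)) abort_config(sprintf("unknown RNG stage '%s'", stage))
  (as.integer(seed) %% 1000003L) * 1997L + idx * 7919L
}

with_substream <- function(seed, stage, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stage))
  force(code)
}

# Days in the month starting at date `d` (a Date on the 1st of the month).
days_in_month <- function(d) {
  nxt <- seq(d, by = "1 month", length.out = 2L)[2L]
  as.integer(nxt - d)
}

layer_label <- function(top, bottom) sprintf("%d_%d", as.integer(top), as.integer(bottom))
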