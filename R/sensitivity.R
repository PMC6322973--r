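.sweep_parameters <- c("media_price", "labor_rate", "harvest_consumables")

# scale one named cost parameter of a catalog by (1 + delta)
perturb_catalog <- function(cat, parameter, delta) {
  parameter <- match.arg(parameter, .sweep_parameters)
  switch(parameter,
         media_price = cat$costs$p_med <- cat$costs$p_med * (1 + delta),
         labor_rate = cat$costs$p_lab <- cat$costs$p_lab * (1 + delta),
         harvest_consumables =
           cat$harvest$p_cons <- cat$harvest$p_cons * (1 + delta))
  cat
}

#' One-at-a-time cost-parameter sensitivity sweep
#'
#' Recomputes annual COG for fixed technology combinations while one cost
#' parameter is scaled by `1 + delta`, and reports the percent change
#' relative to the unperturbed baseline. `media_price` scales the media
#' price, `labor_rate` the labor rate, `harvest_consumables` every harvest
#' technology's per-run consumables price. Because unit counts never depend
#' on prices, each response curve is exactly linear in `delta` with slope
#' equal to the perturbed component's share of annual COG; the sweep makes
#' those shares visible. Technology choice is held fixed per combination by
#' default (set `reoptimize` to re-run the optimizer at every perturbation
#' instead).
#'
#' @param parameter one of `"media_price"`, `"labor_rate"`,
#'   `"harvest_consumables"`.
#' @param deltas signed fractional changes, e.g. `c(-0.3, 0, 0.3)`.
#' @param combos `data.frame` with columns `expansion_id`, `harvest_id`.
#' @param lot_sizes lot sizes to evaluate, EVs/lot.
#' @param n_lot_yr lots per year (all sweeps run at one lot rate).
#' @param bio [biology_params()].
#' @param cat [catalog()].
#' @param reoptimize re-select the cheapest pair at every perturbation
#'   instead of holding `combos` fixed.
#' @param options [cog_options()] (used only when `reoptimize = TRUE`).
#' @return tidy `data.frame`: `parameter`, `delta`, `expansion_id`,
#'   `harvest_id`, `lot_size`, `z_total`, `pct_change_cog`.
#' @export
sensitivity_sweep <- function(parameter, deltas = c(-0.3, 0, 0.3), combos,
                              lot_sizes, n_lot_yr, bio, cat,
                              reoptimize = FALSE, options = cog_options()) {
  parameter <- match.arg(parameter, .sweep_parameters)
  stopifnot(all(is.finite(deltas)))
  if (reoptimize) combos <- data.frame(expansion_id = NA_character_,
                                       harvest_id = NA_character_)
  rows <- list()
  for (ls in lot_sizes) {
    dem <- demand(ls, n_lot_yr)
    for (k in seq_len(nrow(combos))) {
      eval_one <- function(delta) {
        pcat <- perturb_catalog(cat, parameter, delta)
        if (reoptimize) {
          res <- optimize_cog(dem, bio, pcat, options)
          if (is_infeasible(res)) return(NULL)
          res
        } else {
          cost_lot(catalog_tech(pcat, combos$expansion_id[k], "expansion"),
                   catalog_tech(pcat, combos$harvest_id[k], "harvest"),
                   dem, bio, pcat$costs)
        }
      }
      base <- eval_one(0)
      if (is.null(base)) next
      for (d in deltas) {
        sol <- eval_one(d)
        if (is.null(sol)) next
        rows[[length(rows) + 1]] <- data.frame(
          parameter = parameter, delta = d,
          expansion_id = sol$expansion_id, harvest_id = sol$harvest_id,
          lot_size = ls, z_total = sol$z_total,
          pct_change_cog = 100 * (sol$z_total - base$z_total) / base$z_total,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Compare biological scenarios on the same demand axis
#'
#' Runs the optimizer per scenario and lot size (at one common lot rate) and
#' reports each scenario's annual COG as a ratio of the first (baseline)
#' scenario's, at the same lot size. Scenarios differ in their biological
#' parameters only — typically donor-to-donor EV-output variation or
#' culture conditions (e.g. serum starvation) that boost EV output per
#' doubling.
#'
#' @param scenarios list of two or more [biology_params()]; the first is the
#'   baseline.
#' @param lot_sizes lot sizes, EVs/lot.
#' @param n_lot_yr lots per year.
#' @param cat [catalog()].
#' @param options [cog_options()].
#' @return tidy `data.frame`: `scenario`, `lot_size`, `expansion_id`,
#'   `harvest_id`, `z_total`, `cog_ratio_vs_baseline` (NA where a scenario
#'   is infeasible at that lot size).
#' @export
compare_scenarios <- function(scenarios, lot_sizes, n_lot_yr, cat,
                              options = cog_options()) {
  stopifnot(length(scenarios) >= 2)
  rows <- list()
  for (ls in lot_sizes) {
    dem <- demand(ls, n_lot_yr)
    sols <- lapply(scenarios, function(b) optimize_cog(dem, b, cat, options))
    z0 <- if (is_infeasible(sols[[1]])) NA_real_ else sols[[1]]$z_total
    for (s in seq_along(scenarios)) {
      sol <- sols[[s]]
      bad <- is_infeasible(sol)
      rows[[length(rows) + 1]] <- data.frame(
        scenario = scenarios[[s]]$label, lot_size = ls,
        expansion_id = if (bad) NA_character_ else sol$expansion_id,
        harvest_id = if (bad) NA_character_ else sol$harvest_id,
        z_total = if (bad) NA_real_ else sol$z_total,
        cog_ratio_vs_baseline =
          if (bad || is.na(z0)) NA_real_ else sol$z_total / z0,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
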