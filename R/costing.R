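#' Demand specification
#'
#' EV demand is parametrized by lot size (EVs delivered per lot, after
#' harvest losses) and the number of lots run per year. Non-integer
#' lots/year are allowed and read as an average lot rate.
#'
#' @param n_v_lot EVs per lot (> 0).
#' @param n_lot_yr lots per year (> 0).
#' @return list of class `ev_demand`.
#' @export
demand <- function(n_v_lot, n_lot_yr) {
  if (!is.finite(n_v_lot) || n_v_lot <= 0) stopf("demand: n_v_lot must be > 0")
  if (!is.finite(n_lot_yr) || n_lot_yr <= 0)
    stopf("demand: n_lot_yr must be > 0")
  structure(list(n_v_lot = n_v_lot, n_lot_yr = n_lot_yr),
            class = "ev_demand")
}

#' EVs required at the end of cell expansion
#'
#' Harvest loses a fraction `1 - recovery` of the EVs in the conditioned
#' media, so the culture must over-produce: the pre-harvest requirement is
#' the lot size divided by the harvest technology's recovery.
#'
#' @param dem [demand()].
#' @param th one harvest-technology row.
#' @return EV count needed before harvest.
#' @export
required_evs_pre_harvest <- function(dem, th) {
  dem$n_v_lot / th$recovery
}

#' Expansion units needed for a lot
#'
#' Number of vessels needed so their combined maximum EV output covers the
#' pre-harvest requirement, rounded up to a whole unit ([ceil_guard()]
#' absorbs float residue before the ceiling).
#'
#' @param n_v_pre pre-harvest EV requirement.
#' @param te one expansion-technology row.
#' @param bio [biology_params()].
#' @return integer unit count (>= 1).
#' @export
expansion_units <- function(n_v_pre, te, bio) {
  vmax <- max_evs_per_unit(te, bio)
  if (vmax <= 0) stopf("expansion_units: technology '%s' produces no EVs",
                       te$tech_id)
  max(1, ceil_guard(n_v_pre / vmax))
}

# conditioned-media volume of one expansion unit, L
unit_media_volume <- function(te) {
  te$v_pln * te$a_pln + te$V_sub
}

#' Harvest units needed for a lot
#'
#' The whole conditioned-media volume of the lot must pass through the
#' harvest technology; the unit count is that volume over the technology's
#' maximum sample volume, rounded up (EV-free buffer tops up the final
#' partial unit at negligible cost, so fractional units always round up,
#' never down).
#'
#' @param u_e expansion unit count.
#' @param te one expansion-technology row.
#' @param th one harvest-technology row.
#' @return integer unit count (>= 1).
#' @export
harvest_units <- function(u_e, te, th) {
  max(1, ceil_guard(u_e * unit_media_volume(te) / th$V_max))
}

#' Per-lot consumables cost of cell expansion
#'
#' Vessels, media (priced per liter of conditioned media) and, for
#' microcarrier bioreactors, the microcarriers themselves.
#'
#' @param u_e expansion unit count.
#' @param te one expansion-technology row.
#' @param costs [global_costs()].
#' @return USD per lot.
#' @export
expansion_consumables <- function(u_e, te, costs) {
  u_e * (te$p_vess + costs$p_med * unit_media_volume(te) +
           costs$p_mc * te$d_mc * te$V_sub)
}

#' Operators needed to run a number of units
#'
#' @param units unit count.
#' @param per_operator max units one operator can manage.
#' @return integer operator count (>= 1 when `units >= 1`).
#' @export
operators_needed <- function(units, per_operator) {
  ceil_guard(units / per_operator)
}

#' Per-lot labor cost of cell expansion
#'
#' Operator wages for seeding and conditioned-media collection, scaled by
#' `1 + beta` for non-operator labor overhead.
#'
#' @param m_e operator count.
#' @param te one expansion-technology row.
#' @param costs [global_costs()].
#' @return USD per lot.
#' @export
expansion_labor <- function(m_e, te, costs) {
  m_e * costs$p_lab * (te$t_seed + te$t_coll) * (1 + costs$beta)
}

#' Capital equipment cost of cell expansion
#'
#' Incubators (one per `U_inc` units), biosafety cabinets (one per `U_bsc`
#' operators, only for technologies whose handling needs one) and ancillary
#' equipment (one per `U_anc` units). This is a capital figure; it is
#' amortized over the depreciation horizon when annualized.
#'
#' @param u_e expansion unit count.
#' @param m_e operator count.
#' @param te one expansion-technology row.
#' @param costs [global_costs()].
#' @return USD (capital).
#' @export
expansion_equipment <- function(u_e, m_e, te, costs) {
  delta <- as.numeric(te$needs_bsc)
  te$p_inc * ceil_guard(u_e / te$U_inc) +
    costs$p_bsc * ceil_guard(m_e * delta / costs$U_bsc) +
    te$p_anc * ceil_guard(u_e / te$U_anc)
}

#' Per-lot consumables cost of EV harvest
#'
#' One harvest unit is one complete run of the multi-step purification
#' protocol, with one consumables price per run.
#'
#' @param u_h harvest unit count.
#' @param th one harvest-technology row.
#' @return USD per lot.
#' @export
harvest_consumables <- function(u_h, th) {
  u_h * th$p_cons
}

#' Per-lot labor cost of EV harvest
#'
#' Hands-on time only; waiting between protocol steps is not labor.
#'
#' @param m_h operator count.
#' @param th one harvest-technology row.
#' @param costs [global_costs()].
#' @return USD per lot.
#' @export
harvest_labor <- function(m_h, th, costs) {
  m_h * costs$p_lab * th$t_proc * (1 + costs$beta)
}

#' Capital equipment cost of EV harvest
#'
#' Ancillary equipment is always charged; biosafety cabinets are charged
#' only for the extra cabinets beyond those the expansion stage already
#' provides (harvest operators always work in a cabinet).
#'
#' @param u_h harvest unit count.
#' @param m_h harvest operator count.
#' @param m_e expansion operator count (to credit existing cabinets).
#' @param te one expansion-technology row.
#' @param th one harvest-technology row.
#' @param costs [global_costs()].
#' @return USD (capital).
#' @export
harvest_equipment <- function(u_h, m_h, m_e, te, th, costs) {
  anc <- th$p_anc * ceil_guard(u_h / th$U_anc)
  delta <- as.numeric(te$needs_bsc)
  bsc_h <- ceil_guard(m_h / costs$U_bsc)
  bsc_e <- ceil_guard(m_e * delta / costs$U_bsc)
  if (bsc_h > bsc_e) anc + costs$p_bsc * (bsc_h - bsc_e) else anc
}

new_stage_costs <- function(consumables, labor, equipment) {
  list(consumables = consumables, labor = labor, equipment = equipment)
}

annual_cog_stage <- function(stage, dem, costs) {
  dem$n_lot_yr * (stage$consumables + stage$labor) +
    stage$equipment / costs$t_dep
}

#' Annualize per-lot stage costs
#'
#' Consumables and labor recur every lot; equipment is shared between lots
#' and only depreciates, so annual cost of goods is
#' `lots/year * (consumables + labor) + equipment / t_dep`. The same affine
#' form applies to both stages.
#'
#' @param stage list with elements `consumables`, `labor` (USD/lot) and
#'   `equipment` (USD capital).
#' @param dem [demand()].
#' @param costs [global_costs()].
#' @return USD per year.
#' @export
annual_cog_expansion <- function(stage, dem, costs) {
  annual_cog_stage(stage, dem, costs)
}

#' @rdname annual_cog_expansion
#' @export
annual_cog_harvest <- function(stage, dem, costs) {
  annual_cog_stage(stage, dem, costs)
}

#' Fully cost one (expansion, harvest) technology pair for a demand
#'
#' Composes the whole per-lot model: pre-harvest EV requirement from the
#' harvest recovery, unit and operator counts for both stages, per-lot
#' consumables and labor, capital equipment, annualization, and the culture
#' duration implied by the per-unit EV load (cultures are terminated as soon
#' as just enough EVs have accumulated, so the load per unit is
#' `n_v_pre / u_e`).
#'
#' @param te one expansion-technology row (or a tech_id with `cat` given).
#' @param th one harvest-technology row.
#' @param dem [demand()].
#' @param bio [biology_params()].
#' @param costs [global_costs()].
#' @return list of class `ev_lot_solution`: ids, `n_v_pre_harvest`, unit and
#'   operator counts, `culture_h`, per-stage cost breakdowns, and annual
#'   figures `z_expansion`, `z_harvest`, `z_total`.
#' @export
cost_lot <- function(te, th, dem, bio, costs) {
  n_v_pre <- required_evs_pre_harvest(dem, th)
  u_e <- expansion_units(n_v_pre, te, bio)
  u_h <- harvest_units(u_e, te, th)
  m_e <- operators_needed(u_e, te$U_m)
  m_h <- operators_needed(u_h, th$U_m)
  exp_stage <- new_stage_costs(
    consumables = expansion_consumables(u_e, te, costs),
    labor = expansion_labor(m_e, te, costs),
    equipment = expansion_equipment(u_e, m_e, te, costs)
  )
  hrv_stage <- new_stage_costs(
    consumables = harvest_consumables(u_h, th),
    labor = harvest_labor(m_h, th, costs),
    equipment = harvest_equipment(u_h, m_h, m_e, te, th, costs)
  )
  z_e <- annual_cog_expansion(exp_stage, dem, costs)
  z_h <- annual_cog_harvest(hrv_stage, dem, costs)
  structure(
    list(
      expansion_id = te$tech_id, harvest_id = th$tech_id,
      n_v_pre_harvest = n_v_pre, u_e = u_e, u_h = u_h,
      m_e = m_e, m_h = m_h,
      culture_h = culture_duration(te, bio, n_v_pre / u_e),
      expansion = exp_stage, harvest = hrv_stage,
      z_expansion = z_e, z_harvest = z_h, z_total = z_e + z_h,
      n_v_lot = dem$n_v_lot, n_lot_yr = dem$n_lot_yr
    ),
    class = "ev_lot_solution"
  )
}

# expansion-only variant: product is cells, not EVs; harvest stage skipped
cost_lot_expansion_only <- function(te, dem, bio, costs) {
  n_cells_lot <- dem$n_v_lot
  per_unit <- cells_per_unit(te, te$d_c_max)
  u_e <- max(1, ceil_guard(n_cells_lot / per_unit))
  m_e <- operators_needed(u_e, te$U_m)
  exp_stage <- new_stage_costs(
    consumables = expansion_consumables(u_e, te, costs),
    labor = expansion_labor(m_e, te, costs),
    equipment = expansion_equipment(u_e, m_e, te, costs)
  )
  z_e <- annual_cog_expansion(exp_stage, dem, costs)
  structure(
    list(
      expansion_id = te$tech_id, harvest_id = NA_character_,
      n_v_pre_harvest = NA_real_, u_e = u_e, u_h = NA_integer_,
      m_e = m_e, m_h = NA_integer_,
      culture_h = bio$t_d * log2(te$d_c_max / te$d_c_min),
      expansion = exp_stage,
      harvest = new_stage_costs(0, 0, 0),
      z_expansion = z_e, z_harvest = 0, z_total = z_e,
      n_v_lot = dem$n_v_lot, n_lot_yr = dem$n_lot_yr
    ),
    class = "ev_lot_solution"
  )
}

#' @export
print.ev_lot_solution <- function(x, ...) {
  cat(format_lot_solution(x), sep = "\n")
  invisible(x)
}

format_lot_solution <- function(x) {
  lines <- c(
    sprintf("Lot solution: %s + %s", x$expansion_id,
            if (is.na(x$harvest_id)) "(no harvest)" else x$harvest_id),
    sprintf("  demand: %.3g EVs/lot x %g lots/year", x$n_v_lot, x$n_lot_yr),
    sprintf("  units: %g expansion (%g operators), %s harvest (%s operators)",
            x$u_e, x$m_e,
            ifelse(is.na(x$u_h), "-", format(x$u_h)),
            ifelse(is.na(x$m_h), "-", format(x$m_h))),
    sprintf("  culture duration: %.1f h", x$culture_h),
    "  per-lot costs (USD):",
    sprintf("    expansion: consumables %.2f, labor %.2f, equipment (capital) %.2f",
            x$expansion$consumables, x$expansion$labor,
            x$expansion$equipment),
    sprintf("    harvest:   consumables %.2f, labor %.2f, equipment (capital) %.2f",
            x$harvest$consumables, x$harvest$labor, x$harvest$equipment),
    sprintf("  annual COG (USD/yr): expansion %.2f + harvest %.2f = %.2f",
            x$z_expansion, x$z_harvest, x$z_total)
  )
  lines
}

#' Flatten lot solutions for reporting
#'
#' @param x an `ev_lot_solution`.
#' @param row.names,optional,... ignored (base-generic signature).
#' @return one-row `data.frame` with ids, counts, per-stage cost components
#'   and annual figures.
#' @export
as.data.frame.ev_lot_solution <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(
    expansion_id = x$expansion_id, harvest_id = x$harvest_id,
    n_v_lot = x$n_v_lot, n_lot_yr = x$n_lot_yr,
    n_v_pre_harvest = x$n_v_pre_harvest,
    u_e = x$u_e, u_h = x$u_h, m_e = x$m_e, m_h = x$m_h,
    culture_h = x$culture_h,
    exp_consumables = x$expansion$consumables,
    exp_labor = x$expansion$labor,
    exp_equipment = x$expansion$equipment,
    hrv_consumables = x$harvest$consumables,
    hrv_labor = x$harvest$labor,
    hrv_equipment = x$harvest$equipment,
    z_expansion = x$z_expansion, z_harvest = x$z_harvest,
    z_total = x$z_total,
    stringsAsFactors = FALSE
  )
}

#' Serialize a lot solution to JSON
#'
#' @param x an `ev_lot_solution`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lot_solution <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
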