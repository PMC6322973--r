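#' Optimizer options
#'
#' @param fixed_recovery force every harvest technology's recovery to 100%
#'   (comparisons then contrast harvest technologies at identical expansion
#'   trains, since the pre-harvest requirement equals the lot size for every
#'   candidate).
#' @param expansion_only treat the lot size as cells per lot and skip the
#'   harvest stage entirely (for validating the expansion module against
#'   cell-manufacturing cost models); a technology is infeasible when the
#'   cells needed for seeding already reach the lot size.
#' @param lots_window allowed lots-per-year range, default `c(10, 200)`:
#'   below the floor a lot size is needlessly large for the demand, above
#'   the cap consecutive lots would overlap in daily operations.
#' @param min_culture_h minimum lag between seeding and harvest, h. Pairs
#'   that would meet their lot faster are excluded as operationally
#'   impractical.
#' @return list of class `ev_options`.
#' @export
cog_options <- function(fixed_recovery = FALSE, expansion_only = FALSE,
                        lots_window = c(10, 200), min_culture_h = 24) {
  stopifnot(length(lots_window) == 2, lots_window[1] <= lots_window[2])
  structure(list(fixed_recovery = isTRUE(fixed_recovery),
                 expansion_only = isTRUE(expansion_only),
                 lots_window = as.numeric(lots_window),
                 min_culture_h = min_culture_h),
            class = "ev_options")
}

.feas_reasons <- c("ok", "expansion_space_limit", "harvest_space_limit",
                   "too_fast_24h", "lots_below_min", "lots_above_max",
                   "seed_exceeds_lot")

feasibility_status <- function(reason) {
  reason <- match.arg(reason, .feas_reasons)
  list(feasible = reason == "ok", reason = reason)
}

#' Check feasibility of one technology pair for a demand
#'
#' Applies, in order: the lots-per-year window, the facility space limits
#' (`u_e <= U_max` of the expansion technology, `u_h <= U_max` of the
#' harvest technology; limits inclusive) and the minimum culture lag (the
#' per-unit EV load must take at least `min_culture_h` hours to accumulate).
#'
#' @param te one expansion-technology row.
#' @param th one harvest-technology row (ignored in expansion-only mode).
#' @param dem [demand()].
#' @param bio [biology_params()].
#' @param costs [global_costs()].
#' @param options [cog_options()].
#' @return list with elements `feasible` (logical) and `reason` (one of
#'   `ok`, `expansion_space_limit`, `harvest_space_limit`, `too_fast_24h`,
#'   `lots_below_min`, `lots_above_max`, `seed_exceeds_lot`).
#' @export
check_feasibility <- function(te, th, dem, bio, costs,
                              options = cog_options()) {
  if (dem$n_lot_yr < options$lots_window[1])
    return(feasibility_status("lots_below_min"))
  if (dem$n_lot_yr > options$lots_window[2])
    return(feasibility_status("lots_above_max"))
  if (options$expansion_only) {
    u_e <- max(1, ceil_guard(dem$n_v_lot / cells_per_unit(te, te$d_c_max)))
    if (u_e > te$U_max)
      return(feasibility_status("expansion_space_limit"))
    if (u_e * cells_per_unit(te, te$d_c_min) >= dem$n_v_lot)
      return(feasibility_status("seed_exceeds_lot"))
    if (bio$t_d * log2(te$d_c_max / te$d_c_min) < options$min_culture_h)
      return(feasibility_status("too_fast_24h"))
    return(feasibility_status("ok"))
  }
  n_v_pre <- required_evs_pre_harvest(dem, th)
  u_e <- expansion_units(n_v_pre, te, bio)
  if (u_e > te$U_max)
    return(feasibility_status("expansion_space_limit"))
  u_h <- harvest_units(u_e, te, th)
  if (u_h > th$U_max)
    return(feasibility_status("harvest_space_limit"))
  if (culture_duration(te, bio, n_v_pre / u_e) < options$min_culture_h)
    return(feasibility_status("too_fast_24h"))
  feasibility_status("ok")
}

apply_options_to_catalog <- function(cat, options) {
  if (options$fixed_recovery) cat$harvest$recovery <- 1
  cat
}

# deterministic tie-break: cheaper, then fewer units, then lexicographic ids
solution_beats <- function(cand, best) {
  if (is.null(best)) return(TRUE)
  if (cand$z_total != best$z_total) return(cand$z_total < best$z_total)
  cu <- cand$u_e + ifelse(is.na(cand$u_h), 0, cand$u_h)
  bu <- best$u_e + ifelse(is.na(best$u_h), 0, best$u_h)
  if (cu != bu) return(cu < bu)
  ck <- paste(cand$expansion_id, cand$harvest_id)
  bk <- paste(best$expansion_id, best$harvest_id)
  ck < bk
}

#' Find the cheapest feasible technology combination
#'
#' Exhaustively enumerates every (expansion, harvest) technology pair in the
#' catalog (outer loop over harvest technologies, inner loop over expansion
#' technologies), filters by [check_feasibility()], fully costs the
#' survivors with [cost_lot()] and returns the annual-COG minimizer. Exact
#' cost ties are broken deterministically by fewer total units, then by
#' lexicographic technology-id pair. The result does not depend on catalog
#' row order.
#'
#' @param dem [demand()].
#' @param bio [biology_params()].
#' @param cat [catalog()].
#' @param options [cog_options()].
#' @return the optimal `ev_lot_solution`, or an `ev_infeasible` report
#'   listing the per-pair exclusion reasons when no pair survives.
#' @export
optimize_cog <- function(dem, bio, cat, options = cog_options()) {
  cat <- apply_options_to_catalog(cat, options)
  best <- NULL
  reasons <- list()
  hrv_ids <- if (options$expansion_only) NA_character_ else
    cat$harvest$tech_id
  for (hid in hrv_ids) {
    th <- if (is.na(hid)) NULL else catalog_tech(cat, hid, "harvest")
    for (i in seq_len(nrow(cat$expansion))) {
      te <- cat$expansion[i, ]
      fs <- check_feasibility(te, th, dem, bio, cat$costs, options)
      reasons[[length(reasons) + 1]] <- data.frame(
        expansion_id = te$tech_id, harvest_id = hid,
        reason = fs$reason, stringsAsFactors = FALSE
      )
      if (!fs$feasible) next
      sol <- if (options$expansion_only)
        cost_lot_expansion_only(te, dem, bio, cat$costs)
      else cost_lot(te, th, dem, bio, cat$costs)
      if (solution_beats(sol, best)) best <- sol
    }
  }
  if (is.null(best))
    return(structure(list(demand = dem,
                          reasons = do.call(rbind, reasons)),
                     class = "ev_infeasible"))
  best
}

#' @export
print.ev_infeasible <- function(x, ...) {
  cat(sprintf("No feasible technology pair for %.3g EVs/lot x %g lots/year\n",
              x$demand$n_v_lot, x$demand$n_lot_yr))
  tab <- table(x$reasons$reason)
  for (r in names(tab)) cat(sprintf("  %s: %d pair(s)\n", r, tab[[r]]))
  invisible(x)
}

#' Is an optimizer result infeasible?
#' @param x result of [optimize_cog()].
#' @return logical.
#' @export
is_infeasible <- function(x) inherits(x, "ev_infeasible")

#' Optimal solutions over a lot size x annual demand grid
#'
#' For each grid cell the lot rate is `annual_demand / lot_size` lots/year;
#' cells whose rate falls outside the lots-per-year window are flagged
#' `out_of_range`, cells where no technology pair is feasible are flagged
#' `infeasible`, and the rest hold the [optimize_cog()] optimum.
#'
#' @param lot_sizes strictly increasing vector of lot sizes, EVs/lot.
#' @param annual_demands strictly increasing vector of annual demands,
#'   EVs/year.
#' @param bio [biology_params()].
#' @param cat [catalog()].
#' @param options [cog_options()].
#' @return list of class `ev_solution_grid`: the axes, a `cells` list-matrix
#'   (rows = lot sizes, columns = annual demands) and convenience matrices
#'   `status`, `expansion_id`, `harvest_id`, `z_total`.
#' @export
solution_grid <- function(lot_sizes, annual_demands, bio, cat,
                          options = cog_options()) {
  stopifnot(all(diff(lot_sizes) > 0), all(diff(annual_demands) > 0))
  nr <- length(lot_sizes); nc <- length(annual_demands)
  cells <- matrix(vector("list", nr * nc), nr, nc)
  status <- matrix(NA_character_, nr, nc)
  eid <- matrix(NA_character_, nr, nc)
  hid <- matrix(NA_character_, nr, nc)
  z <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      rate <- annual_demands[j] / lot_sizes[i]
      if (rate < options$lots_window[1] || rate > options$lots_window[2]) {
        status[i, j] <- "out_of_range"
        next
      }
      res <- optimize_cog(demand(lot_sizes[i], rate), bio, cat, options)
      cells[[i, j]] <- res
      if (is_infeasible(res)) {
        status[i, j] <- "infeasible"
      } else {
        status[i, j] <- "ok"
        eid[i, j] <- res$expansion_id
        hid[i, j] <- res$harvest_id
        z[i, j] <- res$z_total
      }
    }
  }
  structure(
    list(lot_sizes = lot_sizes, annual_demands = annual_demands,
         cells = cells, status = status,
         expansion_id = eid, harvest_id = hid, z_total = z),
    class = "ev_solution_grid"
  )
}

#' Long-format view of a solution grid
#'
#' @param x an `ev_solution_grid`.
#' @param row.names,optional,... ignored (base-generic signature).
#' @return `data.frame` with one row per cell: `lot_size`, `annual_demand`,
#'   `lots_per_year`, `expansion_id`, `harvest_id`, `z_total`, `status`.
#' @export
as.data.frame.ev_solution_grid <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  grid <- expand.grid(lot_size = x$lot_sizes,
                      annual_demand = x$annual_demands,
                      KEEP.OUT.ATTRS = FALSE)
  grid$lots_per_year <- grid$annual_demand / grid$lot_size
  grid$expansion_id <- as.vector(x$expansion_id)
  grid$harvest_id <- as.vector(x$harvest_id)
  grid$z_total <- as.vector(x$z_total)
  grid$status <- as.vector(x$status)
  grid
}

#' @export
print.ev_solution_grid <- function(x, ...) {
  cat(render_grid(x), sep = "\n")
  invisible(x)
}

# plain-text rendering: each cell shows expansion id over harvest id
render_grid <- function(x) {
  cell_txt <- matrix("", length(x$lot_sizes), length(x$annual_demands))
  for (i in seq_along(x$lot_sizes)) {
    for (j in seq_along(x$annual_demands)) {
      cell_txt[i, j] <- switch(
        x$status[i, j],
        out_of_range = ".",
        infeasible = "x",
        ok = sprintf("%s/%s", x$expansion_id[i, j], x$harvest_id[i, j])
      )
    }
  }
  w <- max(nchar(cell_txt), nchar("lot\\demand"), 8)
  hdr <- paste(c(formatC("lot\\demand", width = 14),
                 formatC(format(x$annual_demands, digits = 3), width = w)),
               collapse = " ")
  rows <- vapply(seq_along(x$lot_sizes), function(i) {
    paste(c(formatC(format(x$lot_sizes[i], digits = 3), width = 14),
            formatC(cell_txt[i, ], width = w)), collapse = " ")
  }, character(1))
  c(hdr, rows, "(. = outside lots/year window, x = no feasible pair)")
}

switches_from_ids <- function(eid, hid, axis_names) {
  out <- list()
  add <- function(axis, a1, a2, b, e1, e2, h1, h2) {
    if (is.na(e1) || is.na(e2)) return()
    sw <- if (e1 != e2 && h1 != h2) "both"
    else if (e1 != e2) "expansion"
    else if (h1 != h2) "harvest"
    else "none"
    out[[length(out) + 1]] <<- data.frame(
      axis = axis, from = a1, to = a2, at = b, switch = sw,
      stringsAsFactors = FALSE
    )
  }
  nr <- nrow(eid); nc <- ncol(eid)
  for (j in seq_len(nc)) for (i in seq_len(nr - 1))
    add(axis_names[1], i, i + 1, j, eid[i, j], eid[i + 1, j],
        hid[i, j], hid[i + 1, j])
  for (i in seq_len(nr)) for (j in seq_len(nc - 1))
    add(axis_names[2], j, j + 1, i, eid[i, j], eid[i, j + 1],
        hid[i, j], hid[i, j + 1])
  if (!length(out))
    return(data.frame(axis = character(), from = integer(), to = integer(),
                      at = integer(), switch = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Technology switches between adjacent grid cells
#'
#' Labels every adjacent pair of solved cells with the kind of change in the
#' optimum: `none`, `expansion` (expansion technology only), `harvest`
#' (harvest technology only), or `both`. Mirrors the border annotations of a
#' solution-map heat plot.
#'
#' @param grid an `ev_solution_grid`.
#' @return `data.frame` with columns `axis` (`"lot_size"` steps move along
#'   the lot-size axis, `"annual_demand"` along the demand axis), `from`,
#'   `to` (axis indices of the two cells), `at` (index on the other axis)
#'   and `switch`.
#' @export
switch_map <- function(grid) {
  switches_from_ids(grid$expansion_id, grid$harvest_id,
                    c("lot_size", "annual_demand"))
}
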