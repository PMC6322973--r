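#' @name catalog
#' @title Technology catalogs
#'
#' @description
#' A catalog bundles the parameter tables the cost model runs on: one row per
#' cell-expansion technology, one row per EV-harvest technology, and a set of
#' global cost parameters (media and labor prices, overhead multiplier,
#' depreciation horizon, ...). Catalogs are read from YAML/JSON documents or
#' from per-table CSV files, and every load is validated against the model's
#' invariants.
#'
#' Cell-expansion rows describe vessel geometry and capacity:
#' `a_pln` (growth area per unit, cm^2; also used for hollow-fiber membrane
#' area), `V_sub` (working volume of a microcarrier single-use bioreactor, L),
#' `v_pln` (media volume per growth area, L/cm^2), `a_mc`/`d_mc` (microcarrier
#' specific area, cm^2/g, and density, g/L), seeding and maximum cell
#' densities `d_c_min`/`d_c_max` (cells/cm^2), prices (`p_vess`, `p_inc`,
#' `p_anc`, USD), capacity limits (`U_inc`, `U_anc` units per equipment item,
#' `U_m` units per operator, `U_max` units per lot), labor times (`t_seed`,
#' `t_coll`, h) and `needs_bsc` (whether handling requires a biosafety
#' cabinet). EV-harvest rows carry `recovery` (fraction of EVs surviving
#' harvest), `V_max` (max sample volume per unit run, L), `p_cons`
#' (consumables per run, USD), `t_proc` (hands-on labor per run, h) and the
#' analogous `U_m`, `U_max`, `p_anc`, `U_anc` limits.
NULL

.expansion_kinds <- c("planar", "microcarrier_sub", "hollow_fiber")

.expansion_cols <- c(
  "tech_id", "kind", "a_pln", "V_sub", "v_pln", "a_mc", "d_mc",
  "d_c_min", "d_c_max", "p_vess", "p_inc", "U_inc", "p_anc", "U_anc",
  "U_m", "U_max", "t_seed", "t_coll", "needs_bsc", "provenance"
)

.harvest_cols <- c(
  "tech_id", "recovery", "V_max", "p_cons", "t_proc",
  "U_m", "U_max", "p_anc", "U_anc", "provenance"
)

.cost_fields <- c("p_med", "p_lab", "beta", "p_mc", "p_bsc", "U_bsc", "t_dep")

#' Construct one cell-expansion technology record
#'
#' @param tech_id short label, e.g. `"T-175"`, `"L-10"`, `"SUB-20L"`.
#' @param kind one of `"planar"`, `"microcarrier_sub"`, `"hollow_fiber"`.
#'   Hollow-fiber devices are parameterized like planar vessels (membrane
#'   area in `a_pln`, media per area in `v_pln`).
#' @param a_pln growth (or membrane) surface area per unit, cm^2; 0 for
#'   microcarrier bioreactors.
#' @param V_sub bioreactor working volume per unit, L; 0 for planar vessels.
#' @param v_pln media volume per growth area, L/cm^2 (planar / hollow-fiber).
#' @param a_mc microcarrier specific surface area, cm^2/g.
#' @param d_mc microcarrier density in the vessel, g/L.
#' @param d_c_min seeding cell density, cells/cm^2.
#' @param d_c_max maximum allowable cell density, cells/cm^2.
#' @param p_vess vessel price, USD/unit.
#' @param p_inc incubator (or equivalent controller) price, USD.
#' @param U_inc max units per incubator.
#' @param p_anc ancillary equipment price, USD.
#' @param U_anc max units per ancillary item.
#' @param U_m max units one operator can manage.
#' @param U_max max units per lot (facility space constraint).
#' @param t_seed seeding labor time per lot, h.
#' @param t_coll conditioned-media collection labor time per lot, h.
#' @param needs_bsc does handling require a biosafety cabinet?
#' @param provenance free-text origin tag for the parameter values
#'   (e.g. `"placeholder"`, `"literature"`, `"user"`).
#' @return one-row `data.frame` with the expansion-technology columns.
#' @seealso [catalog()], [harvest_tech()]
#' @export
expansion_tech <- function(tech_id, kind, a_pln = 0, V_sub = 0, v_pln = 0,
                           a_mc = 0, d_mc = 0, d_c_min, d_c_max,
                           p_vess, p_inc, U_inc, p_anc, U_anc,
                           U_m, U_max, t_seed, t_coll, needs_bsc,
                           provenance = "user") {
  kind <- match.arg(kind, .expansion_kinds)
  data.frame(
    tech_id = as.character(tech_id), kind = kind,
    a_pln = a_pln, V_sub = V_sub, v_pln = v_pln, a_mc = a_mc, d_mc = d_mc,
    d_c_min = d_c_min, d_c_max = d_c_max,
    p_vess = p_vess, p_inc = p_inc, U_inc = U_inc,
    p_anc = p_anc, U_anc = U_anc, U_m = U_m, U_max = U_max,
    t_seed = t_seed, t_coll = t_coll, needs_bsc = isTRUE(needs_bsc),
    provenance = as.character(provenance),
    stringsAsFactors = FALSE
  )
}

#' Construct one EV-harvest technology record
#'
#' @param tech_id short label, e.g. `"UC"`, `"SEC2"`, `"UF2"`.
#' @param recovery fraction of EVs in conditioned media surviving harvest,
#'   in (0, 1].
#' @param V_max maximum sample volume per unit run, L.
#' @param p_cons consumables price for one complete run, USD.
#' @param t_proc total hands-on labor time per run, h (waiting between steps
#'   is not labor).
#' @param U_m max units one operator can manage.
#' @param U_max max units per lot (space constraint).
#' @param p_anc ancillary equipment price (centrifuge, pump, ...), USD.
#' @param U_anc max units per ancillary item.
#' @param provenance free-text origin tag for the parameter values.
#' @return one-row `data.frame` with the harvest-technology columns.
#' @seealso [catalog()], [expansion_tech()]
#' @export
harvest_tech <- function(tech_id, recovery, V_max, p_cons, t_proc,
                         U_m, U_max, p_anc, U_anc, provenance = "user") {
  data.frame(
    tech_id = as.character(tech_id), recovery = recovery, V_max = V_max,
    p_cons = p_cons, t_proc = t_proc, U_m = U_m, U_max = U_max,
    p_anc = p_anc, U_anc = U_anc, provenance = as.character(provenance),
    stringsAsFactors = FALSE
  )
}

#' Global cost parameters
#'
#' @param p_med media price, USD/L.
#' @param p_lab operator labor rate, USD/h.
#' @param beta non-operator labor overhead multiplier (supervision,
#'   management), dimensionless; labor cost is scaled by `1 + beta`.
#' @param p_mc microcarrier price, USD/g.
#' @param p_bsc biosafety-cabinet price, USD.
#' @param U_bsc max operators sharing one biosafety cabinet.
#' @param t_dep equipment depreciation horizon, years.
#' @return named list of class `ev_global_costs`.
#' @export
global_costs <- function(p_med = 150, p_lab = 200, beta = 0.2, p_mc = 6,
                         p_bsc = 12000, U_bsc = 2, t_dep = 5) {
  structure(
    list(p_med = p_med, p_lab = p_lab, beta = beta, p_mc = p_mc,
         p_bsc = p_bsc, U_bsc = U_bsc, t_dep = t_dep),
    class = "ev_global_costs"
  )
}

#' Assemble and validate a technology catalog
#'
#' @param expansion `data.frame` of cell-expansion technologies, one row per
#'   technology (rows as built by [expansion_tech()]).
#' @param harvest `data.frame` of EV-harvest technologies, one row per
#'   technology (rows as built by [harvest_tech()]).
#' @param costs [global_costs()] object.
#' @return validated list of class `ev_catalog` with elements `expansion`,
#'   `harvest`, `costs`.
#' @export
catalog <- function(expansion, harvest, costs = global_costs()) {
  cat <- structure(
    list(expansion = as.data.frame(expansion),
         harvest = as.data.frame(harvest),
         costs = costs),
    class = "ev_catalog"
  )
  validate_catalog(cat)
}

#' @export
print.ev_catalog <- function(x, ...) {
  cat(sprintf("EV manufacturing technology catalog\n"))
  cat(sprintf("  expansion technologies: %s\n",
              paste(x$expansion$tech_id, collapse = ", ")))
  cat(sprintf("  harvest technologies:   %s\n",
              paste(x$harvest$tech_id, collapse = ", ")))
  cat(sprintf("  media $%g/L, labor $%g/h, overhead x%g, depreciation %g yr\n",
              x$costs$p_med, x$costs$p_lab, 1 + x$costs$beta, x$costs$t_dep))
  invisible(x)
}

.check <- function(ok, tech_id, field, msg) {
  if (!isTRUE(ok))
    stopf("catalog validation: tech '%s', field '%s': %s", tech_id, field, msg)
}

validate_expansion_row <- function(te) {
  id <- te$tech_id
  .check(te$kind %in% .expansion_kinds, id, "kind",
         sprintf("unknown kind '%s'", te$kind))
  for (f in c("a_pln", "V_sub", "v_pln", "a_mc", "d_mc", "p_vess", "p_inc",
              "p_anc", "t_seed", "t_coll"))
    .check(is.finite(te[[f]]) && te[[f]] >= 0, id, f, "must be >= 0")
  .check(te$d_c_min > 0, id, "d_c_min", "must be > 0")
  .check(te$d_c_max > te$d_c_min, id, "d_c_max", "must exceed d_c_min")
  for (f in c("U_inc", "U_anc", "U_m", "U_max"))
    .check(is.finite(te[[f]]) && te[[f]] >= 1, id, f, "must be >= 1")
  if (te$kind == "microcarrier_sub") {
    .check(te$V_sub > 0, id, "V_sub", "microcarrier SUB needs V_sub > 0")
    .check(te$a_pln == 0, id, "a_pln", "must be 0 for a microcarrier SUB")
    .check(te$a_mc > 0, id, "a_mc", "microcarrier SUB needs a_mc > 0")
    .check(te$d_mc > 0, id, "d_mc", "microcarrier SUB needs d_mc > 0")
  } else {
    .check(te$a_pln > 0, id, "a_pln", "planar-type vessel needs a_pln > 0")
    .check(te$V_sub == 0, id, "V_sub", "must be 0 for a planar-type vessel")
    .check(te$v_pln > 0, id, "v_pln", "planar-type vessel needs v_pln > 0")
  }
  .check(is.logical(te$needs_bsc) && !is.na(te$needs_bsc), id, "needs_bsc",
         "must be TRUE or FALSE")
  invisible(te)
}

validate_harvest_row <- function(th) {
  id <- th$tech_id
  .check(th$recovery > 0 && th$recovery <= 1, id, "recovery",
         "must be in (0, 1]")
  .check(th$V_max > 0, id, "V_max", "must be > 0")
  for (f in c("p_cons", "t_proc", "p_anc"))
    .check(is.finite(th[[f]]) && th[[f]] >= 0, id, f, "must be >= 0")
  for (f in c("U_m", "U_max", "U_anc"))
    .check(is.finite(th[[f]]) && th[[f]] >= 1, id, f, "must be >= 1")
  invisible(th)
}

validate_global_costs <- function(costs) {
  for (f in .cost_fields)
    .check(is.finite(costs[[f]]) && costs[[f]] >= 0, "<global>", f,
           "must be >= 0")
  .check(costs$t_dep > 0, "<global>", "t_dep", "must be > 0")
  .check(costs$U_bsc >= 1, "<global>", "U_bsc", "must be >= 1")
  invisible(costs)
}

#' Validate a catalog against the model invariants
#'
#' Checks non-emptiness, tech-id uniqueness, geometry consistency per
#' technology kind, and sign/range constraints on every parameter. Errors
#' name the offending technology and field.
#'
#' @param cat an `ev_catalog` (or an unclassed list with the same shape).
#' @return the catalog, invisibly classed `ev_catalog`, if valid.
#' @export
validate_catalog <- function(cat) {
  if (!nrow(cat$expansion))
    stopf("catalog validation: expansion technology list is empty")
  if (!nrow(cat$harvest))
    stopf("catalog validation: harvest technology list is empty")
  miss <- setdiff(setdiff(.expansion_cols, "provenance"),
                  names(cat$expansion))
  if (length(miss))
    stopf("catalog validation: expansion table lacks column(s): %s",
          paste(miss, collapse = ", "))
  miss <- setdiff(setdiff(.harvest_cols, "provenance"), names(cat$harvest))
  if (length(miss))
    stopf("catalog validation: harvest table lacks column(s): %s",
          paste(miss, collapse = ", "))
  if (is.null(cat$expansion$provenance)) cat$expansion$provenance <- "user"
  if (is.null(cat$harvest$provenance)) cat$harvest$provenance <- "user"
  if (anyDuplicated(cat$expansion$tech_id))
    stopf("catalog validation: duplicated expansion tech_id '%s'",
          cat$expansion$tech_id[duplicated(cat$expansion$tech_id)][1])
  if (anyDuplicated(cat$harvest$tech_id))
    stopf("catalog validation: duplicated harvest tech_id '%s'",
          cat$harvest$tech_id[duplicated(cat$harvest$tech_id)][1])
  for (i in seq_len(nrow(cat$expansion)))
    validate_expansion_row(cat$expansion[i, ])
  for (i in seq_len(nrow(cat$harvest)))
    validate_harvest_row(cat$harvest[i, ])
  validate_global_costs(cat$costs)
  class(cat) <- "ev_catalog"
  invisible(cat)
}

#' Read a catalog from a YAML or JSON document
#'
#' The document has three sections: `costs` (a mapping of the
#' [global_costs()] fields), `expansion` and `harvest` (each a sequence of
#' mappings, one per technology, keyed by the [expansion_tech()] /
#' [harvest_tech()] field names). The shipped default catalog
#' (`system.file("extdata", "default_catalog.yaml", package = "evcog")`)
#' doubles as a schema example.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return validated `ev_catalog`.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stopf("catalog file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  doc <- tryCatch(
    switch(ext,
           yaml = , yml = yaml::read_yaml(path),
           json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
           stopf("unsupported catalog format '.%s' (use yaml or json)", ext)),
    error = function(e)
      stopf("catalog format error in '%s': %s", path, conditionMessage(e))
  )
  catalog_from_list(doc)
}

catalog_from_list <- function(doc) {
  for (sec in c("expansion", "harvest", "costs"))
    if (is.null(doc[[sec]]))
      stopf("catalog format error: missing section '%s'", sec)
  exp_rows <- lapply(doc$expansion, function(x) {
    x$provenance <- x$provenance %||% "user"
    do.call(expansion_tech, x)
  })
  hrv_rows <- lapply(doc$harvest, function(x) {
    x$provenance <- x$provenance %||% "user"
    do.call(harvest_tech, x)
  })
  costs <- do.call(global_costs, doc$costs)
  catalog(do.call(rbind, exp_rows), do.call(rbind, hrv_rows), costs)
}

#' Write a catalog to YAML or JSON
#'
#' Inverse of [read_catalog()]: `read_catalog(write_catalog(cat, f))`
#' reproduces the catalog field by field.
#'
#' @param cat an `ev_catalog`.
#' @param path output path, `.yaml`/`.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(cat, path) {
  doc <- list(
    costs = unclass(cat$costs),
    expansion = lapply(seq_len(nrow(cat$expansion)),
                       function(i) as.list(cat$expansion[i, ])),
    harvest = lapply(seq_len(nrow(cat$harvest)),
                     function(i) as.list(cat$harvest[i, ]))
  )
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         yaml = , yml = yaml::write_yaml(doc, path, precision = 17),
         json = jsonlite::write_json(doc, path, auto_unbox = TRUE,
                                     digits = NA, pretty = TRUE),
         stopf("unsupported catalog format '.%s' (use yaml or json)", ext))
  invisible(path)
}

#' Assemble a catalog from per-table CSV files
#'
#' Column headers must match the [expansion_tech()] / [harvest_tech()]
#' argument names (`provenance` optional).
#'
#' @param expansion_csv path to the expansion-technology table.
#' @param harvest_csv path to the harvest-technology table.
#' @param costs a [global_costs()] object, or a path to a two-column CSV
#'   (`field,value`) with the global cost fields.
#' @return validated `ev_catalog`.
#' @export
catalog_from_csv <- function(expansion_csv, harvest_csv,
                             costs = global_costs()) {
  exp <- utils::read.csv(expansion_csv, stringsAsFactors = FALSE)
  hrv <- utils::read.csv(harvest_csv, stringsAsFactors = FALSE)
  if (is.character(costs)) {
    tab <- utils::read.csv(costs, stringsAsFactors = FALSE)
    vals <- as.list(stats::setNames(as.numeric(tab$value), tab$field))
    costs <- do.call(global_costs, vals)
  }
  if (is.null(exp$provenance)) exp$provenance <- "user"
  if (is.null(hrv$provenance)) hrv$provenance <- "user"
  catalog(exp, hrv, costs)
}

#' Path to the shipped default catalog
#'
#' The shipped catalog lists the technologies discussed throughout the
#' package (planar vessels T-175 through cL-120, a hollow-fiber device, 20 L
#' and 50 L microcarrier bioreactors; harvest by UC, PPT, SEC1, SEC2, UF1,
#' UF2). Entries whose `provenance` is `"placeholder"` carry plausible
#' order-of-magnitude values intended to be replaced by the user's own
#' vendor quotes; model behavior, not these numbers, is what the package's
#' tests pin down.
#'
#' @return file path to `default_catalog.yaml`.
#' @export
default_catalog_path <- function() {
  system.file("extdata", "default_catalog.yaml", package = "evcog",
              mustWork = TRUE)
}

#' Generate a random but valid technology catalog
#'
#' Intended for property-style testing and demonstration. Technology scales
#' (growth areas, bioreactor volumes, harvest sample volumes) are spread
#' geometrically over at least two orders of magnitude so that optimizers
#' exercised on these catalogs must switch technologies as lot size grows.
#'
#' @param n_expansion number of expansion technologies (>= 1).
#' @param n_harvest number of harvest technologies (>= 1).
#' @param seed integer seed; the result is a pure function of the arguments.
#' @return validated `ev_catalog`.
#' @export
synthetic_catalog <- function(n_expansion, n_harvest, seed) {
  stopifnot(n_expansion >= 1, n_harvest >= 1)
  with_seed(seed, {
    scale_e <- 10 ^ (seq(0, 3, length.out = max(n_expansion, 2)) +
                       stats::runif(max(n_expansion, 2), -0.2, 0.2))
    exp_rows <- lapply(seq_len(n_expansion), function(i) {
      s <- scale_e[i]
      kind <- if (i %% 3 == 0) "microcarrier_sub" else "planar"
      if (kind == "planar") {
        expansion_tech(
          tech_id = sprintf("EXP%02d", i), kind = kind,
          a_pln = round(175 * s), v_pln = stats::runif(1, 1e-4, 4e-4),
          d_c_min = 5e3, d_c_max = stats::runif(1, 3, 8) * 1e4,
          p_vess = round(10 * s ^ 0.8 + stats::runif(1, 0, 20), 2),
          p_inc = round(stats::runif(1, 8000, 40000)),
          U_inc = sample(2:40, 1),
          p_anc = round(stats::runif(1, 0, 20000)),
          U_anc = sample(1:10, 1),
          U_m = sample(4:40, 1), U_max = sample(20:200, 1),
          t_seed = stats::runif(1, 0.2, 2), t_coll = stats::runif(1, 0.2, 2),
          needs_bsc = sample(c(TRUE, FALSE), 1),
          provenance = "synthetic"
        )
      } else {
        expansion_tech(
          tech_id = sprintf("EXP%02d", i), kind = kind,
          V_sub = round(0.5 * s, 2), a_mc = stats::runif(1, 200, 500),
          d_mc = stats::runif(1, 5, 15),
          d_c_min = 5e3, d_c_max = stats::runif(1, 3, 8) * 1e4,
          p_vess = round(100 * s ^ 0.8, 2),
          p_inc = round(stats::runif(1, 20000, 80000)),
          U_inc = sample(1:4, 1),
          p_anc = round(stats::runif(1, 0, 40000)),
          U_anc = sample(1:4, 1),
          U_m = sample(1:6, 1), U_max = sample(4:20, 1),
          t_seed = stats::runif(1, 1, 4), t_coll = stats::runif(1, 1, 4),
          needs_bsc = FALSE, provenance = "synthetic"
        )
      }
    })
    scale_h <- 10 ^ (seq(-2, 1.3, length.out = max(n_harvest, 2)) +
                       stats::runif(max(n_harvest, 2), -0.2, 0.2))
    hrv_rows <- lapply(seq_len(n_harvest), function(j) {
      s <- scale_h[j]
      harvest_tech(
        tech_id = sprintf("HRV%02d", j),
        recovery = stats::runif(1, 0.2, 1),
        V_max = signif(s, 3),
        p_cons = round(stats::runif(1, 10, 100) * s ^ 0.5, 2),
        t_proc = stats::runif(1, 0.5, 5),
        U_m = sample(2:20, 1), U_max = sample(10:100, 1),
        p_anc = round(stats::runif(1, 0, 60000)),
        U_anc = sample(1:8, 1),
        provenance = "synthetic"
      )
    })
    catalog(do.call(rbind, exp_rows[seq_len(n_expansion)]),
            do.call(rbind, hrv_rows[seq_len(n_harvest)]),
            global_costs())
  })
}

# fetch one technology row by id; errors if absent
catalog_tech <- function(cat, tech_id,
                         which = c("expansion", "harvest")) {
  which <- match.arg(which)
  tab <- cat[[which]]
  i <- match(tech_id, tab$tech_id)
  if (is.na(i)) stopf("no %s technology '%s' in catalog", which, tech_id)
  tab[i, ]
}
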