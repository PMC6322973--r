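#' Clinical dose model
#'
#' Converts between EV counts and clinical doses by protein mass. Defaults
#' follow reported trial practice: 247 micrograms of EV protein per dose,
#' about 0.1 femtograms of protein per purified EV, and seven doses per
#' patient over a course of treatment.
#'
#' @param protein_per_dose_ug EV protein mass per dose, micrograms.
#' @param protein_per_ev_fg protein mass per EV, femtograms.
#' @param doses_per_patient doses administered per patient.
#' @return list of class `ev_dose_model`.
#' @export
dose_model <- function(protein_per_dose_ug = 247, protein_per_ev_fg = 0.1,
                       doses_per_patient = 7) {
  stopifnot(protein_per_dose_ug > 0, protein_per_ev_fg > 0,
            doses_per_patient > 0)
  structure(list(protein_per_dose_ug = protein_per_dose_ug,
                 protein_per_ev_fg = protein_per_ev_fg,
                 doses_per_patient = doses_per_patient),
            class = "ev_dose_model")
}

#' EVs consumed by one dose
#'
#' `protein_per_dose / protein_per_ev` after converting micrograms to
#' femtograms (1 ug = 1e9 fg). Reported raw and rounded to two significant
#' figures, the precision at which such planning figures are quoted.
#'
#' @param model [dose_model()].
#' @return list with `raw` and `rounded` EV counts per dose.
#' @export
evs_per_dose <- function(model) {
  raw <- model$protein_per_dose_ug * 1e9 / model$protein_per_ev_fg
  list(raw = raw, rounded = signif(raw, 2))
}

#' Annual dose and patient capacity of a manufacturing line
#'
#' Doses per year are the annual EV output over the per-dose EV count;
#' patients per year divide by the doses each patient receives. Raw figures
#' are exact; the rounded figures propagate planning precision through the
#' chain (EVs/dose at two significant figures, doses to the nearest
#' thousand, patients — computed from the rounded dose figure — to the
#' nearest ten), matching how such capacity estimates are quoted.
#'
#' @param lot_size EVs per lot.
#' @param lots_per_year lots per year (>= 0).
#' @param model [dose_model()].
#' @return list of class `ev_capacity` with raw and rounded
#'   `doses_per_year` / `patients_per_year` and the underlying
#'   [evs_per_dose()] figures.
#' @export
annual_capacity <- function(lot_size, lots_per_year,
                            model = dose_model()) {
  stopifnot(lot_size > 0, lots_per_year >= 0)
  epd <- evs_per_dose(model)
  annual_evs <- lot_size * lots_per_year
  doses_raw <- annual_evs / epd$raw
  doses_rounded <- round_to(annual_evs / epd$rounded, 1000)
  patients_raw <- doses_raw / model$doses_per_patient
  patients_rounded <- round_to(doses_rounded / model$doses_per_patient, 10)
  structure(
    list(lot_size = lot_size, lots_per_year = lots_per_year,
         evs_per_dose = epd$raw, evs_per_dose_rounded = epd$rounded,
         doses_per_year = doses_raw, doses_per_year_rounded = doses_rounded,
         patients_per_year = patients_raw,
         patients_per_year_rounded = patients_rounded),
    class = "ev_capacity"
  )
}

#' @export
print.ev_capacity <- function(x, ...) {
  cat(format_capacity(x), sep = "\n")
  invisible(x)
}

format_capacity <- function(x) {
  c(sprintf("Dose capacity at %.3g EVs/lot x %g lots/year:",
            x$lot_size, x$lots_per_year),
    sprintf("  EVs per dose:      %.6g   (~%.2g)",
            x$evs_per_dose, x$evs_per_dose_rounded),
    sprintf("  doses per year:    %.6g   (~%g)",
            x$doses_per_year, x$doses_per_year_rounded),
    sprintf("  patients per year: %.6g   (~%g)",
            x$patients_per_year, x$patients_per_year_rounded))
}
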