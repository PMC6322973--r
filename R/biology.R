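#' Biological parameters for EV accumulation
#'
#' The growth/accumulation model assumes exponential cell growth with
#' population doubling time `t_d` and EV release proportional to cumulative
#' new cells: after the population grows from `N_seed` to `N`, the
#' conditioned media holds `alpha * (N - N_seed)` EVs. `alpha` is therefore
#' the EV output per cell per population doubling. Defaults are the
#' mesenchymal-stem-cell values adopted for the model's baseline donors
#' (22 h doubling time, 11,500 EVs per cell per doubling).
#'
#' @param t_d population doubling time, h.
#' @param alpha EV output per cell per population doubling.
#' @param label scenario name for reporting.
#' @return list of class `ev_biology`.
#' @export
biology_params <- function(t_d = 22, alpha = 11500, label = "baseline") {
  if (!is.finite(t_d) || t_d <= 0) stopf("biology: t_d must be > 0")
  if (!is.finite(alpha) || alpha <= 0) stopf("biology: alpha must be > 0")
  structure(list(t_d = t_d, alpha = alpha, label = label),
            class = "ev_biology")
}

#' @export
print.ev_biology <- function(x, ...) {
  cat(sprintf("EV biology scenario '%s': t_d = %g h, alpha = %g EVs/cell/doubling\n",
              x$label, x$t_d, x$alpha))
  invisible(x)
}

#' Scale the EV output of a biology scenario
#'
#' Convenience for scenario comparison: high-producer donors or
#' starvation-type culture conditions are modelled as multiplicative boosts
#' of `alpha` at unchanged doubling time (a high-producing donor at around
#' 3x, serum-starvation at around 10x).
#'
#' @param bio base [biology_params()].
#' @param multiplier factor applied to `alpha`.
#' @param label scenario name.
#' @return new `ev_biology`.
#' @export
scale_alpha <- function(bio, multiplier, label = sprintf("%s x%g alpha",
                                                         bio$label,
                                                         multiplier)) {
  biology_params(t_d = bio$t_d, alpha = bio$alpha * multiplier, label = label)
}

#' Cells held by one unit of an expansion technology at a given density
#'
#' The growth surface is `a_pln` for planar-type vessels and
#' `a_mc * d_mc * V_sub` for microcarrier bioreactors; the two terms are
#' structurally exclusive, so one expression covers both kinds.
#'
#' @param tech one expansion-technology row (see [expansion_tech()]).
#' @param density cell density, cells/cm^2.
#' @return cell count per unit.
#' @export
cells_per_unit <- function(tech, density) {
  density * (tech$a_pln + tech$a_mc * tech$d_mc * tech$V_sub)
}

#' Maximum EVs one unit can accumulate in one lot
#'
#' EVs accumulated while the culture grows from the seeding density to the
#' maximum allowable density: `alpha * (Nc(d_c_max) - Nc(d_c_min))`.
#'
#' @param tech one expansion-technology row.
#' @param bio [biology_params()].
#' @return EV count per unit.
#' @export
max_evs_per_unit <- function(tech, bio) {
  bio$alpha * (cells_per_unit(tech, tech$d_c_max) -
                 cells_per_unit(tech, tech$d_c_min))
}

#' Culture time needed to accumulate a given EV load per unit
#'
#' Inverts the exponential accumulation model: seeding `N_seed` cells and
#' demanding `evs_per_unit` EVs means growing to
#' `N_final = N_seed + evs_per_unit / alpha`, which takes
#' `t_d * log2(N_final / N_seed)` hours. The lot's culture duration feeds the
#' minimum-lag feasibility rule (cultures must run at least 24 h).
#'
#' @param tech one expansion-technology row.
#' @param bio [biology_params()].
#' @param evs_per_unit EV load assigned to one unit; must not exceed
#'   [max_evs_per_unit()] (a relative tolerance of 1e-9 absorbs rounding
#'   residue from unit-count arithmetic).
#' @return duration in hours; 0 when `evs_per_unit` is 0, and
#'   `t_d * log2(d_c_max / d_c_min)` at the maximum load.
#' @export
culture_duration <- function(tech, bio, evs_per_unit) {
  vmax <- max_evs_per_unit(tech, bio)
  if (evs_per_unit < 0) stopf("culture_duration: negative EV load")
  if (evs_per_unit > vmax * (1 + 1e-9))
    stopf("culture_duration: EV load %g exceeds per-unit maximum %g",
          evs_per_unit, vmax)
  evs <- min(evs_per_unit, vmax)
  n_seed <- cells_per_unit(tech, tech$d_c_min)
  bio$t_d * log2((n_seed + evs / bio$alpha) / n_seed)
}

#' Simulate an EV accumulation time course
#'
#' Generates the measurements a culture-sampling experiment would produce
#' under the accumulation model: cells grow exponentially from `n_seed` with
#' doubling time `bio$t_d`; cumulative EVs in the conditioned media are
#' `alpha * (n_cells - n_seed)`. Optional multiplicative lognormal noise
#' (unit mean, coefficient of variation `noise_sd`) perturbs the EV counts
#' at positive times; the seeding row always records zero EVs because fresh
#' media is particle-free.
#'
#' @param bio [biology_params()].
#' @param n_seed cells at seeding.
#' @param duration total sampled time, h.
#' @param step sampling interval, h.
#' @param noise_sd coefficient of variation of the multiplicative EV
#'   measurement noise (0 for exact model values).
#' @param seed integer seed used when `noise_sd > 0`.
#' @return `data.frame` with columns `t_h`, `n_cells`, `n_evs`.
#' @export
synthetic_time_course <- function(bio, n_seed = 5e3, duration = 96,
                                  step = 12, noise_sd = 0, seed = 1) {
  stopifnot(duration >= step, step > 0, n_seed > 0, noise_sd >= 0)
  t <- seq(0, duration, by = step)
  n_cells <- n_seed * 2 ^ (t / bio$t_d)
  n_evs <- bio$alpha * (n_cells - n_seed)
  if (noise_sd > 0) {
    sdlog <- sqrt(log1p(noise_sd ^ 2))
    fac <- with_seed(seed,
                     stats::rlnorm(length(t), meanlog = -sdlog ^ 2 / 2,
                                   sdlog = sdlog))
    n_evs <- n_evs * fac
    n_evs[t == 0] <- 0
  }
  data.frame(t_h = t, n_cells = n_cells, n_evs = n_evs)
}

check_time_course <- function(data) {
  need <- c("t_h", "n_cells", "n_evs")
  if (!all(need %in% names(data)))
    stopf("time course must have columns %s", paste(need, collapse = ", "))
  if (nrow(data) >= 2 && any(diff(data$t_h) <= 0))
    stopf("time course: t_h must be strictly increasing")
  if (any(data$n_cells < 0) || any(data$n_evs < 0))
    stopf("time course: counts must be >= 0")
  if (data$n_evs[1] != 0)
    stopf("time course: first sample must have n_evs = 0 (fresh media)")
  invisible(data)
}

#' Fit biological parameters from a cell/EV time course
#'
#' Two independent regressions recover the model parameters from
#' measurements: the doubling time from the log-linear growth fit
#' `ln(n_cells) ~ t` (`t_d = ln 2 / slope`), and the per-doubling EV output
#' as the least-squares slope through the origin of cumulative EVs against
#' cumulative new cells (`n_evs ~ 0 + (n_cells - n_cells[1])`). The reported
#' R^2 is the coefficient of determination of the EV fit.
#'
#' @param data `data.frame` with columns `t_h`, `n_cells`, `n_evs`
#'   (at least 3 rows, strictly increasing cell counts).
#' @return list of class `ev_fit` with elements `params`
#'   (a [biology_params()]) and `r_squared`.
#' @export
fit_biology <- function(data) {
  check_time_course(data)
  if (nrow(data) < 3)
    stopf("fit_biology: need at least 3 time points, got %d", nrow(data))
  if (any(diff(data$n_cells) <= 0))
    stopf("fit_biology: cell counts must be strictly increasing")
  growth <- stats::lm(log(n_cells) ~ t_h, data = data)
  t_d <- log(2) / stats::coef(growth)[["t_h"]]
  x <- data$n_cells - data$n_cells[1]
  y <- data$n_evs
  alpha <- sum(x * y) / sum(x ^ 2)
  ss_res <- sum((y - alpha * x) ^ 2)
  ss_tot <- sum((y - mean(y)) ^ 2)
  r2 <- 1 - ss_res / ss_tot
  structure(
    list(params = biology_params(t_d = t_d, alpha = alpha, label = "fitted"),
         r_squared = r2),
    class = "ev_fit"
  )
}

#' @export
print.ev_fit <- function(x, ...) {
  cat(sprintf("EV accumulation fit: t_d = %.4g h, alpha = %.6g EVs/cell/doubling (R^2 = %.4f)\n",
              x$params$t_d, x$params$alpha, x$r_squared))
  invisible(x)
}

#' Read / write a time course as CSV
#'
#' Plain CSV with columns `t_h`, `n_cells`, `n_evs`; validated on read.
#'
#' @param path file path.
#' @return `read_time_course()`: the validated `data.frame`.
#' @export
read_time_course <- function(path) {
  check_time_course(utils::read.csv(path))
}

#' @param data time-course `data.frame`.
#' @rdname read_time_course
#' @export
write_time_course <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}
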