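# Hand-built fixture technologies with round numbers, used across tests.

simple_planar <- function(...) {
  args <- list(
    tech_id = "PLN-A", kind = "planar",
    a_pln = 1000, v_pln = 2e-3,           # 2 L of media per unit
    d_c_min = 5e3, d_c_max = 5e4,
    p_vess = 50, p_inc = 10000, U_inc = 4,
    p_anc = 0, U_anc = 1, U_m = 2, U_max = 100,
    t_seed = 1, t_coll = 1, needs_bsc = TRUE
  )
  mod <- list(...)
  args[names(mod)] <- mod
  do.call(expansion_tech, args)
}

simple_sub <- function(...) {
  args <- list(
    tech_id = "SUB-A", kind = "microcarrier_sub",
    V_sub = 20, a_mc = 360, d_mc = 10,
    d_c_min = 5e3, d_c_max = 5e4,
    p_vess = 1500, p_inc = 50000, U_inc = 1,
    p_anc = 20000, U_anc = 2, U_m = 2, U_max = 6,
    t_seed = 3, t_coll = 2, needs_bsc = FALSE
  )
  mod <- list(...)
  args[names(mod)] <- mod
  do.call(expansion_tech, args)
}

simple_harvest <- function(...) {
  args <- list(
    tech_id = "HRV-A", recovery = 0.8, V_max = 0.24,
    p_cons = 100, t_proc = 3, U_m = 2, U_max = 1000,
    p_anc = 0, U_anc = 1
  )
  mod <- list(...)
  args[names(mod)] <- mod
  do.call(harvest_tech, args)
}

simple_catalog <- function(costs = global_costs(beta = 0)) {
  catalog(
    rbind(simple_planar(),
          simple_sub(tech_id = "SUB-B")),
    rbind(simple_harvest(),
          simple_harvest(tech_id = "HRV-B", recovery = 1, V_max = 50,
                         p_cons = 400, t_proc = 4, U_m = 4, U_max = 20,
                         p_anc = 25000, U_anc = 2)),
    costs
  )
}

# random demand inside the default lots/year window, derived from a seed
random_demand <- function(seed) {
  evcog:::with_seed(seed + 10000L, {
    demand(n_v_lot = 10 ^ runif(1, 10, 13.5),
           n_lot_yr = runif(1, 10, 200))
  })
}
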