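bio <- biology_params()

test_that("pre-harvest EV requirement scales inversely with recovery", {
  dem <- demand(1e12, 100)
  expect_equal(required_evs_pre_harvest(dem, simple_harvest(recovery = 1)),
               1e12)
  expect_equal(required_evs_pre_harvest(dem, simple_harvest(recovery = 0.8)),
               1.25e12)
  expect_equal(required_evs_pre_harvest(dem, simple_harvest(recovery = 0.5)),
               2 * required_evs_pre_harvest(dem,
                                            simple_harvest(recovery = 1)))
})

test_that("unit counts round up with a float-residue guard", {
  te <- simple_planar()           # max 5.175e11 EVs/unit
  vmax <- max_evs_per_unit(te, bio)
  expect_equal(expansion_units(vmax, te, bio), 1)        # exact fit
  expect_equal(expansion_units(1e12, te, bio), 2)        # ceil(1.932)
  # a genuine 1e-7 overshoot costs a unit; 1e-12 residue does not
  expect_equal(expansion_units(vmax * (1 + 1e-7), te, bio), 2)
  expect_equal(expansion_units(vmax * (1 + 1e-12), te, bio), 1)

  th <- simple_harvest(V_max = 0.24)
  expect_equal(harvest_units(3, te, th), 25)             # 6 L / 0.24 L
  expect_equal(harvest_units(1, te, simple_harvest(V_max = 2)), 1)  # exact
  expect_equal(harvest_units(1, te, simple_harvest(V_max = 50)), 1) # buffer
})

test_that("per-lot cost components match hand arithmetic", {
  costs <- global_costs(p_med = 150, p_lab = 200, beta = 0, p_mc = 0)
  te <- simple_planar()   # 2 L media, $50 vessel
  expect_equal(expansion_consumables(2, te, costs), 2 * (50 + 300))
  # microcarrier term is structurally absent for planar vessels
  costs_mc <- global_costs(p_mc = 1000)
  expect_equal(expansion_consumables(1, te, costs_mc),
               te$p_vess + costs_mc$p_med * 2)
  free <- simple_planar(p_vess = 0)
  expect_equal(expansion_consumables(3, free, global_costs(p_med = 0)), 0)

  expect_equal(operators_needed(5, 2), 3)
  expect_equal(operators_needed(7, 7), 1)
  expect_equal(operators_needed(1, 10), 1)

  expect_equal(expansion_labor(1, te, costs), 200 * 2)       # beta = 0
  expect_equal(expansion_labor(1, te, global_costs(beta = 1)),
               2 * expansion_labor(1, te, global_costs(beta = 0)))

  eq_te <- simple_planar(p_inc = 10000, U_inc = 4, p_anc = 0,
                         needs_bsc = FALSE)
  expect_equal(expansion_equipment(10, 1, eq_te, global_costs(p_bsc = 1e9)),
               30000)  # BSC term vanishes without the cabinet requirement
  wide <- simple_planar(p_inc = 10000, U_inc = 8, p_anc = 0,
                        needs_bsc = FALSE)
  expect_lte(expansion_equipment(10, 1, wide, costs),
             expansion_equipment(10, 1, eq_te, costs))

  expect_equal(harvest_consumables(25, simple_harvest(p_cons = 100)), 2500)
  expect_equal(harvest_consumables(1, simple_harvest(p_cons = 0)), 0)

  expect_equal(harvest_labor(2, simple_harvest(t_proc = 3),
                             global_costs(p_lab = 200, beta = 0.3)), 1560)
  expect_equal(harvest_labor(1, simple_harvest(t_proc = 0),
                             global_costs(beta = 0)), 0)
})

test_that("harvest equipment charges only the extra biosafety cabinets", {
  costs <- global_costs(p_bsc = 12000, U_bsc = 2)
  te_bsc <- simple_planar(needs_bsc = TRUE)
  te_free <- simple_planar(needs_bsc = FALSE)
  th <- simple_harvest(p_anc = 5000, U_anc = 10)
  # expansion cabinets already cover the harvest operators
  expect_equal(harvest_equipment(5, 2, 4, te_bsc, th, costs), 5000)
  # no expansion cabinets: all harvest cabinets are charged
  expect_equal(harvest_equipment(5, 3, 4, te_free, th, costs),
               5000 + 2 * 12000)
  # ancillary term is independent of the cabinet branch
  expect_equal(harvest_equipment(5, 2, 4, te_bsc,
                                 simple_harvest(p_anc = 0), costs), 0)
})

test_that("annual COG is affine in lots/year with equipment as intercept", {
  stage <- list(consumables = 700, labor = 400, equipment = 30000)
  costs <- global_costs(t_dep = 5)
  z <- function(n) annual_cog_expansion(stage, demand(1e12, n), costs)
  expect_equal(z(10), 10 * 1100 + 6000)
  expect_equal(z(20) - z(10), 10 * 1100)              # slope = variable cost
  expect_equal(annual_cog_harvest(stage, demand(1e12, 10), costs), z(10))
  # amortization limit: long depreciation leaves variable costs only
  expect_equal(annual_cog_expansion(stage, demand(1e12, 10),
                                    global_costs(t_dep = 1e12)),
               10 * 1100, tolerance = 1e-6)
})

test_that("cost_lot composes the full chain and matches the oracle", {
  cat <- simple_catalog()
  dem <- demand(1e12, 100)
  for (i in seq_len(nrow(cat$expansion))) {
    for (j in seq_len(nrow(cat$harvest))) {
      te <- cat$expansion[i, ]; th <- cat$harvest[j, ]
      sol <- cost_lot(te, th, dem, bio, cat$costs)
      orc <- oracle_cost_pair(te, th, dem, bio, cat$costs)
      expect_equal(sol$u_e, orc$u_e)
      expect_equal(sol$u_h, orc$u_h)
      expect_equal(sol$z_total, orc$z, tolerance = 1e-9)
      expect_equal(sol$z_total, sol$z_expansion + sol$z_harvest)
      expect_equal(sol$culture_h, orc$culture_h, tolerance = 1e-9)
    }
  }
})

test_that("zero prices give zero annual COG", {
  zero <- global_costs(p_med = 0, p_lab = 0, beta = 0, p_mc = 0, p_bsc = 0)
  te <- simple_planar(p_vess = 0, p_inc = 0, p_anc = 0)
  th <- simple_harvest(p_cons = 0, p_anc = 0)
  sol <- cost_lot(te, th, demand(1e12, 100), bio, zero)
  expect_equal(sol$z_total, 0)
})

test_that("lower recovery can be absorbed by longer culture, not more vessels", {
  # ample capacity: one bioreactor covers the requirement at either recovery
  te <- simple_sub()
  dem <- demand(1e11, 100)
  hi <- cost_lot(te, simple_harvest(recovery = 1, V_max = 50), dem, bio,
                 global_costs())
  lo <- cost_lot(te, simple_harvest(recovery = 0.5, V_max = 50), dem, bio,
                 global_costs())
  expect_equal(hi$u_e, lo$u_e)
  expect_gt(lo$culture_h, hi$culture_h)
})

test_that("unit counts are non-decreasing step functions of lot size", {
  te <- simple_planar(); th <- simple_harvest()
  lots <- 10 ^ seq(10, 13, length.out = 40)
  sols <- lapply(lots, function(l)
    cost_lot(te, th, demand(l, 100), bio, global_costs()))
  u_e <- vapply(sols, `[[`, numeric(1), "u_e")
  u_h <- vapply(sols, `[[`, numeric(1), "u_h")
  expect_true(all(diff(u_e) >= 0))
  expect_true(all(diff(u_h) >= 0))
})

test_that("COG responds monotonically to prices, beta, recovery and alpha", {
  cat <- simple_catalog(global_costs(beta = 0.2))
  dem <- demand(2e12, 100)
  te <- cat$expansion[1, ]; th <- cat$harvest[1, ]
  base <- cost_lot(te, th, dem, bio, cat$costs)$z_total
  # every price and beta: non-decreasing
  for (f in c("p_med", "p_lab", "p_mc", "p_bsc", "beta")) {
    up <- cat$costs; up[[f]] <- up[[f]] * 2 + 1
    expect_gte(cost_lot(te, th, dem, bio, up)$z_total, base)
  }
  for (f in c("p_vess", "p_inc", "p_anc")) {
    up <- te; up[[f]] <- up[[f]] * 2 + 1
    expect_gte(cost_lot(up, th, dem, bio, cat$costs)$z_total, base)
  }
  # recovery and alpha: non-increasing in the helpful direction
  worse <- th; worse$recovery <- th$recovery / 2
  expect_gte(cost_lot(te, worse, dem, bio, cat$costs)$z_total, base)
  expect_lte(cost_lot(te, th, dem, scale_alpha(bio, 3), cat$costs)$z_total,
             base)
  # capacity limits: relaxing them never raises cost
  for (f in c("U_inc", "U_anc", "U_m")) {
    up <- te; up[[f]] <- up[[f]] * 2
    expect_lte(cost_lot(up, th, dem, bio, cat$costs)$z_total, base)
  }
})

test_that("labor scales exactly with the labor rate; media touches only expansion consumables", {
  te <- simple_planar(); th <- simple_harvest()
  dem <- demand(2e12, 100)
  c1 <- global_costs(p_lab = 200)
  c2 <- global_costs(p_lab = 400)
  s1 <- cost_lot(te, th, dem, bio, c1)
  s2 <- cost_lot(te, th, dem, bio, c2)
  expect_identical(s2$expansion$labor, 2 * s1$expansion$labor)
  expect_identical(s2$harvest$labor, 2 * s1$harvest$labor)
  expect_identical(s2$expansion$consumables, s1$expansion$consumables)

  m1 <- cost_lot(te, th, dem, bio, global_costs(p_med = 150))
  m2 <- cost_lot(te, th, dem, bio, global_costs(p_med = 195))
  expect_identical(m1$harvest, m2$harvest)      # bit-identical harvest stage
  expect_identical(m1$z_harvest, m2$z_harvest)
  expect_gt(m2$expansion$consumables, m1$expansion$consumables)
})

test_that("lot solutions flatten and serialize", {
  sol <- cost_lot(simple_planar(), simple_harvest(), demand(1e12, 100), bio,
                  global_costs())
  df <- as.data.frame(sol)
  expect_equal(nrow(df), 1)
  expect_equal(df$z_total, sol$z_total)
  f <- withr::local_tempfile(fileext = ".json")
  write_lot_solution(sol, f)
  back <- jsonlite::fromJSON(f)
  expect_equal(back$z_total, sol$z_total)
})
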