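# Independent straight-line recomputation of the per-lot cost model and the
# exhaustive pair search. Deliberately written without calling any evcog
# function, so it can serve as an oracle for the package's optimizer.

oracle_ceil <- function(x) {
  n <- round(x)
  if (abs(x - n) <= 1e-9 * max(1, abs(x))) n else ceiling(x)
}

oracle_cost_pair <- function(te, th, dem, bio, costs) {
  n_v_pre <- dem$n_v_lot / th$recovery
  area <- te$a_pln + te$a_mc * te$d_mc * te$V_sub
  ev_max <- bio$alpha * (te$d_c_max - te$d_c_min) * area
  u_e <- max(1, oracle_ceil(n_v_pre / ev_max))
  vol <- te$v_pln * te$a_pln + te$V_sub
  u_h <- max(1, oracle_ceil(u_e * vol / th$V_max))
  m_e <- oracle_ceil(u_e / te$U_m)
  m_h <- oracle_ceil(u_h / th$U_m)
  cons_e <- u_e * (te$p_vess + costs$p_med * vol +
                     costs$p_mc * te$d_mc * te$V_sub)
  lab_e <- m_e * costs$p_lab * (te$t_seed + te$t_coll) * (1 + costs$beta)
  delta <- as.numeric(te$needs_bsc)
  eq_e <- te$p_inc * oracle_ceil(u_e / te$U_inc) +
    costs$p_bsc * oracle_ceil(m_e * delta / costs$U_bsc) +
    te$p_anc * oracle_ceil(u_e / te$U_anc)
  cons_h <- u_h * th$p_cons
  lab_h <- m_h * costs$p_lab * th$t_proc * (1 + costs$beta)
  bsc_h <- oracle_ceil(m_h / costs$U_bsc)
  bsc_e <- oracle_ceil(m_e * delta / costs$U_bsc)
  eq_h <- th$p_anc * oracle_ceil(u_h / th$U_anc) +
    if (bsc_h > bsc_e) costs$p_bsc * (bsc_h - bsc_e) else 0
  z_e <- dem$n_lot_yr * (cons_e + lab_e) + eq_e / costs$t_dep
  z_h <- dem$n_lot_yr * (cons_h + lab_h) + eq_h / costs$t_dep
  n_seed <- te$d_c_min * area
  list(
    u_e = u_e, u_h = u_h, m_e = m_e, m_h = m_h,
    cons_e = cons_e, lab_e = lab_e, eq_e = eq_e,
    cons_h = cons_h, lab_h = lab_h, eq_h = eq_h,
    z_e = z_e, z_h = z_h, z = z_e + z_h,
    culture_h = bio$t_d *
      log2((n_seed + (n_v_pre / u_e) / bio$alpha) / n_seed)
  )
}

oracle_optimize <- function(dem, bio, cat, window = c(10, 200),
                            min_culture_h = 24) {
  if (dem$n_lot_yr < window[1] || dem$n_lot_yr > window[2]) return(NULL)
  best <- NULL
  for (j in seq_len(nrow(cat$harvest))) {
    for (i in seq_len(nrow(cat$expansion))) {
      te <- cat$expansion[i, ]; th <- cat$harvest[j, ]
      r <- oracle_cost_pair(te, th, dem, bio, cat$costs)
      if (r$u_e > te$U_max || r$u_h > th$U_max ||
            r$culture_h < min_culture_h) next
      r$expansion_id <- te$tech_id; r$harvest_id <- th$tech_id
      better <- is.null(best) ||
        r$z < best$z ||
        (r$z == best$z && r$u_e + r$u_h < best$u_e + best$u_h) ||
        (r$z == best$z && r$u_e + r$u_h == best$u_e + best$u_h &&
           paste(r$expansion_id, r$harvest_id) <
             paste(best$expansion_id, best$harvest_id))
      if (better) best <- r
    }
  }
  best
}
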