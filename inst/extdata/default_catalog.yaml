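# Default EV-manufacturing technology catalog.
#
# Entries marked provenance: placeholder carry plausible order-of-magnitude
# values for demonstration and testing; replace them with your own vendor
# quotes and protocol timings before using absolute COG figures. Sample
# volumes of the size-exclusion entries follow published protocol limits
# (SEC1 0.5 ml per column, SEC2 240 ml per unit); media and labor prices are
# widely used planning defaults ($150/L, $200/h).
#
# Units: areas cm^2, volumes L, densities cells/cm^2, prices USD, times h,
# depreciation years.

costs:
  p_med: 150.0      # media price, USD/L
  p_lab: 200.0      # labor rate, USD/h
  beta: 0.2         # non-operator labor overhead multiplier
  p_mc: 6.0         # microcarrier price, USD/g
  p_bsc: 12000.0    # biosafety cabinet price, USD
  U_bsc: 2          # operators per biosafety cabinet
  t_dep: 5.0        # equipment depreciation horizon, years

expansion:
  - tech_id: T-175
    kind: planar
    a_pln: 175.0
    v_pln: 0.0002
    d_c_min: 5000.0
    d_c_max: 50000.0
    p_vess: 10.0
    p_inc: 10000.0
    U_inc: 200
    p_anc: 0.0
    U_anc: 1
    U_m: 40
    U_max: 500
    t_seed: 0.25
    t_coll: 0.25
    needs_bsc: true
    provenance: placeholder
  - tech_id: L-1
    kind: planar
    a_pln: 636.0
    v_pln: 0.0002
    d_c_min: 5000.0
    d_c_max: 50000.0
    p_vess: 40.0
    p_inc: 10000.0
    U_inc: 100
    p_anc: 0.0
    U_anc: 1
    U_m: 30
    U_max: 300
    t_seed: 0.3
    t_coll: 0.3
    needs_bsc: true
    provenance: placeholder
  - tech_id: cT
    kind: planar
    a_pln: 875.0
    v_pln: 0.0002
    d_c_min: 5000.0
    d_c_max: 50000.0
    p_vess: 60.0
    p_inc: 10000.0
    U_inc: 80
    p_anc: 0.0
    U_anc: 1
    U_m: 30
    U_max: 300
    t_seed: 0.3
    t_coll: 0.3
    needs_bsc: true
    provenance: placeholder
  - tech_id: L-10
    kind: planar
    a_pln: 6360.0
    v_pln: 0.0002
    d_c_min: 5000.0
    d_c_max: 50000.0
    p_vess: 280.0
    p_inc: 10000.0
    U_inc: 40
    p_anc: 0.0
    U_anc: 1
    U_m: 20
    U_max: 100
    t_seed: 0.5
    t_coll: 0.5
    needs_bsc: true
    provenance: placeholder
  - tech_id: L-40
    kind: planar
    a_pln: 25440.0
    v_pln: 0.0002
    d_c_min: 5000.0
    d_c_max: 50000.0
    p_vess: 1100.0
    p_inc: 12000.0
    U_inc: 10
    p_anc: 20000.0
    U_anc: 4
    U_m: 8
    U_max: 50
    t_seed: 0.75
    t_coll: 0.75
    needs_bsc: true
    provenance: placeholder
  - tech_id: cL-120
    kind: planar
    a_pln: 76320.0
    v_pln: 0.0002
    d_c_min: 5000.0
    d_c_max: 50000.0
    p_vess: 3300.0
    p_inc: 15000.0
    U_inc: 4
    p_anc: 30000.0
    U_anc: 4
    U_m: 4
    U_max: 20
    t_seed: 1.0
    t_coll: 1.0
    needs_bsc: true
    provenance: placeholder
  - tech_id: HF
    kind: hollow_fiber
    a_pln: 21000.0
    v_pln: 0.00002
    d_c_min: 20000.0
    d_c_max: 400000.0
    p_vess: 2500.0
    p_inc: 30000.0
    U_inc: 4
    p_anc: 0.0
    U_anc: 1
    U_m: 4
    U_max: 10
    t_seed: 2.0
    t_coll: 1.0
    needs_bsc: true
    provenance: placeholder
  - tech_id: SUB-20L
    kind: microcarrier_sub
    V_sub: 20.0
    a_mc: 360.0
    d_mc: 10.0
    d_c_min: 5000.0
    d_c_max: 40000.0
    p_vess: 1500.0
    p_inc: 50000.0
    U_inc: 1
    p_anc: 20000.0
    U_anc: 2
    U_m: 2
    U_max: 6
    t_seed: 3.0
    t_coll: 2.0
    needs_bsc: false
    provenance: placeholder
  - tech_id: SUB-50L
    kind: microcarrier_sub
    V_sub: 50.0
    a_mc: 360.0
    d_mc: 10.0
    d_c_min: 5000.0
    d_c_max: 40000.0
    p_vess: 3000.0
    p_inc: 60000.0
    U_inc: 1
    p_anc: 20000.0
    U_anc: 2
    U_m: 2
    U_max: 4
    t_seed: 3.5
    t_coll: 2.5
    needs_bsc: false
    provenance: placeholder

harvest:
  - tech_id: UC         # ultracentrifugation
    recovery: 0.25
    V_max: 0.42
    p_cons: 20.0
    t_proc: 5.0
    U_m: 2
    U_max: 12
    p_anc: 80000.0
    U_anc: 1
    provenance: placeholder
  - tech_id: PPT        # polymer-induced precipitation
    recovery: 0.8
    V_max: 0.06
    p_cons: 150.0
    t_proc: 1.5
    U_m: 12
    U_max: 200
    p_anc: 8000.0
    U_anc: 6
    provenance: placeholder
  - tech_id: SEC1       # size-exclusion chromatography, 0.5 ml columns
    recovery: 0.8
    V_max: 0.0005
    p_cons: 60.0
    t_proc: 0.5
    U_m: 12
    U_max: 400
    p_anc: 3000.0
    U_anc: 12
    provenance: placeholder
  - tech_id: SEC2       # size-exclusion chromatography, 240 ml units
    recovery: 0.7
    V_max: 0.24
    p_cons: 120.0
    t_proc: 2.0
    U_m: 6
    U_max: 60
    p_anc: 15000.0
    U_anc: 4
    provenance: placeholder
  - tech_id: UF1        # dead-end + tangential-flow ultrafiltration
    recovery: 0.7
    V_max: 0.2
    p_cons: 200.0
    t_proc: 2.5
    U_m: 4
    U_max: 40
    p_anc: 25000.0
    U_anc: 2
    provenance: placeholder
  - tech_id: UF2        # UF1 with larger-volume dead-end filters
    recovery: 0.7
    V_max: 4.0
    p_cons: 400.0
    t_proc: 3.0
    U_m: 4
    U_max: 20
    p_anc: 25000.0
    U_anc: 2
    provenance: placeholder
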