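# Default calibration of the pddasim generative model.
# All times in hours unless noted; lifespan block in days.
# These constants are versioned with the package; changing them changes the
# simulated study conditions, not the analysis code.
version: 1
maturation:
  # deterministic core:
  #   T = T0 / f * (1 + delta_A * g_A * sat(A, K_A)
  #                   - delta_X * g_X * sat(X, K_X) / (1 + g_I * g_A * A / K_I))
  # with sat(u, K) = u / (u + K)
  delta_X: 2.93601          # gain of the accelerating signal (compound X)
  K_X: 100000.0             # units; X response is weakly saturating over assay range
  delta_A: 0.008            # additive deceleration by perceived ascarosides
  K_A: 500.0                # units
  K_I: 2900.0               # units; ascaroside inhibition of the X response
  g_X_enhanced: 1.040352    # X gain when both nhr-8 and daf-12 are lost
  g_X_abolished: 0.05       # X gain under insulin-pathway loss or liganded DAF-12
  g_X_nhr8: 0.1             # residual X gain in nhr-8 single mutants
  g_X_daf12: 0.85           # X gain in daf-12 single mutants (slightly reduced)
  noise_sd_default_h: 2.0   # used when a genotype profile does not set its own
deposition:
  rate_X: 1.0               # units per worm-hour
  rate_A: 1.0               # units per worm-hour (wildtype ascaroside output)
  ascr_nM_to_units: 50.0    # exogenous ascaroside dose -> perceived signal units
  da_threshold_nM: 50.0     # dafachronic acid dose treated as receptor-saturating
preconditioning:
  occupancy: 125            # worms on the conditioning plate (100-150 per assay)
  removal_h: 45.0           # conditioning worms removed at L4, before egg laying
  carryover: 0.93           # fraction of deposited signal persisting on the plate
protocol:
  transfer_time_h: 59.0
  scoring_start_h: 60.0
  scoring_interval_h: 1.0
  staging_time_h: 52.0
  hd_plate_size: 100
  hatch_rate: 0.97          # embryonic survival; assays below 0.95 flagged
  reference_maturation_h: 67.942037  # deterministic wildtype ISO time (T_ref)
staging:
  # stage -> typical hours since egg transfer at 20 C, isolated wildtype;
  # L4 sub-stages interpolated linearly between the L4.2 and L4.5 anchors.
  stage_time_map:
    L1: 14.0
    L2: 26.0
    L3: 40.0
    L4.1: 50.333
    L4.2: 52.0
    L4.3: 53.667
    L4.4: 55.333
    L4.5: 57.0
    L4.6: 58.667
    L4.7: 60.333
    L4.8: 62.0
    L4.9: 63.667
    YA: 65.333
    Adult: 67.0
lifespan:
  # Gompertz hazard h(t) = a * exp(b * t), t in days from adulthood;
  # a = a0 * exp(beta * sat(d_larval, K_L)) * (1 + c_da * sat(da_nM, K_da) *
  #     exp(-(d_larval - 1) / da_density_decay))
  gompertz_b: 0.3
  gompertz_a0: 1.999813e-4
  beta: 2.016377
  K_L: 3.0                  # worms; larval-density response scale
  c_da: 2.91194             # hazard multiplier amplitude for dafachronic acid
  K_da: 10.0                # nM
  da_density_decay: 3.0     # worms; DA effect fades with larval crowding
  protocol_I_larval_density: 100  # rearing density before young-adult transfer
  exclusion_rates:
    internal_hatching: 0.03
    exploded: 0.02
    crawled_off: 0.03
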