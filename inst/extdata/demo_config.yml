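# Demonstration run: the full composite, the seven study velocities,
# four replicas, both crystal and water-only pulls, bond-model fit and a
# small slider sweep driven by the fitted interface viscosity.
seed: 1
builder:
  n_units: 2
  strands_per_sheet: 5
  sheets_per_unit: 5
  polyala_length: 8
  n_bundles: 7
  chains_per_bundle: 8
  amorphous_sequence: GPGGYGPGSQGPSGPGGYGPGGPG
  unit_gap: 3
sasa:
  probe: 0.14
  n_points: 960
  contact_threshold: 0.01
truth:
  bond: {ma: 1.32, U_bond: 8.4, m: 2, xi0: 1.0e-12, temperature: 300}
  xi_water_res: 1.0e-12
  n_contact: auto
  n_total: auto
  hold_length: 5.6
  detach_length: 2.8
protocol:
  velocities: [0.02, 0.05, 0.2, 0.5, 2, 5, 20]
  spring_k: 830
  n_springs: 7
  n_replicas: 4
  temperature: 300
extract:
  smooth_window: 50
fit:
  mode: fix_Ubond
slider:
  enabled: true
  velocities: [0.1, 1, 5]
  inclined_velocity: 0.5
  load_angle: 10
  film_h: 500
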