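# Reference process: 100 V across a mashed-potato cylinder, mild external
# heat loss (the best-fitting overall coefficient from experimental work),
# cold surroundings. Omitted fields fall back to the package defaults.
geometry:
  radius: 0.010        # m
  length: 0.20         # m, electrode-to-electrode gap
grid:
  nr: 16
  nz: 16
process:
  applied_voltage: 100 # V
  drive_mode: constant_voltage
  duration: 150        # s
  dt: 0.5              # s
  T0: 279.15           # K
  snapshot_interval: 50 # s
thermal_bc:
  U: 5                 # W m^-2 K^-1, overall heat transfer coefficient
  T_inf: 286.15        # K
kinetics:
  z: 10                # K
  D_ref: 60            # s
  T_ref: 333.15        # K (60 C)
  target_log_reduction: 12
property_table: mashed_potato_properties.csv
scenarios: builtin
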