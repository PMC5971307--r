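{
  "dims": {"inner_short": 30, "inner_long": 65, "wall_thickness": 9},
  "mesh": {"n_circ": 16, "n_long": 8, "n_layers": 7, "target_volume_ml": 122},
  "material": {"a1": 0.347, "a2": 13.438, "a3": 48.846, "b1": 0.436, "b2": 27.692, "rate_factor": 6},
  "active": {"E0": 200, "fibre_volume_fraction": 0.8},
  "scenario": {"name": "control"},
  "solver": {"dt": 1},
  "p_ed": 1.3,
  "p_ao": 10.7
}
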