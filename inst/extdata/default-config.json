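{
  "workflow": "conditioning",
  "rng_seed": 1,
  "optics": {
    "objective_na": 1.0,
    "back_aperture_diameter": 14.4,
    "beam_width_1e2": 7.2,
    "immersion_index": 1.33,
    "window_aperture_radius": 0.75,
    "focal_depth": 1.2,
    "average_power": 180,
    "repetition_rate": 80,
    "wavelength": 1100
  },
  "qc": {
    "fraction": 0.001,
    "r_min": 6,
    "r_max": 12,
    "sensitivity": 0.5
  },
  "session": {
    "n_neurons": 100,
    "n_trials": 30,
    "inter_delivery_interval": 20,
    "frame_rate": 30,
    "fraction_prereward_tuned": 0.3
  },
  "conditioning": {
    "block": 3,
    "half_window": 30,
    "percentile": 8,
    "window": [-10, 10],
    "response_window": 2,
    "ridge_frames": 12,
    "bin": 0.5,
    "n_subsample": 50,
    "n_reps": 1000,
    "n_perm": 10000
  }
}
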