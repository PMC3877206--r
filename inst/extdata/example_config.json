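{
  "mode": "synthetic",
  "base_spec": {
    "field_width_um": 512,
    "field_height_um": 512,
    "n_stems": 13,
    "seed": 1
  },
  "groups": {
    "t0":  { "n_scenes": 6,
             "overrides": { "perfused_fraction": 0.5,
                            "covered_fraction": 0.0 } },
    "t14": { "n_scenes": 6,
             "overrides": { "perfused_fraction": 0.95,
                            "covered_fraction": 0.6 } }
  },
  "seg": { "default": { "background_radius_um": 50, "ratio_k": 2,
                        "min_object_area_um2": 10 } },
  "negcontrol": "auto",
  "tt_dilation_um": 10,
  "pvs_shell_um": 5,
  "gap_um": 5,
  "hypoxic_cutoff_um": 100,
  "coverage_threshold": 0.10,
  "seed": 42
}
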