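{
  "mode": "fixtures",
  "out_dir": "fixtures",
  "seed": 7,
  "log_level": "info",
  "scenes": [
    { "scene_kind": "spread", "n_ecdna": 20, "frac_untethered": 0.3, "frac_surrounded": 0.1 },
    { "scene_kind": "metaphase", "frac_fish_untethered": 0.2 },
    { "scene_kind": "daughter_pair", "n_micronuclei": 2, "myc_in_mn_frac": 0.1 },
    { "scene_kind": "foci", "n_foci": 5, "n_speckles": 5, "image_shape": [96, 96] }
  ],
  "seg": { "n_otsu_classes": 3, "n_hist_bins": 256, "connectivity": 8 },
  "tether": { "untethered_max_frac": 0.25, "surrounded_frac": 1.0 }
}
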