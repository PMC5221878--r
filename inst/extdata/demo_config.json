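{
  "seed": 7,
  "out_dir": "ctrecur-demo",
  "n_patients": 60,
  "n_phantoms": 3,
  "segmentation": { "half_width": 350, "dice_tolerance": 0.8 },
  "entropy": { "bin_width": 1, "base": 2 },
  "stepwise": { "p_enter": 0.05, "p_remove": 0.10 }
}
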