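{
  "comment": "Fixed cluster geometry and gate polygons for synthetic cytometry data (all values synthetic; FSC/SSC in instrument a.u., FL4 in ERF).",
  "clusters": {
    "noise":   {"center": [120, 90],    "spread": [40, 30]},
    "singlet": {"center": [1000, 800],  "spread": [80, 70]},
    "doublet": {"center": [1750, 1400], "spread": [110, 100]}
  },
  "fl4": {
    "singlet_mean": 180,
    "singlet_sd": 25,
    "noise_mean": 2,
    "noise_sd": 1,
    "family": "truncated-normal"
  },
  "counts": {"n_noise": 300, "n_singlet": 2000, "n_doublet": 200},
  "gates": {
    "G1": [[550, 350], [2350, 350], [2350, 1950], [550, 1950]],
    "G2": [[1400, 1060], [2350, 1060], [2350, 1950], [1400, 1950]]
  }
}
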